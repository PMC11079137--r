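## Goldman-Yang (GY94) codon rate matrix and transition probabilities.
##
## Q[i,j] = pi_j * kappa^[transition] * omega^[nonsynonymous] for codon pairs
## differing at exactly one position, 0 otherwise; the matrix is normalized so
## the expected number of substitutions per codon per unit time at
## stationarity is 1 (branch lengths are therefore in substitutions/codon,
## the CodeML convention).

#' Build a normalized GY94 instantaneous rate matrix
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi a \code{\linkS4class{CodonFrequencies}} or bare 61-vector.
#' @return 61 x 61 rate matrix with zero row sums, satisfying detailed
#'   balance \code{pi_i q_ij = pi_j q_ji} and \code{-sum(pi * diag) = 1}.
#' @export
buildRateMatrix <- function(kappa, omega, pi) {
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.numeric(omega) || omega < 0) stop("omega must be >= 0")
  p <- if (is(pi, "CodonFrequencies")) pi@pi else pi
  stopifnot(length(p) == 61L)
  tab <- codonTable()
  ty <- tab$pairType
  mult <- matrix(0, 61L, 61L)
  mult[ty == 1L] <- 1
  mult[ty == 2L] <- kappa
  mult[ty == 3L] <- omega
  mult[ty == 4L] <- kappa * omega
  Q <- mult * rep(p, each = 61L)   # Q[i,j] gets pi[j]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(p * diag(Q))
  if (!is.finite(scale) || scale <= 1e-12)
    stop("degenerate codon frequencies: rate normalization undefined")
  Q / scale
}

## Symmetrized eigendecomposition of a reversible Q (pi floored to keep the
## similarity transform well-defined when some codons are unobserved).
## P(t) = (A * exp(lambda t)[col]) %*% B with A = U / sqrt(pi)[row],
## B = t(U * sqrt(pi)[row]).
.decomposeQ <- function(Q, pi) {
  p <- pmax(pi, 1e-12)
  s <- sqrt(p)
  B <- Q * (s %o% (1 / s))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(A = e$vectors / s, B = t(e$vectors * s), lambda = e$values)
}

## substitution rate of the unnormalized GY94 generator at stationarity:
## -sum_i pi_i q_ii before scaling. Site-class mixtures share one per-edge
## scale factor (the proportion-weighted mean of these rates), so classes
## with larger omega evolve genuinely faster.
.rawRate <- function(kappa, omega, p) {
  cache <- .hypoxsel_cache
  if (is.null(cache$rawRate)) cache$rawRate <- new.env(parent = emptyenv())
  key <- sprintf("%.17g|%.17g|%.17g|%.17g", kappa, omega,
                 sum(p * seq_len(61L)), sum(p * p))
  r <- cache$rawRate[[key]]
  if (is.null(r)) {
    tab <- codonTable()
    ty <- tab$pairType
    mult <- matrix(0, 61L, 61L)
    mult[ty == 1L] <- 1
    mult[ty == 2L] <- kappa
    mult[ty == 3L] <- omega
    mult[ty == 4L] <- kappa * omega
    Qoff <- mult * rep(p, each = 61L)
    r <- sum(p * rowSums(Qoff))
    cache$rawRate[[key]] <- r
  }
  r
}

## memoized decomposition: during branch-length optimization the same
## (kappa, omega, pi) recurs for every evaluation
.getDecomp <- function(kappa, omega, p) {
  cache <- .hypoxsel_cache
  if (is.null(cache$decomp)) cache$decomp <- new.env(parent = emptyenv())
  ## %.17g round-trips doubles exactly: distinct parameters never share a key
  key <- sprintf("%.17g|%.17g|%.17g|%.17g", kappa, omega,
                 sum(p * seq_len(61L)), sum(p * p))
  d <- cache$decomp[[key]]
  if (is.null(d)) {
    if (length(ls(cache$decomp)) > 400L)
      cache$decomp <- new.env(parent = emptyenv())
    d <- .decomposeQ(buildRateMatrix(kappa, omega, p), p)
    cache$decomp[[key]] <- d
  }
  d
}

.edgeP <- function(dec, t) {
  P <- (dec$A * rep(exp(dec$lambda * t), each = 61L)) %*% dec$B
  P[P < 0] <- 0
  P
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by symmetrized eigendecomposition (the model is reversible);
#' negative round-off entries are clipped to 0.
#'
#' @param Q rate matrix from \code{\link{buildRateMatrix}}.
#' @param t branch length (expected substitutions per codon, >= 0).
#' @param pi the stationary codon frequencies used to build \code{Q}.
#' @return 61 x 61 probability matrix (rows sum to 1 within 1e-10).
#' @export
transitionProbabilities <- function(Q, t, pi) {
  if (t < 0) stop("branch length must be >= 0")
  p <- if (is(pi, "CodonFrequencies")) pi@pi else pi
  .edgeP(.decomposeQ(Q, p), t)
}
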