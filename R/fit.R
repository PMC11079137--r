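## Maximum-likelihood fitting of the omega models: alternating bounded
## quasi-Newton optimization of (kappa + omega/class parameters) and of all
## branch lengths (the latter with analytic gradients from the
## inside/outside passes).

#' Optimizer options for model fitting
#'
#' @param maxRounds maximum alternation rounds between the model-parameter
#'   step and the branch-length step.
#' @param tol stop when a full round improves lnL by less than this.
#' @param restarts number of starting points for the model-parameter step in
#'   the first round (1 default + perturbed, seeded).
#' @param seed integer seed for the restart perturbations.
#' @param branchLengths \code{"estimate"} (joint ML, default), \code{"fixed"}
#'   (keep the input tree's lengths), or \code{"m0"} (fix at the lengths of a
#'   supplied M0 fit, a standard pipeline shortcut for site models).
#' @param m0Fit a \code{FitResult} supplying branch lengths when
#'   \code{branchLengths = "m0"}.
#' @param parMaxIter,blMaxIter L-BFGS-B iteration caps for the two steps.
#' @param fixKappa optional numeric: hold kappa fixed at this value (e.g.
#'   the M0 estimate, a standard shortcut for site-model screens) instead
#'   of estimating it.
#' @param factr L-BFGS-B relative-precision control for the
#'   model-parameter step (its \code{factr}; larger is coarser/faster).
#' @return list of options for \code{\link{fitModel}}.
#' @export
fitOptions <- function(maxRounds = 8L, tol = 1e-4, restarts = 3L, seed = NULL,
                       branchLengths = c("estimate", "fixed", "m0"),
                       m0Fit = NULL, parMaxIter = 100L, blMaxIter = 40L,
                       fixKappa = NULL, factr = 1e7) {
  list(maxRounds = maxRounds, tol = tol, restarts = restarts, seed = seed,
       branchLengths = match.arg(branchLengths), m0Fit = m0Fit,
       parMaxIter = parMaxIter, blMaxIter = blMaxIter, fixKappa = fixKappa,
       factr = factr)
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Fit an omega model by maximum likelihood
#'
#' Joint ML over branch lengths, kappa and the model's omega structure.
#' Branch lengths are optimized with analytic gradients; model parameters
#' with bounded quasi-Newton from multiple (seeded) restarts. Omega slots are
#' bounded to [1e-6, 999].
#'
#' @param aln a \code{CodonAlignment}.
#' @param tree a \code{LabeledTree}; its branch lengths serve as starting
#'   values.
#' @param spec a \code{\link{modelSpec}}.
#' @param options see \code{\link{fitOptions}}.
#' @param pi codon frequencies (default F3x4 from the alignment).
#' @param start optional named numeric of starting values for (some of) the
#'   model parameters, e.g. warm starts from a nested fit.
#' @return A \code{\linkS4class{FitResult}}. Boundary estimates (an omega
#'   slot at 0 or at the cap, vanishing branch lengths) are flagged in
#'   \code{diagnostics$boundary}; non-convergence is flagged (with a warning),
#'   never silently returned.
#' @export
fitModel <- function(aln, tree, spec, options = fitOptions(),
                     pi = codonFrequencies(aln), start = NULL) {
  stopifnot(is(spec, "ModelSpec"))
  eng <- .engine(aln, tree)
  p <- pi@pi
  tmpl <- .paramTemplate(spec, tree)
  fixK <- options$fixKappa
  if (!is.null(fixK)) {
    stopifnot(identical(tmpl$names[1L], "kappa"))
    tmpl$names <- tmpl$names[-1L]
    tmpl$start <- tmpl$start[-1L]
    tmpl$lower <- tmpl$lower[-1L]
    tmpl$upper <- tmpl$upper[-1L]
  }
  mkParams <- function(x) {
    prm <- stats::setNames(x, tmpl$names)
    if (!is.null(fixK)) prm <- c(kappa = fixK, prm)
    prm
  }
  nE <- eng$ti$nEdge
  blen <- switch(options$branchLengths,
    m0 = {
      if (is.null(options$m0Fit))
        stop("branchLengths = 'm0' needs options$m0Fit")
      options$m0Fit@branchLengths
    },
    tree@phylo$edge.length)
  blen <- pmax(blen, 1e-6)
  estimateBL <- options$branchLengths == "estimate"
  ## with fixed branch lengths, per-class pattern likelihoods are reusable
  ## across objective evaluations (only some classes move per parameter)
  patCache <- if (!estimateBL) new.env(parent = emptyenv()) else NULL
  evals <- 0L
  messages <- character(0)

  negllPar <- function(x, bl) {
    evals <<- evals + 1L
    x <- pmin(pmax(x, tmpl$lower), tmpl$upper)
    prm <- mkParams(x)
    cl <- .buildClasses(spec, prm, tree)
    out <- tryCatch(
      -.classLogLik(eng, prm[["kappa"]], p, bl, cl,
                    patCache = patCache)$lnL,
      error = function(e) NA_real_)
    if (!is.finite(out)) 1e10 else out
  }

  parStep <- function(par0, bl, maxit = options$parMaxIter) {
    stats::optim(par0, negllPar, bl = bl, method = "L-BFGS-B",
                 lower = tmpl$lower, upper = tmpl$upper,
                 control = list(maxit = maxit, factr = options$factr,
                                parscale = pmax(abs(par0), 0.1)))
  }

  blStep <- function(par, bl0) {
    prm <- mkParams(par)
    cl <- .buildClasses(spec, prm, tree)
    cacheX <- NULL; cacheRes <- NULL
    evalAt <- function(x) {
      if (!identical(x, cacheX)) {
        evals <<- evals + 1L
        cacheRes <<- .classLogLik(eng, prm[["kappa"]], p, x, cl,
                                  wantGrad = TRUE)
        cacheX <<- x
      }
      cacheRes
    }
    fn <- function(x) {
      out <- tryCatch(-evalAt(x)$lnL, error = function(e) NA_real_)
      if (!is.finite(out)) 1e10 else out
    }
    gr <- function(x) {
      g <- tryCatch(-evalAt(x)$grad, error = function(e) rep(0, length(x)))
      g[!is.finite(g)] <- 0
      g
    }
    stats::optim(bl0, fn, gr, method = "L-BFGS-B",
                 lower = 1e-8, upper = 50,
                 control = list(maxit = options$blMaxIter))
  }

  ## first round: multi-start on the model parameters
  s0 <- tmpl$start
  if (!is.null(start)) {
    hit <- intersect(names(start), tmpl$names)
    s0[match(hit, tmpl$names)] <- start[hit]
    s0 <- pmin(pmax(s0, tmpl$lower), tmpl$upper)
  }
  starts <- list(s0)
  if (options$restarts > 1L) {
    pert <- .withSeed(options$seed, lapply(seq_len(options$restarts - 1L),
      function(i) {
        x <- tmpl$start * exp(stats::runif(length(tmpl$start), -0.7, 0.7))
        pmin(pmax(x, tmpl$lower), tmpl$upper)
      }))
    starts <- c(starts, pert)
  }
  best <- NULL
  for (s in starts) {
    o <- parStep(s, blen, maxit = min(options$parMaxIter, 50L))
    if (is.null(best) || o$value < best$value) best <- o
  }
  par <- best$par
  lnL <- -best$value
  parConv <- best$convergence == 0L
  blConv <- TRUE
  rounds <- 1L
  improved <- Inf
  while (rounds < options$maxRounds && improved > options$tol) {
    lnLprev <- lnL
    if (estimateBL) {
      ob <- blStep(par, blen)
      blen <- ob$par
      blConv <- ob$convergence == 0L
      if (!is.null(ob$message)) messages <- c(messages, ob$message)
    }
    op <- parStep(par, blen)
    par <- op$par
    parConv <- op$convergence == 0L
    lnL <- -op$value
    improved <- lnL - lnLprev
    rounds <- rounds + 1L
    if (!estimateBL && improved <= options$tol) break
  }
  ## convergence = the alternation stabilized (final round gained <= tol);
  ## an L-BFGS-B maxit code on the last polish with a sub-tol gain is not a
  ## failure, but is recorded in the diagnostics
  converged <- improved <= options$tol
  if (!parConv || !blConv)
    messages <- c(messages, "L-BFGS-B stopped at its iteration cap")
  if (!converged)
    warning("fitModel: optimizer did not converge for ", spec@label,
            " (last round improvement ", signif(improved, 3), ")")

  parClamped <- pmin(pmax(par, tmpl$lower), tmpl$upper)
  prm <- mkParams(parClamped)
  cl <- .buildClasses(spec, prm, tree)
  final <- .classLogLik(eng, prm[["kappa"]], p, blen, cl)
  rep_ <- .reportEstimates(spec, prm, tree)

  boundary <- character(0)
  hitLo <- tmpl$names[parClamped <= tmpl$lower * 1.01 + 1e-12]
  hitHi <- tmpl$names[parClamped >= tmpl$upper * 0.999]
  if (length(hitLo)) boundary <- c(boundary, paste0(hitLo, ":lower"))
  if (length(hitHi)) boundary <- c(boundary, paste0(hitHi, ":upper"))
  if (estimateBL && all(blen <= 2e-8))
    boundary <- c(boundary, "branch_lengths:zero")

  new("FitResult", spec = spec, lnL = final$lnL,
      np = .modelNp(spec, tree) - as.integer(!is.null(fixK)),
      kappa = unname(prm[["kappa"]]),
      omega = rep_$omega, classParams = rep_$classParams,
      branchLengths = blen, pi = pi,
      perSiteLnL = final$logLpat[eng$patOfSite],
      diagnostics = list(rounds = rounds, evals = evals,
                         converged = converged, boundary = boundary,
                         seed = options$seed, messages = messages))
}

#' @describeIn fitModel convenience wrapper for the one-ratio (M0) model.
#' @export
fitM0 <- function(aln, tree, options = fitOptions(),
                  pi = codonFrequencies(aln)) {
  fitModel(aln, tree, modelSpec("one_ratio", label = "1ω"), options, pi)
}

## ---- accessors -------------------------------------------------------------

#' Log-likelihood of a fit
#' @param fit a \code{FitResult}.
#' @export
logLik_fit <- function(fit) fit@lnL

#' Omega estimates of a fit (named by slot)
#' @param fit a \code{FitResult}.
#' @export
omegaEstimates <- function(fit) fit@omega

#' Number of free parameters of a fit
#' @param fit a \code{FitResult}.
#' @export
nParams <- function(fit) fit@np
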