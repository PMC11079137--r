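## Marginal ancestral sequence reconstruction under a fitted model, via the
## standard inside/outside (two-pass) computation: the posterior of node v is
## proportional to (inside partial at v) * (outside message into v).

#' Marginal ancestral reconstruction
#'
#' Reconstructs per-node, per-site posteriors over ancestral states under a
#' converged fit (the study design uses the M0 fit). Two modes: codon-level
#' reconstruction collapsed to amino acids by summation before taking the
#' MAP state (default), or reconstruction directly under an amino-acid chain
#' (an F81-style model on the 20 amino acids with empirical frequencies).
#' The mode is recorded in the result.
#'
#' @param aln a \code{CodonAlignment}.
#' @param tree a \code{LabeledTree}.
#' @param fit a converged \code{FitResult} with a single-class omega
#'   structure (one_ratio / multi_ratio / free_ratio) for codon mode.
#' @param mode "codon" or "aa".
#' @return An \code{\linkS4class{AncestralReconstruction}}; codon mode also
#'   stores the per-internal-node codon posteriors (used by
#'   \code{\link{expectedPairCount}}).
#' @export
reconstructAncestors <- function(aln, tree, fit, mode = c("codon", "aa")) {
  mode <- match.arg(mode)
  if (!isTRUE(fit@diagnostics$converged))
    stop("refusing to reconstruct ancestors from an unconverged fit")
  tab <- codonTable(aln@geneticCode)
  naa <- length(tab$aaLevels)
  aaM <- matrix(match(tab$aa[codonStates(aln)], tab$aaLevels),
                nrow(codonStates(aln)), ncol(codonStates(aln)),
                dimnames = dimnames(codonStates(aln)))

  if (mode == "codon") {
    if (!fit@spec@kind %in% c("one_ratio", "multi_ratio", "free_ratio"))
      stop("codon-level reconstruction expects a branch-model fit (M0-style)")
    eng <- .engine(aln, tree)
    p <- fit@pi@pi
    omegaEdge <- .fitOmegaEdge(fit, tree)
    res <- .classLogLik(eng, fit@kappa, p, fit@branchLengths,
                        list(list(prop = 1, omegaEdge = omegaEdge)),
                        keep = TRUE)
    down <- res$downs[[1L]]
    out <- .peelOutside(eng, res$Plists[[1L]], NULL, down, p, wantU = TRUE)
    codonPost <- .nodePosteriors(eng, down, out)
    A <- .aaIndicator(tab)
    aaPost <- lapply(codonPost, function(m) crossprod(A, m))
  } else {
    piAA <- tabulate(aaM[!is.na(aaM)], naa)
    piAA <- pmax(piAA, 0.5) / sum(pmax(piAA, 0.5))
    eng <- .engineFromStates(aaM, tree, naa)
    beta <- 1 / (1 - sum(piAA^2))
    Plist <- lapply(tree@phylo$edge.length, function(t) {
      e <- exp(-beta * t)
      e * diag(naa) + (1 - e) * matrix(piAA, naa, naa, byrow = TRUE)
    })
    down <- .peel(eng, Plist, piAA, keep = TRUE)
    out <- .peelOutside(eng, Plist, NULL, down, piAA, wantU = TRUE)
    aaPost <- .nodePosteriors(eng, down, out)
    codonPost <- NULL
  }

  eng0 <- if (mode == "codon") eng else eng
  ti <- eng0$ti
  nsite <- eng0$nsite
  nn <- ti$nnodeTotal
  mapM <- matrix(NA_integer_, nn, nsite)
  maxPP <- matrix(NA_real_, nn, nsite)
  mapM[seq_len(ti$ntip), ] <- aaM[ti$tipLabel, , drop = FALSE]
  maxPP[seq_len(ti$ntip), ][!is.na(mapM[seq_len(ti$ntip), ])] <- 1
  for (v in names(aaPost)) {
    vi <- as.integer(v)
    pm <- aaPost[[v]][, eng0$patOfSite, drop = FALSE]
    mapM[vi, ] <- apply(pm, 2L, which.max)
    maxPP[vi, ] <- pm[cbind(mapM[vi, ], seq_len(nsite))]
  }
  rec <- new("AncestralReconstruction", mode = mode,
             aaPosterior = lapply(aaPost, function(m)
               m[, eng0$patOfSite, drop = FALSE]),
             map = mapM, maxPP = maxPP, tree = tree,
             aaLevels = tab$aaLevels)
  if (!is.null(codonPost))
    attr(rec, "codonPosterior") <- lapply(codonPost, function(m)
      m[, eng0$patOfSite, drop = FALSE])
  attr(rec, "fit") <- fit
  rec
}

## posterior over states at every internal node: inside * outside, normalized
.nodePosteriors <- function(eng, down, out) {
  ti <- eng$ti
  internal <- setdiff(seq_len(ti$nnodeTotal), seq_len(ti$ntip))
  res <- lapply(internal, function(v) {
    m <- down$partial[[v]] * out$U[[v]]
    sweep(m, 2L, colSums(m), "/")
  })
  names(res) <- as.character(internal)
  res
}

## 61 x 20 indicator: codon -> amino acid
.aaIndicator <- function(tab = codonTable()) {
  A <- matrix(0, 61L, length(tab$aaLevels))
  A[cbind(seq_len(61L), tab$aaIndex)] <- 1
  A
}

## per-edge omega vector implied by a single-class fit
.fitOmegaEdge <- function(fit, tree) {
  switch(fit@spec@kind,
    one_ratio = rep(unname(fit@omega[["omega"]]), nrow(tree@phylo$edge)),
    multi_ratio = {
      slotOfEdge <- unname(fit@spec@slotMap[branchCategories(tree)])
      unname(fit@omega[slotOfEdge])
    },
    free_ratio = unname(fit@omega),
    stop("no single per-edge omega for fit kind ", fit@spec@kind))
}

#' Amino-acid substitutions inferred on a branch
#'
#' A substitution is called at site s when the MAP amino acid at the parent
#' node differs from the MAP state at the child (observed states for leaves).
#' Events where either endpoint's posterior falls below \code{minPP} are
#' flagged \code{lowConfidence}, not dropped.
#'
#' @param recon an \code{AncestralReconstruction}.
#' @param branch focal branch name, tip label, or child node id.
#' @param minPP confidence threshold for the flag (default 0.7).
#' @return data.frame: branch, site, fromAA, toAA, ppFrom, ppTo,
#'   lowConfidence.
#' @export
branchSubstitutions <- function(recon, branch, minPP = 0.7) {
  tree <- recon@tree
  node <- .resolveBranch(tree, branch)
  edge <- tree@phylo$edge
  eidx <- match(node, edge[, 2L])
  if (is.na(eidx)) stop("no branch has child node ", node)
  par <- edge[eidx, 1L]
  fromI <- recon@map[par, ]
  toI <- recon@map[node, ]
  hit <- which(!is.na(fromI) & !is.na(toI) & fromI != toI)
  lab <- if (is.character(branch)) branch else branchLabel(tree, node)
  data.frame(branch = rep(lab, length(hit)), site = hit,
             fromAA = recon@aaLevels[fromI[hit]],
             toAA = recon@aaLevels[toI[hit]],
             ppFrom = recon@maxPP[par, hit], ppTo = recon@maxPP[node, hit],
             lowConfidence = recon@maxPP[par, hit] < minPP |
                             recon@maxPP[node, hit] < minPP,
             row.names = NULL)
}
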