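## Parallel/convergent amino-acid substitution analysis between focal branch
## pairs: classification of shared derived states, model-based expected
## counts, and the observed-vs-expected Poisson test.

#' Classify shared substitutions of a branch pair
#'
#' A site with a substitution on both branches to the same derived amino
#' acid is parallel when the two ancestral states are equal and convergent
#' when they differ; everything else is excluded.
#'
#' @param eventsA,eventsB outputs of \code{\link{branchSubstitutions}} for
#'   the two branches.
#' @param tree optional \code{LabeledTree}; with \code{branchA}/\code{branchB}
#'   given, validates that neither branch is ancestral to the other (the
#'   comparison is undefined in that case).
#' @param branchA,branchB branch identifiers for validation.
#' @return list with data.frames \code{parallel} and \code{convergent}
#'   (site, fromA, fromB, toAA, aaChange); \code{aaChange} is
#'   \code{"A-G"}-style for parallel and \code{"T/N-S"}-style for convergent
#'   sites.
#' @export
classifyPair <- function(eventsA, eventsB, tree = NULL, branchA = NULL,
                         branchB = NULL) {
  if (!is.null(tree) && !is.null(branchA) && !is.null(branchB)) {
    na <- .resolveBranch(tree, branchA)
    nb <- .resolveBranch(tree, branchB)
    if (na == nb) stop("branch pair must consist of two distinct branches")
    if (.isAncestorPair(tree@phylo, na, nb))
      stop("branches are in an ancestor-descendant relation; ",
           "parallel/convergent comparison is undefined")
  }
  m <- merge(eventsA[c("site", "fromAA", "toAA")],
             eventsB[c("site", "fromAA", "toAA")],
             by = "site", suffixes = c("A", "B"))
  m <- m[m$toAAA == m$toAAB, , drop = FALSE]
  mk <- function(d, parallel) {
    if (!nrow(d)) return(data.frame(site = integer(0), fromA = character(0),
                                    fromB = character(0), toAA = character(0),
                                    aaChange = character(0)))
    data.frame(site = d$site, fromA = d$fromAAA, fromB = d$fromAAB,
               toAA = d$toAAA,
               aaChange = if (parallel) paste0(d$fromAAA, "-", d$toAAA)
                 else paste0(d$fromAAA, "/", d$fromAAB, "-", d$toAAA),
               row.names = NULL)
  }
  list(parallel = mk(m[m$fromAAA == m$fromAAB, , drop = FALSE], TRUE),
       convergent = mk(m[m$fromAAA != m$fromAAB, , drop = FALSE], FALSE))
}

#' Expected numbers of parallel and convergent substitutions for a pair
#'
#' Per site, the probability that both branches independently realize an
#' amino-acid change to a common derived state is computed from the
#' reconstructed posterior of each branch's parent node and the amino-acid
#' substitution process induced by the fitted codon model on that branch
#' (codon transition matrix collapsed through the genetic code); summing
#' over sites gives the expected counts under independent evolution.
#'
#' @param recon a codon-mode \code{\link{reconstructAncestors}} result.
#' @param fit the single-class (M0-style) fit behind \code{recon}.
#' @param branchA,branchB branch identifiers (focal names, tip labels or
#'   child node ids).
#' @param model \code{"collapsed"} (default: amino-acid process induced by
#'   the codon model) or \code{"flat"} (same per-site change probability,
#'   derived state uniform over the 19 alternatives).
#' @return list(parallel, convergent, total) of expected counts.
#' @export
expectedPairCount <- function(recon, fit, branchA, branchB,
                              model = c("collapsed", "flat")) {
  model <- match.arg(model)
  tree <- recon@tree
  codonPost <- attr(recon, "codonPosterior")
  if (is.null(codonPost))
    stop("expected counts need a codon-mode reconstruction")
  na <- .resolveBranch(tree, branchA)
  nb <- .resolveBranch(tree, branchB)
  if (na == nb) stop("branch pair must consist of two distinct branches")
  if (.isAncestorPair(tree@phylo, na, nb))
    stop("branches are in an ancestor-descendant relation")
  J <- lapply(c(na, nb), function(nd) .branchAAJoint(recon, fit, nd, model))
  nsite <- dim(J[[1L]])[3L]
  par_s <- conv_s <- numeric(nsite)
  for (s in seq_len(nsite)) {
    J1 <- J[[1L]][, , s]; J2 <- J[[2L]][, , s]
    diag(J1) <- 0; diag(J2) <- 0
    par_s[s] <- sum(J1 * J2)
    conv_s[s] <- sum(colSums(J1) * colSums(J2)) - par_s[s]
  }
  list(parallel = sum(par_s), convergent = sum(conv_s),
       total = sum(par_s) + sum(conv_s))
}

## 20 x 20 x nsite joint distribution of (parent AA, child AA) on a branch
.branchAAJoint <- function(recon, fit, node, model) {
  tree <- recon@tree
  edge <- tree@phylo$edge
  eidx <- match(node, edge[, 2L])
  par <- edge[eidx, 1L]
  q <- attr(recon, "codonPosterior")[[as.character(par)]]  # 61 x nsite
  if (is.null(q)) stop("no codon posterior stored for node ", par)
  p <- fit@pi@pi
  omegaEdge <- .fitOmegaEdge(fit, tree)
  Q <- buildRateMatrix(fit@kappa, omegaEdge[eidx], p)
  P <- transitionProbabilities(Q, fit@branchLengths[eidx], p)
  A <- .aaIndicator()
  R <- P %*% A                                   # 61 x 20
  naa <- ncol(A)
  nsite <- ncol(q)
  J <- array(0, c(naa, naa, nsite))
  for (s in seq_len(nsite))
    J[, , s] <- crossprod(A, q[, s] * R)
  if (model == "flat") {
    ## same per-site change probability, but ancestral state from the parent
    ## posterior and derived state uniform over the 19 alternatives
    for (s in seq_len(nsite)) {
      Js <- J[, , s]
      qaa <- rowSums(Js)
      chg <- sum(Js) - sum(diag(Js))
      flat <- matrix(qaa * chg / (naa - 1), naa, naa)
      diag(flat) <- qaa * (1 - chg)
      J[, , s] <- flat
    }
  }
  J
}

#' Poisson test of observed vs expected parallel/convergent counts
#'
#' Upper-tail Poisson probability P(X >= observed) with mean equal to the
#' model-based expected count. By convention observed = 0 gives p = 1, and
#' expected = 0 with observed > 0 gives p = 0.
#'
#' @param observed nonnegative integer count.
#' @param expected nonnegative expected count (Poisson mean).
#' @return the p-value.
#' @export
convergenceTest <- function(observed, expected) {
  if (observed < 0 || expected < 0) stop("counts must be nonnegative")
  if (observed == 0) return(1)
  if (expected == 0) return(0)
  stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
}

#' Scan all focal branch pairs for parallel/convergent substitutions
#'
#' For each gene alignment and each unordered pair of focal branches:
#' reconstruct ancestors under the gene's M0 fit, call per-branch
#' substitutions, classify shared derived states, compute expected counts
#' and the Poisson p-value. Output mirrors the study's report shape: a site
#' table (Branches, Genes, Sites, AA change) and a pair table with observed,
#' expected and p-value totalled over genes; pairs with zero observed events
#' are omitted (set \code{includeEmpty = TRUE} to keep them).
#'
#' @param alns named list of \code{CodonAlignment}s (one per gene).
#' @param tree a \code{LabeledTree} with focal branches.
#' @param fits optional named list of M0 \code{FitResult}s per gene (fitted
#'   here when missing).
#' @param pairs optional character matrix/data.frame of branch-name pairs;
#'   default: all unordered focal pairs not in an ancestor-descendant
#'   relation (explicitly supplied ancestor-descendant pairs are an error).
#' @param minPP confidence threshold forwarded to
#'   \code{\link{branchSubstitutions}}.
#' @param expectedModel forwarded to \code{\link{expectedPairCount}}.
#' @param includeEmpty keep pairs with zero observed events.
#' @param options \code{\link{fitOptions}} for any M0 fits performed here.
#' @return list(sites, pairs) of data.frames.
#' @export
runConvergenceScan <- function(alns, tree, fits = NULL, pairs = NULL,
                               minPP = 0.7, expectedModel = "collapsed",
                               includeEmpty = FALSE,
                               options = fitOptions()) {
  foc <- focalBranches(tree)
  if (length(foc) < 2L) stop("need at least two focal branches")
  if (is.null(pairs)) {
    cmb <- utils::combn(names(foc), 2L)
    keep <- !apply(cmb, 2L, function(pr)
      .isAncestorPair(tree@phylo, foc[[pr[1L]]], foc[[pr[2L]]]))
    pairs <- t(cmb[, keep, drop = FALSE])
  } else {
    pairs <- as.matrix(pairs)
    for (r in seq_len(nrow(pairs)))
      if (.isAncestorPair(tree@phylo, .resolveBranch(tree, pairs[r, 1L]),
                          .resolveBranch(tree, pairs[r, 2L])))
        stop("configured pair ", pairs[r, 1L], " vs ", pairs[r, 2L],
             " is an ancestor-descendant pair")
  }
  geneNames <- names(alns)
  if (is.null(geneNames)) geneNames <- paste0("gene", seq_along(alns))
  siteRows <- list()
  pairObs <- matrix(0, nrow(pairs), 2L,
                    dimnames = list(NULL, c("parallel", "convergent")))
  pairExp <- matrix(0, nrow(pairs), 2L,
                    dimnames = list(NULL, c("parallel", "convergent")))
  for (gi in seq_along(alns)) {
    aln <- alns[[gi]]
    fit <- if (!is.null(fits)) fits[[geneNames[gi]]] else NULL
    if (is.null(fit)) fit <- fitM0(aln, tree, options)
    recon <- reconstructAncestors(aln, tree, fit, mode = "codon")
    ev <- lapply(names(foc), function(b)
      branchSubstitutions(recon, b, minPP = minPP))
    names(ev) <- names(foc)
    for (r in seq_len(nrow(pairs))) {
      b1 <- pairs[r, 1L]; b2 <- pairs[r, 2L]
      cls <- classifyPair(ev[[b1]], ev[[b2]], tree, b1, b2)
      ex <- expectedPairCount(recon, fit, b1, b2, model = expectedModel)
      pairExp[r, ] <- pairExp[r, ] + c(ex$parallel, ex$convergent)
      for (type in c("parallel", "convergent")) {
        d <- cls[[type]]
        if (!nrow(d)) next
        pairObs[r, type] <- pairObs[r, type] + nrow(d)
        siteRows[[length(siteRows) + 1L]] <- data.frame(
          Branches = paste(b1, "vs.", b2), Genes = geneNames[gi],
          Sites = d$site, AA_change = d$aaChange, type = type,
          row.names = NULL)
      }
    }
  }
  sites <- if (length(siteRows)) do.call(rbind, siteRows)
    else data.frame(Branches = character(0), Genes = character(0),
                    Sites = integer(0), AA_change = character(0),
                    type = character(0))
  pairTab <- data.frame(
    Branches = paste(pairs[, 1L], "vs.", pairs[, 2L]),
    observedParallel = pairObs[, "parallel"],
    observedConvergent = pairObs[, "convergent"],
    Observed = rowSums(pairObs),
    expectedParallel = pairExp[, "parallel"],
    expectedConvergent = pairExp[, "convergent"],
    Expected = rowSums(pairExp), row.names = NULL)
  pairTab$p_value <- mapply(convergenceTest, pairTab$Observed,
                            pairTab$Expected)
  if (!includeEmpty) {
    keepPair <- pairTab$Observed > 0
    sites <- sites[sites$Branches %in% pairTab$Branches[keepPair], ,
                   drop = FALSE]
    pairTab <- pairTab[keepPair, , drop = FALSE]
  }
  rownames(sites) <- rownames(pairTab) <- NULL
  list(sites = sites, pairs = pairTab)
}

#' Totals of a parallel/convergent site table
#'
#' Counts parallel sites (AA change of the form \code{"A-G"}), convergent
#' sites (\code{"T/N-S"}, i.e. containing "/") and the combined total from a
#' site table as produced by \code{\link{runConvergenceScan}} (or a
#' transcription of a published table with an \code{AA_change} column).
#'
#' @param sites data.frame with column \code{AA_change}.
#' @return list(parallel, convergent, combined).
#' @export
summarizeObservedCounts <- function(sites) {
  if (!"AA_change" %in% names(sites))
    stop("site table needs an AA_change column")
  conv <- grepl("/", sites$AA_change, fixed = TRUE)
  list(parallel = sum(!conv), convergent = sum(conv),
       combined = nrow(sites))
}
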