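## Per-site posterior probabilities of the positive-selection class:
## naive empirical Bayes (NEB, parameters plugged in at their MLEs) and
## Bayes empirical Bayes (BEB, integrating over a uniform grid prior on the
## key mixture parameters, following the published construction: M8 varies
## (p0, omega_s) with p and q fixed at their MLEs; model A varies
## (p0, p1, omega_2) with omega_0 fixed at its MLE).

.bebOmegaGrid <- function(n) 1 + (seq_len(n) - 0.5) * 10 / n
.bebProbGrid <- function(n) (seq_len(n) - 0.5) / n

## per-pattern log-likelihood of a single site class; scaleE fixes the
## mixture's common per-edge rate scaling (held at the MLE during BEB)
.classPatternLogL <- function(eng, kappa, p, blen, omegaEdge, scaleE) {
  .classLogLik(eng, kappa, p, blen,
               list(list(prop = 1, omegaEdge = omegaEdge)),
               scaleOverride = scaleE)$logLmat[1L, ]
}

#' Per-site posteriors of the positive-selection class
#'
#' For an M8 or branch-site model A fit, computes each codon column's
#' posterior probability of belonging to the positive-selection class
#' (omega > 1), by BEB (default) or NEB.
#'
#' @param fit a converged \code{FitResult} of kind \code{"M8"} or
#'   \code{"branch_site_A"}.
#' @param aln,tree the data the model was fitted to.
#' @param method \code{"BEB"} or \code{"NEB"}.
#' @param gridSize BEB grid resolution per dimension (default 10, the
#'   published convention).
#' @return data.frame with columns \code{site}, \code{pp} (posterior of the
#'   positive-selection class) and \code{method}; the full per-class
#'   posterior matrix (classes x sites, columns summing to 1) is attached as
#'   attribute \code{"classPosterior"}.
#' @export
sitePosteriors <- function(fit, aln, tree, method = c("BEB", "NEB"),
                           gridSize = 10L) {
  method <- match.arg(method)
  kind <- fit@spec@kind
  if (!kind %in% c("M8", "branch_site_A"))
    stop("site posteriors are defined for M8 or branch-site A fits, got ",
         kind)
  if (!isTRUE(fit@diagnostics$converged))
    stop("refusing to compute site posteriors from an unconverged fit ",
         "(diagnostics$converged is FALSE)")
  eng <- .engine(aln, tree)
  p <- fit@pi@pi
  blen <- fit@branchLengths
  kappa <- fit@kappa
  nE <- eng$ti$nEdge
  cp <- fit@classParams
  classesMLE <- .buildClasses(fit@spec, .paramsFromFit(fit), tree)
  scaleMLE <- .classScale(kappa, p, classesMLE)$scaleE

  if (method == "NEB") {
    prm <- .paramsFromFit(fit)
    classes <- .buildClasses(fit@spec, prm, tree)
    res <- .classLogLik(eng, kappa, p, blen, classes)
    post <- .normalizeClassPost(res$logLmat, res$props)
    posIdx <- if (kind == "M8") nrow(post) else c(3L, 4L)
    pp <- colSums(post[posIdx, , drop = FALSE])
    return(.sitePostResult(pp[eng$patOfSite],
                           post[, eng$patOfSite, drop = FALSE], "NEB"))
  }

  same <- function(w) rep(w, nE)
  pg <- .bebProbGrid(gridSize)
  og <- .bebOmegaGrid(gridSize)
  if (kind == "M8") {
    means <- betaCategoryMeans(cp$p, cp$q, 10L)
    logLbeta <- vapply(means, function(w)
      .classPatternLogL(eng, kappa, p, blen, same(w), scaleMLE), numeric(eng$npat))
    logLws <- vapply(og, function(w)
      .classPatternLogL(eng, kappa, p, blen, same(w), scaleMLE), numeric(eng$npat))
    grid <- expand.grid(ip0 = seq_len(gridSize), iws = seq_len(gridSize))
    propFun <- function(g) c(rep(pg[g$ip0] / 10, 10), 1 - pg[g$ip0])
    logLFun <- function(g) cbind(logLbeta, logLws[, g$iws])
    posIdx <- 11L
    nclass <- 11L
  } else {
    fgEdge <- tree@phylo$edge[, 2L] %in% fit@spec@foreground
    mixW <- function(bg, fg) ifelse(fgEdge, fg, bg)
    w0 <- cp$w0
    logL0 <- .classPatternLogL(eng, kappa, p, blen, mixW(w0, w0), scaleMLE)
    logL1 <- .classPatternLogL(eng, kappa, p, blen, mixW(1, 1), scaleMLE)
    logL2a <- vapply(og, function(w2)
      .classPatternLogL(eng, kappa, p, blen, mixW(w0, w2), scaleMLE),
      numeric(eng$npat))
    logL2b <- vapply(og, function(w2)
      .classPatternLogL(eng, kappa, p, blen, mixW(1, w2), scaleMLE),
      numeric(eng$npat))
    grid <- expand.grid(ip0 = seq_len(gridSize), ip1 = seq_len(gridSize),
                        iw2 = seq_len(gridSize))
    grid <- grid[pg[grid$ip0] + pg[grid$ip1] < 1, , drop = FALSE]
    propFun <- function(g) {
      p0 <- pg[g$ip0]; p1 <- pg[g$ip1]
      c(p0, p1, (1 - p0 - p1) * p0 / (p0 + p1),
        (1 - p0 - p1) * p1 / (p0 + p1))
    }
    logLFun <- function(g) cbind(logL0, logL1, logL2a[, g$iw2],
                                 logL2b[, g$iw2])
    posIdx <- c(3L, 4L)
    nclass <- 4L
  }

  npat <- eng$npat
  logwg <- numeric(nrow(grid))
  postNum <- matrix(0, nclass, npat)
  denomAcc <- 0
  pieces <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    g <- grid[gi, , drop = FALSE]
    props <- propFun(g)
    lmat <- t(logLFun(g))                      # class x pat
    m <- apply(lmat, 2L, max)
    rel <- exp(sweep(lmat, 2L, m)) * props
    fpat <- colSums(rel)
    logwg[gi] <- sum(eng$weights * (log(fpat) + m))
    pieces[[gi]] <- sweep(rel, 2L, fpat, "/")  # class posterior given g
  }
  wg <- exp(logwg - max(logwg))
  wg <- wg / sum(wg)
  for (gi in seq_len(nrow(grid)))
    postNum <- postNum + wg[gi] * pieces[[gi]]
  pp <- colSums(postNum[posIdx, , drop = FALSE])
  .sitePostResult(pp[eng$patOfSite], postNum[, eng$patOfSite, drop = FALSE],
                  "BEB")
}

.sitePostResult <- function(pp, classPost, method) {
  out <- data.frame(site = seq_along(pp), pp = pmin(pmax(pp, 0), 1),
                    method = method)
  attr(out, "classPosterior") <- classPost
  out
}

## rebuild the packed parameter vector of a fit
.paramsFromFit <- function(fit) {
  cp <- fit@classParams
  switch(fit@spec@kind,
    M8 = c(kappa = fit@kappa, p0 = cp$p0, p = cp$p, q = cp$q, ws = cp$ws),
    M8a = c(kappa = fit@kappa, p0 = cp$p0, p = cp$p, q = cp$q),
    branch_site_A = c(kappa = fit@kappa, a = cp$p0 / (cp$p0 + cp$p1),
                      b = cp$p0 + cp$p1, w0 = cp$w0, w2 = cp$w2),
    branch_site_A_null = c(kappa = fit@kappa, a = cp$p0 / (cp$p0 + cp$p1),
                           b = cp$p0 + cp$p1, w0 = cp$w0),
    one_ratio = c(kappa = fit@kappa, omega = unname(fit@omega["omega"])),
    stop("unsupported fit kind: ", fit@spec@kind))
}

.normalizeClassPost <- function(logLmat, props) {
  m <- apply(logLmat, 2L, max)
  rel <- exp(sweep(logLmat, 2L, m)) * props
  sweep(rel, 2L, colSums(rel), "/")
}

#' Call positively selected sites at a posterior-probability threshold
#'
#' Sites with PP >= threshold (inclusive) are reported in alignment
#' coordinates and, when a \code{CoordinateMap} is supplied, also in
#' reference-sequence residue numbering (NA where the reference is gapped).
#'
#' @param posteriors output of \code{\link{sitePosteriors}}.
#' @param threshold inclusion threshold in (0.5, 1); default 0.8.
#' @param coordMap optional \code{\link{mapColumnsToReference}} result.
#' @param aln optional alignment, used to report the reference amino acid.
#' @return data.frame: site, refResidue, refAA, pp, method.
#' @export
callSelectedSites <- function(posteriors, threshold = 0.8, coordMap = NULL,
                              aln = NULL) {
  if (threshold <= 0.5 || threshold >= 1)
    stop("threshold must be in (0.5, 1)")
  hit <- posteriors[posteriors$pp >= threshold, , drop = FALSE]
  refRes <- rep(NA_integer_, nrow(hit))
  refAA <- rep(NA_character_, nrow(hit))
  if (!is.null(coordMap) && nrow(hit)) {
    refRes <- columnToResidue(coordMap, hit$site)
    if (!is.null(aln))
      refAA <- aminoAcidMatrix(aln)[coordMap@reference, hit$site]
  }
  data.frame(site = hit$site, refResidue = refRes, refAA = refAA,
             pp = hit$pp, method = hit$method, row.names = NULL)
}
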