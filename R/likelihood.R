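## Phylogenetic likelihood of a codon alignment by Felsenstein pruning,
## with per-site scaling, site-class mixtures, and analytic derivatives of
## the log-likelihood with respect to branch lengths (inside/outside passes).
##
## The likelihood is computed on the rooted tree as given; under a reversible
## model it is invariant to root placement, and the two root-adjacent branch
## lengths are identifiable only through their sum (a flat ridge the
## optimizer may walk along; lnL and omega estimates are unaffected).

## ---- alignment patterns ----------------------------------------------------

.alignPatterns <- function(aln) {
  st <- codonStates(aln)
  key <- apply(st, 2L, paste, collapse = ",")
  upat <- !duplicated(key)
  patId <- match(key, key[upat])
  pat <- st[, upat, drop = FALSE]
  w <- tabulate(patId, sum(upat))
  siteOfPat <- match(seq_len(sum(upat)), patId)
  list(pat = pat, weights = w, patOfSite = patId, siteOfPat = siteOfPat,
       npat = sum(upat), nsite = ncol(st))
}

## ---- tree indexing ---------------------------------------------------------

.treeIndex <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  edge <- phy$edge
  nnodeTotal <- ntip + phy$Nnode
  childEdges <- vector("list", nnodeTotal)
  for (e in seq_len(nrow(edge)))
    childEdges[[edge[e, 1L]]] <- c(childEdges[[edge[e, 1L]]], e)
  ## internal nodes in preorder (root first) by DFS
  pre <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    kids <- edge[childEdges[[v]], 2L]
    stack <- c(stack, kids[kids > ntip])
  }
  list(edge = edge, nEdge = nrow(edge), ntip = ntip, root = root,
       nnodeTotal = nnodeTotal, childEdges = childEdges,
       preNodes = pre, postNodes = rev(pre), tipLabel = phy$tip.label)
}

.engine <- function(aln, tree) {
  phy <- tree@phylo
  checkTreeAlignment(tree, aln)
  ap <- .alignPatterns(aln)
  ti <- .treeIndex(phy)
  tipStates <- ap$pat[match(ti$tipLabel, rownames(ap$pat)), , drop = FALSE]
  list(ti = ti, tipStates = tipStates, weights = ap$weights,
       patOfSite = ap$patOfSite, siteOfPat = ap$siteOfPat,
       npat = ap$npat, nsite = ap$nsite, ns = 61L)
}

## engine over an arbitrary discrete state space (e.g. 20 amino acids)
.engineFromStates <- function(stateMatrix, tree, ns) {
  phy <- tree@phylo
  ti <- .treeIndex(phy)
  key <- apply(stateMatrix, 2L, paste, collapse = ",")
  upat <- !duplicated(key)
  patId <- match(key, key[upat])
  pat <- stateMatrix[, upat, drop = FALSE]
  tipStates <- pat[match(ti$tipLabel, rownames(pat)), , drop = FALSE]
  list(ti = ti, tipStates = tipStates, weights = tabulate(patId, sum(upat)),
       patOfSite = patId, siteOfPat = match(seq_len(sum(upat)), patId),
       npat = sum(upat), nsite = ncol(stateMatrix), ns = as.integer(ns))
}

## contribution of an edge: P %*% (child partial), with one-hot/missing tips
.edgeContrib <- function(P, ti, child, tipStates, partial, npat, ns = nrow(P)) {
  if (child <= ti$ntip) {
    st <- tipStates[child, ]
    if (!anyNA(st)) return(P[, st, drop = FALSE])
    ## missing state = all-ones partial, so the column is rowSums of the
    ## operand (1 for a P matrix, 0 for its derivative dP)
    C <- matrix(rowSums(P), ns, npat)
    ok <- which(!is.na(st))
    if (length(ok)) C[, ok] <- P[, st[ok], drop = FALSE]
    C
  } else {
    P %*% partial[[child]]
  }
}

## ---- inside (down) pass ----------------------------------------------------

.peel <- function(eng, Plist, pi, keep = FALSE) {
  ti <- eng$ti
  npat <- eng$npat
  ns <- eng$ns
  if (!keep) {
    lp <- tryCatch(
      peelCore(Plist, ti$edge, ti$childEdges, ti$postNodes,
               eng$tipStates, pi, ti$ntip),
      error = function(e) {
        pat <- suppressWarnings(as.integer(sub(".*pattern ", "",
                                               conditionMessage(e))))
        if (!is.na(pat))
          stop("non-finite likelihood at site ", eng$siteOfPat[pat])
        stop(e)
      })
    return(list(logLpat = lp, partial = NULL, contrib = NULL))
  }
  partial <- vector("list", ti$nnodeTotal)
  contrib <- if (keep) vector("list", ti$nEdge) else NULL
  logscale <- numeric(npat)
  for (v in ti$postNodes) {
    M <- NULL
    for (eidx in ti$childEdges[[v]]) {
      C <- .edgeContrib(Plist[[eidx]], ti, ti$edge[eidx, 2L],
                        eng$tipStates, partial, npat)
      if (keep) contrib[[eidx]] <- C
      M <- if (is.null(M)) C else M * C
    }
    s <- .colSums(M, ns, npat)
    bad <- !is.finite(s) | s <= 0
    if (any(bad))
      stop("non-finite likelihood at site ",
           eng$siteOfPat[which(bad)[1L]])
    M <- M / rep(s, each = ns)
    logscale <- logscale + log(s)
    partial[[v]] <- M
  }
  logLpat <- log(.colSums(partial[[ti$root]] * pi, ns, npat)) + logscale
  list(logLpat = logLpat, partial = partial, contrib = contrib)
}

## ---- outside (up) pass: branch-length derivatives and node posteriors ------

## Returns dlogL_pat/dt_e (nEdge x npat) for one site class, and optionally
## the outside messages U for marginal ancestral reconstruction.
.peelOutside <- function(eng, Plist, dPlist, down, pi, wantU = FALSE) {
  ti <- eng$ti
  npat <- eng$npat
  ns <- eng$ns
  U <- vector("list", ti$nnodeTotal)
  U[[ti$root]] <- matrix(pi, ns, npat)
  ratio <- if (!is.null(dPlist)) matrix(0, ti$nEdge, npat) else NULL
  for (v in ti$preNodes) {
    kids <- ti$childEdges[[v]]
    k <- length(kids)
    ## sibling products via prefix/suffix
    Slist <- vector("list", k)
    if (k == 1L) {
      Slist[[1L]] <- matrix(1, ns, npat)
    } else {
      acc <- matrix(1, ns, npat)
      for (i in seq_len(k)) { Slist[[i]] <- acc
        acc <- acc * down$contrib[[kids[i]]] }
      acc <- matrix(1, ns, npat)
      for (i in rev(seq_len(k))) { Slist[[i]] <- Slist[[i]] * acc
        acc <- acc * down$contrib[[kids[i]]] }
    }
    for (i in seq_len(k)) {
      eidx <- kids[i]
      child <- ti$edge[eidx, 2L]
      W <- U[[v]] * Slist[[i]]
      if (!is.null(dPlist)) {
        num <- .colSums(W * .edgeContrib(dPlist[[eidx]], ti, child,
                                         eng$tipStates, down$partial, npat),
                        ns, npat)
        den <- .colSums(W * down$contrib[[eidx]], ns, npat)
        ratio[eidx, ] <- num / den
      }
      if (child > ti$ntip || wantU) {
        Uc <- crossprod(Plist[[eidx]], W)
        s <- .colSums(Uc, ns, npat)
        s[s <= 0 | !is.finite(s)] <- 1
        U[[child]] <- Uc / rep(s, each = ns)
      }
    }
  }
  list(ratio = ratio, U = U)
}

## missing-data contribution of dP columns for tips is handled by
## .edgeContrib: rows of dP sum to 0, so missing tips contribute 0.

## ---- site-class evaluation -------------------------------------------------

## per-edge common scaling of a site-class mixture: every class's generator
## for edge e is divided by scaleE[e] = sum_k p_k r(omega_{k,e}), so one
## unit of branch length is one expected substitution per codon averaged
## over classes, while relative class rates are preserved
.classScale <- function(kappa, pi, classes) {
  omEdge <- lapply(classes, `[[`, "omegaEdge")
  uo <- sort(unique(unlist(omEdge)))
  rates <- vapply(uo, function(w) .rawRate(kappa, w, pi), numeric(1L))
  props <- vapply(classes, `[[`, numeric(1L), "prop")
  rateMat <- do.call(rbind, lapply(omEdge, function(oe)
    rates[match(oe, uo)]))                      # class x edge
  list(uo = uo, omEdge = omEdge, rateMat = rateMat, props = props,
       scaleE = as.numeric(props %*% rateMat))
}

## classes: list of list(prop = scalar, omegaEdge = numeric nEdge)
## Returns total lnL, per-pattern mixture logL, and per-class pieces.
.classLogLik <- function(eng, kappa, pi, blen, classes, keep = FALSE,
                         wantGrad = FALSE, patCache = NULL,
                         scaleOverride = NULL) {
  nE <- eng$ti$nEdge
  cs <- .classScale(kappa, pi, classes)
  scaleE <- if (is.null(scaleOverride)) cs$scaleE else scaleOverride
  omEdge <- cs$omEdge
  uo <- cs$uo
  rates <- vapply(uo, function(w) .rawRate(kappa, w, pi), numeric(1L))
  decs <- vector("list", length(uo))
  getDec <- function(oi) {
    if (is.null(decs[[oi]]))
      decs[[oi]] <<- .getDecomp(kappa, uo[oi], pi)
    decs[[oi]]
  }
  Pc <- new.env(parent = emptyenv())
  getP <- function(oi, e) {
    key <- paste0(oi, ".", e)
    P <- Pc[[key]]
    if (is.null(P)) {
      P <- .edgeP(getDec(oi), blen[e] * rates[oi] / scaleE[e])
      Pc[[key]] <- P
    }
    P
  }
  props <- vapply(classes, `[[`, numeric(1L), "prop")
  npat <- eng$npat
  logLmat <- matrix(0, length(classes), npat)
  grad <- if (wantGrad) matrix(0, nE, npat) else NULL
  ratios <- if (wantGrad) vector("list", length(classes)) else NULL
  downs <- vector("list", length(classes))
  PlistAll <- vector("list", length(classes))
  useCache <- !is.null(patCache) && !keep && !wantGrad
  for (ci in seq_along(classes)) {
    oidx <- match(omEdge[[ci]], uo)
    if (useCache) {
      ## branch lengths are fixed for the whole fit, so a class's pattern
      ## log-likelihood is determined by (kappa, per-edge omega): cache it
      ## and skip the pruning pass when only other parameters moved
      ckey <- paste(sprintf("%.17g", c(kappa, omEdge[[ci]], scaleE)),
                    collapse = ",")
      hit <- patCache[[ckey]]
      if (!is.null(hit)) {
        logLmat[ci, ] <- hit
        next
      }
      Plist <- lapply(seq_len(nE), function(e) getP(oidx[e], e))
      down <- .peel(eng, Plist, pi, keep = FALSE)
      if (length(ls(patCache)) > 4000L)
        rm(list = ls(patCache), envir = patCache)
      patCache[[ckey]] <- down$logLpat
      logLmat[ci, ] <- down$logLpat
      next
    }
    Plist <- lapply(seq_len(nE), function(e) getP(oidx[e], e))
    down <- .peel(eng, Plist, pi, keep = keep || wantGrad)
    logLmat[ci, ] <- down$logLpat
    if (wantGrad) {
      dPlist <- lapply(seq_len(nE), function(e) {
        d <- getDec(oidx[e])
        f <- rates[oidx[e]] / scaleE[e]
        f * ((d$A * rep(d$lambda * exp(d$lambda * blen[e] * f),
                        each = 61L)) %*% d$B)
      })
      ratios[[ci]] <- .peelOutside(eng, Plist, dPlist, down, pi)$ratio
      down$contrib <- NULL   # free before next class
    }
    if (keep) { downs[[ci]] <- down; PlistAll[[ci]] <- Plist }
  }
  ## mix classes in log space
  m <- apply(logLmat, 2L, max)
  Lrel <- exp(sweep(logLmat, 2L, m))           # class x pat
  mixrel <- colSums(Lrel * props)
  logLpat <- log(mixrel) + m
  if (wantGrad) {
    wcls <- sweep(Lrel * props, 2L, mixrel, "/")  # posterior class weights
    for (ci in seq_along(classes))
      grad <- grad + ratios[[ci]] * rep(wcls[ci, ], each = nE)
    grad <- as.numeric(grad %*% eng$weights)
  }
  list(lnL = sum(logLpat * eng$weights), logLpat = logLpat,
       logLmat = logLmat, props = props, grad = grad,
       downs = downs, Plists = PlistAll, decs = decs, uo = uo)
}

## ---- public likelihood -----------------------------------------------------

#' Log-likelihood of a codon alignment on a labeled tree
#'
#' Computes the GY94 likelihood by pruning, with gap/ambiguous codons
#' marginalized as missing data. \code{omega} may be a scalar (one ratio for
#' all branches) or a named vector over branch categories of the tree
#' (multi-ratio). Alternatively, \code{siteClasses} gives a mixture over site
#' classes, each a \code{list(prop=, omega=)} with \code{omega} again scalar
#' or named by category; the classes share a common per-edge rate scaling
#' (proportion-weighted mean rate = 1), so larger-omega classes evolve
#' proportionally faster.
#'
#' @param aln a \code{CodonAlignment}.
#' @param tree a \code{LabeledTree} whose leaves match the alignment; branch
#'   lengths in expected substitutions per codon.
#' @param kappa transition/transversion ratio.
#' @param omega scalar or named-by-category omega (ignored when
#'   \code{siteClasses} is given).
#' @param pi a \code{CodonFrequencies} (default: F3x4 from the alignment).
#' @param siteClasses optional site-class mixture (see Details).
#' @return list with \code{lnL} (total) and \code{perSite} (per codon column;
#'   sums to \code{lnL}).
#' @export
alignmentLogLikelihood <- function(aln, tree, kappa, omega = NULL,
                                   pi = codonFrequencies(aln),
                                   siteClasses = NULL) {
  eng <- .engine(aln, tree)
  p <- pi@pi
  blen <- tree@phylo$edge.length
  if (is.null(siteClasses)) {
    if (is.null(omega)) stop("supply omega or siteClasses")
    siteClasses <- list(list(prop = 1, omega = omega))
  }
  classes <- lapply(siteClasses, function(cl)
    list(prop = cl$prop,
         omegaEdge = .omegaPerEdge(cl$omega, tree)))
  res <- .classLogLik(eng, kappa, p, blen, classes)
  list(lnL = res$lnL, perSite = res$logLpat[eng$patOfSite])
}

## scalar, named-by-category, or per-edge omega -> per-edge vector
.omegaPerEdge <- function(omega, tree) {
  nE <- nrow(tree@phylo$edge)
  if (length(omega) == 1L && is.null(names(omega)))
    return(rep(unname(omega), nE))
  if (length(omega) == nE && is.null(names(omega))) return(omega)
  cat <- branchCategories(tree)
  miss <- setdiff(unique(cat), names(omega))
  if (length(miss))
    stop("no omega supplied for category: ", paste(miss, collapse = ", "))
  unname(omega[cat])
}
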