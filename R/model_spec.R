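## Model definitions: the omega structures in scope and their parameter
## bookkeeping (packing, bounds, site-class construction, np counting).

#' Define an omega model
#'
#' @param kind one of \code{"one_ratio"} (M0), \code{"free_ratio"},
#'   \code{"multi_ratio"}, \code{"M8"}, \code{"M8a"},
#'   \code{"branch_site_A"}, \code{"branch_site_A_null"}.
#' @param slotMap for \code{multi_ratio}: named character mapping each branch
#'   category to an omega-slot name (categories sharing a slot share omega).
#'   Convenience: \code{slotMap = "by_category"} gives every category its own
#'   slot.
#' @param foreground for branch-site models: focal branch name(s) (as in
#'   \code{focalBranches}) or child node ids of the foreground branches.
#' @param tree the \code{LabeledTree} the model applies to (needed to resolve
#'   \code{slotMap}/\code{foreground}).
#' @param label report label; a default is derived from \code{kind}.
#' @return A \code{\linkS4class{ModelSpec}}.
#' @export
modelSpec <- function(kind, tree = NULL, slotMap = NULL, foreground = NULL,
                      label = NULL) {
  kind <- match.arg(kind, .modelKinds)
  sm <- character(0)
  fg <- integer(0)
  if (kind == "multi_ratio") {
    if (is.null(tree)) stop("multi_ratio requires the tree")
    cats <- unique(branchCategories(tree))
    if (is.null(slotMap) || identical(slotMap, "by_category"))
      sm <- stats::setNames(cats, cats)
    else {
      miss <- setdiff(cats, names(slotMap))
      if (length(miss))
        stop("slotMap misses categories: ", paste(miss, collapse = ", "))
      sm <- slotMap[cats]
    }
  }
  if (kind %in% c("branch_site_A", "branch_site_A_null")) {
    if (is.null(foreground) || length(foreground) == 0L)
      stop("branch-site models need a nonempty foreground")
    if (is.character(foreground)) {
      if (is.null(tree)) stop("resolving focal names requires the tree")
      foc <- focalBranches(tree)
      miss <- setdiff(foreground, names(foc))
      if (length(miss))
        stop("unknown focal branch: ", paste(miss, collapse = ", "))
      fg <- unname(foc[foreground])
    } else fg <- as.integer(foreground)
    if (!is.null(tree)) {
      nE <- nrow(tree@phylo$edge)
      fgEdges <- match(fg, tree@phylo$edge[, 2L])
      if (anyNA(fgEdges)) stop("foreground node is not a branch of the tree")
      if (length(fg) >= nE)
        stop("foreground must be a proper subset of branches")
    }
  }
  if (is.null(label))
    label <- switch(kind, one_ratio = "1ω", free_ratio = "free-ratio",
                    multi_ratio = paste0(length(unique(sm)), "ω"),
                    M8 = "M8", M8a = "M8a",
                    branch_site_A = "branch-site A",
                    branch_site_A_null = "branch-site A null")
  new("ModelSpec", kind = kind, slotMap = sm, foreground = fg, label = label)
}

#' Number of omega-slot names of a multi-ratio spec (in first-appearance order)
#' @keywords internal
.slotNames <- function(spec) unique(unname(spec@slotMap))

## ---- discretized beta for M8/M8a -------------------------------------------

#' Means of the 10 equal-probability categories of a Beta(p, q)
#'
#' Category k (k = 1..n) covers the probability mass ((k-1)/n, k/n]; it is
#' represented by its conditional mean, computed in closed form from the
#' incomplete beta function.
#' @param p,q beta shape parameters (> 0).
#' @param n number of categories.
#' @return numeric vector of n category means in (0, 1).
#' @export
betaCategoryMeans <- function(p, q, n = 10L) {
  ## qbeta warns about limited accuracy for the extreme shapes the optimizer
  ## probes near the bounds; the means are clamped below regardless
  edges <- suppressWarnings(stats::qbeta(seq(0, 1, length.out = n + 1L),
                                         p, q))
  mass1 <- stats::pbeta(edges, p + 1, q)
  means <- (mass1[-1L] - mass1[-(n + 1L)]) * (p / (p + q)) * n
  pmin(pmax(means, 1e-8), 1 - 1e-8)
}

## ---- parameter packing -----------------------------------------------------

## Each kind defines: names, default starts, lower/upper bounds, and a
## builder params -> list of site classes (prop, omegaEdge) given the tree.

.paramTemplate <- function(spec, tree) {
  nE <- nrow(tree@phylo$edge)
  switch(spec@kind,
    one_ratio = list(
      names = c("kappa", "omega"),
      start = c(2, 0.3),
      lower = c(0.05, 1e-6), upper = c(99, 999)),
    multi_ratio = {
      sl <- .slotNames(spec)
      list(names = c("kappa", paste0("omega_", sl)),
           start = c(2, rep(0.3, length(sl))),
           lower = c(0.05, rep(1e-6, length(sl))),
           upper = c(99, rep(999, length(sl))))
    },
    free_ratio = list(
      names = c("kappa", paste0("omega_e", seq_len(nE))),
      start = c(2, rep(0.3, nE)),
      lower = c(0.05, rep(1e-6, nE)), upper = c(99, rep(999, nE))),
    M8 = list(
      names = c("kappa", "p0", "p", "q", "ws"),
      start = c(2, 0.9, 0.5, 2, 2),
      lower = c(0.05, 1e-6, 0.005, 0.005, 1),
      upper = c(99, 1 - 1e-6, 99, 99, 999)),
    M8a = list(
      names = c("kappa", "p0", "p", "q"),
      start = c(2, 0.9, 0.5, 2),
      lower = c(0.05, 1e-6, 0.005, 0.005),
      upper = c(99, 1 - 1e-6, 99, 99)),
    branch_site_A = list(
      ## proportions via a = p0/(p0+p1), b = p0+p1
      names = c("kappa", "a", "b", "w0", "w2"),
      start = c(2, 0.7, 0.85, 0.1, 2),
      lower = c(0.05, 1e-6, 1e-6, 1e-6, 1),
      upper = c(99, 1 - 1e-6, 1 - 1e-6, 1, 999)),
    branch_site_A_null = list(
      names = c("kappa", "a", "b", "w0"),
      start = c(2, 0.7, 0.85, 0.1),
      lower = c(0.05, 1e-6, 1e-6, 1e-6),
      upper = c(99, 1 - 1e-6, 1 - 1e-6, 1)))
}

## params (named) -> site classes: list(prop, omegaEdge)
.buildClasses <- function(spec, params, tree) {
  nE <- nrow(tree@phylo$edge)
  same <- function(w) rep(w, nE)
  switch(spec@kind,
    one_ratio = list(list(prop = 1, omegaEdge = same(params[["omega"]]))),
    multi_ratio = {
      sl <- .slotNames(spec)
      w <- stats::setNames(params[paste0("omega_", sl)], sl)
      slotOfEdge <- unname(spec@slotMap[branchCategories(tree)])
      list(list(prop = 1, omegaEdge = unname(w[slotOfEdge])))
    },
    free_ratio = list(list(prop = 1,
      omegaEdge = unname(params[paste0("omega_e", seq_len(nE))]))),
    M8 = , M8a = {
      ws <- if (spec@kind == "M8") params[["ws"]] else 1
      p0 <- params[["p0"]]
      means <- betaCategoryMeans(params[["p"]], params[["q"]], 10L)
      cl <- lapply(means, function(w)
        list(prop = p0 / 10, omegaEdge = same(w)))
      c(cl, list(list(prop = 1 - p0, omegaEdge = same(ws))))
    },
    branch_site_A = , branch_site_A_null = {
      w2 <- if (spec@kind == "branch_site_A") params[["w2"]] else 1
      w0 <- params[["w0"]]
      a <- params[["a"]]; b <- params[["b"]]
      fgEdge <- tree@phylo$edge[, 2L] %in% spec@foreground
      mixW <- function(bg, fg) ifelse(fgEdge, fg, bg)
      list(
        list(prop = a * b,             omegaEdge = mixW(w0, w0)),
        list(prop = (1 - a) * b,       omegaEdge = mixW(1, 1)),
        list(prop = a * (1 - b),       omegaEdge = mixW(w0, w2)),
        list(prop = (1 - a) * (1 - b), omegaEdge = mixW(1, w2)))
    })
}

## number of free parameters: branch lengths of the input (rooted) tree
## + kappa + model-specific omega/class parameters
.modelNp <- function(spec, tree) {
  nE <- nrow(tree@phylo$edge)
  extra <- switch(spec@kind,
    one_ratio = 1L,
    multi_ratio = length(.slotNames(spec)),
    free_ratio = nE,
    M8 = 4L, M8a = 3L,
    branch_site_A = 4L, branch_site_A_null = 3L)
  as.integer(nE + 1L + extra)
}

## interpretable omega vector + class-parameter list from fitted params
.reportEstimates <- function(spec, params, tree) {
  switch(spec@kind,
    one_ratio = list(omega = c(omega = unname(params[["omega"]])),
                     classParams = list()),
    multi_ratio = {
      sl <- .slotNames(spec)
      list(omega = stats::setNames(unname(params[paste0("omega_", sl)]), sl),
           classParams = list())
    },
    free_ratio = {
      nE <- nrow(tree@phylo$edge)
      list(omega = stats::setNames(
             unname(params[paste0("omega_e", seq_len(nE))]),
             paste0("edge", seq_len(nE))),
           classParams = list())
    },
    M8 = list(omega = c(ws = unname(params[["ws"]])),
              classParams = as.list(params[c("p0", "p", "q", "ws")])),
    M8a = list(omega = c(ws = 1),
               classParams = c(as.list(params[c("p0", "p", "q")]),
                               list(ws = 1))),
    branch_site_A = , branch_site_A_null = {
      a <- params[["a"]]; b <- params[["b"]]
      w2 <- if (spec@kind == "branch_site_A") unname(params[["w2"]]) else 1
      list(omega = c(w0 = unname(params[["w0"]]), w2 = w2),
           classParams = list(p0 = a * b, p1 = (1 - a) * b,
                              p2a = a * (1 - b), p2b = (1 - a) * (1 - b),
                              w0 = unname(params[["w0"]]), w2 = w2))
    })
}
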