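#' @import methods
NULL

setOldClass("phylo")

#' CodonAlignment: an in-frame codon multiple sequence alignment
#'
#' Holds a taxa x codon-column matrix of sense-codon states (integer indices
#' 1..61 in the engine's codon ordering; \code{NA} marks gap/ambiguous codons,
#' treated as fully missing states by the likelihood). Construct with
#' \code{\link{readCodonAlignment}} or \code{\link{codonAlignment}}.
#'
#' @slot states integer matrix, taxa in rows (rownames = taxon names), codon
#'   columns 1-based.
#' @slot geneticCode genetic code identifier ("standard").
#' @export
setClass("CodonAlignment",
  representation(states = "matrix", geneticCode = "character"))

setValidity("CodonAlignment", function(object) {
  st <- object@states
  msgs <- character()
  if (!is.integer(st[1L])) msgs <- c(msgs, "states must be an integer matrix")
  if (is.null(rownames(st)) || anyDuplicated(rownames(st)))
    msgs <- c(msgs, "taxon names must be present and unique")
  if (ncol(st) < 1L) msgs <- c(msgs, "alignment must have at least 1 codon")
  ok <- st[!is.na(st)]
  if (length(ok) && (min(ok) < 1L || max(ok) > 61L))
    msgs <- c(msgs, "codon states must be in 1..61")
  if (!identical(object@geneticCode, "standard"))
    msgs <- c(msgs, "only the standard genetic code is supported")
  if (length(msgs)) msgs else TRUE
})

#' LabeledTree: rooted phylogeny with per-branch habitat categories
#'
#' Wraps an \code{ape} \code{phylo} object (rooted, with branch lengths in
#' expected substitutions per codon) together with a per-edge category label
#' (the habitat partition driving the multi-ratio branch models) and named
#' focal branches for convergence analysis.
#'
#' @slot phylo rooted \code{phylo}.
#' @slot category character vector, one entry per edge (rows of
#'   \code{phylo$edge}); \code{"background"} is the reference category.
#' @slot focal named integer vector: focal branch name -> child node id of the
#'   branch.
#' @export
setClass("LabeledTree",
  representation(phylo = "phylo", category = "character", focal = "integer"))

setValidity("LabeledTree", function(object) {
  phy <- object@phylo
  msgs <- character()
  if (!ape::is.rooted(phy)) msgs <- c(msgs, "tree must be rooted")
  if (is.null(phy$edge.length)) msgs <- c(msgs, "tree must have branch lengths")
  else if (any(phy$edge.length < 0)) msgs <- c(msgs, "negative branch length")
  if (length(object@category) != nrow(phy$edge))
    msgs <- c(msgs, "category must have one entry per edge")
  if (anyNA(object@category)) msgs <- c(msgs, "every branch needs a category")
  if (length(object@focal)) {
    if (is.null(names(object@focal)) || anyDuplicated(names(object@focal)))
      msgs <- c(msgs, "focal branches must have unique names")
    nn <- ape::Ntip(phy) + phy$Nnode
    if (any(object@focal < 1L | object@focal > nn))
      msgs <- c(msgs, "focal branch node id out of range")
  }
  if (length(msgs)) msgs else TRUE
})

#' CodonFrequencies: equilibrium frequencies of the 61 sense codons
#'
#' @slot pi numeric 61-vector, nonnegative, summing to 1.
#' @slot scheme one of "F3x4", "F61", "uniform".
#' @export
setClass("CodonFrequencies",
  representation(pi = "numeric", scheme = "character"))

setValidity("CodonFrequencies", function(object) {
  msgs <- character()
  if (length(object@pi) != 61L) msgs <- c(msgs, "pi must have length 61")
  if (any(object@pi < 0)) msgs <- c(msgs, "pi entries must be >= 0")
  if (abs(sum(object@pi) - 1) > 1e-12) msgs <- c(msgs, "pi must sum to 1")
  if (!object@scheme %in% c("F3x4", "F61", "uniform"))
    msgs <- c(msgs, "unknown frequency scheme")
  if (length(msgs)) msgs else TRUE
})

#' CoordinateMap: alignment columns vs reference-taxon residue numbering
#'
#' Bijection between the non-gap codon columns of a reference taxon and its
#' 1-based residue indices, used to report selected sites in both alignment
#' and reference (e.g. human) coordinates.
#'
#' @slot column integer, 1-based alignment codon columns (strictly increasing).
#' @slot residue integer, 1-based residue index in the ungapped reference.
#' @slot reference reference taxon name.
#' @export
setClass("CoordinateMap",
  representation(column = "integer", residue = "integer",
                 reference = "character"))

setValidity("CoordinateMap", function(object) {
  msgs <- character()
  if (length(object@column) != length(object@residue))
    msgs <- c(msgs, "column and residue must have equal length")
  if (is.unsorted(object@column, strictly = TRUE))
    msgs <- c(msgs, "columns must be strictly increasing")
  if (length(object@residue) &&
      !identical(object@residue, seq_along(object@residue)))
    msgs <- c(msgs, "residues must be 1..n in order")
  if (length(msgs)) msgs else TRUE
})

#' ModelSpec: an omega-model definition
#'
#' Describes one of the selection models in scope: \code{one_ratio} (M0),
#' \code{free_ratio}, \code{multi_ratio} (the 2/3/5-ratio habitat ladder),
#' \code{M8}, \code{M8a}, \code{branch_site_A}, \code{branch_site_A_null}.
#'
#' @slot kind model kind.
#' @slot slotMap for multi_ratio: named character, habitat category ->
#'   omega-slot name; empty otherwise.
#' @slot foreground for branch-site models: child node ids of foreground
#'   branches; empty otherwise.
#' @slot label free-text label used in reports (e.g. "2ω").
#' @export
setClass("ModelSpec",
  representation(kind = "character", slotMap = "character",
                 foreground = "integer", label = "character"))

.modelKinds <- c("one_ratio", "free_ratio", "multi_ratio",
                 "M8", "M8a", "branch_site_A", "branch_site_A_null")

setValidity("ModelSpec", function(object) {
  msgs <- character()
  if (!object@kind %in% .modelKinds)
    msgs <- c(msgs, paste("unknown model kind:", object@kind))
  if (object@kind == "multi_ratio" && length(object@slotMap) == 0L)
    msgs <- c(msgs, "multi_ratio requires a category -> omega-slot map")
  if (object@kind %in% c("branch_site_A", "branch_site_A_null") &&
      length(object@foreground) == 0L)
    msgs <- c(msgs, "branch-site models require a nonempty foreground set")
  if (length(msgs)) msgs else TRUE
})

#' FitResult: a maximum-likelihood fit of an omega model
#'
#' @slot spec the \code{ModelSpec} fitted.
#' @slot lnL maximized log-likelihood.
#' @slot np number of free parameters (branch lengths of the input rooted
#'   tree + kappa + model-specific omega/class parameters).
#' @slot kappa ML transition/transversion ratio.
#' @slot omega named numeric: omega per slot (one_ratio: "omega"; multi_ratio:
#'   one per slot; free_ratio: one per edge; site/branch-site models: class
#'   omegas).
#' @slot classParams list of site-class parameters (M8: p0, p, q, ws;
#'   branch-site: p0, p1, w0, w2) or empty.
#' @slot branchLengths numeric, per edge of the input tree.
#' @slot pi the \code{CodonFrequencies} used.
#' @slot perSiteLnL numeric, per-codon-column log-likelihood.
#' @slot diagnostics list: rounds, evals, converged, boundary flags, seed.
#' @export
setClass("FitResult",
  representation(spec = "ModelSpec", lnL = "numeric", np = "integer",
                 kappa = "numeric", omega = "numeric", classParams = "list",
                 branchLengths = "numeric", pi = "CodonFrequencies",
                 perSiteLnL = "numeric", diagnostics = "list"))

setValidity("FitResult", function(object) {
  msgs <- character()
  if (!is.finite(object@lnL)) msgs <- c(msgs, "lnL must be finite")
  if (abs(sum(object@perSiteLnL) - object@lnL) > 1e-6)
    msgs <- c(msgs, "per-site lnL must sum to total lnL")
  if (length(msgs)) msgs else TRUE
})

#' LRTResult: a likelihood-ratio test between nested fits
#'
#' @slot stat 2 * (lnL_alt - lnL_null), clamped at 0.
#' @slot df degrees of freedom (np difference).
#' @slot p chi-square p-value.
#' @slot comparison label, e.g. "2ω vs. 1ω".
#' @slot null,alt the two fits (may be empty lists when built from bare lnL).
#' @export
setClass("LRTResult",
  representation(stat = "numeric", df = "integer", p = "numeric",
                 comparison = "character", null = "list", alt = "list"))

setValidity("LRTResult", function(object) {
  msgs <- character()
  if (object@stat < 0) msgs <- c(msgs, "stat must be >= 0")
  if (object@df < 1L) msgs <- c(msgs, "df must be >= 1")
  if (object@p < 0 || object@p > 1) msgs <- c(msgs, "p must be in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' AncestralReconstruction: marginal ancestral states under a fitted model
#'
#' @slot mode "codon" (codon-level posteriors collapsed to amino acids) or
#'   "aa" (direct amino-acid chain).
#' @slot aaPosterior list over nodes (names = node ids as character) of
#'   20 x n_site amino-acid posterior matrices (internal nodes only).
#' @slot map integer matrix (n_node_total x n_site): MAP amino-acid index per
#'   node and site (tips = observed states, NA where missing).
#' @slot maxPP numeric matrix like \code{map}: posterior of the MAP state
#'   (1 for observed tips).
#' @slot tree the \code{LabeledTree} used.
#' @slot aaLevels the 20 amino-acid levels indexing \code{map}.
#' @export
setClass("AncestralReconstruction",
  representation(mode = "character", aaPosterior = "list", map = "matrix",
                 maxPP = "matrix", tree = "LabeledTree", aaLevels = "character"))

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d taxa x %d codons (%s code), %.1f%% missing\n",
              nrow(object@states), ncol(object@states), object@geneticCode,
              100 * mean(is.na(object@states))))
})

setMethod("show", "LabeledTree", function(object) {
  cats <- table(object@category)
  cat(sprintf("LabeledTree: %d tips, %d edges\n", ape::Ntip(object@phylo),
              nrow(object@phylo$edge)))
  cat("  categories:", paste(sprintf("%s(%d)", names(cats), cats),
                             collapse = ", "), "\n")
  if (length(object@focal))
    cat("  focal branches:", paste(names(object@focal), collapse = ", "), "\n")
})

setMethod("show", "CodonFrequencies", function(object) {
  cat(sprintf("CodonFrequencies (%s): 61 sense codons, sum = %.6f\n",
              object@scheme, sum(object@pi)))
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s (%s)\n", object@label, object@kind))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %s  lnL = %.3f  np = %d  kappa = %.3f\n",
              object@spec@label, object@lnL, object@np, object@kappa))
  om <- object@omega
  if (length(om) <= 8L)
    cat("  omega:", paste(sprintf("%s=%.4g", names(om), om), collapse = "  "),
        "\n")
  else cat(sprintf("  omega: %d per-branch values in [%.4g, %.4g]\n",
                   length(om), min(om), max(om)))
  if (!isTRUE(object@diagnostics$converged))
    cat("  WARNING: optimizer did not converge\n")
})

setMethod("show", "LRTResult", function(object) {
  cat(sprintf("LRT %s: 2ΔL = %.3f, df = %d, p = %.4g\n",
              object@comparison, object@stat, object@df, object@p))
})

setMethod("show", "AncestralReconstruction", function(object) {
  cat(sprintf("AncestralReconstruction (%s-level): %d nodes x %d sites\n",
              object@mode, nrow(object@map), ncol(object@map)))
})
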