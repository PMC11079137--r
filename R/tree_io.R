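## Category-labeled trees: reading, branch categories, collapse ladder,
## focal branches.

.CATEGORIES <- c("background", "high-altitude", "cave",
                 "fully-aquatic", "semi-aquatic")

## child node id for a taxon set: single taxon -> tip node; several -> MRCA
.nodeForTaxa <- function(phy, taxa_in) {
  tips <- match(taxa_in, phy$tip.label)
  if (anyNA(tips))
    stop("unknown taxa in category/focal config: ",
         paste(taxa_in[is.na(tips)], collapse = ", "))
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(phy, tips)
}

## all edge indices within the clade rooted at `node` (including its stem edge)
.cladeEdges <- function(phy, node, includeStem = TRUE) {
  desc <- node
  queue <- node
  repeat {
    kids <- phy$edge[phy$edge[, 1L] %in% queue, 2L]
    if (!length(kids)) break
    desc <- c(desc, kids)
    queue <- kids
  }
  idx <- which(phy$edge[, 2L] %in% desc)
  if (!includeStem) idx <- setdiff(idx, which(phy$edge[, 2L] == node))
  idx
}

#' Construct a LabeledTree from a phylo object and a category config
#'
#' @param phy a rooted \code{phylo} with branch lengths (expected
#'   substitutions per codon).
#' @param categories named list: category id -> taxon name(s). A single taxon
#'   labels its pendant branch; several taxa label the whole clade spanned by
#'   their MRCA (stem branch included). Unlabeled branches are
#'   \code{"background"}.
#' @param focal named list of focal branches for convergence analysis (the
#'   study's branches a-o): name -> taxon (pendant branch) or taxa (stem
#'   branch of their MRCA).
#' @param pamlCategory optional per-edge integer labels parsed from PAML-style
#'   \code{#k} suffixes (internal use by \code{\link{readLabeledTree}}).
#' @return A \code{\linkS4class{LabeledTree}}.
#' @export
labeledTree <- function(phy, categories = list(), focal = list(),
                        pamlCategory = NULL) {
  if (is.null(phy$edge.length))
    phy$edge.length <- rep(0.1, nrow(phy$edge))
  cat_edge <- rep(NA_character_, nrow(phy$edge))
  for (cat in names(categories)) {
    taxa_in <- unlist(categories[[cat]], use.names = FALSE)
    node <- .nodeForTaxa(phy, taxa_in)
    idx <- if (length(taxa_in) == 1L) which(phy$edge[, 2L] == node)
           else .cladeEdges(phy, node)
    clash <- !is.na(cat_edge[idx]) & cat_edge[idx] != cat
    if (any(clash))
      stop("conflicting category labels for branch(es) ",
           paste(idx[clash], collapse = ", "), ": ",
           unique(cat_edge[idx][clash])[1L], " vs ", cat)
    cat_edge[idx] <- cat
  }
  if (!is.null(pamlCategory)) {
    pc <- ifelse(pamlCategory == 0L, NA_character_,
                 paste0("cat", pamlCategory))
    clash <- !is.na(cat_edge) & !is.na(pc) & cat_edge != pc
    if (any(clash))
      stop("category config conflicts with PAML #k labels on branch(es) ",
           paste(which(clash), collapse = ", "))
    cat_edge[is.na(cat_edge)] <- pc[is.na(cat_edge)]
  }
  cat_edge[is.na(cat_edge)] <- "background"
  foc <- integer(0)
  if (length(focal)) {
    foc <- vapply(focal, function(x)
      .nodeForTaxa(phy, unlist(x, use.names = FALSE)), integer(1L))
    root <- ape::Ntip(phy) + 1L
    if (any(foc == root)) stop("a focal branch cannot be the root")
  }
  new("LabeledTree", phylo = phy, category = cat_edge, focal = foc)
}

## strip "#k" suffixes from tip/node labels, returning per-edge integers
.parsePamlLabels <- function(phy) {
  lab <- rep(0L, nrow(phy$edge))
  grab <- function(x) {
    k <- rep(0L, length(x))
    hit <- grepl("#\\d+\\s*$", x)
    k[hit] <- as.integer(sub("^.*#(\\d+)\\s*$", "\\1", x[hit]))
    k
  }
  ktip <- grab(phy$tip.label)
  phy$tip.label <- sub("\\s*#\\d+\\s*$", "", phy$tip.label)
  knode <- integer(phy$Nnode)
  if (!is.null(phy$node.label)) {
    knode <- grab(phy$node.label)
    phy$node.label <- sub("\\s*#\\d+\\s*$", "", phy$node.label)
  }
  ntip <- ape::Ntip(phy)
  kall <- c(ktip, knode)
  lab <- kall[phy$edge[, 2L]]
  list(phy = phy, label = lab)
}

#' Read a Newick tree with habitat-category labels
#'
#' Accepts PAML-style \code{#k} branch labels in the Newick and/or an explicit
#' category configuration (e.g. from the YAML run config). Supplying
#' conflicting labels through both routes is an error.
#'
#' @param path Newick file.
#' @param categories,focal as in \code{\link{labeledTree}}.
#' @param alignment optional \code{CodonAlignment}; if given, the tree's leaf
#'   set must equal the alignment's taxa (the symmetric difference is
#'   reported otherwise).
#' @return A \code{\linkS4class{LabeledTree}}.
#' @export
readLabeledTree <- function(path, categories = list(), focal = list(),
                            alignment = NULL) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file: ", path)
  parsed <- .parsePamlLabels(phy)
  tr <- labeledTree(parsed$phy, categories = categories, focal = focal,
                    pamlCategory = parsed$label)
  if (!is.null(alignment)) checkTreeAlignment(tr, alignment)
  tr
}

#' Validate that tree leaves and alignment taxa coincide
#' @param tree a \code{LabeledTree}.
#' @param aln a \code{CodonAlignment}.
#' @export
checkTreeAlignment <- function(tree, aln) {
  tl <- tree@phylo$tip.label
  ta <- taxa(aln)
  extraT <- setdiff(tl, ta)
  extraA <- setdiff(ta, tl)
  if (length(extraT) || length(extraA))
    stop("tree/alignment taxon mismatch; only in tree: {",
         paste(extraT, collapse = ", "), "}; only in alignment: {",
         paste(extraA, collapse = ", "), "}")
  invisible(TRUE)
}

#' Collapse the 5-category habitat partition for the branch-model ladder
#'
#' \code{"five"} keeps \{background, high-altitude, cave, fully-aquatic,
#' semi-aquatic\}; \code{"three"} merges the terrestrial pair and the aquatic
#' pair into \{background, terrestrial, aquatic\}; \code{"two"} merges all
#' hypoxia-tolerant categories into \{background, hypoxic\}; \code{"one"}
#' collapses everything to background. Idempotent and order-independent:
#' collapsing five -> three -> two equals five -> two.
#'
#' @param tree a \code{LabeledTree}.
#' @param level "five", "three", "two" or "one".
#' @return A \code{LabeledTree} with collapsed edge categories.
#' @export
collapseCategories <- function(tree, level = c("five", "three", "two", "one")) {
  level <- match.arg(level)
  cat <- tree@category
  terrestrial <- c("high-altitude", "cave", "terrestrial")
  aquatic <- c("fully-aquatic", "semi-aquatic", "aquatic")
  newcat <- switch(level,
    five = cat,
    three = ifelse(cat %in% terrestrial, "terrestrial",
            ifelse(cat %in% aquatic, "aquatic", cat)),
    two = ifelse(cat == "background", "background", "hypoxic"),
    one = rep("background", length(cat)))
  initialize(tree, category = newcat)
}

#' Branch categories per edge
#' @param tree a \code{LabeledTree}.
#' @export
branchCategories <- function(tree) tree@category

#' Named focal branches (child node ids)
#' @param tree a \code{LabeledTree}.
#' @export
focalBranches <- function(tree) tree@focal

#' Human-readable branch label for an edge (tip name, or smallest enclosed
#' tip pair for internal branches)
#' @param tree a \code{LabeledTree}.
#' @param node child node id of the branch.
#' @export
branchLabel <- function(tree, node) {
  phy <- tree@phylo
  ntip <- ape::Ntip(phy)
  vapply(node, function(nd) {
    if (nd <= ntip) return(phy$tip.label[nd])
    tips <- phy$tip.label[intersect(.nodeDescendants(phy, nd), seq_len(ntip))]
    paste0("mrca(", tips[1L], ",", tips[length(tips)], ")")
  }, character(1L))
}

## all descendant nodes of `node` (excluding itself)
.nodeDescendants <- function(phy, node) {
  desc <- integer(0)
  queue <- node
  repeat {
    kids <- phy$edge[phy$edge[, 1L] %in% queue, 2L]
    if (!length(kids)) break
    desc <- c(desc, kids)
    queue <- kids
  }
  desc
}

## TRUE if a is an ancestor of b (or vice versa)
.isAncestorPair <- function(phy, a, b) {
  b %in% .nodeDescendants(phy, a) || a %in% .nodeDescendants(phy, b)
}
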