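## Shared fixtures: habitat-labeled trees and simulated alignments.

## deterministic habitat-labeled tree: consecutive tip pairs form cherries
## (so the focal tips t1/t3/t5 always sit in disjoint parent subtrees), a
## balanced topology above them, and seeded branch lengths
balancedClades <- function(parts) {
  if (length(parts) == 1L) return(parts)
  k <- ceiling(length(parts) / 2)
  paste0("(", balancedClades(parts[seq_len(k)]), ",",
         balancedClades(parts[-seq_len(k)]), ")")
}

habitatTree <- function(ntaxa = 8L, seed = 1L, minLen = 0.05, maxLen = 0.3) {
  stopifnot(ntaxa >= 8L, ntaxa %% 2L == 0L)
  labs <- paste0("t", seq_len(ntaxa))
  pairs <- vapply(seq_len(ntaxa / 2L), function(i)
    paste0("(", labs[2L * i - 1L], ",", labs[2L * i], ")"), character(1L))
  phy <- ape::read.tree(text = paste0(balancedClades(pairs), ";"))
  set.seed(seed)
  phy$edge.length <- stats::runif(nrow(phy$edge), minLen, maxLen)
  labeledTree(phy,
              categories = list("high-altitude" = "t1", "cave" = "t3",
                                "fully-aquatic" = "t5",
                                "semi-aquatic" = "t7"),
              focal = list(a = "t1", b = "t3", c = "t5"))
}

## habitat tree whose categories cover whole 2-tip clades (stem included),
## giving each omega slot enough branch length for recovery studies
cladeHabitatTree <- function(ntaxa = 12L, seed = 1L, minLen = 0.05,
                             maxLen = 0.3) {
  stopifnot(ntaxa >= 8L, ntaxa %% 2L == 0L)
  labs <- paste0("t", seq_len(ntaxa))
  pairs <- vapply(seq_len(ntaxa / 2L), function(i)
    paste0("(", labs[2L * i - 1L], ",", labs[2L * i], ")"), character(1L))
  phy <- ape::read.tree(text = paste0(balancedClades(pairs), ";"))
  set.seed(seed)
  phy$edge.length <- stats::runif(nrow(phy$edge), minLen, maxLen)
  labeledTree(phy,
              categories = list("high-altitude" = c("t1", "t2"),
                                "cave" = c("t3", "t4"),
                                "fully-aquatic" = c("t5", "t6"),
                                "semi-aquatic" = c("t7", "t8")),
              focal = list(a = c("t1", "t2"), b = c("t3", "t4"),
                           c = c("t5", "t6")))
}

## 24-taxon tree whose four habitat categories each cover a 4-tip clade
## (7 edges, ~2.4 substitutions/codon of category branch length), sized for
## multi-ratio slot recovery
recoveryHabitatTree <- function(seed = 1L, minLen = 0.05, maxLen = 0.3) {
  blk <- function(a) sprintf("((t%d:1,t%d:1):1,(t%d:1,t%d:1):1):1",
                             a, a + 1L, a + 2L, a + 3L)
  txt <- sprintf("(((%s,%s):1,(%s,%s):1):1,((%s,%s):1):1);",
                 blk(1L), blk(5L), blk(9L), blk(13L), blk(17L), blk(21L))
  phy <- ape::read.tree(text = txt)
  set.seed(seed)
  phy$edge.length <- stats::runif(nrow(phy$edge), minLen, maxLen)
  labeledTree(phy,
              categories = list("high-altitude" = c("t1", "t4"),
                                "cave" = c("t5", "t8"),
                                "fully-aquatic" = c("t9", "t12"),
                                "semi-aquatic" = c("t13", "t16")))
}

## plain background-only tree
plainTree <- function(ntaxa, seed, minLen = 0.03, maxLen = 0.25) {
  set.seed(seed)
  phy <- ape::rtree(ntaxa)
  phy$edge.length <- stats::runif(nrow(phy$edge), minLen, maxLen)
  labeledTree(phy)
}

## concatenate codon alignments column-wise (same taxa)
concatAlignments <- function(a, b) {
  stopifnot(identical(taxa(a), taxa(b)))
  new("CodonAlignment", states = cbind(codonStates(a), codonStates(b)),
      geneticCode = "standard")
}

quietFit <- function(expr) suppressWarnings(expr)

## fixture for forced-event recovery: each focal branch's parent keeps two
## independent supporting lineages, so the forced ancestral states stay
## identifiable under marginal reconstruction
convergenceFixtureTree <- function(seed = 1L) {
  txt <- paste0("((((a1:0.1,m1:0.1,m2:0.1):0.15,",
                "(c1:0.1,n1:0.1,n2:0.1):0.15):0.1,",
                "(o1:0.12,o2:0.12):0.2):0.08,(o3:0.12,o4:0.12):0.2);")
  phy <- ape::read.tree(text = txt)
  labeledTree(phy,
              categories = list("high-altitude" = "a1", "cave" = "c1"),
              focal = list(a = "a1", c = "c1", estN = c("c1", "n1")))
}
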