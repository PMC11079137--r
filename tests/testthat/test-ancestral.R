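test_that("marginal reconstruction matches exhaustive Bayes on a 3-taxon toy", {
  tr <- labeledTree(ape::read.tree(text = "((A:0.15,B:0.2):0.1,C:0.3);"))
  aln <- codonAlignment(c(A = "ATGGCT", B = "ATGGCA", C = "CTGGCT"))
  pi <- codonFrequencies(aln, "F3x4")
  fit <- quietFit(fitM0(aln, tr, fitOptions(seed = 1, restarts = 1,
                                            maxRounds = 2L,
                                            branchLengths = "fixed")))
  rec <- reconstructAncestors(aln, tr, fit, mode = "codon")
  ## independent enumeration: root node (5) and inner node (6)
  Q <- oracleQ(fit@kappa, fit@omega[["omega"]], fit@pi@pi)
  phy <- tr@phylo
  Pe <- lapply(fit@branchLengths, function(t) as.matrix(Matrix::expm(Q * t)))
  st <- codonStates(aln)[phy$tip.label, ]
  edge <- phy$edge
  tab <- codonTable()
  for (s in 1:2) {
    joint <- matrix(0, 61, 61)  # root x inner
    for (r in 1:61) for (u in 1:61) {
      pr <- fit@pi@pi[r]
      for (e in seq_len(nrow(edge))) {
        pa <- c(NA, NA, NA, r, u)[edge[e, 1L]]
        ch <- edge[e, 2L]
        pr <- pr * if (ch <= 3) Pe[[e]][pa, st[ch, s]]
          else Pe[[e]][pa, u]
      }
      joint[r, u] <- pr
    }
    pRoot <- rowSums(joint) / sum(joint)
    pInner <- colSums(joint) / sum(joint)
    A <- matrix(0, 61, 20); A[cbind(1:61, tab$aaIndex)] <- 1
    expect_equal(unname(rec@aaPosterior[["4"]][, s]),
                 unname(as.numeric(crossprod(A, pRoot))), tolerance = 1e-6)
    expect_equal(unname(rec@aaPosterior[["5"]][, s]),
                 unname(as.numeric(crossprod(A, pInner))), tolerance = 1e-6)
  }
  ## posteriors are proper
  for (m in rec@aaPosterior)
    expect_lt(max(abs(colSums(m) - 1)), 1e-8)
})

test_that("concordant leaves dominate the root posterior", {
  tr <- labeledTree(ape::read.tree(text = "(A:0.2,B:0.25);"))
  aln <- codonAlignment(c(A = "TGG", B = "TGG"))   # Trp, single codon
  pu <- new("CodonFrequencies", pi = rep(1 / 61, 61), scheme = "uniform")
  fit <- quietFit(fitM0(aln, tr, fitOptions(seed = 1, restarts = 1,
                                            maxRounds = 2L,
                                            branchLengths = "fixed"),
                        pi = pu))
  rec <- reconstructAncestors(aln, tr, fit)
  w <- match("W", rec@aaLevels)
  root <- ape::Ntip(tr@phylo) + 1L
  expect_equal(rec@map[root, 1L], w)
  piW <- sum(pu@pi[codonTable()$aa == "W"])
  expect_gt(rec@aaPosterior[[as.character(root)]][w, 1L], piW)
  ## parent and child reconstruct identically: no substitution events
  expect_equal(nrow(branchSubstitutions(rec, "A")), 0L)
})

test_that("branch substitutions recover planted events", {
  tr <- habitatTree(8L, seed = 15L)
  fe <- data.frame(branch = "a", site = 7L, fromAA = "T", toAA = "S")
  sim <- simulateConvergenceScenario(tr, 80L, fe, kappa = 2.5,
                                     omega = 0.1, seed = 55)
  fit <- quietFit(fitM0(sim$alignment, tr, fitOptions(seed = 1,
                                                      restarts = 1)))
  rec <- reconstructAncestors(sim$alignment, tr, fit)
  ev <- branchSubstitutions(rec, "a")
  hit <- ev[ev$site == 7L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$fromAA, "T")
  expect_equal(hit$toAA, "S")
})

test_that("amino-acid mode reconstruction is available and recorded", {
  tr <- plainTree(6L, seed = 18L)
  sim <- simulateAlignment(tr, 60L, kappa = 2, omega = 0.2, seed = 9)
  fit <- quietFit(fitM0(sim$alignment, tr, fitOptions(seed = 1,
                                                      restarts = 1)))
  rec <- reconstructAncestors(sim$alignment, tr, fit, mode = "aa")
  expect_equal(rec@mode, "aa")
  for (m in rec@aaPosterior)
    expect_lt(max(abs(colSums(m) - 1)), 1e-8)
  ## codon and aa modes agree on clear MAP states most of the time
  recC <- reconstructAncestors(sim$alignment, tr, fit, mode = "codon")
  root <- ape::Ntip(tr@phylo) + 1L
  agree <- mean(rec@map[root, ] == recC@map[root, ])
  expect_gt(agree, 0.8)
})
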