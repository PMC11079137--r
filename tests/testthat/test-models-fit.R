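test_that("parameter counts follow the rooted-tree convention", {
  set.seed(1)
  phy <- ape::rtree(43L)
  phy$edge.length <- runif(nrow(phy$edge), 0.05, 0.2)
  tips <- phy$tip.label
  tr <- labeledTree(phy, categories = list(
    "high-altitude" = tips[1L], "cave" = tips[2L],
    "fully-aquatic" = tips[3L], "semi-aquatic" = tips[4L]))
  np <- function(spec, tree) hypoxsel:::.modelNp(spec, tree)
  t1 <- collapseCategories(tr, "one")
  t2 <- collapseCategories(tr, "two")
  t3 <- collapseCategories(tr, "three")
  nps <- c(np(modelSpec("one_ratio"), t1),
           np(modelSpec("multi_ratio", tree = t2), t2),
           np(modelSpec("multi_ratio", tree = t3), t3),
           np(modelSpec("multi_ratio", tree = tr), tr))
  expect_equal(nps, c(86L, 87L, 88L, 90L))
  ## free-ratio: np(1-ratio) + (number of branches - 1)
  expect_equal(np(modelSpec("free_ratio"), tr),
               86L + nrow(phy$edge) - 1L)
  expect_equal(np(modelSpec("M8"), tr), nrow(phy$edge) + 5L)
  expect_equal(np(modelSpec("M8a"), tr), nrow(phy$edge) + 4L)
})

test_that("model specs validate their structure", {
  tr <- habitatTree(8L, seed = 2L)
  expect_error(modelSpec("multi_ratio"), "tree")
  expect_error(modelSpec("branch_site_A", tree = tr, foreground = "zzz"),
               "unknown focal")
  expect_error(modelSpec("branch_site_A", tree = tr,
                         foreground = character(0)), "nonempty")
  ## foreground = all branches is rejected
  allNodes <- tr@phylo$edge[, 2L]
  expect_error(modelSpec("branch_site_A", tree = tr, foreground = allNodes),
               "proper subset")
  sp <- modelSpec("multi_ratio", tree = tr)
  expect_equal(sort(hypoxsel:::.slotNames(sp)),
               sort(unique(branchCategories(tr))))
})

test_that("beta discretization reproduces closed-form category means", {
  ## symmetric Beta(1,1): category means are bin midpoints
  expect_equal(betaCategoryMeans(1, 1, 10L),
               seq(0.05, 0.95, by = 0.1), tolerance = 1e-10)
  ## mean of the category means equals the distribution mean
  for (pq in list(c(0.5, 2), c(2, 3), c(5, 1))) {
    m <- betaCategoryMeans(pq[1L], pq[2L], 10L)
    expect_equal(mean(m), pq[1L] / sum(pq), tolerance = 1e-6)
    expect_true(!is.unsorted(m))
  }
})

test_that("M0 and multi-ratio fits recover generating parameters", {
  tr <- habitatTree(10L, seed = 6L, minLen = 0.05, maxLen = 0.3)
  sim <- simulateAlignment(tr, 250L, kappa = 2.5, omega = 0.25, seed = 17)
  fit <- quietFit(fitM0(sim$alignment, tr, fitOptions(seed = 1,
                                                      restarts = 2)))
  expect_true(abs(fit@omega[["omega"]] - 0.25) < 0.08)
  expect_true(abs(fit@kappa - 2.5) < 0.8)
  expect_equal(sum(fit@perSiteLnL), fit@lnL, tolerance = 1e-6)

  ## two-ratio recovery: hypoxic omega 0.5 vs background 0.1
  t2 <- collapseCategories(tr, "two")
  sim2 <- simulateAlignment(t2, 300L, kappa = 2.5,
                            omega = c(background = 0.1, hypoxic = 0.5),
                            seed = 23)
  f2 <- quietFit(fitModel(sim2$alignment, t2,
                          modelSpec("multi_ratio", tree = t2),
                          fitOptions(seed = 2, restarts = 2)))
  expect_true(abs(f2@omega[["background"]] - 0.1) < 0.1)
  expect_true(abs(f2@omega[["hypoxic"]] - 0.5) < 0.2)
  expect_gt(f2@lnL,
            quietFit(fitM0(sim2$alignment, t2,
                           fitOptions(seed = 2, restarts = 1)))@lnL - 1e-4)
})

test_that("identical sequences give a flagged boundary fit", {
  tr <- plainTree(5L, seed = 9L)
  aln <- codonAlignment(setNames(rep("ATGGCTAAGCCT", 5L),
                                 tr@phylo$tip.label))
  fit <- quietFit(fitM0(aln, tr, fitOptions(seed = 1, restarts = 1,
                                            maxRounds = 3L)))
  expect_true(all(fit@branchLengths < 1e-6))
  expect_true(length(fit@diagnostics$boundary) > 0)
})

test_that("fits are invariant to taxon order permutation", {
  tr <- plainTree(6L, seed = 12L)
  sim <- simulateAlignment(tr, 120L, kappa = 2, omega = 0.3, seed = 31)
  st <- codonStates(sim$alignment)
  perm <- new("CodonAlignment", states = st[rev(seq_len(nrow(st))), ],
              geneticCode = "standard")
  f1 <- quietFit(fitM0(sim$alignment, tr, fitOptions(seed = 3,
                                                     restarts = 1)))
  f2 <- quietFit(fitM0(perm, tr, fitOptions(seed = 3, restarts = 1)))
  expect_equal(f1@lnL, f2@lnL, tolerance = 1e-4)
  expect_equal(f1@omega[["omega"]], f2@omega[["omega"]], tolerance = 1e-3)
})

test_that("nested model pairs keep lnL ordered and LRTs well-formed", {
  tr <- habitatTree(8L, seed = 4L)
  sim <- simulateAlignment(tr, 150L, kappa = 2.5, omega = 0.2, seed = 19)
  lad <- quietFit(runBranchModelLadder(sim$alignment, tr,
                                       fitOptions(seed = 5, restarts = 1),
                                       gene = "SIM"))
  expect_true(lad$fits$w2@lnL >= lad$fits$w1@lnL - 1e-4)
  expect_true(lad$fits$w3@lnL >= lad$fits$w2@lnL - 1e-4)
  expect_true(lad$fits$w5@lnL >= lad$fits$w3@lnL - 1e-4)
  expect_equal(vapply(lad$lrts, function(x) x@df, integer(1L)),
               c(w2_vs_w1 = 1L, w3_vs_w2 = 1L, w5_vs_w3 = 2L))
  expect_identical(colnames(lad$report),
                   c("Genes", "Model", "minus_lnL", "np", "LRT",
                     "Comparisons", "p_value", "omega_non_hypoxia",
                     "omega_terrestrial", "omega_aquatic"))

  sm <- quietFit(fitSiteModels(sim$alignment, tr,
                               fitOptions(seed = 5, restarts = 1,
                                          branchLengths = "m0",
                                          m0Fit = lad$fits$w1)))
  expect_true(sm$m8@lnL >= sm$m8a@lnL - 1e-6)
  expect_equal(sm$lrt@df, 1L)

  bs <- quietFit(fitBranchSite(sim$alignment, tr, "a",
                               fitOptions(seed = 5, restarts = 1,
                                          branchLengths = "m0",
                                          m0Fit = lad$fits$w1)))
  expect_true(bs$alt@lnL >= bs$null@lnL - 1e-6)
  expect_equal(bs$lrt@df, 1L)
})
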