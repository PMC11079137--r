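test_that("simulation is deterministic and respects degenerate lengths", {
  tr <- habitatTree(8L, seed = 2L)
  s1 <- simulateAlignment(tr, 50L, kappa = 2, omega = 0.3, seed = 7)
  s2 <- simulateAlignment(tr, 50L, kappa = 2, omega = 0.3, seed = 7)
  expect_identical(codonStates(s1$alignment), codonStates(s2$alignment))
  s3 <- simulateAlignment(tr, 50L, kappa = 2, omega = 0.3, seed = 8)
  expect_false(identical(codonStates(s1$alignment),
                         codonStates(s3$alignment)))
  expect_equal(s1$truth$seed, 7)

  ## zero branch lengths: all taxa identical to the root
  tr0 <- tr
  tr0@phylo$edge.length[] <- 0
  s0 <- simulateAlignment(tr0, 30L, kappa = 2, omega = 0.3, seed = 1)
  st <- codonStates(s0$alignment)
  expect_true(all(apply(st, 2L, function(x) length(unique(x)) == 1L)))
  root <- ape::Ntip(tr@phylo) + 1L
  expect_identical(unname(st[1L, ]), s0$truth$nodeStates[root, ])
})

test_that("long simulations reproduce the stationary codon frequencies", {
  tr <- plainTree(6L, seed = 5L, minLen = 0.1, maxLen = 0.3)
  pi <- defaultCodonFrequencies()
  sim <- simulateAlignment(tr, 10000L, kappa = 2.5, omega = 0.2, pi = pi,
                           seed = 42)
  emp <- tabulate(codonStates(sim$alignment), 61L)
  emp <- emp / sum(emp)
  expect_lt(max(abs(emp - pi@pi)), 0.01)
})

test_that("recorded substitution events track branch length", {
  tr <- plainTree(8L, seed = 16L, minLen = 0.02, maxLen = 0.4)
  sim <- simulateAlignment(tr, 1500L, kappa = 2.5, omega = 0.3,
                           seed = 11, recordEvents = TRUE)
  ev <- sim$truth$events
  expect_true(all(ev$fromCodon != ev$toCodon))
  counts <- tabulate(ev$edge, nrow(tr@phylo$edge))
  expect_gt(cor(counts, tr@phylo$edge.length, method = "spearman"), 0.9)
  ## endpoint states are consistent with the recorded event chains
  ns <- sim$truth$nodeStates
  edge <- tr@phylo$edge
  for (e in sample(seq_len(nrow(edge)), 5L)) {
    sites <- ev$site[ev$edge == e]
    for (s in unique(sites)) {
      chain <- ev[ev$edge == e & ev$site == s, ]
      expect_equal(chain$fromCodon[1L], ns[edge[e, 1L], s])
      expect_equal(chain$toCodon[nrow(chain)], ns[edge[e, 2L], s])
    }
  }
})

test_that("forced events overwrite end states and build truth tables", {
  tr <- habitatTree(8L, seed = 9L)
  fe <- data.frame(branch = c("a", "b"), site = c(4L, 4L),
                   fromAA = c("A", "A"), toAA = c("S", "S"))
  sim <- simulateConvergenceScenario(tr, 40L, fe, seed = 21)
  tab <- codonTable()
  foc <- focalBranches(tr)
  expect_equal(tab$aa[sim$truth$nodeStates[foc[["a"]], 4L]], "S")
  expect_equal(tab$aa[sim$truth$nodeStates[foc[["b"]], 4L]], "S")
  expect_equal(sim$truth$pairs$type, "parallel")
  expect_equal(sim$truth$pairs$site, 4L)

  ## mirrored convergent pattern
  fe2 <- data.frame(branch = c("a", "b"), site = c(9L, 9L),
                    fromAA = c("T", "N"), toAA = c("S", "S"))
  sim2 <- simulateConvergenceScenario(tr, 40L, fe2, seed = 22)
  expect_equal(sim2$truth$pairs$type, "convergent")

  ## neutral scenario: no forced events, empty truth
  sim3 <- simulateConvergenceScenario(tr, 40L, fe[0, ], seed = 23)
  expect_equal(nrow(sim3$truth$pairs), 0L)

  ## duplicated (branch, site) forcing is a conflict
  feBad <- data.frame(branch = c("a", "a"), site = c(4L, 4L),
                      fromAA = c("A", "A"), toAA = c("S", "G"))
  expect_error(simulateAlignment(tr, 40L, kappa = 2, omega = 0.2,
                                 seed = 1, forcedEvents = feBad),
               "conflict")
})

test_that("fitting a generating model to its simulation recovers truth", {
  tr <- habitatTree(8L, seed = 25L, minLen = 0.08, maxLen = 0.3)
  sim <- simulateAlignment(tr, 400L, kappa = 3, omega = 0.15, seed = 33)
  fit <- quietFit(fitM0(sim$alignment, tr, fitOptions(seed = 4,
                                                      restarts = 2)))
  expect_lt(abs(fit@omega[["omega"]] - 0.15), 0.05)
  expect_lt(abs(fit@kappa - 3), 1)
  ## fitted branch lengths correlate with the generating ones
  expect_gt(cor(fit@branchLengths, tr@phylo$edge.length), 0.8)
})
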