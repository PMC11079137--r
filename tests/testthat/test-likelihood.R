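test_that("pruning equals the closed form on degenerate trees", {
  pu <- new("CodonFrequencies", pi = rep(1 / 61, 61), scheme = "uniform")
  ## two concordant taxa at one codon: L = sum_r pi_r P1[r,c] P2[r,c]
  tr <- labeledTree(ape::read.tree(text = "(A:0.1,B:0.2);"))
  aln <- codonAlignment(c(A = "ATG", B = "ATG"))
  Q <- buildRateMatrix(2, 0.5, pu)
  ic <- match("ATG", codonTable()$codons)
  Lexp <- sum(pu@pi * transitionProbabilities(Q, 0.1, pu)[, ic] *
                transitionProbabilities(Q, 0.2, pu)[, ic])
  ll <- alignmentLogLikelihood(aln, tr, kappa = 2, omega = 0.5, pi = pu)
  expect_equal(ll$lnL, log(Lexp), tolerance = 1e-10)
  ## a fully missing taxon contributes nothing
  aln2 <- codonAlignment(c(A = "ATG", B = "NNN"))
  ll2 <- alignmentLogLikelihood(aln2, tr, kappa = 2, omega = 0.5, pi = pu)
  expect_equal(ll2$lnL, log(sum(pu@pi *
    transitionProbabilities(Q, 0.1, pu)[, ic])), tolerance = 1e-10)
})

test_that("pruning matches exhaustive enumeration on small random draws", {
  set.seed(31)
  for (rep in 1:5) {
    tr <- plainTree(4L, seed = 100 + rep)
    sim <- simulateAlignment(tr, 3L, kappa = runif(1, 1, 4),
                             omega = runif(1, 0.05, 1.5), seed = 200 + rep)
    k <- runif(1, 0.8, 4); w <- runif(1, 0.05, 1.2)
    pi <- codonFrequencies(sim$alignment, "F3x4")
    ll <- alignmentLogLikelihood(sim$alignment, tr, kappa = k, omega = w,
                                 pi = pi)
    expect_equal(ll$lnL, oracleLogLik(sim$alignment, tr, k, w, pi@pi),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to re-rooting and sums per site", {
  tr <- habitatTree(8L, seed = 21L)
  sim <- simulateAlignment(tr, 60L, kappa = 2, omega = 0.3, seed = 5)
  pi <- codonFrequencies(sim$alignment)
  ll <- alignmentLogLikelihood(sim$alignment, tr, kappa = 2.2, omega = 0.25,
                               pi = pi)
  expect_equal(sum(ll$perSite), ll$lnL, tolerance = 1e-8)
  ## re-root on several branches: lnL unchanged (reversibility)
  phy <- tr@phylo
  for (og in c(1L, 4L, 6L)) {
    re <- ape::root(phy, outgroup = og, resolve.root = TRUE)
    llr <- alignmentLogLikelihood(sim$alignment, labeledTree(re),
                                  kappa = 2.2, omega = 0.25, pi = pi)
    expect_equal(llr$lnL, ll$lnL, tolerance = 1e-8)
  }
})

test_that("analytic branch-length gradients match central differences", {
  tr <- habitatTree(8L, seed = 13L)
  sim <- simulateAlignment(tr, 80L, kappa = 2.5, omega = 0.2, seed = 8)
  eng <- hypoxsel:::.engine(sim$alignment, tr)
  pi <- codonFrequencies(sim$alignment)@pi
  blen <- tr@phylo$edge.length
  nE <- length(blen)
  ## a two-class mixture exercises the class-weighted gradient
  cl <- list(list(prop = 0.8, omegaEdge = rep(0.1, nE)),
             list(prop = 0.2, omegaEdge = rep(1.5, nE)))
  res <- hypoxsel:::.classLogLik(eng, 2.5, pi, blen, cl, wantGrad = TRUE)
  h <- 1e-5
  for (e in c(1L, nE %/% 2L, nE)) {
    b2 <- blen; b2[e] <- b2[e] + h
    b3 <- blen; b3[e] <- b3[e] - h
    fd <- (hypoxsel:::.classLogLik(eng, 2.5, pi, b2, cl)$lnL -
             hypoxsel:::.classLogLik(eng, 2.5, pi, b3, cl)$lnL) / (2 * h)
    expect_equal(res$grad[e], fd, tolerance = 1e-5)
  }
})

test_that("site-class mixtures mix per-site likelihoods before logging", {
  tr <- plainTree(5L, seed = 3L)
  sim <- simulateAlignment(tr, 40L, kappa = 2, omega = 0.2, seed = 4)
  pi <- codonFrequencies(sim$alignment)
  ## classes sharing one omega collapse exactly to the one-ratio model,
  ## whatever the proportions (the common rate scaling cancels)
  pure <- alignmentLogLikelihood(sim$alignment, tr, 2, omega = 0.3,
                                 pi = pi)
  mix0 <- alignmentLogLikelihood(sim$alignment, tr, 2, pi = pi,
                                 siteClasses = list(
                                   list(prop = 0.6, omega = 0.3),
                                   list(prop = 0.4, omega = 0.3)))
  expect_equal(mix0$lnL, pure$lnL, tolerance = 1e-9)

  ## white box: the mixture equals the proportion-weighted average of the
  ## per-class (commonly scaled) site likelihoods
  eng <- hypoxsel:::.engine(sim$alignment, tr)
  nE <- nrow(tr@phylo$edge)
  cl <- list(list(prop = 0.7, omegaEdge = rep(0.1, nE)),
             list(prop = 0.3, omegaEdge = rep(2, nE)))
  res <- hypoxsel:::.classLogLik(eng, 2, pi@pi, tr@phylo$edge.length, cl)
  manual <- log(0.7 * exp(res$logLmat[1L, ]) +
                  0.3 * exp(res$logLmat[2L, ]))
  expect_equal(res$logLpat, manual, tolerance = 1e-8)
  ## per pattern, the mixture cannot exceed the best pure class
  expect_true(all(res$logLpat <=
                    pmax(res$logLmat[1L, ], res$logLmat[2L, ]) + 1e-9))
  ## the omega = 2 class runs genuinely faster than the omega = 0.1 class
  ## under the shared scaling
  cs <- hypoxsel:::.classScale(2, pi@pi, cl)
  expect_gt(cs$rateMat[2L, 1L], cs$rateMat[1L, 1L])
})
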