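## The study's model menus: the habitat multi-ratio ladder, the M8/M8a site
## test and the branch-site test, each with its nested LRT.

.table1Columns <- c("Genes", "Model", "minus_lnL", "np", "LRT", "Comparisons",
                    "p_value", "omega_non_hypoxia", "omega_terrestrial",
                    "omega_aquatic")

#' Fit the habitat branch-model ladder (1-, 2-, 3-, 5-ratio)
#'
#' Fits the one-ratio model and the multi-ratio models obtained by
#' collapsing the tree's 5-category habitat partition (\{background,
#' high-altitude, cave, fully-aquatic, semi-aquatic\} -> \{background,
#' terrestrial, aquatic\} -> \{background, hypoxic\}), and runs the nested
#' LRT ladder 2-vs-1 (df 1), 3-vs-2 (df 1) and 5-vs-3 (df 2).
#'
#' @param aln a \code{CodonAlignment}.
#' @param tree a \code{LabeledTree} carrying the 5-category habitat labels.
#' @param options \code{\link{fitOptions}}.
#' @param gene gene name used in the report.
#' @param pi codon frequencies.
#' @return list with \code{fits} (named: w1, w2, w3, w5), \code{lrts}
#'   (named: w2_vs_w1, w3_vs_w2, w5_vs_w3) and \code{report}, a data.frame
#'   shaped like the study's branch-model table (columns
#'   Genes/Model/minus_lnL/np/LRT/Comparisons/p_value plus the three omega
#'   group columns, 5-ratio entries as "high-altitude/cave" and
#'   "fully-aquatic/semi-aquatic" pairs).
#' @export
runBranchModelLadder <- function(aln, tree, options = fitOptions(),
                                 gene = "gene", pi = codonFrequencies(aln)) {
  levels_ <- c(w1 = "one", w2 = "two", w3 = "three", w5 = "five")
  trees <- lapply(levels_, function(lv) collapseCategories(tree, lv))
  ncats <- vapply(trees, function(tr)
    length(unique(branchCategories(tr))), integer(1L))
  if (!(ncats[["w2"]] == 2L && ncats[["w3"]] == 3L && ncats[["w5"]] == 5L))
    stop("the 2/3/5-ratio ladder needs branches in all five habitat ",
         "categories (background, high-altitude, cave, fully-aquatic, ",
         "semi-aquatic); found ", ncats[["w5"]], " after collapse")
  fits <- list()
  opt1 <- options
  if (opt1$branchLengths == "m0" && is.null(opt1$m0Fit))
    opt1$branchLengths <- "estimate"
  fits$w1 <- fitModel(aln, trees$w1, modelSpec("one_ratio", label = "1ω"),
                      opt1, pi)
  if (options$branchLengths == "m0" && is.null(options$m0Fit))
    options$m0Fit <- fits$w1
  warm <- c(kappa = fits$w1@kappa)
  for (nm in c("w2", "w3", "w5")) {
    tr <- trees[[nm]]
    ncat <- length(unique(branchCategories(tr)))
    spec <- modelSpec("multi_ratio", tree = tr,
                      label = paste0(ncat, "ω"))
    st <- c(warm, stats::setNames(
      rep(unname(fits$w1@omega["omega"]), ncat),
      paste0("omega_", .slotNames(spec))))
    fits[[nm]] <- fitModel(aln, tr, spec, options, pi, start = st)
  }
  lrts <- list(
    w2_vs_w1 = likelihoodRatioTest(fits$w1, fits$w2, "2ω vs. 1ω"),
    w3_vs_w2 = likelihoodRatioTest(fits$w2, fits$w3, "3ω vs. 2ω"),
    w5_vs_w3 = likelihoodRatioTest(fits$w3, fits$w5, "5ω vs. 3ω"))
  fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.3f", x))
  om <- function(fit, cats) {
    v <- vapply(cats, function(cc)
      if (cc %in% names(fit@omega)) unname(fit@omega[[cc]]) else NA_real_,
      numeric(1L))
    paste(fmt(v), collapse = "/")
  }
  w1v <- fmt(unname(fits$w1@omega["omega"]))
  rows <- list(
    data.frame(Genes = gene, Model = "1ω",
               minus_lnL = -fits$w1@lnL, np = fits$w1@np,
               LRT = NA_real_, Comparisons = NA_character_,
               p_value = NA_real_, omega_non_hypoxia = w1v,
               omega_terrestrial = w1v, omega_aquatic = w1v),
    data.frame(Genes = gene, Model = "2ω",
               minus_lnL = -fits$w2@lnL, np = fits$w2@np,
               LRT = lrts$w2_vs_w1@stat, Comparisons = "2ω vs. 1ω",
               p_value = lrts$w2_vs_w1@p,
               omega_non_hypoxia = om(fits$w2, "background"),
               omega_terrestrial = om(fits$w2, "hypoxic"),
               omega_aquatic = om(fits$w2, "hypoxic")),
    data.frame(Genes = gene, Model = "3ω",
               minus_lnL = -fits$w3@lnL, np = fits$w3@np,
               LRT = lrts$w3_vs_w2@stat, Comparisons = "3ω vs. 2ω",
               p_value = lrts$w3_vs_w2@p,
               omega_non_hypoxia = om(fits$w3, "background"),
               omega_terrestrial = om(fits$w3, "terrestrial"),
               omega_aquatic = om(fits$w3, "aquatic")),
    data.frame(Genes = gene, Model = "5ω",
               minus_lnL = -fits$w5@lnL, np = fits$w5@np,
               LRT = lrts$w5_vs_w3@stat, Comparisons = "5ω vs. 3ω",
               p_value = lrts$w5_vs_w3@p,
               omega_non_hypoxia = om(fits$w5, "background"),
               omega_terrestrial = om(fits$w5, c("high-altitude", "cave")),
               omega_aquatic = om(fits$w5,
                                  c("fully-aquatic", "semi-aquatic"))))
  report <- do.call(rbind, rows)[, .table1Columns]
  list(fits = fits, lrts = lrts, report = report)
}

#' Fit the M8/M8a site-model pair and test for positively selected sites
#'
#' M8 mixes 10 equal-probability categories of a discretized Beta(p, q) over
#' omega in (0,1) with an extra class at omega_s >= 1 (proportion 1 - p0);
#' M8a fixes omega_s = 1. The LRT has df 1 (plain chi-square by default,
#' matching the study's usage).
#'
#' @inheritParams runBranchModelLadder
#' @return list(m8a, m8, lrt).
#' @export
fitSiteModels <- function(aln, tree, options = fitOptions(),
                          pi = codonFrequencies(aln)) {
  m8a <- fitModel(aln, tree, modelSpec("M8a"), options, pi)
  warm <- c(kappa = m8a@kappa, p0 = m8a@classParams$p0,
            p = m8a@classParams$p, q = m8a@classParams$q, ws = 1.5)
  m8 <- fitModel(aln, tree, modelSpec("M8"), options, pi, start = warm)
  if (m8@lnL < m8a@lnL - 1e-6) {
    ## the null is nested at the omega_s = 1 boundary: restart there
    warm["ws"] <- 1 + 1e-6
    m8b <- fitModel(aln, tree, modelSpec("M8"), options, pi, start = warm)
    if (m8b@lnL > m8@lnL) m8 <- m8b
  }
  lrt <- likelihoodRatioTest(m8a, m8, "M8 vs. M8a")
  list(m8a = m8a, m8 = m8, lrt = lrt)
}

#' Fit the branch-site model A and its null on a foreground branch set
#'
#' Model A allows omega_2 >= 1 on the foreground branches for a fraction of
#' sites (classes 2a/2b); the null fixes omega_2 = 1. LRT df 1.
#'
#' @inheritParams runBranchModelLadder
#' @param foreground focal branch name(s) or child node ids; must be a
#'   nonempty proper subset of the branches.
#' @return list(null, alt, lrt).
#' @export
fitBranchSite <- function(aln, tree, foreground, options = fitOptions(),
                          pi = codonFrequencies(aln)) {
  null <- fitModel(aln, tree,
                   modelSpec("branch_site_A_null", tree = tree,
                             foreground = foreground),
                   options, pi)
  warm <- c(kappa = null@kappa,
            a = null@classParams$p0 /
                (null@classParams$p0 + null@classParams$p1),
            b = null@classParams$p0 + null@classParams$p1,
            w0 = null@classParams$w0, w2 = 2)
  alt <- fitModel(aln, tree,
                  modelSpec("branch_site_A", tree = tree,
                            foreground = foreground),
                  options, pi, start = warm)
  if (alt@lnL < null@lnL - 1e-6) {
    warm["w2"] <- 1 + 1e-6
    alt2 <- fitModel(aln, tree,
                     modelSpec("branch_site_A", tree = tree,
                               foreground = foreground),
                     options, pi, start = warm)
    if (alt2@lnL > alt@lnL) alt <- alt2
  }
  lrt <- likelihoodRatioTest(null, alt, "Model A vs. null")
  list(null = null, alt = alt, lrt = lrt)
}
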