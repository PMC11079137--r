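## Study orchestration: run the full analysis menu over a set of gene
## alignments and emit the report tables.

#' Read and validate a study run configuration
#'
#' The YAML layout mirrors the study design: \code{genes} (name -> alignment
#' path), \code{tree} (Newick path), \code{categories} (habitat category ->
#' taxa), \code{focal} (focal branch name -> taxon/taxa), \code{analyses}
#' (subset of ladder, site, branch_site, convergence), \code{foregrounds}
#' (focal names for the branch-site scan), \code{pp_threshold} (default
#' 0.8), \code{alpha} (default 0.05), \code{seed}, \code{out_dir},
#' \code{reference_taxon} (optional, for dual site numbering).
#'
#' @param path YAML file, or a list with the same fields.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$genes) || length(cfg$genes) == 0L)
    stop("empty gene list in config")
  if (is.null(names(cfg$genes)) || any(!nzchar(names(cfg$genes))))
    stop("genes must be a named map: gene name -> alignment path")
  for (g in names(cfg$genes))
    if (is.character(cfg$genes[[g]]) && !file.exists(cfg$genes[[g]]))
      stop("alignment file not found for gene ", g, ": ", cfg$genes[[g]])
  if (is.character(cfg$tree) && !file.exists(cfg$tree))
    stop("tree file not found: ", cfg$tree)
  cfg$pp_threshold <- cfg$pp_threshold %||% 0.8
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$seed <- cfg$seed %||% 1L
  cfg$analyses <- cfg$analyses %||%
    c("ladder", "site", "branch_site", "convergence")
  if (cfg$pp_threshold <= 0.5 || cfg$pp_threshold >= 1)
    stop("pp_threshold must be in (0.5, 1)")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full selection/convergence study over a gene set
#'
#' Per gene: M0 and free-ratio fits with their LRT, the habitat branch-model
#' ladder, M8/M8a with BEB site calls, branch-site scans over the configured
#' foregrounds with BEB, and (across genes) the parallel/convergent
#' substitution scan over focal branch pairs. A failure in one gene's stage
#' is recorded and the run continues. All randomness derives from
#' \code{config$seed}; re-running with the same config reproduces every
#' number.
#'
#' @param config a \code{\link{readRunConfig}} result, a path to one, or an
#'   equivalent list. \code{genes} values may also be \code{CodonAlignment}
#'   objects and \code{tree} a \code{LabeledTree} directly.
#' @param options base \code{\link{fitOptions}}; the seed is overridden from
#'   the config.
#' @return list: \code{genes} (per-gene fits and tables), \code{table1}
#'   (branch-model report), \code{freeRatio} (M1-vs-M0 tests),
#'   \code{bebSites} (site-model BEB calls), \code{branchSite} (per
#'   gene x foreground LRT + site counts), \code{convergence}
#'   (sites + pairs), \code{summary}, \code{errors}. Written as TSVs to
#'   \code{config$out_dir} when set.
#' @export
runStudy <- function(config, options = fitOptions()) {
  cfg <- readRunConfig(config)
  options$seed <- cfg$seed
  tree <- if (is(cfg$tree, "LabeledTree")) cfg$tree
    else readLabeledTree(cfg$tree, categories = cfg$categories %||% list(),
                         focal = cfg$focal %||% list())
  alns <- lapply(cfg$genes, function(g)
    if (is(g, "CodonAlignment")) g else readCodonAlignment(g))
  geneNames <- names(alns)
  errors <- list()
  note <- function(gene, stage, e) {
    errors[[paste(gene, stage, sep = "/")]] <<- conditionMessage(e)
    message("gene ", gene, " stage ", stage, " failed: ",
            conditionMessage(e))
    NULL
  }
  genes <- list()
  table1 <- list(); freeRows <- list(); bebRows <- list(); bsRows <- list()
  m0fits <- list()
  for (g in geneNames) {
    aln <- alns[[g]]
    res <- list()
    res$m0 <- tryCatch(fitM0(aln, tree, options), error = function(e)
      note(g, "m0", e))
    if (is.null(res$m0)) { genes[[g]] <- res; next }
    m0fits[[g]] <- res$m0
    optM0 <- options; optM0$branchLengths <- "m0"; optM0$m0Fit <- res$m0

    res$freeRatio <- tryCatch({
      fr <- fitModel(aln, tree, modelSpec("free_ratio"), options)
      list(fit = fr, lrt = likelihoodRatioTest(res$m0, fr, "M1 vs. M0"))
    }, error = function(e) note(g, "free_ratio", e))
    if (!is.null(res$freeRatio))
      freeRows[[g]] <- data.frame(
        Genes = g, minus_lnL_M0 = -res$m0@lnL,
        minus_lnL_M1 = -res$freeRatio$fit@lnL,
        LRT = res$freeRatio$lrt@stat, df = res$freeRatio$lrt@df,
        p_value = res$freeRatio$lrt@p)

    if ("ladder" %in% cfg$analyses) {
      res$ladder <- tryCatch(
        runBranchModelLadder(aln, tree, options, gene = g),
        error = function(e) note(g, "ladder", e))
      if (!is.null(res$ladder)) table1[[g]] <- res$ladder$report
    }
    if ("site" %in% cfg$analyses) {
      res$siteModels <- tryCatch({
        sm <- fitSiteModels(aln, tree, optM0)
        post <- sitePosteriors(sm$m8, aln, tree, method = "BEB")
        cmap <- if (!is.null(cfg$reference_taxon))
          mapColumnsToReference(aln, cfg$reference_taxon) else NULL
        calls <- callSelectedSites(post, cfg$pp_threshold, cmap, aln)
        list(m8a = sm$m8a, m8 = sm$m8, lrt = sm$lrt, posteriors = post,
             calls = calls)
      }, error = function(e) note(g, "site", e))
      if (!is.null(res$siteModels) && nrow(res$siteModels$calls))
        bebRows[[g]] <- cbind(Genes = g, Model = "M8",
                              p_value = res$siteModels$lrt@p,
                              res$siteModels$calls)
    }
    if ("branch_site" %in% cfg$analyses && length(cfg$foregrounds)) {
      res$branchSite <- list()
      for (fgName in cfg$foregrounds) {
        bs <- tryCatch({
          b <- fitBranchSite(aln, tree, fgName, optM0)
          post <- sitePosteriors(b$alt, aln, tree, method = "BEB")
          calls <- callSelectedSites(post, cfg$pp_threshold)
          node <- focalBranches(tree)[[fgName]]
          eidx <- match(node, tree@phylo$edge[, 2L])
          list(fits = b, posteriors = post, calls = calls,
               category = branchCategories(tree)[eidx])
        }, error = function(e) note(g, paste0("branch_site:", fgName), e))
        res$branchSite[[fgName]] <- bs
        if (!is.null(bs))
          bsRows[[paste(g, fgName)]] <- data.frame(
            Genes = g, Foreground = fgName, Category = bs$category,
            LRT = bs$fits$lrt@stat, p_value = bs$fits$lrt@p,
            nSites = nrow(bs$calls),
            Sites = paste(bs$calls$site, collapse = ","))
      }
    }
    genes[[g]] <- res
  }

  convergence <- NULL
  if ("convergence" %in% cfg$analyses && length(focalBranches(tree)) >= 2L) {
    convergence <- tryCatch(
      runConvergenceScan(alns, tree, fits = m0fits, options = options),
      error = function(e) note("(all)", "convergence", e))
  }

  bind0 <- function(rows) if (length(rows)) do.call(rbind, rows) else NULL
  bsTab <- bind0(bsRows)
  out <- list(
    genes = genes,
    table1 = bind0(table1),
    freeRatio = bind0(freeRows),
    bebSites = bind0(bebRows),
    branchSite = bsTab,
    convergence = convergence,
    summary = studySummary(bsTab, convergence, alpha = cfg$alpha),
    errors = errors,
    config = cfg)
  if (!is.null(cfg$out_dir)) .writeStudyReports(out, cfg$out_dir)
  out
}

#' Summary arithmetic of a study
#'
#' From the branch-site table: the number of significant (positively
#' selected) foreground branches, their positively selected site total, the
#' subtotal on hypoxia-tolerant (non-background) branches, and that
#' subtotal's share of the total as a whole percent (half-up rounding).
#' From the convergence scan: total parallel and convergent sites.
#'
#' @param branchSite data.frame with columns Category, p_value, nSites (or
#'   NULL).
#' @param convergence \code{\link{runConvergenceScan}} output (or NULL).
#' @param alpha significance level for branch-site LRTs.
#' @return list of counts; percentHypoxic is NA when no sites were called.
#' @export
studySummary <- function(branchSite, convergence = NULL, alpha = 0.05) {
  s <- list(nSelectedBranches = 0L, totalSelectedSites = 0L,
            hypoxicSelectedSites = 0L, percentHypoxic = NA_real_,
            nParallel = NA_integer_, nConvergent = NA_integer_)
  if (!is.null(branchSite) && nrow(branchSite)) {
    sig <- branchSite[branchSite$p_value < alpha, , drop = FALSE]
    s$nSelectedBranches <- nrow(sig)
    s$totalSelectedSites <- sum(sig$nSites)
    hyp <- sig$Category != "background"
    s$hypoxicSelectedSites <- sum(sig$nSites[hyp])
    if (s$totalSelectedSites > 0)
      s$percentHypoxic <- floor(100 * s$hypoxicSelectedSites /
                                  s$totalSelectedSites + 0.5)
  }
  if (!is.null(convergence)) {
    cnt <- summarizeObservedCounts(convergence$sites)
    s$nParallel <- cnt$parallel
    s$nConvergent <- cnt$convergent
  }
  s
}

.writeStudyReports <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible())
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(out$table1, "branch_models.tsv")
  wr(out$freeRatio, "free_ratio.tsv")
  wr(out$bebSites, "beb_sites.tsv")
  wr(out$branchSite, "branch_site.tsv")
  if (!is.null(out$convergence)) {
    wr(out$convergence$sites, "convergence_sites.tsv")
    wr(out$convergence$pairs, "convergence_pairs.tsv")
  }
  writeLines(yaml::as.yaml(out$summary), file.path(dir, "summary.yaml"))
  invisible(dir)
}
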