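## Likelihood-ratio tests between nested omega models.

.nestingOK <- function(kindNull, kindAlt) {
  allowed <- list(
    one_ratio = c("multi_ratio", "free_ratio"),
    multi_ratio = c("multi_ratio", "free_ratio"),
    M8a = "M8",
    branch_site_A_null = "branch_site_A")
  kindAlt %in% allowed[[kindNull]]
}

#' Likelihood-ratio test of two nested fits
#'
#' The statistic 2ΔL = 2 (lnL_alt - lnL_null) is referred to a chi-square
#' distribution with df = np_alt - np_null. Small negative statistics (within
#' \code{tol}, an optimizer artifact) are clamped to 0; larger ones raise an
#' error surfacing the optimizer failure.
#'
#' @param null,alt \code{FitResult}s of the null and alternative model.
#' @param comparison label, e.g. \code{"2ω vs. 1ω"} (derived from the model
#'   labels by default).
#' @param tol negative-statistic tolerance.
#' @return A \code{\linkS4class{LRTResult}}.
#' @export
likelihoodRatioTest <- function(null, alt, comparison = NULL, tol = 0.02) {
  if (!.nestingOK(null@spec@kind, alt@spec@kind))
    stop("models are not nested: ", null@spec@kind, " vs ", alt@spec@kind)
  if (alt@np <= null@np)
    stop("alternative must have more parameters than the null")
  if (is.null(comparison))
    comparison <- paste(alt@spec@label, "vs.", null@spec@label)
  res <- lrtFromLogLik(null@lnL, alt@lnL, df = alt@np - null@np,
                       comparison = comparison, tol = tol)
  res@null <- list(null)
  res@alt <- list(alt)
  res
}

#' Likelihood-ratio test from bare log-likelihoods
#'
#' Used both internally and for in-table arithmetic (recomputing a printed
#' LRT from its two reported -lnL values).
#'
#' @param lnLNull,lnLAlt log-likelihoods (or negated pairs; the statistic is
#'   2 |difference| direction-checked via \code{tol}).
#' @param df degrees of freedom (> 0).
#' @param comparison label.
#' @param tol tolerance for a negative statistic before erroring.
#' @return A \code{\linkS4class{LRTResult}}.
#' @export
lrtFromLogLik <- function(lnLNull, lnLAlt, df, comparison = "alt vs. null",
                          tol = 0.02) {
  stat <- 2 * (lnLAlt - lnLNull)
  if (stat < -tol)
    stop("alternative lnL below null by ", -stat / 2,
         ": optimizer failure in one of the fits")
  stat <- max(stat, 0)
  new("LRTResult", stat = stat, df = as.integer(df),
      p = stats::pchisq(stat, df = df, lower.tail = FALSE),
      comparison = comparison, null = list(), alt = list())
}
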