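#' Concordance (AUC) of a score against a binary outcome
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, ties counted one-half; computed via midranks (equivalent to
#' brute-force pair counting).
#'
#' @param score Numeric score vector.
#' @param outcome Logical/0-1 outcome vector.
#' @return AUC in \[0, 1\], or `NA` when either class is empty.
#' @export
concordance <- function(score, outcome) {
  outcome <- as.logical(outcome)
  stopifnot(length(score) == length(outcome), !anyNA(score), !anyNA(outcome))
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)  # midranks handle ties as 1/2
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Hanley-McNeil asymptotic standard error of an AUC
auc_se_hanley <- function(auc, n1, n0) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
}

#' Pearson chi-square test of homogeneity of proportions
#'
#' Pearson chi-square on the 2 x k table of (endorsed, not endorsed) by
#' cohort, without continuity correction; df = k - 1; p from the upper tail.
#' An all-or-none item yields statistic 0 and p = 1.
#'
#' @param endorsed Integer vector of endorsement counts per cohort.
#' @param totals Integer vector of cohort sizes.
#' @return List `statistic`, `df`, `p`.
#' @export
chi2_homogeneity <- function(endorsed, totals) {
  stopifnot(length(endorsed) == length(totals), length(totals) >= 2)
  if (any(totals <= 0)) stop("cohort totals must be positive", call. = FALSE)
  if (any(endorsed < 0) || any(endorsed > totals)) {
    stop("endorsed counts must lie in [0, total]", call. = FALSE)
  }
  k <- length(totals)
  obs <- rbind(endorsed, totals - endorsed)
  p_hat <- sum(endorsed) / sum(totals)
  if (p_hat == 0 || p_hat == 1) {
    return(list(statistic = 0, df = k - 1L, p = 1))
  }
  expd <- rbind(totals * p_hat, totals * (1 - p_hat))
  stat <- sum((obs - expd)^2 / expd)
  list(statistic = stat, df = k - 1L,
       p = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE))
}

#' Maximum pairwise cohort difference in percentage points
#'
#' @param rates Numeric vector of per-cohort endorsement rates in \[0, 1\].
#' @return `100 * (max - min)`.
#' @export
max_pp_difference <- function(rates) {
  stopifnot(length(rates) >= 2, all(rates >= 0), all(rates <= 1))
  100 * (max(rates) - min(rates))
}

#' Cross-cohort endorsement concordance of one sign
#'
#' Scores every neonate by its cohort's endorsement rate of the sign and
#' computes the concordance between endorsed and non-endorsed neonates (ties
#' one-half).  A sign endorsed at identical rates in all cohorts gives 0.5;
#' one endorsed by all or by none is degenerate and returns `NA`.  The CI
#' uses the Hanley-McNeil asymptotic variance.
#'
#' @inheritParams chi2_homogeneity
#' @param conf_level Confidence level (default 0.95).
#' @return List `auc`, `se`, `ci` (length-2, clamped to \[0, 1\]).
#' @export
endorsement_auc <- function(endorsed, totals, conf_level = 0.95) {
  stopifnot(length(endorsed) == length(totals))
  n1 <- sum(endorsed); n0 <- sum(totals) - n1
  if (n1 == 0 || n0 == 0) {
    return(list(auc = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_)))
  }
  rates <- endorsed / totals
  score <- rep(rates, totals)
  outcome <- unlist(mapply(function(e, n) c(rep(TRUE, e), rep(FALSE, n - e)),
                           endorsed, totals, SIMPLIFY = FALSE))
  auc <- concordance(score, outcome)
  se <- auc_se_hanley(auc, n1, n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  list(auc = auc, se = se, ci = ci)
}

#' Screen binary signs across cohorts
#'
#' Stage-1 statistics for every binary sign: per-cohort endorsement counts
#' and rates, the Pearson chi-square homogeneity test, the maximum pairwise
#' rate difference in percentage points, and the cross-cohort endorsement
#' concordance.  Signs never observed overall are excluded as
#' `never_observed`; signs whose rates differ by more than `pp_threshold`
#' percentage points (strictly, on rates computed from counts) are excluded
#' as `heterogeneity`.  Signs endorsed by every neonate are retained by the
#' screen but flagged `zero_variance` for the regression stage.
#'
#' @param rows Analysis-row data.frame ([extract_analysis_rows()] layout);
#'   only cohorts present in `rows` are compared, so pass the derivation
#'   cohorts only.
#' @param pp_threshold Heterogeneity exclusion threshold in percentage
#'   points (default 50).
#' @param sign_ids Binary sign columns to screen (default all 21).
#' @return Data.frame, one row per sign: counts/rates per cohort,
#'   `chi2_stat`, `chi2_df`, `chi2_p`, `max_pp_difference`, `auc`,
#'   `auc_lo`, `auc_hi`, `zero_variance`, `excluded`, `reason`.  The
#'   retained candidate set (excluding also zero-variance signs) is in
#'   attribute `candidates`.
#' @export
screen_items <- function(rows, pp_threshold = 50, sign_ids = binary_items()) {
  cohorts <- unique(rows$cohort_id)
  if (length(cohorts) < 2) stop("need >= 2 cohorts to screen", call. = FALSE)
  totals <- as.integer(table(factor(rows$cohort_id, levels = cohorts)))
  res <- lapply(sign_ids, function(id) {
    endorsed <- as.integer(tapply(rows[[id]],
                                  factor(rows$cohort_id, levels = cohorts),
                                  sum))
    rates <- endorsed / totals
    ch <- chi2_homogeneity(endorsed, totals)
    auc <- endorsement_auc(endorsed, totals)
    never <- sum(endorsed) == 0
    always <- sum(endorsed) == sum(totals)
    pp <- max_pp_difference(rates)
    excluded <- never || pp > pp_threshold
    reason <- if (never) "never_observed" else
      if (pp > pp_threshold) "heterogeneity" else ""
    stats_row <- data.frame(binary_id = id, stringsAsFactors = FALSE)
    stats_row[paste0("n_", cohorts)] <- as.list(endorsed)
    stats_row[paste0("rate_", cohorts)] <- as.list(rates)
    cbind(stats_row, data.frame(
      chi2_stat = ch$statistic, chi2_df = ch$df, chi2_p = ch$p,
      max_pp_difference = pp,
      auc = auc$auc, auc_lo = auc$ci[1], auc_hi = auc$ci[2],
      zero_variance = never || always,
      excluded = excluded, reason = reason, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "candidates") <-
    out$binary_id[!out$excluded & !out$zero_variance]
  attr(out, "excluded") <- stats::setNames(out$reason[out$excluded],
                                           out$binary_id[out$excluded])
  out
}

#' Format a p-value the way clinical journals print it
#'
#' Two decimals at or above 0.01 (three below 0.01), and `"<.001"` below
#' 0.001; no leading zero.
#'
#' @param p Numeric p-value vector.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  out <- ifelse(p < 0.001, "<.001",
         ifelse(p < 0.01, sub("^0", "", sprintf("%.3f", p)),
                sub("^0", "", sprintf("%.2f", p))))
  out
}
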