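#' Weighted Cohen's kappa for ordered categories
#'
#' Chance-corrected agreement `(P_o - P_e) / (1 - P_e)` with agreement
#' weights `w_ij = 1 - |i - j| / (r - 1)` (linear, Cicchetti-Allison;
#' `"unweighted"` uses the identity weights, recovering plain kappa).  The
#' confidence interval uses the large-sample variance of weighted kappa
#' (Fleiss, Cohen & Everitt).
#'
#' @param tab Square r x r contingency table of counts (rows: first rater /
#'   scale, columns: second).
#' @param weights `"linear"` (default) or `"unweighted"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List `kappa`, `se`, `ci`, `po`, `pe`, `weights`.  Degenerate
#'   marginals with `P_e = 1` return `NA` kappa.
#' @examples
#' weighted_kappa(matrix(c(87, 13, 2, 47, 58, 23, 25, 41, 128), 3,
#'                       byrow = TRUE))
#' @export
weighted_kappa <- function(tab, weights = c("linear", "unweighted"),
                           conf_level = 0.95) {
  weights <- match.arg(weights)
  tab <- as.matrix(tab)
  r <- nrow(tab)
  stopifnot(r == ncol(tab), r >= 2, all(tab >= 0))
  n <- sum(tab)
  if (n == 0) stop("empty table", call. = FALSE)
  w <- if (weights == "linear") {
    1 - abs(outer(seq_len(r), seq_len(r), "-")) / (r - 1)
  } else {
    diag(r)
  }
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  if (1 - pe < .Machine$double.eps^0.5) {
    return(list(kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                po = po, pe = pe, weights = weights))
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt large-sample variance
  wbar_r <- drop(w %*% pc)   # row-conditional expected weight
  wbar_c <- drop(pr %*% w)
  term <- outer(wbar_r, wbar_c, "+")
  s <- sum(p * (w - term * (1 - kappa))^2)
  var_k <- (s - (kappa - pe * (1 - kappa))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(0, var_k))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kappa, se = se,
       ci = pmax(-1, pmin(1, kappa + c(-1, 1) * z * se)),
       po = po, pe = pe, weights = weights)
}

#' Cross-classify original vs simplified score categories
#'
#' 3 x 3 counts of neonates by original FNAST category (cutpoints fixed at
#' 8 and 12) and simplified-scale category at candidate cutpoints.
#'
#' @param original,simplified Integer score vectors (same length).
#' @param simplified_cutpoints Length-2 increasing cutpoints on the 0--8
#'   scale.
#' @param original_cutpoints Original-scale cutpoints (default `c(8, 12)`).
#' @return 3 x 3 integer matrix, rows = original, columns = simplified.
#' @export
crosstab_categories <- function(original, simplified, simplified_cutpoints,
                                original_cutpoints = c(8, 12)) {
  stopifnot(length(original) == length(simplified))
  oc <- categorize(original, original_cutpoints)
  sc <- categorize(simplified, simplified_cutpoints)
  tab <- table(original = oc, simplified = sc)
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(original = levels(oc), simplified = levels(sc)))
  m
}

#' Calibrate simplified-scale cutpoints by maximum weighted kappa
#'
#' Exhaustive grid over integer cutpoint pairs `1 <= t1 < t2 <= 8` (28
#' pairs): for each pair, cross-classify against the original categories and
#' compute linear-weighted kappa; the maximizing pair is returned, ties
#' broken by smallest `t1` then smallest `t2`.  The full grid is retained
#' for reporting.
#'
#' @param original,simplified Integer score vectors, or an analysis-row
#'   data.frame passed as `rows` with `original_score` / `simplified_score`
#'   columns.
#' @param rows Optional analysis-row data.frame (overrides the score
#'   vectors).
#' @return Object of class `nas_calibration`: `thresholds` (c(t1, t2)),
#'   `kappa`, `se`, `ci`, `crosstab`, `grid` (data.frame t1, t2, kappa).
#' @export
select_thresholds <- function(original, simplified, rows = NULL) {
  if (!is.null(rows)) {
    original <- rows$original_score
    simplified <- rows$simplified_score
  }
  if (length(unique(simplified)) < 2) {
    stop("simplified scores are constant; calibration is degenerate",
         call. = FALSE)
  }
  grid <- expand.grid(t1 = 1:8, t2 = 1:8)
  grid <- grid[grid$t1 < grid$t2, ]
  grid <- grid[order(grid$t1, grid$t2), ]
  grid$kappa <- vapply(seq_len(nrow(grid)), function(i) {
    tab <- crosstab_categories(original, simplified,
                               c(grid$t1[i], grid$t2[i]))
    weighted_kappa(tab)$kappa
  }, numeric(1))
  if (all(is.na(grid$kappa))) {
    stop("weighted kappa degenerate for every cutpoint pair", call. = FALSE)
  }
  best <- which(grid$kappa == max(grid$kappa, na.rm = TRUE))[1]  # ordered grid => smallest t1, t2
  thresholds <- c(t1 = grid$t1[best], t2 = grid$t2[best])
  tab <- crosstab_categories(original, simplified, unname(thresholds))
  wk <- weighted_kappa(tab)
  structure(list(thresholds = thresholds, kappa = wk$kappa, se = wk$se,
                 ci = wk$ci, crosstab = tab,
                 grid = `rownames<-`(grid, NULL)),
            class = "nas_calibration")
}

#' @export
print.nas_calibration <- function(x, ...) {
  cat(sprintf("Simplified-scale cutpoints (%d, %d); weighted kappa %.3f (95%% CI %.3f-%.3f)\n",
              x$thresholds[1], x$thresholds[2], x$kappa, x$ci[1], x$ci[2]))
  print(x$crosstab)
  invisible(x)
}

#' External validation of the selected signs
#'
#' Refits a logistic model of treatment on the selected signs on an
#' independent single-cohort validation set (no cohort terms) and reports
#' its concordance with a Hanley-McNeil CI.
#'
#' @param rows Validation analysis-row data.frame containing `treated` and
#'   one column per selected sign.
#' @param selected Character vector of selected sign columns.
#' @return List `fit` ([fit_logistic()]), `auc`, `ci`, `n`.
#' @export
validate_external <- function(rows, selected) {
  miss <- setdiff(c("treated", selected), names(rows))
  if (length(miss)) {
    stop("validation rows missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  y <- as.numeric(rows$treated)
  x <- as.matrix(rows[selected])
  storage.mode(x) <- "numeric"
  fit <- fit_logistic(y, x)
  res <- model_auc(fit, ci = TRUE)
  list(fit = fit, auc = res$auc, ci = res$ci, n = nrow(rows))
}
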