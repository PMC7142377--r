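#' Published per-cohort endorsement counts of the dichotomized signs
#'
#' Endorsement counts of each binary sign at the analysis point, as published
#' for the three derivation cohorts (Louisville n = 127, Tufts-led multisite
#' trial n = 203, University of Kentucky n = 94) and the external validation
#' cohort (n = 109).  Generalized convulsions was never observed and is
#' carried with zero counts.
#'
#' @return Data.frame: `binary_id`, one integer count column per cohort
#'   (`louisville`, `tufts`, `kentucky`, `mother`).  Cohort sizes are in
#'   attribute `cohort_n`.
#' @export
reference_endorsement_counts <- function() {
  m <- matrix(c(
    #                         lou  tuf  ken  mom
    98, 42, 75, 31,    # high_pitched_crying
    70, 108, 80, 82,   # sleeps_lt3h
    36, 35, 64, 42,    # hyperactive_moro
    119, 163, 64, 85,  # tremors_disturbed
    60, 67, 19, 41,    # tremors_undisturbed
    120, 182, 87, 99,  # increased_muscle_tone
    36, 48, 20, 21,    # excoriation
    5, 3, 5, 1,        # myoclonic_jerks
    0, 0, 0, 0,        # generalized_convulsions
    8, 10, 8, 6,       # sweating
    30, 81, 18, 1,     # temp_ge_37_2
    4, 14, 3, 4,       # yawning_gt3
    55, 50, 19, 13,    # mottling
    25, 21, 13, 13,    # nasal_stuffiness
    40, 67, 41, 34,    # sneezing_gt3
    4, 5, 8, 3,        # nasal_flaring
    57, 60, 41, 53,    # resp_rate_gt60
    72, 63, 61, 29,    # excessive_sucking
    33, 35, 32, 31,    # poor_feeding
    25, 24, 27, 19,    # regurgitation
    32, 34, 38, 28     # loose_watery_stools
  ), ncol = 4, byrow = TRUE)
  out <- data.frame(binary_id = binary_items(), stringsAsFactors = FALSE)
  out[c("louisville", "tufts", "kentucky", "mother")] <-
    as.data.frame(matrix(as.integer(m), ncol = 4))
  attr(out, "cohort_n") <- c(louisville = 127L, tufts = 203L,
                             kentucky = 94L, mother = 109L)
  out
}

#' Published grade-level frequencies of the original items
#'
#' Counts of each recorded grade level among the 424 derivation neonates at
#' the analysis point (never-observed levels have count 0).  Used to
#' calibrate the synthetic generator's grade-escalation thresholds and to
#' cross-check that level counts aggregate to the binary endorsement counts.
#'
#' @return Data.frame `item_id`, `grade`, `count`.
#' @export
reference_level_counts <- function() {
  items <- fnast_items()
  counts <- c(
    187, 28,        # crying: excessive, continuous
    83, 96, 79,     # sleeps: <3, <2, <1
    127, 8,         # moro
    201, 145,       # tremors disturbed
    88, 58,         # tremors undisturbed
    389,            # muscle tone
    104,            # excoriation
    13,             # myoclonic jerks
    0,              # convulsions
    26,             # sweating
    129, 0,         # temperature
    21,             # yawning
    124,            # mottling
    59,             # nasal stuffiness
    148,            # sneezing
    17,             # nasal flaring
    138, 20,        # respiratory rate
    196,            # excessive sucking
    100,            # poor feeding
    76, 0,          # vomiting: regurgitation, projectile
    88, 16          # stools: loose, watery
  )
  data.frame(item_id = items$item_id, grade = items$grade,
             count = as.integer(counts), stringsAsFactors = FALSE)
}

#' Published 3x3 crosstab of original vs simplified categories
#'
#' Counts of the 424 derivation neonates cross-classified by original FNAST
#' category (rows: 0-7, 8-11, >=12) and simplified-scale category at the
#' published cutpoints 4 and 5 (columns: 0-3, 4, >=5).
#'
#' @return 3x3 integer matrix with dimnames `original` x `simplified`.
#' @export
reference_crosstab <- function() {
  matrix(c(87, 13, 2,
           47, 58, 23,
           25, 41, 128),
         nrow = 3, byrow = TRUE,
         dimnames = list(original = c("low", "medium", "high"),
                         simplified = c("low", "medium", "high")))
}

#' Deterministic analysis-row fixture matching the published marginals
#'
#' Builds one analysis row per neonate for the three derivation cohorts (127
#' + 203 + 94 = 424 rows) and, optionally, the validation cohort (109 rows),
#' such that every per-cohort binary-sign count equals the published count
#' exactly.  The joint structure is arbitrary but fixed: within a cohort,
#' sign j is endorsed on a cyclically shifted block of rows, so repeated
#' calls are identical.  Treated flags are assigned to the first rows of
#' each cohort in proportion to the published overall treated fraction
#' (238/424); original/simplified scores are derived from the fixture flags.
#' Intended for screening-stage regression tests, not as a realistic joint
#' distribution.
#'
#' @param include_validation Include the validation-cohort block
#'   (default TRUE).
#' @return Analysis-row data.frame in the layout of
#'   [extract_analysis_rows()].
#' @export
fixture_analysis_rows <- function(include_validation = TRUE) {
  ref <- reference_endorsement_counts()
  ns <- attr(ref, "cohort_n")
  cohorts <- c("louisville", "tufts", "kentucky",
               if (include_validation) "mother")
  treated_frac <- 238 / 424
  items <- fnast_items()
  bin_ids <- binary_items(items)
  # one representative weight per binary sign: the minimum grade weight
  wmin <- tapply(items$weight, items$binary_id, min)[bin_ids]

  blocks <- lapply(seq_along(cohorts), function(ci) {
    cohort <- cohorts[ci]
    n <- ns[[cohort]]
    flags <- matrix(0L, n, length(bin_ids), dimnames = list(NULL, bin_ids))
    for (j in seq_along(bin_ids)) {
      cnt <- ref[[cohort]][j]
      if (cnt > 0) {
        start <- ((j - 1) * 17L) %% n  # fixed stagger decorrelates columns
        idx <- (start + seq_len(cnt) - 1L) %% n + 1L
        flags[idx, j] <- 1L
      }
    }
    simp <- apply(flags, 1, function(f)
      score_simplified(stats::setNames(f == 1L, bin_ids)))
    data.frame(
      neonate_id = sprintf("%s_%03d", cohort, seq_len(n)),
      cohort_id = cohort,
      treated = seq_len(n) <= round(n * treated_frac),
      analysis_day = 3L,
      original_score = as.numeric(flags %*% wmin),
      simplified_score = as.integer(simp),
      stringsAsFactors = FALSE
    ) |> cbind(as.data.frame(flags))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Deterministic score pairs reproducing the published 3x3 crosstab
#'
#' Builds 424 (original score, simplified score) pairs whose categorization
#' at the original cutpoints (8, 12) and simplified cutpoints (4, 5)
#' reproduces [reference_crosstab()] cell by cell, using one representative
#' score per category.
#'
#' @return Data.frame `original_score`, `simplified_score`.
#' @export
fixture_crosstab_scores <- function() {
  tab <- reference_crosstab()
  rep_orig <- c(5, 9, 13)   # low / medium / high at cutpoints (8, 12)
  rep_simp <- c(2, 4, 6)    # low / medium / high at cutpoints (4, 5)
  rows <- expand.grid(i = 1:3, j = 1:3)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(k) {
    i <- rows$i[k]; j <- rows$j[k]
    if (tab[i, j] == 0) return(NULL)
    data.frame(original_score = rep(rep_orig[i], tab[i, j]),
               simplified_score = rep(rep_simp[j], tab[i, j]))
  }))
  rownames(out) <- NULL
  out
}
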