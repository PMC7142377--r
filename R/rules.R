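#' Consecutive-score treatment-initiation rule
#'
#' A rule is a set of clauses `(k, threshold)`; pharmacologic treatment is
#' triggered by the earliest run of `k` consecutive assessments all scoring at
#' least `threshold`, for any clause.  "Consecutive" means adjacent in the
#' chronological assessment sequence, crossing day boundaries.
#'
#' @param ... One or more numeric length-2 vectors `c(k, threshold)`.
#' @return An object of class `nas_rule`.
#' @examples
#' treatment_rule(c(3, 8), c(2, 12))  # Kentucky-site criterion
#' @export
treatment_rule <- function(...) {
  clauses <- list(...)
  if (!length(clauses)) stop("at least one clause required", call. = FALSE)
  for (cl in clauses) {
    if (length(cl) != 2 || cl[1] < 1 || cl[2] <= 0 || cl[1] != round(cl[1])) {
      stop("each clause must be c(k >= 1 integer, threshold > 0)",
           call. = FALSE)
    }
  }
  structure(list(clauses = lapply(clauses, as.numeric)), class = "nas_rule")
}

#' @export
print.nas_rule <- function(x, ...) {
  txt <- vapply(x$clauses, function(cl)
    sprintf("%d consecutive score(s) >= %g", as.integer(cl[1]), cl[2]), "")
  cat("Treatment-initiation rule:", paste(txt, collapse = "  OR  "), "\n")
  invisible(x)
}

#' Site treatment rules used by the derivation and validation cohorts
#'
#' Kentucky sites (Louisville, University of Kentucky): 3 consecutive scores
#' of at least 8 or 2 consecutive scores of at least 12.  Multisite trial
#' (Tufts-led): 2 consecutive scores of at least 8 or 1 score of at least 12.
#' External validation cohort: 2 consecutive scores of at least 9 or 1 score
#' of at least 13.
#'
#' @return Named list of [treatment_rule()] objects keyed by cohort id.
#' @export
default_site_rules <- function() {
  kentucky <- treatment_rule(c(3, 8), c(2, 12))
  list(
    louisville = kentucky,
    tufts      = treatment_rule(c(2, 8), c(1, 12)),
    kentucky   = kentucky,
    mother     = treatment_rule(c(2, 9), c(1, 13))
  )
}

#' Day treatment is first triggered by a rule
#'
#' Scans the chronological score sequence for the earliest run satisfying any
#' clause of the rule and returns the day of the final assessment of that
#' run, or `NA` if no clause is ever satisfied (or the sequence is empty).
#'
#' @param days Integer vector of day-of-life per assessment (chronological).
#' @param scores Numeric score per assessment, same length.
#' @param rule A [treatment_rule()].
#' @return Integer day, or `NA_integer_`.
#' @export
first_treatment_day <- function(days, scores, rule) {
  stopifnot(inherits(rule, "nas_rule"), length(days) == length(scores))
  n <- length(scores)
  if (n == 0) return(NA_integer_)
  best <- NA_integer_
  for (cl in rule$clauses) {
    k <- cl[1]; thr <- cl[2]
    run <- 0L
    for (i in seq_len(n)) {
      run <- if (scores[i] >= thr) run + 1L else 0L
      if (run >= k) { best <- min(best, i, na.rm = TRUE); break }
    }
  }
  if (is.na(best)) NA_integer_ else as.integer(days[best])
}

#' Extract one analysis row per neonate
#'
#' Implements the single-assessment-point design: for each neonate, the
#' assessment with the highest original score on the day treatment was first
#' triggered (per its cohort's rule), or on day 3 of life if never treated;
#' ties broken by the earliest assessment.  Returns the dichotomized signs,
#' the original and simplified scores, cohort and treated flag.  Neonates
#' with no assessment on their analysis day are dropped with a warning that
#' reports the count (also attached as attribute `n_dropped`).
#'
#' @param assessments Long-form assessment table: columns `neonate_id`,
#'   `cohort_id`, `day_of_life`, `assessment_index`, `item_id`, `grade`.
#'   One row per recorded (endorsed) item grade; assessments where no sign
#'   was observed may be declared through `schedule` instead.
#' @param rules Named list of [treatment_rule()] per `cohort_id`
#'   (default [default_site_rules()]).
#' @param schedule Optional data.frame (`neonate_id`, `cohort_id`,
#'   `day_of_life`, `assessment_index`) enumerating every assessment that
#'   took place, including all-absent ones.  When `NULL`, the assessments
#'   table itself defines the schedule.
#' @param untreated_day Analysis day for never-treated neonates (default 3,
#'   the median day of treatment initiation among treated neonates).
#' @param items Item catalogue.
#' @return Data.frame with one row per neonate: `neonate_id`, `cohort_id`,
#'   `treated`, `analysis_day`, `original_score`, `simplified_score`, and one
#'   0/1 column per binary sign.
#' @export
extract_analysis_rows <- function(assessments, rules = default_site_rules(),
                                  schedule = NULL, untreated_day = 3,
                                  items = fnast_items()) {
  req <- c("neonate_id", "cohort_id", "day_of_life", "assessment_index",
           "item_id", "grade")
  miss <- setdiff(req, names(assessments))
  if (length(miss)) {
    stop("assessments table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_grades_table(assessments, items)

  sc <- assessment_scores(assessments, schedule = schedule, items = items)
  sc <- sc[order(sc$neonate_id, sc$day_of_life, sc$assessment_index), ]
  ids <- unique(sc$neonate_id)
  bin_ids <- binary_items(items)

  sc_by <- split(seq_len(nrow(sc)), factor(sc$neonate_id, levels = ids))
  as_by <- split(seq_len(nrow(assessments)),
                 factor(assessments$neonate_id, levels = ids))

  keep <- logical(length(ids))
  treated_v <- logical(length(ids)); aday_v <- integer(length(ids))
  orig_v <- numeric(length(ids)); simp_v <- integer(length(ids))
  cohort_v <- character(length(ids))
  flag_m <- matrix(0L, length(ids), length(bin_ids),
                   dimnames = list(NULL, bin_ids))
  dropped <- 0L
  for (i in seq_along(ids)) {
    s <- sc[sc_by[[i]], ]
    cohort <- s$cohort_id[1]
    rule <- rules[[cohort]]
    if (is.null(rule)) {
      stop("no treatment rule for cohort '", cohort, "'", call. = FALSE)
    }
    tday <- first_treatment_day(s$day_of_life, s$original_score, rule)
    treated <- !is.na(tday)
    aday <- if (treated) tday else as.integer(untreated_day)
    on_day <- s[s$day_of_life == aday, ]
    if (nrow(on_day) == 0) { dropped <- dropped + 1L; next }
    pick <- on_day[which.max(on_day$original_score), ]  # earliest max (chronological order)
    a <- assessments[as_by[[i]], ]
    sel <- a$day_of_life == aday & a$assessment_index == pick$assessment_index
    grades <- stats::setNames(a$grade[sel], a$item_id[sel])
    flags <- binarize(grades, items)
    keep[i] <- TRUE
    treated_v[i] <- treated; aday_v[i] <- aday
    orig_v[i] <- pick$original_score; simp_v[i] <- score_simplified(flags)
    cohort_v[i] <- cohort; flag_m[i, ] <- as.integer(flags)
  }
  if (dropped > 0) {
    warning(sprintf("%d neonate(s) had no assessment on the analysis day and were dropped",
                    dropped), call. = FALSE)
  }
  out <- data.frame(neonate_id = ids[keep], cohort_id = cohort_v[keep],
                    treated = treated_v[keep], analysis_day = aday_v[keep],
                    original_score = orig_v[keep],
                    simplified_score = simp_v[keep],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(flag_m[keep, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

# grades of one specific assessment, as a named vector
assessment_grades <- function(assessments, neonate, day, index) {
  sel <- assessments$neonate_id == neonate &
    assessments$day_of_life == day & assessments$assessment_index == index
  stats::setNames(assessments$grade[sel], assessments$item_id[sel])
}

check_grades_table <- function(assessments, items = fnast_items()) {
  if (nrow(assessments) == 0) return(invisible(TRUE))
  lk <- .item_lookup(items)
  bad_item <- setdiff(unique(assessments$item_id), lk$items)
  if (length(bad_item)) {
    stop("unknown item_id(s): ", paste(bad_item, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(assessments$item_id, assessments$grade, sep = ":")
  bad <- !(key %in% names(lk$weight))
  if (any(bad)) {
    stop("unknown grade label(s): ",
         paste(unique(key[bad]), collapse = ", "), call. = FALSE)
  }
  akey <- paste(assessments$neonate_id, assessments$day_of_life,
                assessments$assessment_index, assessments$item_id)
  if (anyDuplicated(akey)) {
    stop("duplicate item grade within an assessment: ",
         akey[duplicated(akey)][1], call. = FALSE)
  }
  if (any(assessments$day_of_life < 1) || any(assessments$assessment_index < 1)) {
    stop("day_of_life and assessment_index must be >= 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-assessment original scores
#'
#' Aggregates a long-form assessment table to one row per assessment with its
#' original FNAST score (sum of recorded grade weights).
#'
#' @inheritParams extract_analysis_rows
#' @return Data.frame `neonate_id`, `cohort_id`, `day_of_life`,
#'   `assessment_index`, `original_score`, chronologically ordered within
#'   neonate.
#' @export
assessment_scores <- function(assessments, schedule = NULL,
                              items = fnast_items()) {
  lk <- .item_lookup(items)
  base <- if (!is.null(schedule)) {
    schedule[c("neonate_id", "cohort_id", "day_of_life", "assessment_index")]
  } else {
    unique(assessments[c("neonate_id", "cohort_id", "day_of_life",
                         "assessment_index")])
  }
  key_of <- function(d) paste(d$neonate_id, d$day_of_life, d$assessment_index,
                              sep = "\r")
  base$original_score <- 0
  if (nrow(assessments)) {
    w <- unname(lk$weight[paste(assessments$item_id, assessments$grade,
                                sep = ":")])
    tot <- rowsum(w, key_of(assessments))
    idx <- match(key_of(base), rownames(tot))
    hit <- !is.na(idx)
    base$original_score[hit] <- tot[idx[hit], 1]
  }
  base <- base[order(base$neonate_id, base$day_of_life,
                     base$assessment_index), ]
  rownames(base) <- NULL
  base
}
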