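#' Simulation configuration for synthetic multi-cohort assessment data
#'
#' The generator emulates the statistical structure the analysis assumes:
#' each neonate has a latent withdrawal-severity trajectory `S(t) = H *
#' max(0, 1 - |t - P| / width)` (unimodal, peaking at day `P` with height
#' `H`); at every assessment each binary sign is endorsed independently with
#' probability `plogis(offset[sign, cohort] + loading[sign] * S)`; endorsed
#' graded items escalate to higher grades by comparing a severity-linked
#' logistic latent `S + e` against per-item thresholds.  Treatment is
#' score-rule-driven: a neonate is treated on the day its cohort's
#' consecutive-score rule first triggers on the simulated original-score
#' sequence.  Default offsets, grade thresholds and severity heights are
#' moment-matched so that analysis-point endorsement rates track the
#' published per-cohort rates and the treated fraction tracks 238/424.
#'
#' @param cohorts List of cohort specs `list(id, n, rule, validation)`;
#'   default: the three derivation cohorts (n = 127, 203, 94) plus the
#'   synthetic validation cohort (n = 109) with their site rules.
#' @param loadings Named non-negative vector: severity loading per binary
#'   sign.
#' @param offsets Numeric matrix, rows = binary signs, columns = cohort ids:
#'   per-cohort logit offsets (rater bias + baseline).  `-Inf` encodes a
#'   never-observed sign.
#' @param grade_thresholds Named list per graded `item_id`: increasing
#'   numeric thresholds (length = number of levels - 1) for grade
#'   escalation; `Inf` encodes a never-observed level.
#' @param severity List `peak_day_mean`, `peak_day_sd`, `height_mean` (named
#'   per cohort), `height_sd`, `width`.
#' @param assessments_per_day,days Assessment schedule (defaults 6 per day,
#'   days 1..5).
#' @param untreated_day Analysis day for never-treated neonates (default 3).
#' @param seed Mandatory integer seed.
#' @return Validated config list of class `nas_sim_config`.
#' @export
sim_config <- function(cohorts = default_sim_cohorts(),
                       loadings = default_loadings(),
                       offsets = default_offsets(),
                       grade_thresholds = default_grade_thresholds(),
                       severity = default_severity(),
                       assessments_per_day = 6, days = 5,
                       untreated_day = 3, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  bin_ids <- binary_items()
  stopifnot(all(bin_ids %in% names(loadings)), all(loadings >= 0),
            all(bin_ids %in% rownames(offsets)),
            assessments_per_day >= 1, days >= 1)
  ids <- vapply(cohorts, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate cohort ids", call. = FALSE)
  for (co in cohorts) {
    if (co$n < 1) stop("cohort n must be >= 1", call. = FALSE)
    if (!inherits(co$rule, "nas_rule")) {
      stop("each cohort needs a treatment_rule", call. = FALSE)
    }
    if (!co$id %in% colnames(offsets)) {
      stop("no offset column for cohort '", co$id, "'", call. = FALSE)
    }
    if (!co$id %in% names(severity$height_mean)) {
      stop("no severity height for cohort '", co$id, "'", call. = FALSE)
    }
  }
  for (th in grade_thresholds) {
    if (is.unsorted(th, strictly = TRUE) && length(th) > 1) {
      stop("grade thresholds must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(cohorts = cohorts, loadings = loadings, offsets = offsets,
                 grade_thresholds = grade_thresholds, severity = severity,
                 assessments_per_day = as.integer(assessments_per_day),
                 days = as.integer(days),
                 untreated_day = as.integer(untreated_day),
                 seed = as.integer(seed)),
            class = "nas_sim_config")
}

#' Default cohort specifications
#'
#' Three derivation cohorts at the published sizes with their site rules and
#' a synthetic stand-in for the external validation cohort.
#'
#' @return List of cohort specs for [sim_config()].
#' @export
default_sim_cohorts <- function() {
  rules <- default_site_rules()
  list(
    list(id = "louisville", n = 127L, rule = rules$louisville,
         validation = FALSE),
    list(id = "tufts", n = 203L, rule = rules$tufts, validation = FALSE),
    list(id = "kentucky", n = 94L, rule = rules$kentucky, validation = FALSE),
    list(id = "mother", n = 109L, rule = rules$mother, validation = TRUE)
  )
}

#' Simulate multi-cohort longitudinal FNAST assessments
#'
#' Generates the full longitudinal record stream, the assessment schedule,
#' a per-neonate truth log (latent severity parameters, triggered treatment
#' day), and analysis rows extracted directly from the simulated arrays
#' (identical, by construction and by test, to running
#' [extract_analysis_rows()] on the emitted long table).  Identical configs
#' (including seed) give identical output.
#'
#' @param config A [sim_config()].
#' @param include_long Build the long assessment table and schedule (default
#'   TRUE).  Replicate studies that only need analysis rows and the truth
#'   log can skip it for speed; the random stream is unaffected.
#' @return List of class `nas_simulation`: `assessments` (long table:
#'   neonate_id, cohort_id, day_of_life, assessment_index, item_id, grade),
#'   `schedule`, `truth` (neonate_id, cohort_id, peak_day, peak_height,
#'   treated, treatment_day), `analysis` (analysis-row table), `config`.
#'   `assessments` and `schedule` are `NULL` when `include_long = FALSE`.
#' @export
simulate_cohorts <- function(config, include_long = TRUE) {
  stopifnot(inherits(config, "nas_sim_config"))
  set.seed(config$seed)
  items <- fnast_items()
  bin_ids <- binary_items(items)
  item_ids <- unique(items$item_id)  # parallel to bin_ids, one graded item each
  m <- config$assessments_per_day
  days <- config$days
  nA <- m * days
  day_of_col <- rep(seq_len(days), each = m)
  idx_of_col <- rep(seq_len(m), times = days)
  t_of_col <- (day_of_col - 1) + (idx_of_col - 0.5) / m
  # per-item grade labels and weights by level
  lv <- split(items[c("grade", "weight")], factor(items$item_id, item_ids))

  long <- list(); sched <- list(); truth <- list(); arows <- list()
  for (co in config$cohorts) {
    n <- co$n
    ids <- sprintf("%s_%04d", co$id, seq_len(n))
    sv <- config$severity
    P <- pmin(pmax(stats::rnorm(n, sv$peak_day_mean, sv$peak_day_sd), 1),
              days - 0.5)
    # peak height is deliberately unbounded below: negative H encodes a
    # milder-than-baseline neonate, and the between-neonate spread of H is
    # what separates treated from untreated trajectories
    H <- stats::rnorm(n, sv$height_mean[[co$id]], sv$height_sd)
    S <- H * pmax(0, 1 - abs(outer(rep(1, n), t_of_col) -
                               outer(P, rep(1, nA))) / sv$width)
    # occasion/rater noise, shared by all items of one assessment: makes
    # single high scores possible without sustained runs, so the max-of-day
    # analysis marginals decouple from the consecutive-score trigger
    S <- S + matrix(stats::rnorm(n * nA, 0, sv$occasion_sd), n, nA)

    E <- vector("list", length(bin_ids)); names(E) <- bin_ids
    Lv <- vector("list", length(bin_ids)); names(Lv) <- bin_ids
    score <- matrix(0, n, nA)
    for (j in seq_along(bin_ids)) {
      bid <- bin_ids[j]; iid <- item_ids[j]
      pr <- stats::plogis(config$offsets[bid, co$id] +
                            config$loadings[bid] * S)
      u <- matrix(stats::runif(n * nA), n, nA)
      e <- u < pr
      nlev <- nrow(lv[[iid]])
      level <- matrix(1L, n, nA)
      if (nlev > 1) {
        z <- S + matrix(stats::rlogis(n * nA), n, nA)
        th <- config$grade_thresholds[[iid]]
        for (k in seq_along(th)) level <- level + (z > th[k])
      }
      E[[bid]] <- e
      Lv[[bid]] <- level
      w <- lv[[iid]]$weight
      score <- score + e * matrix(w[level], n, nA)
    }

    # treatment scan: earliest assessment completing any clause's run
    tcol <- rep(NA_integer_, n)
    for (cl in co$rule$clauses) {
      k <- cl[1]; thr <- cl[2]
      run <- integer(n); hitcol <- rep(NA_integer_, n)
      for (j in seq_len(nA)) {
        run <- ifelse(score[, j] >= thr, run + 1L, 0L)
        new_hit <- is.na(hitcol) & run >= k
        hitcol[new_hit] <- j
      }
      tcol <- pmin(tcol, hitcol, na.rm = TRUE)
    }
    treated <- !is.na(tcol)
    tday <- ifelse(treated, day_of_col[ifelse(is.na(tcol), 1L, tcol)],
                   NA_integer_)

    # analysis point: earliest max-score assessment on the analysis day
    aday <- ifelse(treated, tday, config$untreated_day)
    acol <- vapply(seq_len(n), function(i) {
      cols <- which(day_of_col == aday[i])
      cols[which.max(score[i, cols])]
    }, integer(1))
    flags <- matrix(FALSE, n, length(bin_ids),
                    dimnames = list(NULL, bin_ids))
    for (bid in bin_ids) flags[, bid] <- E[[bid]][cbind(seq_len(n), acol)]
    simp <- as.integer(
      flags[, "sleeps_lt3h"] +
        (flags[, "tremors_disturbed"] | flags[, "tremors_undisturbed"]) +
        flags[, "increased_muscle_tone"] + flags[, "temp_ge_37_2"] +
        flags[, "resp_rate_gt60"] + flags[, "excessive_sucking"] +
        flags[, "poor_feeding"] + flags[, "regurgitation"])
    ar <- data.frame(neonate_id = ids, cohort_id = co$id, treated = treated,
                     analysis_day = as.integer(aday),
                     original_score = score[cbind(seq_len(n), acol)],
                     simplified_score = simp, stringsAsFactors = FALSE)
    ar[bin_ids] <- as.data.frame(matrix(as.integer(flags), n,
                                        length(bin_ids)))
    # grade level at the analysis assessment (NA when not endorsed);
    # consumed by the offline moment-matching of grade thresholds
    lvl <- matrix(NA_integer_, n, length(bin_ids),
                  dimnames = list(NULL, item_ids))
    for (j in seq_along(bin_ids)) {
      v <- Lv[[bin_ids[j]]][cbind(seq_len(n), acol)]
      v[!flags[, bin_ids[j]]] <- NA_integer_
      lvl[, j] <- v
    }
    attr(ar, "grade_levels") <- lvl
    arows[[co$id]] <- ar

    truth[[co$id]] <- data.frame(
      neonate_id = ids, cohort_id = co$id, peak_day = P, peak_height = H,
      treated = treated, treatment_day = as.integer(tday),
      validation = isTRUE(co$validation), stringsAsFactors = FALSE)

    if (include_long) {
      sched[[co$id]] <- data.frame(
        neonate_id = rep(ids, each = nA), cohort_id = co$id,
        day_of_life = rep(day_of_col, times = n),
        assessment_index = rep(idx_of_col, times = n),
        stringsAsFactors = FALSE)

      # flat vectors instead of 84 small data.frames: rbind dominates runtime
      li <- lapply(seq_along(bin_ids), function(j) which(E[[bin_ids[j]]]))
      lens <- lengths(li)
      cell <- unlist(li, use.names = FALSE)
      row_i <- (cell - 1L) %% n + 1L
      col_j <- (cell - 1L) %/% n + 1L
      item_rep <- rep(item_ids, lens)
      grade <- character(length(cell))
      pos <- cumsum(c(0L, lens))
      for (j in seq_along(bin_ids)) {
        if (lens[j] == 0) next
        sel <- (pos[j] + 1L):pos[j + 1L]
        grade[sel] <- lv[[item_ids[j]]]$grade[Lv[[bin_ids[j]]][li[[j]]]]
      }
      long[[co$id]] <- data.frame(
        neonate_id = ids[row_i], cohort_id = co$id,
        day_of_life = day_of_col[col_j],
        assessment_index = idx_of_col[col_j],
        item_id = item_rep, grade = grade, stringsAsFactors = FALSE)
    }
  }

  analysis <- do.call(rbind, arows)
  rownames(analysis) <- NULL
  attr(analysis, "grade_levels") <-
    do.call(rbind, lapply(arows, attr, "grade_levels"))
  assessments <- schedule <- NULL
  if (include_long) {
    assessments <- do.call(rbind, long)
    o <- order(assessments$neonate_id, assessments$day_of_life,
               assessments$assessment_index, assessments$item_id)
    assessments <- assessments[o, ]
    rownames(assessments) <- NULL
    schedule <- do.call(rbind, sched)
    rownames(schedule) <- NULL
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(assessments = assessments, schedule = schedule,
                 truth = truth, analysis = analysis, config = config),
            class = "nas_simulation")
}

#' @export
print.nas_simulation <- function(x, ...) {
  cat(sprintf("Synthetic FNAST simulation: %d neonates in %d cohort(s)\n",
              nrow(x$truth), length(unique(x$truth$cohort_id))))
  tr <- tapply(x$truth$treated, x$truth$cohort_id, mean)
  cat("Treated fraction by cohort:",
      paste(sprintf("%s %.2f", names(tr), tr), collapse = ", "), "\n")
  invisible(x)
}
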