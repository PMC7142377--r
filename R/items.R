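#' The 21-item Finnegan (FNAST) item catalogue
#'
#' Returns the full graded item catalogue of the original 21-item Finnegan
#' Neonatal Abstinence Scoring Tool: one row per (item, grade level) with its
#' integer weight (1--5) and the binary sign the grade collapses to when the
#' scale is dichotomized.  Within an item, weights strictly increase with
#' grade severity.  The two vomiting grades (regurgitation, projectile) form
#' one graded item that collapses to the single binary sign "regurgitation";
#' loose and watery stools collapse to "loose or watery stools".  The two
#' tremor items are distinct graded items and distinct binary signs; they are
#' combined ("any tremors") only on the simplified 8-item scale.
#'
#' @return A data.frame with columns `item_id`, `label`, `grade`,
#'   `grade_order` (1 = least severe), `weight` (integer), `binary_id`.
#' @seealso [binary_items()], [simplified_items()], [score_original()]
#' @export
fnast_items <- function() {
  L <- function(item_id, label, binary_id, grades, weights) {
    data.frame(
      item_id = item_id, label = label, grade = grades,
      grade_order = seq_along(grades), weight = as.integer(weights),
      binary_id = binary_id, stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    L("high_pitched_crying", "High-pitched crying", "high_pitched_crying",
      c("excessive", "continuous"), c(2, 3)),
    L("sleeps_after_feeding", "Sleeps after feeding", "sleeps_lt3h",
      c("less_than_3h", "less_than_2h", "less_than_1h"), c(1, 2, 3)),
    L("moro_reflex", "Moro reflex", "hyperactive_moro",
      c("hyperactive", "markedly_hyperactive"), c(2, 3)),
    L("tremors_disturbed", "Tremors when disturbed", "tremors_disturbed",
      c("mild", "moderate_severe"), c(1, 2)),
    L("tremors_undisturbed", "Tremors when undisturbed", "tremors_undisturbed",
      c("mild", "moderate_severe"), c(3, 4)),
    L("muscle_tone", "Increased muscle tone", "increased_muscle_tone",
      "increased", 2),
    L("excoriation", "Excoriation", "excoriation", "present", 1),
    L("myoclonic_jerks", "Myoclonic jerks", "myoclonic_jerks", "present", 3),
    L("convulsions", "Generalized convulsions", "generalized_convulsions",
      "generalized", 5),
    L("sweating", "Sweating", "sweating", "present", 1),
    L("body_temperature", "Body temperature", "temp_ge_37_2",
      c("temp_37_2_to_38_3", "temp_ge_38_4"), c(1, 2)),
    L("yawning", "Yawning >3 times/scoring interval", "yawning_gt3",
      "more_than_3", 1),
    L("mottling", "Mottling", "mottling", "present", 1),
    L("nasal_stuffiness", "Nasal stuffiness", "nasal_stuffiness", "present", 1),
    L("sneezing", "Sneezing >3 times/scoring interval", "sneezing_gt3",
      "more_than_3", 1),
    L("nasal_flaring", "Nasal flaring", "nasal_flaring", "present", 2),
    L("respiratory_rate", "Respiratory rate", "resp_rate_gt60",
      c("over_60", "over_60_with_retractions"), c(1, 2)),
    L("excessive_sucking", "Excessive sucking", "excessive_sucking",
      "present", 1),
    L("poor_feeding", "Poor feeding", "poor_feeding", "present", 2),
    L("vomiting", "Vomiting", "regurgitation",
      c("regurgitation", "projectile"), c(2, 3)),
    L("stools", "Stools", "loose_watery_stools",
      c("loose", "watery"), c(2, 3))
  )
  rownames(out) <- NULL
  out
}

#' Binary (dichotomized) FNAST signs
#'
#' The 21 binary signs obtained by dichotomizing each graded item as
#' present/absent ("if any sign was recorded the neonate is coded as having
#' the sign").  Generalized convulsions is carried as a binary sign even
#' though it is never observed in the published sample; the screening stage
#' excludes it as never-observed.
#'
#' @param items Item catalogue, as returned by [fnast_items()].
#' @return Character vector of the 21 binary sign identifiers, in catalogue
#'   order.
#' @export
binary_items <- function(items = fnast_items()) {
  unique(items$binary_id)
}

#' The simplified 8-item scale
#'
#' Identifiers of the 8 unit-weight indicators making up the simplified
#' scale: sleeps <3 h after feeding, any tremors (disturbed or undisturbed),
#' increased muscle tone, body temperature >=37.2 degC, respiratory rate
#' >60/min, excessive sucking, poor feeding, regurgitation.  `any_tremors` is
#' a derived indicator that exists only on this scale.
#'
#' @return Character vector of length 8.
#' @export
simplified_items <- function() {
  c("sleeps_lt3h", "any_tremors", "increased_muscle_tone", "temp_ge_37_2",
    "resp_rate_gt60", "excessive_sucking", "poor_feeding", "regurgitation")
}

# Binary signs whose presence adds one point to the simplified score, in
# terms of the underlying 19/21 dichotomized signs (tremors still separate).
simplified_source_binaries <- function() {
  c("sleeps_lt3h", "tremors_disturbed", "tremors_undisturbed",
    "increased_muscle_tone", "temp_ge_37_2", "resp_rate_gt60",
    "excessive_sucking", "poor_feeding", "regurgitation")
}

# lookup table grade -> weight / binary group, keyed "item_id:grade"
.item_lookup <- function(items = fnast_items()) {
  key <- paste(items$item_id, items$grade, sep = ":")
  list(
    weight = stats::setNames(items$weight, key),
    binary = stats::setNames(items$binary_id, key),
    items = unique(items$item_id)
  )
}

check_grades <- function(grades, items = fnast_items()) {
  if (length(grades) == 0) return(invisible(TRUE))
  if (is.null(names(grades)) || any(!nzchar(names(grades)))) {
    stop("grades must be a named character vector (item_id -> grade)",
         call. = FALSE)
  }
  if (anyDuplicated(names(grades))) {
    stop("multiple grades recorded for item(s): ",
         paste(unique(names(grades)[duplicated(names(grades))]),
               collapse = ", "), call. = FALSE)
  }
  lk <- .item_lookup(items)
  bad_item <- setdiff(names(grades), lk$items)
  if (length(bad_item)) {
    stop("unknown item_id(s): ", paste(bad_item, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(names(grades), grades, sep = ":")
  bad <- !(key %in% names(lk$weight))
  if (any(bad)) {
    stop("unknown grade label(s): ", paste(key[bad], collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Original FNAST score of one assessment
#'
#' Sum over items of the integer weight of the recorded grade; items with no
#' recorded grade contribute 0.
#'
#' @param grades Named character vector mapping `item_id` to the recorded
#'   grade label; items absent from the vector are absent signs.
#' @param items Item catalogue ([fnast_items()]).
#' @return Integer total score.
#' @examples
#' score_original(c(high_pitched_crying = "continuous",
#'                  sleeps_after_feeding = "less_than_1h",
#'                  moro_reflex = "markedly_hyperactive"))  # 3 + 3 + 3 = 9
#' @export
score_original <- function(grades, items = fnast_items()) {
  check_grades(grades, items)
  if (length(grades) == 0) return(0L)
  lk <- .item_lookup(items)
  sum(lk$weight[paste(names(grades), grades, sep = ":")])
}

#' Dichotomize one assessment into binary signs
#'
#' Each of the 21 binary signs is present iff any constituent grade of its
#' source item is recorded (e.g. either Moro grade marks "hyperactive Moro
#' reflex"; loose or watery stools mark "loose or watery stools";
#' regurgitation or projectile vomiting mark "regurgitation").
#'
#' @inheritParams score_original
#' @return Named logical vector over [binary_items()].
#' @export
binarize <- function(grades, items = fnast_items()) {
  check_grades(grades, items)
  ids <- binary_items(items)
  flags <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (length(grades)) {
    lk <- .item_lookup(items)
    flags[unique(lk$binary[paste(names(grades), grades, sep = ":")])] <- TRUE
  }
  flags
}

#' Simplified 8-item score
#'
#' One point per present simplified-scale indicator; "any tremors" scores if
#' either tremor sign is present.  Range 0--8.
#'
#' @param flags Named logical vector of binary signs, as from [binarize()]
#'   (missing names are treated as absent).
#' @return Integer in 0..8.
#' @export
score_simplified <- function(flags) {
  stopifnot(is.logical(flags), !is.null(names(flags)))
  get <- function(id) isTRUE(unname(flags[id]))
  pts <- c(
    get("sleeps_lt3h"),
    get("tremors_disturbed") || get("tremors_undisturbed"),
    get("increased_muscle_tone"),
    get("temp_ge_37_2"),
    get("resp_rate_gt60"),
    get("excessive_sucking"),
    get("poor_feeding"),
    get("regurgitation")
  )
  sum(pts)
}

#' Assign a score to a severity category
#'
#' Categories are `low` = \[0, c1), `medium` = \[c1, c2), `high` = \[c2, Inf)
#' on integer scores.  The original FNAST uses predetermined cutpoints
#' (8, 12); the simplified scale's cutpoints are calibrated (see
#' [select_thresholds()]).
#'
#' @param score Integer score vector.
#' @param cutpoints Length-2 increasing numeric `(c1, c2)`.
#' @return Ordered factor with levels `low < medium < high`.
#' @examples
#' categorize(c(7, 12, 4), cutpoints = c(8, 12))
#' @export
categorize <- function(score, cutpoints = c(8, 12)) {
  stopifnot(length(cutpoints) == 2, cutpoints[1] < cutpoints[2])
  lab <- ifelse(score < cutpoints[1], "low",
         ifelse(score < cutpoints[2], "medium", "high"))
  factor(lab, levels = c("low", "medium", "high"), ordered = TRUE)
}

# maximum attainable original score, from the catalogue itself
max_original_score <- function(items = fnast_items()) {
  sum(tapply(items$weight, items$item_id, max))
}
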