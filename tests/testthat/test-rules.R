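test_that("first_treatment_day honours every clause form", {
  multisite <- treatment_rule(c(2, 8), c(1, 12))
  kentucky <- treatment_rule(c(3, 8), c(2, 12))
  # 2 consecutive >= 8 triggers at the run's final assessment
  expect_equal(first_treatment_day(c(1, 1, 1), c(7, 8, 8), multisite), 1)
  # a single score >= 12 triggers immediately
  expect_equal(first_treatment_day(1, 12, multisite), 1)
  # no 3 consecutive >= 8 and no 2 consecutive >= 12: never triggers
  expect_true(is.na(first_treatment_day(c(1, 1, 2, 2, 3),
                                        c(8, 7, 8, 7, 8), kentucky)))
  # runs cross day boundaries
  expect_equal(first_treatment_day(c(1, 2, 2), c(8, 8, 8), kentucky), 2)
  # earliest satisfying run wins across clauses
  expect_equal(first_treatment_day(c(1, 1, 1), c(12, 12, 8), kentucky), 1)
  # empty sequence
  expect_true(is.na(first_treatment_day(integer(0), numeric(0), multisite)))
  expect_error(treatment_rule())
  expect_error(treatment_rule(c(0, 8)))
})

test_that("extract_analysis_rows picks the max-score assessment of the analysis day", {
  rules <- list(site = treatment_rule(c(2, 8), c(1, 12)))
  # treated on day 2: day-2 scores 9, 11, 10 -> the 11 is kept
  entries <- list(
    list(neonate = "a", cohort = "site", day = 1, index = 1,
         grades = c(muscle_tone = "increased")),
    list(neonate = "a", cohort = "site", day = 2, index = 1,
         grades = c(sleeps_after_feeding = "less_than_1h",
                    tremors_undisturbed = "moderate_severe",
                    moro_reflex = "hyperactive")),                    # 9
    list(neonate = "a", cohort = "site", day = 2, index = 2,
         grades = c(sleeps_after_feeding = "less_than_1h",
                    tremors_undisturbed = "moderate_severe",
                    moro_reflex = "hyperactive",
                    muscle_tone = "increased")),                      # 11
    list(neonate = "a", cohort = "site", day = 2, index = 3,
         grades = c(sleeps_after_feeding = "less_than_1h",
                    tremors_undisturbed = "moderate_severe",
                    excoriation = "present", sweating = "present",
                    nasal_stuffiness = "present"))                    # 10
  )
  rows <- extract_analysis_rows(make_assessments(entries), rules,
                                schedule = make_schedule(entries))
  expect_equal(nrow(rows), 1)
  expect_true(rows$treated)
  expect_equal(rows$analysis_day, 2)
  expect_equal(rows$original_score, 11)
  expect_equal(rows$increased_muscle_tone, 1L)
  expect_equal(rows$excoriation, 0L)
})

test_that("never-treated neonates are analysed on day 3, earliest tie kept", {
  rules <- list(site = treatment_rule(c(2, 8), c(1, 12)))
  entries <- list(
    list(neonate = "b", cohort = "site", day = 3, index = 1,
         grades = c(sweating = "present", mottling = "present",
                    sneezing = "more_than_3",
                    excessive_sucking = "present",
                    nasal_flaring = "present")),  # 6, earlier
    list(neonate = "b", cohort = "site", day = 3, index = 2,
         grades = c(poor_feeding = "present", vomiting = "regurgitation",
                    excoriation = "present", excessive_sucking = "present"))  # 6, later
  )
  rows <- extract_analysis_rows(make_assessments(entries), rules,
                                schedule = make_schedule(entries))
  expect_false(rows$treated)
  expect_equal(rows$analysis_day, 3)
  expect_equal(rows$original_score, 6)
  expect_equal(rows$sweating, 1L)       # the earlier of the tied assessments
  expect_equal(rows$poor_feeding, 0L)
})

test_that("neonates with no assessment on the analysis day are dropped with a count", {
  rules <- list(site = treatment_rule(c(2, 8), c(1, 12)))
  entries <- list(
    list(neonate = "c", cohort = "site", day = 1, index = 1,
         grades = c(sweating = "present")),
    list(neonate = "d", cohort = "site", day = 3, index = 1,
         grades = c(sweating = "present"))
  )
  expect_warning(
    rows <- extract_analysis_rows(make_assessments(entries), rules,
                                  schedule = make_schedule(entries)),
    "no assessment on the analysis day")
  expect_equal(nrow(rows), 1)
  expect_equal(rows$neonate_id, "d")
  expect_equal(attr(rows, "n_dropped"), 1L)
})

test_that("assessment tables are validated", {
  rules <- list(site = treatment_rule(c(2, 8), c(1, 12)))
  bad <- data.frame(neonate_id = "x", cohort_id = "site", day_of_life = 1,
                    assessment_index = 1, item_id = "bogus_item",
                    grade = "present", stringsAsFactors = FALSE)
  expect_error(extract_analysis_rows(bad, rules), "bogus_item")
  dup <- data.frame(neonate_id = "x", cohort_id = "site",
                    day_of_life = c(3, 3), assessment_index = c(1, 1),
                    item_id = c("sweating", "sweating"),
                    grade = c("present", "present"), stringsAsFactors = FALSE)
  expect_error(extract_analysis_rows(dup, rules), "duplicate")
  unknown_cohort <- data.frame(neonate_id = "x", cohort_id = "elsewhere",
                               day_of_life = 3, assessment_index = 1,
                               item_id = "sweating", grade = "present",
                               stringsAsFactors = FALSE)
  expect_error(extract_analysis_rows(unknown_cohort, rules), "elsewhere")
})
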