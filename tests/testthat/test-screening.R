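test_that("chi2_homogeneity reproduces the published p-values", {
  n <- deriv_n()
  # printed two-decimal p-values from the published endorsement table
  expect_equal(round(chi2_homogeneity(c(120, 182, 87), n)$p, 2), 0.28)
  expect_equal(round(chi2_homogeneity(c(36, 48, 20), n)$p, 2), 0.44)
  # small-cell item, no continuity correction: prints .04
  expect_equal(round(chi2_homogeneity(c(4, 5, 8), n)$p, 2), 0.04)
  # homogeneous rates give statistic 0
  res <- chi2_homogeneity(c(10, 10, 10), c(100, 100, 100))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 2)
  # degenerate all-or-none path
  expect_equal(chi2_homogeneity(c(0, 0, 0), n)$p, 1)
  expect_equal(chi2_homogeneity(n, n)$p, 1)
  expect_error(chi2_homogeneity(c(1, 2), c(10, 0)), "positive")
})

test_that("every printed p-value in the endorsement table is reproduced", {
  ref <- reference_endorsement_counts()
  n <- deriv_n()
  printed <- c(
    high_pitched_crying = "<.001", sleeps_lt3h = "<.001",
    hyperactive_moro = "<.001", tremors_disturbed = "<.001",
    tremors_undisturbed = "<.001", increased_muscle_tone = ".28",
    excoriation = ".44", myoclonic_jerks = ".16", sweating = ".49",
    temp_ge_37_2 = "<.001", yawning_gt3 = ".21", mottling = "<.001",
    nasal_stuffiness = ".06", sneezing_gt3 = ".13", nasal_flaring = ".04",
    resp_rate_gt60 = ".007", excessive_sucking = "<.001",
    poor_feeding = ".005", regurgitation = ".002",
    loose_watery_stools = "<.001")
  for (id in names(printed)) {
    cnt <- as.integer(ref[ref$binary_id == id,
                          c("louisville", "tufts", "kentucky")])
    expect_equal(format_pvalue(chi2_homogeneity(cnt, n)$p),
                 printed[[id]], info = id)
  }
})

test_that("chi2_homogeneity agrees with brute-force expected counts", {
  set.seed(21)
  for (rep in 1:40) {
    k <- sample(2:4, 1)
    tot <- sample(20:200, k, replace = TRUE)
    e <- vapply(tot, function(t) sample.int(t - 1, 1), integer(1))
    res <- chi2_homogeneity(e, tot)
    # independent oracle: explicit O/E sum over the full 2 x k table
    p_hat <- sum(e) / sum(tot)
    obs <- rbind(e, tot - e)
    expd <- rbind(tot * p_hat, tot * (1 - p_hat))
    stat <- sum((obs - expd)^2 / expd)
    expect_equal(res$statistic, stat, tolerance = 1e-12)
    expect_equal(res$p, stats::pchisq(stat, k - 1, lower.tail = FALSE))
  }
})

test_that("max_pp_difference matches direct subtraction of published rates", {
  n <- deriv_n()
  expect_equal(round(max_pp_difference(deriv_counts("high_pitched_crying") / n), 1),
               59.1)
  expect_lte(max_pp_difference(deriv_counts("sleeps_lt3h") / n), 50)
  expect_equal(round(max_pp_difference(deriv_counts("sleeps_lt3h") / n), 1),
               31.9)
  expect_equal(max_pp_difference(c(0.2, 0.2, 0.2)), 0)
})

test_that("endorsement_auc reproduces the published concordances", {
  n <- deriv_n()
  crying <- endorsement_auc(deriv_counts("high_pitched_crying"), n)
  expect_equal(round(crying$auc, 2), 0.79)
  moro <- endorsement_auc(deriv_counts("hyperactive_moro"), n)
  expect_equal(round(moro$auc, 2), 0.72)
  # equal rates in every cohort: pure ties
  expect_equal(endorsement_auc(c(10, 20, 30), c(100, 200, 300))$auc, 0.5)
  # degenerate
  expect_true(is.na(endorsement_auc(c(0, 0), c(5, 5))$auc))
  expect_true(is.na(endorsement_auc(c(5, 5), c(5, 5))$auc))
})

test_that("endorsement_auc equals brute-force pair counting", {
  set.seed(31)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    tot <- sample(3:25, k, replace = TRUE)
    e <- vapply(tot, function(t) sample.int(t + 1, 1) - 1L, integer(1))
    if (sum(e) == 0 || sum(e) == sum(tot)) next
    rates <- e / tot
    score <- rep(rates, tot)
    outcome <- unlist(mapply(function(ei, ni) c(rep(1, ei), rep(0, ni - ei)),
                             e, tot, SIMPLIFY = FALSE))
    expect_equal(endorsement_auc(e, tot)$auc,
                 auc_bruteforce(score, outcome), tolerance = 1e-12)
  }
})

test_that("screen_items excludes exactly the published signs on the fixture", {
  rows <- fixture_analysis_rows(include_validation = FALSE)
  scr <- screen_items(rows)
  excl <- attr(scr, "excluded")
  expect_setequal(names(excl), c("high_pitched_crying", "hyperactive_moro",
                                 "generalized_convulsions"))
  expect_equal(unname(excl["generalized_convulsions"]), "never_observed")
  expect_equal(unname(excl["high_pitched_crying"]), "heterogeneity")
  expect_equal(unname(excl["hyperactive_moro"]), "heterogeneity")
  # candidates: 21 signs minus 3 exclusions (no zero-variance sign here)
  expect_equal(length(attr(scr, "candidates")), 18)
  # statistics carried for every sign
  expect_equal(nrow(scr), 21)
  expect_true(all(scr$chi2_p >= 0 & scr$chi2_p <= 1))
  expect_true(all(scr$max_pp_difference >= 0 & scr$max_pp_difference <= 100))
})

test_that("homogeneous and constant signs take the documented paths", {
  set.seed(41)
  n <- 60
  rows <- data.frame(
    neonate_id = as.character(1:n),
    cohort_id = rep(c("a", "b", "c"), each = n / 3),
    treated = rep(c(TRUE, FALSE), n / 2), stringsAsFactors = FALSE)
  for (id in binary_items()) rows[[id]] <- rbinom(n, 1, 0.3)
  rows$increased_muscle_tone <- 1L   # present in every neonate
  rows$generalized_convulsions <- 0L
  scr <- screen_items(rows)
  r <- scr[scr$binary_id == "increased_muscle_tone", ]
  expect_false(r$excluded)          # only the two stated criteria exclude
  expect_true(r$zero_variance)      # but flagged for the regression stage
  expect_false("increased_muscle_tone" %in% attr(scr, "candidates"))
  # a homogeneous-rate fixture yields no heterogeneity exclusions
  rows2 <- rows
  rows2$increased_muscle_tone <- rbinom(n, 1, 0.5)
  scr2 <- screen_items(rows2)
  expect_false(any(scr2$reason == "heterogeneity"))
})

test_that("fixture marginals reproduce the published combined counts", {
  rows <- fixture_analysis_rows(include_validation = TRUE)
  expect_equal(nrow(rows), 533)
  deriv <- rows[rows$cohort_id != "mother", ]
  expect_equal(nrow(deriv), 424)
  expect_equal(sum(rows$cohort_id == "mother"), 109)
  expect_equal(sum(deriv$high_pitched_crying[deriv$cohort_id == "louisville"]),
               98)
  # summed derivation counts equal the published totals
  expect_equal(sum(deriv$increased_muscle_tone), 389)
  expect_equal(sum(deriv$tremors_disturbed), 346)   # 201 mild + 145 moderate
  expect_equal(sum(deriv$tremors_undisturbed), 146) # 88 + 58
  expect_equal(sum(deriv$sleeps_lt3h), 258)         # 83 + 96 + 79
  expect_equal(sum(deriv$hyperactive_moro), 135)    # 127 + 8
  expect_equal(sum(deriv$regurgitation), 76)
  expect_equal(sum(deriv$loose_watery_stools), 104) # 88 + 16
  # level counts aggregate to the binary counts
  lc <- reference_level_counts()
  agg <- tapply(lc$count, fnast_items()$binary_id, sum)
  for (id in binary_items()) {
    expect_equal(unname(agg[id]), sum(deriv[[id]]), info = id)
  }
})

test_that("format_pvalue mimics journal formatting", {
  expect_equal(format_pvalue(c(0.2846, 0.4443, 0.0397, 0.00697, 0.0004)),
               c(".28", ".44", ".04", ".007", "<.001"))
})
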