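test_that("intercept-only MLE is the log-odds of the outcome", {
  # 238 treated of 424, as in the published derivation sample
  y <- c(rep(1, 238), rep(0, 186))
  fit <- fit_logistic(y, NULL)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), log(238 / 186), tolerance = 1e-9)
})

test_that("IRLS matches brute-force optimisation on 2-parameter problems", {
  set.seed(51)
  for (rep in 1:10) {
    n <- 80
    x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x[, 1]))
    if (sum(y) < 3 || sum(1 - y) < 3) next
    fit <- fit_logistic(y, x)
    # independent oracle: direct Nelder-Mead/BFGS maximisation of the
    # log-likelihood
    nll <- function(b) -sum(y * (b[1] + b[2] * x[, 1]) -
                              log1p(exp(b[1] + b[2] * x[, 1])))
    opt <- optim(c(0, 0), nll, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-6)
    expect_equal(fit$loglik, -opt$value, tolerance = 1e-8)
  }
})

test_that("IRLS agrees with glm() including covariance", {
  set.seed(52)
  n <- 300
  x <- cbind(a = rbinom(n, 1, 0.4), b = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + x[, 1] + 0.5 * x[, 2]))
  fit <- fit_logistic(y, x)
  g <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-7)
  expect_equal(unname(diag(fit$vcov)), unname(diag(vcov(g))),
               tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-9)
})

test_that("parameter recovery within 3 SE at n = 5000", {
  set.seed(53)
  n <- 5000
  x <- cbind(x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.3))
  beta <- c(-0.4, 0.9, -0.6)
  y <- rbinom(n, 1, plogis(beta[1] + x %*% beta[2:3]))
  fit <- fit_logistic(y, x)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))
})

test_that("perfect separation is flagged, not fatal", {
  y <- rep(c(0, 1), each = 20)
  x <- matrix(y, ncol = 1, dimnames = list(NULL, "dup"))
  fit <- fit_logistic(y, x)
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_true(all(is.na(wald_tests(fit)$p)))
  # Firth penalization keeps the estimate finite
  firth <- fit_logistic(y, x, firth = TRUE)
  expect_false(firth$separation)
  expect_true(all(abs(firth$coefficients) < 15))
})

test_that("degenerate designs raise named errors", {
  y <- rbinom(40, 1, 0.5)
  expect_error(fit_logistic(y, matrix(1, 40, 1,
                                      dimnames = list(NULL, "const"))),
               "constant.*const")
  x <- cbind(a = rnorm(40))
  x <- cbind(x, b = x[, "a"])
  expect_error(fit_logistic(y, x), "collinear")
})

test_that("log-likelihood is non-decreasing across IRLS iterations", {
  # monitored indirectly: step-halving guarantees the final loglik is at
  # least the null loglik, even on a nasty near-separated design
  set.seed(54)
  n <- 60
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
  y <- as.numeric(x[, 1] + rnorm(n, sd = 0.1) > 0)
  fit <- fit_logistic(y, x)
  null <- fit_logistic(y, NULL)
  expect_gte(fit$loglik, null$loglik)
})

test_that("model_auc equals brute-force pair counting", {
  y <- c(1, 1, 1, 0, 0, 0)
  # perfect ranking
  fit <- list(fitted = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), y = y)
  expect_equal(model_auc(fit), 1.0)
  # one tied pair across classes: 8.5 of 9 pairs concordant
  fit$fitted <- c(0.9, 0.8, 0.7, 0.7, 0.5, 0.4)
  expect_equal(model_auc(fit), 8.5 / 9)
  expect_equal(model_auc(fit), auc_bruteforce(fit$fitted, y))
  # constant probabilities
  fit$fitted <- rep(0.5, 6)
  expect_equal(model_auc(fit), 0.5)
  # single-class outcome undefined
  fit$y <- rep(1, 6)
  expect_true(is.na(model_auc(fit)))
})

test_that("lr and score entry tests agree with glm anova on a known case", {
  set.seed(55)
  n <- 200
  x0 <- cbind(c0 = rbinom(n, 1, 0.5))
  z <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.2 + 0.6 * x0[, 1] + 0.8 * z))
  null <- fit_logistic(y, x0)
  full <- fit_logistic(y, cbind(x0, z = z))
  lr <- lr_test(full, null)
  a <- anova(glm(y ~ x0 + z, family = binomial()), test = "LRT")
  expect_equal(lr$statistic, a$Deviance[3], tolerance = 1e-7)
  expect_equal(lr$p, a$`Pr(>Chi)`[3], tolerance = 1e-7)
  sc <- anova(glm(y ~ x0 + z, family = binomial()), test = "Rao")
  expect_equal(fnast8:::score_test_add(null, z)$statistic, sc$Rao[3],
               tolerance = 1e-6)
})

test_that("stepwise boundary behaviour and collinearity guard", {
  set.seed(56)
  n <- 240
  rows <- data.frame(
    neonate_id = as.character(1:n),
    cohort_id = rep(c("a", "b"), each = n / 2), stringsAsFactors = FALSE)
  rows$s1 <- rbinom(n, 1, 0.5)
  rows$s2 <- rbinom(n, 1, 0.5)
  rows$s3 <- rbinom(n, 1, 0.5)
  rows$treated <- rbinom(n, 1, plogis(-0.5 + 1.2 * rows$s1)) == 1
  # p_enter = p_remove = 1 admits everything
  all_in <- forward_stepwise(rows, c("s1", "s2", "s3"), p_enter = 1.0000001,
                             p_remove = 1.0000001)
  expect_setequal(all_in$selected, c("s1", "s2", "s3"))
  # p_enter = 0 admits nothing
  none <- forward_stepwise(rows, c("s1", "s2", "s3"), p_enter = 0)
  expect_equal(none$selected, character(0))
  # a duplicate of an entered sign is never co-selected
  rows$s1_copy <- rows$s1
  dup <- forward_stepwise(rows, c("s1", "s1_copy", "s2", "s3"))
  expect_false(all(c("s1", "s1_copy") %in% dup$selected))
  expect_true(any(dup$trace$action == "skip_collinear"))
})

test_that("a single strong candidate is selected with a one-step trace", {
  set.seed(57)
  n <- 300
  rows <- data.frame(
    neonate_id = as.character(1:n),
    cohort_id = rep(c("a", "b"), each = n / 2), stringsAsFactors = FALSE)
  rows$s1 <- rbinom(n, 1, 0.5)
  rows$treated <- rbinom(n, 1, plogis(-1 + 2 * rows$s1)) == 1
  sw <- forward_stepwise(rows, "s1")
  expect_equal(sw$selected, "s1")
  expect_equal(sw$trace$action, "add")
  expect_gt(sw$auc, 0.5)
})

test_that("univariate cohort-adjusted models: coverage and separation", {
  set.seed(58)
  covered <- 0
  n_rep <- 100
  for (rep in seq_len(n_rep)) {
    n <- 400
    rows <- data.frame(
      neonate_id = as.character(1:n),
      cohort_id = rep(c("a", "b", "c"), length.out = n),
      stringsAsFactors = FALSE)
    rows$null_item <- rbinom(n, 1, 0.4)   # no true effect, no confounding
    rows$treated <- rbinom(n, 1, 0.5) == 1
    um <- univariate_item_models(rows, "null_item")
    if (um$or_lo <= 1 && um$or_hi >= 1) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.92)
  # sign identical to outcome: separation flagged, batch unaffected
  rows <- data.frame(
    neonate_id = as.character(1:200),
    cohort_id = rep(c("a", "b"), each = 100), stringsAsFactors = FALSE)
  rows$treated <- rep(c(TRUE, FALSE), 100)
  rows$mirror <- as.integer(rows$treated)
  rows$benign <- rbinom(200, 1, 0.5)
  um <- univariate_item_models(rows, c("mirror", "benign"))
  expect_true(um$separation[um$binary_id == "mirror"])
  expect_true(um$converged[um$binary_id == "benign"])
})
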