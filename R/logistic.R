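#' Maximum-likelihood logistic regression via IRLS
#'
#' Self-contained Newton / iteratively reweighted least squares fit of a
#' binary logistic model.  Log-likelihood is guaranteed non-decreasing by
#' step-halving.  Convergence is declared when the largest absolute score
#' (gradient) component falls below `tol_score` or the relative change in
#' log-likelihood falls below `tol_ll`, within `max_iter` iterations.  If any
#' coefficient exceeds `sep_threshold` in absolute value the fit is flagged
#' as probable separation (non-finite MLE); downstream Wald p-values are
#' suppressed for such fits.  An optional Firth bias-reduction penalty gives
#' finite estimates under separation.
#'
#' @param y 0/1 (or logical) outcome vector.
#' @param x Numeric design matrix, one row per observation.  An intercept
#'   column is prepended unless `intercept = FALSE`.
#' @param intercept Prepend an intercept column (default TRUE).
#' @param max_iter,tol_score,tol_ll IRLS controls.
#' @param sep_threshold Absolute coefficient bound beyond which probable
#'   separation is flagged (default 15 on the logit scale).
#' @param firth Use Firth's penalized score (default FALSE).
#' @return Object of class `nas_fit`: `coefficients`, `vcov`, `loglik`,
#'   `converged`, `separation`, `n_iter`, `fitted`, `y`, `x`, `firth`.
#' @export
fit_logistic <- function(y, x, intercept = TRUE, max_iter = 50,
                         tol_score = 1e-8, tol_ll = 1e-10,
                         sep_threshold = 15, firth = FALSE) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (is.null(x)) x <- matrix(numeric(0), length(y), 0)
  x <- as.matrix(x)
  if (intercept) {
    x <- cbind(`(Intercept)` = 1, x)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) != nrow(x)", call. = FALSE)
  if (n <= p) stop("need more observations than parameters", call. = FALSE)
  pred_cols <- setdiff(colnames(x), "(Intercept)")
  const <- vapply(pred_cols, function(cn) all(x[, cn] == x[1, cn]), TRUE)
  if (any(const)) {
    stop("constant predictor column(s): ",
         paste(pred_cols[const], collapse = ", "), call. = FALSE)
  }
  qrx <- qr(x)
  if (qrx$rank < p) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):p]]
    stop("singular design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  loglik <- function(eta) sum(y * eta - log1p(exp(eta)))
  beta <- rep(0, p)
  eta <- drop(x %*% beta)
  ll <- loglik(eta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(x, x * w)
    score <- crossprod(x, y - mu)
    if (firth) {
      # hat diagonal of W^(1/2) X (X'WX)^-1 X' W^(1/2)
      xw <- x * sqrt(w)
      h <- rowSums((xw %*% solve(info)) * xw)
      score <- crossprod(x, y - mu + h * (0.5 - mu))
    }
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break  # information singular (e.g. deep separation)
    # step-halving keeps the (penalized) log-likelihood non-decreasing
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * drop(step)
      eta_new <- drop(x %*% beta_new)
      ll_new <- loglik(eta_new)
      if (firth) {
        mu_n <- stats::plogis(eta_new)
        ll_new <- ll_new +
          0.5 * determinant(crossprod(x, x * (mu_n * (1 - mu_n))))$modulus
      }
      if (ll_new >= ll_obj(ll, firth, x, eta) - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- beta_new; eta <- eta_new
    ll_prev <- ll; ll <- loglik(eta)
    if (max(abs(score)) < tol_score ||
        abs(ll - ll_prev) < tol_ll * (abs(ll_prev) + tol_ll)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  separation <- any(abs(beta) > sep_threshold)
  mu <- stats::plogis(eta)
  info <- crossprod(x, x * (mu * (1 - mu)))
  vcov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(vcov) <- list(colnames(x), colnames(x))
  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(x)),
    vcov = vcov, loglik = ll, converged = converged && !separation,
    separation = separation, n_iter = iter,
    fitted = mu, y = y, x = x, firth = firth
  ), class = "nas_fit")
}

# objective value used in step-halving comparisons
ll_obj <- function(ll, firth, x, eta) {
  if (!firth) return(ll)
  mu <- stats::plogis(eta)
  ll + 0.5 * determinant(crossprod(x, x * (mu * (1 - mu))))$modulus
}

#' @export
print.nas_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: %d obs, %d coef, logLik %.3f, %s%s\n",
              length(x$y), length(x$coefficients), x$loglik,
              if (x$converged) "converged" else "NOT converged",
              if (x$separation) " (probable separation)" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Wald z-tests of a logistic fit
#'
#' @param fit A [fit_logistic()] result.
#' @return Data.frame `term`, `estimate`, `se`, `z`, `p`; p-values are `NA`
#'   for non-converged or separated fits.
#' @export
wald_tests <- function(fit) {
  se <- sqrt(diag(fit$vcov))
  z <- fit$coefficients / se
  p <- 2 * stats::pnorm(-abs(z))
  if (!fit$converged) p[] <- NA_real_
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients), se = unname(se),
             z = unname(z), p = unname(p), stringsAsFactors = FALSE)
}

#' Likelihood-ratio test of nested logistic fits
#'
#' @param fit_full,fit_null Nested [fit_logistic()] results (null within
#'   full).
#' @return List `statistic`, `df`, `p`.
#' @export
lr_test <- function(fit_full, fit_null) {
  df <- length(fit_full$coefficients) - length(fit_null$coefficients)
  stopifnot(df >= 1)
  stat <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Rao score test for adding column z to a fitted null model
score_test_add <- function(fit_null, z) {
  mu <- fit_null$fitted
  w <- mu * (1 - mu)
  x0 <- fit_null$x
  u <- sum(z * (fit_null$y - mu))
  xtwz <- crossprod(x0, z * w)
  v <- sum(z * z * w) - drop(crossprod(xtwz, solve(crossprod(x0, x0 * w),
                                                   xtwz)))
  if (v <= 0) return(list(statistic = NA_real_, p = NA_real_))
  stat <- u^2 / v
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Concordance of a fitted model
#'
#' AUC of the fitted probabilities against the outcome, ties one-half.
#'
#' @param fit A converged [fit_logistic()] result.
#' @param y Optional outcome override (defaults to the fit's own outcome).
#' @param ci Also return a Hanley-McNeil 95% CI.
#' @return AUC, or list `auc`, `ci` when `ci = TRUE`; `NA` when the outcome
#'   has a single class.
#' @export
model_auc <- function(fit, y = fit$y, ci = FALSE) {
  auc <- concordance(fit$fitted, y)
  if (!ci) return(auc)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  se <- auc_se_hanley(auc, n1, n0)
  list(auc = auc, ci = pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * se)))
}

# cohort indicator columns, reference = largest cohort
cohort_indicators <- function(cohort_id) {
  tab <- sort(table(cohort_id), decreasing = TRUE)
  levels <- names(tab)
  if (length(levels) < 2) {
    return(matrix(numeric(0), nrow = length(cohort_id), ncol = 0))
  }
  out <- sapply(levels[-1], function(l) as.numeric(cohort_id == l))
  colnames(out) <- paste0("cohort_", levels[-1])
  out
}

#' Per-item cohort-adjusted logistic models
#'
#' One logistic model per candidate sign: treated ~ sign + cohort
#' indicators.  Reports the sign's odds ratio with Wald 95% CI and p-value;
#' separated or non-converged fits are reported with `NA` p-values rather
#' than failing the batch.
#'
#' @param rows Analysis-row data.frame.
#' @param sign_ids Candidate binary sign columns.
#' @return Data.frame `binary_id`, `or`, `or_lo`, `or_hi`, `p`,
#'   `converged`, `separation`.
#' @export
univariate_item_models <- function(rows, sign_ids) {
  y <- as.numeric(rows$treated)
  coh <- cohort_indicators(rows$cohort_id)
  out <- lapply(sign_ids, function(id) {
    xi <- rows[[id]]
    res <- tryCatch({
      xm <- cbind(xi, coh)
      colnames(xm)[1] <- id
      fit <- fit_logistic(y, xm)
      wt <- wald_tests(fit)
      row <- wt[wt$term == id, ]
      data.frame(binary_id = id, or = exp(row$estimate),
                 or_lo = exp(row$estimate - 1.96 * row$se),
                 or_hi = exp(row$estimate + 1.96 * row$se),
                 p = row$p, converged = fit$converged,
                 separation = fit$separation, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(binary_id = id, or = NA_real_, or_lo = NA_real_,
                 or_hi = NA_real_, p = NA_real_, converged = FALSE,
                 separation = NA, stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Tremor parameterization of the candidate set
#'
#' The simplified scale scores tremors as a single "any tremors" indicator,
#' but the two dichotomized tremor signs also exist separately.  In `"any"`
#' mode (the default model parameterization) the two tremor candidates are
#' replaced by their union `any_tremors`; in `"separate"` mode they are left
#' as two indicators.
#'
#' @param rows Analysis-row data.frame.
#' @param candidates Candidate sign columns.
#' @param mode `"any"` or `"separate"`.
#' @return List `rows`, `candidates`.
#' @export
tremor_parameterization <- function(rows, candidates,
                                    mode = c("any", "separate")) {
  mode <- match.arg(mode)
  trem <- intersect(c("tremors_disturbed", "tremors_undisturbed"),
                    candidates)
  if (mode == "any" && length(trem) > 0) {
    rows$any_tremors <- as.integer(
      (rows[["tremors_disturbed"]] %||% 0) |
        (rows[["tremors_undisturbed"]] %||% 0))
    candidates <- c(setdiff(candidates, trem), "any_tremors")
  }
  list(rows = rows, candidates = candidates)
}

#' Forward stepwise logistic selection with forced cohort adjustment
#'
#' Iterates: for every candidate not in the model, compute its entry p-value
#' against the current model (likelihood-ratio test by default, Rao score
#' test optionally); add the candidate with the smallest p if p <
#' `p_enter` (ties broken lexicographically by id); then re-test every
#' non-forced included sign by Wald p and remove signs with p >=
#' `p_remove`, largest first, one at a time with refitting.  Stops when no
#' addition is possible.  Candidates whose augmented design is rank
#' deficient or whose fit fails are skipped for that step with a logged
#' note.
#'
#' @param rows Analysis-row data.frame with `treated`, `cohort_id` and one
#'   column per candidate sign.
#' @param candidates Character vector of candidate sign columns.
#' @param p_enter,p_remove Entry / retention thresholds (defaults .10, .05).
#' @param entry_test `"lr"` (default) or `"score"`.
#' @param firth Passed to [fit_logistic()].
#' @return List of class `nas_stepwise`: `selected` (character), `fit`
#'   (final [fit_logistic()] on forced + selected terms), `trace`
#'   (data.frame of step, action, term, p), `auc`, `p_enter`, `p_remove`.
#' @export
forward_stepwise <- function(rows, candidates, p_enter = 0.10,
                             p_remove = 0.05, entry_test = c("lr", "score"),
                             firth = FALSE) {
  entry_test <- match.arg(entry_test)
  y <- as.numeric(rows$treated)
  forced <- cohort_indicators(rows$cohort_id)
  xmat <- as.matrix(rows[candidates])
  storage.mode(xmat) <- "numeric"

  design <- function(sel) cbind(forced, xmat[, sel, drop = FALSE])
  refit <- function(sel) fit_logistic(y, design(sel), firth = firth)

  selected <- character(0)
  visited <- character(0)  # selected-set states already seen (cycle guard)
  trace <- list()
  note <- function(step, action, term, p) {
    trace[[length(trace) + 1]] <<- data.frame(
      step = step, action = action, term = term, p = p,
      stringsAsFactors = FALSE)
  }
  current <- refit(selected)
  step <- 0L
  repeat {
    step <- step + 1L
    pool <- sort(setdiff(candidates, selected))  # lexicographic tie-break
    if (!length(pool)) break
    entry_p <- rep(NA_real_, length(pool))
    for (i in seq_along(pool)) {
      cand <- pool[i]
      xa <- design(c(selected, cand))
      if (qr(cbind(1, xa))$rank < ncol(xa) + 1) {
        note(step, "skip_collinear", cand, NA_real_)
        next
      }
      entry_p[i] <- tryCatch({
        if (entry_test == "lr") {
          lr_test(refit(c(selected, cand)), current)$p
        } else {
          score_test_add(current, xmat[, cand])$p
        }
      }, error = function(e) {
        note(step, "skip_error", cand, NA_real_)
        NA_real_
      })
    }
    if (all(is.na(entry_p)) || min(entry_p, na.rm = TRUE) >= p_enter) break
    best <- pool[which.min(entry_p)]  # first minimum = lexicographic tie-break
    selected <- c(selected, best)
    current <- refit(selected)
    note(step, "add", best, min(entry_p, na.rm = TRUE))
    # backward pass: drop failing signs one at a time, worst first
    repeat {
      if (!length(selected)) break
      wt <- wald_tests(current)
      wt <- wt[wt$term %in% selected, ]
      if (!nrow(wt) || all(is.na(wt$p)) ||
          max(wt$p, na.rm = TRUE) < p_remove) break
      worst <- wt$term[which.max(wt$p)]
      selected <- setdiff(selected, worst)
      current <- refit(selected)
      note(step, "remove", worst, max(wt$p, na.rm = TRUE))
    }
    # cycle guard: entry and retention use different statistics, so a sign
    # can oscillate in and out near the thresholds; stop on a repeat state
    state <- paste(sort(selected), collapse = "|")
    if (state %in% visited) {
      note(step, "stop_cycle", state, NA_real_)
      break
    }
    visited <- c(visited, state)
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), action = character(0),
               term = character(0), p = numeric(0))
  structure(list(selected = selected, fit = current, trace = trace,
                 auc = model_auc(current), p_enter = p_enter,
                 p_remove = p_remove, entry_test = entry_test),
            class = "nas_stepwise")
}

#' @export
print.nas_stepwise <- function(x, ...) {
  cat(sprintf("Forward stepwise (entry %s, p_enter %.2f, p_remove %.2f)\n",
              x$entry_test, x$p_enter, x$p_remove))
  cat("Selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("Model AUC: %.3f\n", x$auc))
  invisible(x)
}
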