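#' Pointwise one-sample t-tests against chance, Bonferroni corrected
#'
#' One-sample t-test per time point of the subjects x times accuracy matrix
#' against the chance level, with the 0.05 alpha Bonferroni corrected over the
#' number of tested time points. Time points with zero variance across
#' subjects (undefined t) are flagged non-significant with a warning.
#'
#' @param acc subjects x times matrix of decoding accuracies.
#' @param chance chance level (default 0.25 for four classes).
#' @param alpha familywise alpha before correction (default 0.05).
#' @param tail `"greater"` (above-chance, default) or `"two_sided"`.
#' @return list with `t`, `p` (uncorrected), `p_bonf`, `significant` (logical
#'   per time point), `alpha_per_point`.
#' @export
pointwise_vs_chance <- function(acc, chance = 0.25, alpha = 0.05,
                                tail = c("greater", "two_sided")) {
  tail <- match.arg(tail)
  if (nrow(acc) < 2) stop("need >= 2 subjects")
  n <- nrow(acc)
  m <- colMeans(acc)
  v <- apply(acc, 2, stats::var)
  t <- (m - chance) / sqrt(v / n)
  # 0/0 (constant at chance) is undefined; +-Inf (constant away from chance)
  # is an unambiguous extreme and keeps its p of 0
  bad <- is.nan(t)
  if (any(bad)) {
    warning(sum(bad), " time point(s) with zero variance; treated as ",
            "non-significant")
  }
  p <- if (tail == "greater") stats::pt(t, n - 1, lower.tail = FALSE)
       else 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
  p[bad] <- 1
  t[bad] <- NA_real_
  n_tests <- ncol(acc)
  p_bonf <- pmin(p * n_tests, 1)
  list(t = t, p = p, p_bonf = p_bonf, significant = p_bonf < alpha,
       alpha_per_point = alpha / n_tests)
}

#' Spearman rank correlation
#'
#' Tie-corrected rank correlation with the t-approximation p-value
#' (stats::cor.test). Constant inputs give an NA rho with a warning rather
#' than an error.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# JZS marginal-likelihood integrand over the g scale mixture: the Bayes
# factor for a t statistic with effective sample size N and df nu under a
# Cauchy(0, r) prior on the standardized effect equals
#   integral_0^inf (1 + N g)^{-1/2} (1 + t^2 / ((1 + N g) nu))^{-(nu+1)/2}
#                  invgamma(g; 1/2, r^2/2) dg
#   / (1 + t^2 / nu)^{-(nu+1)/2}
.jzs_bf_from_t <- function(t, N, nu, prior_scale) {
  r2 <- prior_scale^2
  num_int <- stats::integrate(function(g) {
    (1 + N * g)^(-0.5) *
      (1 + t^2 / ((1 + N * g) * nu))^(-(nu + 1) / 2) *
      sqrt(r2 / (2 * pi)) * g^(-1.5) * exp(-r2 / (2 * g))
  }, 0, Inf, rel.tol = 1e-9, stop.on.error = FALSE)
  if (num_int$message != "OK" && num_int$value <= 0) {
    stop("JZS integration failed: ", num_int$message)
  }
  num_int$value / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

#' JZS (default Cauchy-prior) Bayes factor for t-tests
#'
#' Bayes factor BF10 against the point null, with a Cauchy prior of scale
#' `prior_scale` (default sqrt(2)/2) on the standardized effect size,
#' evaluated by numerical integration of the g-scale-mixture marginal
#' likelihood. Two-sample (independent groups) and one-sample variants.
#'
#' @param a,b numeric samples (`b = NULL` for one-sample against `mu`).
#' @param prior_scale Cauchy prior scale (default sqrt(2)/2).
#' @param mu one-sample null value.
#' @return a `bayes_factor` list: `bf10`, `bf01`, `t`, `df`, `n`,
#'   `prior_scale`, `test`.
#' @export
jzs_bf <- function(a, b = NULL, prior_scale = sqrt(2) / 2, mu = 0) {
  if (is.null(b)) {
    if (length(a) < 2) stop("need n >= 2")
    n <- length(a)
    t <- (mean(a) - mu) / (stats::sd(a) / sqrt(n))
    N <- n
    nu <- n - 1
    test <- "one_sample"
  } else {
    if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
      (n1 + n2 - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    N <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
    test <- "two_sample"
  }
  bf10 <- .jzs_bf_from_t(t, N, nu, prior_scale)
  structure(list(bf10 = bf10, bf01 = 1 / bf10, t = t, df = nu,
                 n = if (is.null(b)) length(a) else c(length(a), length(b)),
                 prior_scale = prior_scale, test = test),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("<JZS %s BF10 = %.4g (t = %.3f, df = %.1f, r = %.3f)>\n",
              x$test, x$bf10, x$t, x$df, x$prior_scale))
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' @param a,b numeric samples.
#' @return list with `t`, `df` (Welch-Satterthwaite), `p`, `ci` (95%).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero variance in both groups")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       ci = unname(tt$conf.int))
}

#' TOST equivalence test (two one-sided Welch tests)
#'
#' Tests whether the group difference lies within `(-delta, +delta)`: one
#' one-sided Welch test of `diff > -delta` and one of `diff < +delta`;
#' equivalence is claimed iff both are significant at `alpha`. Bounds can be
#' given in raw units or standardized (Cohen's d) units, in which case they
#' are scaled by the pooled sd.
#'
#' @param a,b numeric samples.
#' @param delta equivalence bound (> 0).
#' @param units `"standardized"` (default) or `"raw"`.
#' @param alpha significance level (default 0.05).
#' @return list with `equivalent`, `p_lower`, `p_upper`, `t_lower`, `t_upper`,
#'   `df`, `delta_raw`, `delta`, `units`.
#' @export
tost_equivalence <- function(a, b, delta = 0.5,
                             units = c("standardized", "raw"), alpha = 0.05) {
  units <- match.arg(units)
  if (delta <= 0) stop("delta must be > 0")
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  delta_raw <- if (units == "standardized") {
    sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
                 (n1 + n2 - 2))
    delta * sp
  } else delta
  se <- sqrt(stats::var(a) / n1 + stats::var(b) / n2)
  df <- se^4 / ((stats::var(a) / n1)^2 / (n1 - 1) +
                  (stats::var(b) / n2)^2 / (n2 - 1))
  d <- mean(a) - mean(b)
  t_lower <- (d + delta_raw) / se   # H0: diff <= -delta vs H1: diff > -delta
  t_upper <- (d - delta_raw) / se   # H0: diff >= +delta vs H1: diff < +delta
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df)
  list(equivalent = p_lower < alpha && p_upper < alpha,
       p_lower = p_lower, p_upper = p_upper,
       t_lower = t_lower, t_upper = t_upper, df = df,
       delta_raw = delta_raw, delta = delta, units = units)
}

#' Logistic model of tinnitus status on the prediction score
#'
#' Maximum-likelihood logistic regression of group membership (tinnitus = 1)
#' on the per-subject prediction score, optionally controlling for mean
#' hearing ability (PTA-4, or the extended PTA including 6000/8000 Hz).
#' Reports coefficients with Wald standard errors and p-values, the odds
#' ratio per 1 sd of the prediction score, and the reversed linear model
#' (score on group + covariate). Perfect separation is detected and reported
#' as an explicit diagnostic.
#'
#' @param score numeric per-subject prediction scores.
#' @param group factor/character with `"tinnitus"` and `"control"`.
#' @param pta optional numeric covariate (mean hearing ability, dB HL).
#' @return a `logistic_model` list: `coefficients` (data.frame), `or_per_sd`,
#'   `score_sd`, `separation`, `reversed` (lm coefficient table for the score
#'   ~ group model).
#' @export
logistic_tinnitus_model <- function(score, group, pta = NULL) {
  y <- as.integer(group == "tinnitus")
  if (length(unique(y)) < 2) stop("both groups must be present")
  df <- data.frame(y = y, prediction_score = score)
  form <- y ~ prediction_score
  if (!is.null(pta)) {
    df$pta <- pta
    form <- y ~ prediction_score + pta
  }
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = df))
  eta <- stats::fitted(fit)
  separation <- !fit$converged || all(abs(eta - y) < 1e-8)
  if (separation) {
    warning("(quasi-)perfect separation detected; coefficients unreliable")
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], row.names = NULL)
  s_sd <- stats::sd(score)
  b_score <- coefs$estimate[coefs$term == "prediction_score"]
  rev_form <- if (is.null(pta)) prediction_score ~ y else
    prediction_score ~ y + pta
  rev_fit <- stats::lm(rev_form, data = df)
  rsm <- summary(rev_fit)$coefficients
  reversed <- data.frame(term = rownames(rsm), estimate = rsm[, 1],
                         se = rsm[, 2], t = rsm[, 3], p = rsm[, 4],
                         row.names = NULL)
  structure(list(coefficients = coefs, or_per_sd = exp(b_score * s_sd),
                 score_sd = s_sd, separation = separation,
                 reversed = reversed, fit = fit),
            class = "logistic_model")
}

#' Bayes-factor curve over subsampled trial counts
#'
#' For each requested trial count, draw (without replacement, per carrier
#' frequency and condition) that many trials per condition from every
#' subject's epochs, rerun the decoding + prediction-score stages, and
#' compute the two-sample JZS Bayes factor on the group difference of the
#' windowed prediction score. Quantifies how the group effect's evidence
#' depends on the number of trials available for the classifier.
#'
#' @param cohort a cohort from [simulate_cohort()].
#' @param trial_counts trial counts per condition (default
#'   `c(200, 750, 1500, 3600)`).
#' @param seed integer seed for the subsampling.
#' @param cfg a `decoder_config`.
#' @param w a `window_spec`.
#' @param prior_scale JZS prior scale.
#' @return data.frame with `n_trials`, `bf10`, `t`, plus attribute `scores`
#'   (subjects x counts matrix of windowed scores).
#' @export
subsample_bf_curve <- function(cohort, trial_counts = c(200, 750, 1500, 3600),
                               seed = 1L, cfg = decoder_config(),
                               w = window_spec(), prior_scale = sqrt(2) / 2) {
  res <- data.frame(n_trials = numeric(0), bf10 = numeric(0), t = numeric(0))
  groups <- vapply(cohort$subjects, `[[`, character(1), "group")
  all_scores <- matrix(NA_real_, length(cohort$subjects), length(trial_counts))
  for (ci in seq_along(trial_counts)) {
    count <- trial_counts[ci]
    scores <- rep(NA_real_, length(cohort$subjects))
    ok <- TRUE
    for (s in seq_along(cohort$subjects)) {
      ep <- cohort$subjects[[s]]$epochs
      sub <- subsample_epochs(ep, count, cfg$train_condition,
                              seed = derive_seed(seed, ci * 1000L + s))
      if (is.null(sub)) {
        warning("trial count ", count, " exceeds availability; skipped")
        ok <- FALSE
        break
      }
      scores[s] <- subject_prediction_score(sub, cfg, w)
    }
    if (!ok) next
    all_scores[, ci] <- scores
    bf <- jzs_bf(scores[groups == "tinnitus"], scores[groups == "control"],
                 prior_scale = prior_scale)
    res <- rbind(res, data.frame(n_trials = count, bf10 = bf$bf10, t = bf$t))
  }
  attr(res, "scores") <- all_scores
  res
}

#' Subsample an epochs container to a fixed trial count per condition
#'
#' Draws `count` non-omission trials per condition, balanced over carrier
#' frequencies (count/K per tone class), without replacement. Returns NULL if
#' any condition lacks enough trials of some class. Drawing the full
#' available count returns all trials (identity draw).
#'
#' @param epochs a `meg_epochs`.
#' @param count trials per condition.
#' @param train_condition unused placeholder kept for API symmetry.
#' @param seed integer seed.
#' @export
subsample_epochs <- function(epochs, count, train_condition = "random",
                             seed = 1L) {
  conds <- unique(epochs$condition)
  classes <- sort(unique(epochs$labels))
  K <- length(classes)
  per_class <- count / K
  cells <- list()
  take_all <- logical(0)
  for (cc in conds) {
    avail_cond <- sum(epochs$condition == cc & !epochs$is_omission)
    if (avail_cond < count) return(NULL)
    for (k in classes) {
      idx <- which(epochs$condition == cc & epochs$labels == k &
                     !epochs$is_omission)
      # the full-availability draw keeps every trial (identity draw even
      # though class counts fluctuate around count/K)
      if (avail_cond > count && length(idx) < floor(per_class)) return(NULL)
      cells[[length(cells) + 1L]] <- idx
      take_all[length(cells)] <- avail_cond == count
    }
  }
  keep <- withr::with_seed(seed, {
    unlist(lapply(seq_along(cells), function(ci) {
      idx <- cells[[ci]]
      n_take <- min(length(idx), ceiling(per_class))
      if (take_all[ci] || n_take == length(idx)) idx else sample(idx, n_take)
    }))
  })
  keep <- sort(keep)
  meg_epochs(epochs$data[keep, , , drop = FALSE], epochs$times_s,
             epochs$labels[keep], epochs$condition[keep],
             sfreq = epochs$sfreq, subject_id = epochs$subject_id,
             is_omission = epochs$is_omission[keep])
}

#' Windowed pre-stimulus prediction score of one subject
#'
#' Cross-decodes the ordered and random conditions from classifiers trained
#' on the random condition within the training window, forms the
#' ordered-minus-random difference, and returns its mean over the training
#' and testing windows. The random-condition testing uses cross-validation
#' folds (no resubstitution).
#'
#' @param epochs a `meg_epochs` containing random and ordered trials.
#' @param cfg a `decoder_config`.
#' @param w a `window_spec`.
#' @param return_course if TRUE return the full testing-time course instead
#'   of the scalar.
#' @export
subject_prediction_score <- function(epochs, cfg = decoder_config(),
                                     w = window_spec(),
                                     return_course = FALSE) {
  tew <- w$test_window_s
  trw <- w$train_window_s
  acc_ord <- cross_decode(epochs, epochs, cfg, test_condition = "ordered",
                          train_window_s = trw, test_window_s = tew)
  acc_rand <- cv_random_windowed(epochs, cfg, trw, tew)
  sc <- diff_score(acc_ord, acc_rand)
  ws <- suppressWarnings(window_score(sc, w))
  if (return_course) ws else ws$window_mean
}

# CV-based temporal generalization of the random condition restricted to a
# train/test window pair (train post-stimulus, test pre-stimulus on held-out
# folds)
cv_random_windowed <- function(epochs, cfg, train_window_s, test_window_s) {
  keep <- epochs$condition == cfg$train_condition & !epochs$is_omission
  dat <- epochs$data[keep, , , drop = FALSE]
  y <- epochs$labels[keep]
  fold <- .stratified_folds(y, cfg$n_folds, cfg$fold_seed)
  tr_idx <- .time_index(epochs$times_s, .clip_window(train_window_s,
                                                     epochs$times_s))
  te_idx <- .time_index(epochs$times_s, test_window_s)
  acc <- matrix(0, length(tr_idx), length(te_idx))
  for (f in seq_len(cfg$n_folds)) {
    tr <- fold != f
    for (ti in seq_along(tr_idx)) {
      model <- fit_shrinkage_lda(dat[tr, , tr_idx[ti]], y[tr], cfg$shrinkage)
      pred <- .predict_all_times(model, dat[!tr, , , drop = FALSE], te_idx)
      acc[ti, ] <- acc[ti, ] + colSums(pred == y[!tr])
    }
  }
  timegen_matrix(acc / length(y), epochs$times_s[tr_idx],
                 epochs$times_s[te_idx], test_condition = cfg$train_condition,
                 subject_id = epochs$subject_id)
}

.clip_window <- function(win, times) {
  c(max(win[1], min(times)), min(win[2], max(times)))
}
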