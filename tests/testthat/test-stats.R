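# Group-level statistics: Welch, Spearman, Bayes factors, equivalence,
# logistic models, trial subsampling.

test_that("Welch's t matches the textbook formula", {
  set.seed(1)
  a <- rnorm(14, 0.2, 1.3); b <- rnorm(9, -0.1, 0.6)
  got <- welch_t(a, b)
  se2a <- var(a) / length(a); se2b <- var(b) / length(b)
  t_ref <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df_ref <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  expect_equal(got$t, t_ref, tolerance = 1e-12)
  expect_equal(got$df, df_ref, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(abs(t_ref), df_ref, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(welch_t(a, a)$t, 0)
  # equal variance, equal n: Welch df approaches the pooled df
  set.seed(2)
  x <- rnorm(40); y <- rnorm(40)
  expect_lt(abs(welch_t(x, y)$df - 78), 6)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Spearman correlation has its rank-based fixed points", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  set.seed(3)
  y <- rnorm(20); z <- rnorm(20)
  expect_equal(spearman_cor(y, z)$rho, spearman_cor(exp(y), z)$rho,
               tolerance = 1e-12)  # monotone-transform invariance
  expect_warning(out <- spearman_cor(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman_cor(1:3, 1:3), "n >= 4")
})

test_that("JZS Bayes factors favor the null at t = 0 and the effect when large", {
  set.seed(4)
  a <- rnorm(40); b <- a  # identical groups, t = 0
  expect_lt(jzs_bf(a, b)$bf10, 1)
  a2 <- rnorm(40, 1.2, 1); b2 <- rnorm(40, 0, 1)
  expect_gt(jzs_bf(a2, b2)$bf10, 3)
  bf <- jzs_bf(a2, b2)
  expect_equal(bf$bf10 * bf$bf01, 1, tolerance = 1e-10)
  expect_gt(jzs_bf(rnorm(20, 0.9, 1))$bf10, 3)  # one-sample variant
})

test_that("JZS Bayes factors match an independent quadrature oracle", {
  # oracle route: marginal likelihood as noncentral-t mixed over a Cauchy
  # prior on delta, instead of the g-scale-mixture integral
  oracle_bf <- function(t, N, nu, r) {
    num <- suppressWarnings(stats::integrate(function(delta)
      stats::dt(t, nu, ncp = delta * sqrt(N)) * stats::dcauchy(delta, 0, r),
      -Inf, Inf, rel.tol = 1e-8)$value)
    num / stats::dt(t, nu)
  }
  set.seed(5)
  cases <- list(list(a = rnorm(15, 0.5), b = rnorm(20)),
                list(a = rnorm(8), b = rnorm(8)),
                list(a = rnorm(40, 0.8), b = rnorm(40)))
  for (cs in cases) {
    got <- jzs_bf(cs$a, cs$b)
    ref <- oracle_bf(got$t, length(cs$a) * length(cs$b) /
                       (length(cs$a) + length(cs$b)),
                     got$df, sqrt(2) / 2)
    expect_equal(got$bf10, ref, tolerance = 0.01)
  }
})

test_that("TOST equivalence matches a one-sided t oracle", {
  set.seed(6)
  a <- rnorm(60); b <- rnorm(60)
  res <- tost_equivalence(a, b, delta = 0.5)
  expect_true(res$equivalent)  # zero true difference, generous bound
  # independent recomputation of both one-sided Welch p-values
  se <- sqrt(var(a) / 60 + var(b) / 60)
  df <- se^4 / ((var(a) / 60)^2 / 59 + (var(b) / 60)^2 / 59)
  d0 <- mean(a) - mean(b)
  expect_equal(res$p_lower,
               pt((d0 + res$delta_raw) / se, df, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p_upper, pt((d0 - res$delta_raw) / se, df),
               tolerance = 1e-12)
  # a difference far beyond the bound is not equivalent
  expect_false(tost_equivalence(a + 2, b, delta = 0.5)$equivalent)
  expect_error(tost_equivalence(a, b, delta = 0), "delta")
  raw <- tost_equivalence(a, b, delta = 0.4, units = "raw")
  expect_equal(raw$delta_raw, 0.4)
})

test_that("the logistic tinnitus model reports null predictors as null", {
  set.seed(7)
  n <- 40
  group <- rep(c("tinnitus", "control"), each = n)
  score <- rnorm(2 * n)           # carries no group information
  pta <- 15 + 10 * (group == "tinnitus") + rnorm(2 * n, 0, 4)
  fit <- logistic_tinnitus_model(score, group, pta)
  cf <- fit$coefficients
  expect_gt(cf$p[cf$term == "prediction_score"], 0.05)
  expect_lt(cf$p[cf$term == "pta"], 0.05)
  expect_false(fit$separation)
  # odds ratio per sd is definitionally exp(b * sd)
  b <- cf$estimate[cf$term == "prediction_score"]
  expect_equal(fit$or_per_sd, exp(b * sd(score)), tolerance = 1e-12)
  # reversed model is reported
  expect_true("y" %in% fit$reversed$term)
})

test_that("the logistic slope is recovered across simulated cohorts", {
  # parameter recovery against the known generative log-odds slope
  b_true <- 1.2
  ests <- vapply(1:200, function(r) {
    withr::with_seed(2000 + r, {
      score <- rnorm(80, 0, 1)
      y <- rbinom(80, 1, stats::plogis(b_true * score))
      group <- ifelse(y == 1, "tinnitus", "control")
      if (length(unique(group)) < 2) return(NA_real_)
      fit <- logistic_tinnitus_model(score, group)
      fit$coefficients$estimate[fit$coefficients$term == "prediction_score"]
    })
  }, numeric(1))
  ests <- ests[is.finite(ests)]
  mc_se <- sd(ests) / sqrt(length(ests))
  # small-sample ML bias inflates slopes slightly; allow it on top of MC error
  expect_lt(abs(mean(ests) - b_true), 3 * mc_se + 0.15)
})

test_that("perfect separation is diagnosed, not silently fitted", {
  score <- c(rnorm(20, -3), rnorm(20, 3))
  group <- rep(c("control", "tinnitus"), each = 20)
  expect_warning(fit <- logistic_tinnitus_model(score, group), "separation")
  expect_true(fit$separation)
})

test_that("the full-count subsample draw reproduces the direct analysis", {
  d <- tiny_design(60)
  co <- simulate_cohort(d, 2, seed = 77,
                        sensors = make_sensor_model(6, 4, seed = 2))
  cfg <- decoder_config(fold_seed = 5)
  w <- window_spec()
  curve <- subsample_bf_curve(co, trial_counts = c(60), seed = 3, cfg = cfg,
                              w = w)
  direct <- vapply(co$subjects, function(s)
    subject_prediction_score(s$epochs, cfg, w), numeric(1))
  expect_equal(attr(curve, "scores")[, 1], direct, tolerance = 1e-12)
  # a count beyond availability is skipped with a warning
  expect_warning(out <- subsample_bf_curve(co, trial_counts = c(500),
                                           seed = 3, cfg = cfg, w = w),
                 "exceeds availability")
  expect_identical(nrow(out), 0L)
})

test_that("evidence for a real group effect grows with trial count", {
  bfs <- sapply(1:3, function(r) {
    d <- tiny_design(200)
    co <- simulate_cohort(d, 8, seed = 800 + r,
                          sensors = make_sensor_model(16, 4,
                                                      seed = derive_seed(800 + r, 1)))
    curve <- subsample_bf_curve(co, trial_counts = c(48, 200),
                                seed = r, cfg = decoder_config(fold_seed = r))
    curve$bf10
  })
  expect_gt(median(bfs[2, ]), median(bfs[1, ]))
})
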