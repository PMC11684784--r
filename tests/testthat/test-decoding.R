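# Shrinkage LDA, cross-validated and cross-condition decoding, confusion
# bias score.

test_that("separable noiseless classes are decoded perfectly", {
  ep <- separable_epochs(n_per_class = 10)
  res <- cv_decode_random(ep, decoder_config(fold_seed = 4))
  expect_equal(res$accuracy, rep(1, 5))
  expect_true(all(res$timegen$acc == 1))  # patterns generalize across time
  # resubstitution via cross-decoding is also perfect
  tg <- cross_decode(ep, ep, decoder_config(fold_seed = 4))
  expect_true(all(tg$acc == 1))
})

test_that("the temporal generalization diagonal equals the accuracy course", {
  ep <- separable_epochs(n_per_class = 10, noise_sd = 1.5, seed = 2)
  res <- cv_decode_random(ep, decoder_config(fold_seed = 9))
  expect_equal(diag(res$timegen$acc), res$accuracy)
  res2 <- cv_decode_random(ep, decoder_config(fold_seed = 9), timegen = FALSE)
  expect_equal(res2$accuracy, res$accuracy)  # same folds, same course
})

test_that("two-class LDA matches a closed-form discriminant oracle", {
  # independent oracle: classify by the sign of (x - (m0+m1)/2)' S^-1 (m1-m0)
  set.seed(5)
  n <- 20
  y <- rep(0:1, each = n / 2)
  for (t in 1:3) {
    x <- matrix(rnorm(n * 2), n, 2) + 0.8 * cbind(y, -y)
    m0 <- colMeans(x[y == 0, ]); m1 <- colMeans(x[y == 1, ])
    xc <- x
    xc[y == 0, ] <- sweep(x[y == 0, ], 2, m0)
    xc[y == 1, ] <- sweep(x[y == 1, ], 2, m1)
    S <- crossprod(xc) / (n - 2)
    w <- solve(S, m1 - m0)
    oracle <- as.integer((x - rep((m0 + m1) / 2, each = n)) %*% w > 0)
    model <- fit_shrinkage_lda(x, y, shrinkage = 0)
    expect_identical(predict(model, x), oracle)
  }
})

test_that("unregularized LDA agrees with an established implementation", {
  skip_if_not_installed("MASS")
  set.seed(8)
  n <- 60
  y <- rep(0:3, each = n / 4)
  x <- matrix(rnorm(n * 3), n, 3) + 1.2 * cbind(y == 1, y == 2, y == 3)
  ours <- predict(fit_shrinkage_lda(x, y, shrinkage = 0), x)
  ref <- as.integer(as.character(predict(MASS::lda(x, grouping = y))$class))
  expect_identical(ours, ref)
})

test_that("label-permuted decoding sits at chance", {
  fx <- tiny_subject(seed = 17, n_trials_per_condition = 120, n_channels = 10)
  ep <- fx$epochs
  accs <- vapply(1:5, function(r) {
    perm <- ep
    keep <- perm$condition == "random"
    perm$labels[keep] <- withr::with_seed(100 + r,
                                          sample(perm$labels[keep]))
    res <- cv_decode_random(perm, decoder_config(fold_seed = r),
                            train_window_s = c(0, 0.2),
                            test_window_s = c(0, 0.2), timegen = FALSE)
    mean(res$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.05)
})

test_that("decoding is deterministic given the fold seed", {
  ep <- separable_epochs(n_per_class = 10, noise_sd = 1, seed = 3)
  r1 <- cv_decode_random(ep, decoder_config(fold_seed = 11))
  r2 <- cv_decode_random(ep, decoder_config(fold_seed = 11))
  expect_identical(r1$timegen$acc, r2$timegen$acc)
  expect_identical(cross_decode(ep, ep)$acc, cross_decode(ep, ep)$acc)
})

test_that("mismatched containers and broken stratification are rejected", {
  ep <- separable_epochs(n_per_class = 8)
  ep2 <- separable_epochs(n_per_class = 8, n_channels = 4)
  expect_error(cross_decode(ep, ep2), "channel mismatch")
  ep3 <- separable_epochs(n_per_class = 2)
  expect_error(cv_decode_random(ep3, decoder_config(n_folds = 5)),
               "stratification|fewer than 2")
})

test_that("the confusion bias score behaves at its fixed points", {
  K <- 4; n_t <- 3
  eye <- array(0, c(n_t, K, K))
  for (t in 1:n_t) eye[t, , ] <- diag(10, K)
  expect_equal(bias_score(confusion_tensor(eye, 1:3, n_trials = 40)),
               rep(0, 3))
  up1 <- array(0, c(n_t, K, K))
  for (t in 1:n_t) for (i in 1:K) up1[t, i, (i %% K) + 1] <- 5
  expect_equal(bias_score(confusion_tensor(up1, 1:3, n_trials = 20)),
               rep(1, 3))
  unif <- array(1, c(n_t, K, K))
  expect_equal(bias_score(confusion_tensor(unif, 1:3, n_trials = 16)),
               rep(0, 3))
  # invariant to positive rescaling of counts
  arb <- array(stats::runif(n_t * K * K), c(n_t, K, K))
  b1 <- bias_score(confusion_tensor(arb, 1:3, n_trials = 1))
  b2 <- bias_score(confusion_tensor(7 * arb, 1:3, n_trials = 7))
  expect_equal(b1, b2, tolerance = 1e-12)
  # non-cyclic variant drops the wrapped cells but keeps the fixed points
  expect_equal(bias_score(confusion_tensor(eye, 1:3, n_trials = 40),
                          cyclic = FALSE), rep(0, 3))
  expect_error(bias_score(confusion_tensor(arb, 1:3)), "trial counts")
  expect_error(bias_score(confusion_tensor(array(1, c(2, 2, 2)), 1:2,
                                           n_trials = 4)), "K >= 3")
})

test_that("group averaging is the element-wise mean and order-invariant", {
  mk <- function(v) timegen_matrix(matrix(v, 2, 3), 1:2 / 10, 1:3 / 10)
  a <- mk(0.2); b <- mk(0.6)
  expect_equal(group_average(list(a))$acc, a$acc)
  expect_equal(group_average(list(a, b))$acc, matrix(0.4, 2, 3))
  c3 <- mk(0.9)
  expect_equal(group_average(list(a, b, c3))$acc,
               group_average(list(c3, a, b))$acc)
  bad <- timegen_matrix(matrix(0.5, 2, 2), 1:2 / 10, 1:2 / 10)
  expect_error(group_average(list(a, bad)), "mismatch")
})

test_that("cross-decoding a control-like subject dips below chance", {
  # deactivation of the predicted tone before onset drives ordered-condition
  # pre-stimulus accuracy under 1/K at the late training times
  scores <- vapply(1:3, function(r) {
    fx <- tiny_subject(seed = 50 + r, alpha_pre = -0.3,
                       n_trials_per_condition = 200, n_channels = 12)
    tg <- cross_decode(fx$epochs, fx$epochs, decoder_config(fold_seed = r),
                       test_condition = "ordered",
                       train_window_s = c(0.47, 0.5),
                       test_window_s = c(-0.42, -0.34))
    mean(tg$acc)
  }, numeric(1))
  expect_lt(mean(scores), 0.25)
})
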