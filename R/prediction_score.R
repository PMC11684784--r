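#' Windowing defaults for pre-stimulus inference
#'
#' Training window 470-570 ms (the late reactivation interval that carried the
#' strongest group effect) and testing window -400-0 ms (the pre-stimulus
#' interval). When the training window exceeds the epoch (e.g. epochs ending
#' at +500 ms), downstream windowing clips it to the epoch with a warning.
#'
#' @param train_window_s training-time window (s).
#' @param test_window_s testing-time window (s).
#' @export
window_spec <- function(train_window_s = c(0.470, 0.570),
                        test_window_s = c(-0.400, 0)) {
  if (train_window_s[1] >= train_window_s[2]) stop("train_lo must be < train_hi")
  structure(list(train_window_s = train_window_s,
                 test_window_s = test_window_s),
            class = "window_spec")
}

#' Regression slopes of decoding accuracy over entropy conditions
#'
#' At every (training time, testing time) point, ordinary least squares of
#' accuracy on a numeric condition code (default 0..n-1, random -> ordered)
#' with an intercept; the slope is retained and the intercept discarded. The
#' slope matrix is the Study-1-style neural prediction score.
#'
#' @param acc_by_condition list of `timegen_matrix`, ordered random -> ordered.
#' @param coding numeric condition codes, strictly increasing (default
#'   `0:(n-1)`).
#' @return a `prediction_score` (mode `"beta_slope"`).
#' @export
beta_slopes <- function(acc_by_condition, coding = NULL) {
  n <- length(acc_by_condition)
  if (n < 2) stop("need at least two conditions")
  if (is.null(coding)) coding <- seq_len(n) - 1
  if (any(diff(coding) <= 0)) stop("coding must be strictly increasing")
  ref <- acc_by_condition[[1]]
  for (m in acc_by_condition[-1]) {
    if (!isTRUE(all.equal(m$train_times_s, ref$train_times_s)) ||
        !isTRUE(all.equal(m$test_times_s, ref$test_times_s))) {
      stop("time axis mismatch across conditions")
    }
  }
  xc <- coding - mean(coding)
  sxx <- sum(xc^2)
  # slope = sum_c xc_c * acc_c / sum xc^2, elementwise over the matrix
  slope <- Reduce(`+`, Map(function(m, w) w * m$acc, acc_by_condition,
                           xc / sxx))
  structure(list(score = slope, mode = "beta_slope",
                 train_times_s = ref$train_times_s,
                 test_times_s = ref$test_times_s,
                 subject_id = ref$subject_id, condition_coding = coding),
            class = "prediction_score")
}

#' Ordered-minus-random accuracy difference
#'
#' Element-wise difference of the two temporal generalization matrices: the
#' Study-2-style neural prediction score. Identical to [beta_slopes()] with
#' coding `c(0, 1)`.
#'
#' @param acc_ordered,acc_random `timegen_matrix` with identical axes.
#' @return a `prediction_score` (mode `"ordered_minus_random"`).
#' @export
diff_score <- function(acc_ordered, acc_random) {
  if (!isTRUE(all.equal(acc_ordered$train_times_s, acc_random$train_times_s)) ||
      !isTRUE(all.equal(acc_ordered$test_times_s, acc_random$test_times_s))) {
    stop("time axis mismatch")
  }
  structure(list(score = acc_ordered$acc - acc_random$acc,
                 mode = "ordered_minus_random",
                 train_times_s = acc_ordered$train_times_s,
                 test_times_s = acc_ordered$test_times_s,
                 subject_id = acc_ordered$subject_id,
                 condition_coding = c(0, 1)),
            class = "prediction_score")
}

#' Collapse a prediction-score matrix over the training window
#'
#' Mean over the training window per testing time, restricted to the testing
#' window; optionally the value at one named testing time (e.g. -0.380 s, a
#' time point of pronounced group difference). Windows reaching beyond the
#' epoch are clipped with a warning.
#'
#' @param score a `prediction_score` (or `timegen_matrix`).
#' @param w a `window_spec`.
#' @param at_test_time_s optional single testing time for a scalar summary.
#' @return list with `test_times_s`, `time_course`, `window_mean` (scalar mean
#'   over both windows), and `at_value` if requested.
#' @export
window_score <- function(score, w = window_spec(), at_test_time_s = NULL) {
  mat <- if (inherits(score, "timegen_matrix")) score$acc else score$score
  tr_t <- score$train_times_s
  te_t <- score$test_times_s
  clip <- function(win, tt, what) {
    lo <- max(win[1], min(tt))
    hi <- min(win[2], max(tt))
    if (lo > win[1] || hi < win[2]) {
      warning(sprintf("%s window [%g, %g] clipped to epoch [%g, %g]",
                      what, win[1], win[2], lo, hi))
    }
    if (lo > hi) stop("empty ", what, " window after clipping")
    c(lo, hi)
  }
  trw <- clip(w$train_window_s, tr_t, "training")
  tew <- clip(w$test_window_s, te_t, "testing")
  ri <- which(tr_t >= trw[1] - 1e-9 & tr_t <= trw[2] + 1e-9)
  ci <- which(te_t >= tew[1] - 1e-9 & te_t <= tew[2] + 1e-9)
  if (length(ri) == 0 || length(ci) == 0) stop("empty window after clipping")
  tc <- colMeans(mat[ri, ci, drop = FALSE])
  out <- list(test_times_s = te_t[ci], time_course = tc,
              window_mean = mean(tc))
  if (!is.null(at_test_time_s)) {
    j <- which.min(abs(te_t[ci] - at_test_time_s))
    if (abs(te_t[ci][j] - at_test_time_s) > 0.5 / 100 + 1e-9) {
      warning("requested testing time is not on the grid; nearest used")
    }
    out$at_value <- tc[j]
    out$at_time_s <- te_t[ci][j]
  }
  out
}
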