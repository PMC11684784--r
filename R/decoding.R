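#' Decoder configuration
#'
#' @param n_folds folds for cross-validated decoding within the training
#'   condition (default 5, stratified by tone class).
#' @param shrinkage covariance shrinkage intensity in `[0, 1]`, or
#'   `"auto"` (Ledoit-Wolf analytic shrinkage toward the scaled identity).
#' @param train_condition condition the classifier is trained on (default
#'   `"random"`, the only condition free of predictability structure).
#' @param exclude_omissions drop omission trials before decoding (default
#'   TRUE).
#' @param fold_seed seed for the stratified fold assignment.
#' @export
decoder_config <- function(n_folds = 5L, shrinkage = "auto",
                           train_condition = "random",
                           exclude_omissions = TRUE, fold_seed = 1L) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  structure(list(n_folds = as.integer(n_folds), shrinkage = shrinkage,
                 train_condition = train_condition,
                 exclude_omissions = exclude_omissions,
                 fold_seed = as.integer(fold_seed)),
            class = "decoder_config")
}

#' Fit a multiclass shrinkage-regularized LDA
#'
#' Linear discriminant analysis with a pooled within-class covariance
#' regularized toward the scaled identity `nu * I` (`nu` = mean variance):
#' `S_reg = (1 - lambda) S + lambda nu I`. With `shrinkage = "auto"`, `lambda`
#' is the Ledoit-Wolf analytic estimate computed from the class-centred data,
#' which keeps the fit stable when trials are scarce relative to channels.
#' Discriminant scores are the usual linear functions
#' `x' W_k - m_k' W_k / 2 + log pi_k` with `W_k = S_reg^{-1} m_k`.
#'
#' @param x trials x channels matrix.
#' @param y integer class labels (0-based tone ids).
#' @param shrinkage `"auto"` or a fixed value in `[0, 1]`.
#' @return an `lda_model` with `means`, `W` (channels x K), `b` (K), `classes`.
#' @export
fit_shrinkage_lda <- function(x, y, shrinkage = "auto") {
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) stop("need at least two classes")
  n <- nrow(x)
  p <- ncol(x)
  means <- matrix(0, K, p)
  xc <- x
  prior <- numeric(K)
  for (k in seq_len(K)) {
    idx <- y == classes[k]
    if (sum(idx) < 2) stop("class ", classes[k], " has fewer than 2 trials")
    means[k, ] <- colMeans(x[idx, , drop = FALSE])
    xc[idx, ] <- sweep(x[idx, , drop = FALSE], 2, means[k, ])
    prior[k] <- mean(idx)
  }
  S <- crossprod(xc) / (n - K)
  nu <- mean(diag(S))
  lambda <- if (identical(shrinkage, "auto")) {
    # Ledoit-Wolf: lambda* = sum Var(s_ij) / sum (s_ij - target_ij)^2
    xc2 <- xc^2
    num <- (sum(crossprod(xc2)) / n - sum((crossprod(xc) / n)^2)) / n
    den <- sum((S - diag(nu, p))^2)
    if (den <= 0) 0 else min(1, max(0, num / den))
  } else shrinkage
  S_reg <- (1 - lambda) * S + lambda * diag(nu, p)
  # degenerate case: zero within-class variance (noiseless separable data)
  # falls back to a spherical metric, i.e. nearest-class-mean classification
  if (nu <= 0 || !all(is.finite(S_reg))) {
    S_reg <- diag(1, p)
  } else if (rcond(S_reg) < 1e-12) {
    S_reg <- S_reg + diag(1e-8 * nu, p)
  }
  W <- solve(S_reg, t(means))                      # p x K
  b <- -0.5 * colSums(t(means) * W) + log(prior)   # K
  structure(list(means = means, W = W, b = b, classes = classes,
                 lambda = lambda),
            class = "lda_model")
}

#' @param object an `lda_model`.
#' @param newdata trials x channels matrix.
#' @param ... unused.
#' @return integer vector of predicted class labels.
#' @rdname fit_shrinkage_lda
#' @export
predict.lda_model <- function(object, newdata, ...) {
  sc <- newdata %*% object$W + rep(object$b, each = nrow(newdata))
  object$classes[max.col(sc, ties.method = "first")]
}

# predictions of one fitted model applied to every testing time of a 3-D
# epoch array: returns trials x test-times integer matrix of predicted labels
.predict_all_times <- function(model, dat, t_idx) {
  n <- dim(dat)[1]
  x <- matrix(aperm(dat[, , t_idx, drop = FALSE], c(1, 3, 2)),
              n * length(t_idx), dim(dat)[2])
  matrix(predict(model, x), n, length(t_idx))
}

# stratified fold assignment: classes spread as evenly as possible over folds
.stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (k in unique(y)) {
      idx <- sample(which(y == k))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

.time_index <- function(times, window) {
  if (is.null(window)) return(seq_along(times))
  idx <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(idx) == 0) stop("empty time window after clipping to the epoch")
  idx
}

#' Cross-validated decoding of the training condition
#'
#' Stratified k-fold cross-validation restricted to the configured training
#' condition (random): per training time point an LDA is fit on the training
#' folds and applied to the held-out fold at every testing time point,
#' yielding an accuracy time course (train time = test time, the temporal
#' generalization diagonal), a training-time x testing-time accuracy matrix,
#' and a testing-time x K x K confusion tensor from the diagonal
#' (train = test) predictions. Chance level is 1/K.
#'
#' @param epochs a `meg_epochs`.
#' @param cfg a `decoder_config`.
#' @param train_window_s optional `(lo, hi)` restricting training times.
#' @param test_window_s optional `(lo, hi)` restricting testing times.
#' @param timegen compute the full temporal generalization matrix (default
#'   TRUE); if FALSE only the diagonal accuracy time course and confusion
#'   tensor are computed (train times = test times required).
#' @return list with `times_s` (train times), `test_times_s`, `accuracy`
#'   (diagonal time course), `timegen` (`timegen_matrix` or NULL), `confusion`
#'   (`confusion_tensor`), `n_trials`.
#' @export
cv_decode_random <- function(epochs, cfg = decoder_config(),
                             train_window_s = NULL, test_window_s = NULL,
                             timegen = TRUE) {
  keep <- epochs$condition == cfg$train_condition
  if (cfg$exclude_omissions) keep <- keep & !epochs$is_omission
  if (!any(keep)) stop("no trials in the training condition")
  dat <- epochs$data[keep, , , drop = FALSE]
  y <- epochs$labels[keep]
  classes <- sort(unique(y))
  K <- length(classes)
  fold <- .stratified_folds(y, cfg$n_folds, cfg$fold_seed)
  tab <- table(y, fold)
  if (any(tab < 2)) stop("stratification error: a class has < 2 trials in a fold")
  tr_idx <- .time_index(epochs$times_s, train_window_s)
  te_idx <- .time_index(epochs$times_s, test_window_s)
  if (!timegen && !identical(tr_idx, te_idx)) {
    stop("timegen = FALSE requires identical train and test windows")
  }
  n_tr <- length(tr_idx)
  n_te <- length(te_idx)
  acc_gen <- if (timegen) matrix(0, n_tr, n_te) else NULL
  correct_diag <- matrix(0, n_tr, 1)
  conf <- array(0, c(n_tr, K, K))
  n_total <- length(y)
  for (f in seq_len(cfg$n_folds)) {
    tr <- fold != f
    te <- !tr
    n_te_trials <- sum(te)
    for (ti in seq_len(n_tr)) {
      model <- fit_shrinkage_lda(dat[tr, , tr_idx[ti]], y[tr], cfg$shrinkage)
      if (timegen) {
        pred <- .predict_all_times(model, dat[te, , , drop = FALSE], te_idx)
        acc_gen[ti, ] <- acc_gen[ti, ] + colSums(pred == y[te])
        # diagonal (train time == test time) feeds the confusion tensor
        d <- match(tr_idx[ti], te_idx)
        if (!is.na(d)) {
          pd <- pred[, d]
          correct_diag[ti] <- correct_diag[ti] + sum(pd == y[te])
          conf[ti, , ] <- conf[ti, , ] +
            table(factor(y[te], classes), factor(pd, classes))
        }
      } else {
        pd <- predict(model, dat[te, , tr_idx[ti]])
        correct_diag[ti] <- correct_diag[ti] + sum(pd == y[te])
        conf[ti, , ] <- conf[ti, ,] +
          table(factor(y[te], classes), factor(pd, classes))
      }
    }
  }
  tg <- NULL
  if (timegen) {
    tg <- timegen_matrix(acc_gen / n_total, epochs$times_s[tr_idx],
                         epochs$times_s[te_idx],
                         test_condition = cfg$train_condition,
                         subject_id = epochs$subject_id)
  }
  acc <- as.numeric(correct_diag) / n_total
  structure(list(times_s = epochs$times_s[tr_idx],
                 test_times_s = epochs$times_s[te_idx],
                 accuracy = acc, timegen = tg,
                 confusion = confusion_tensor(conf, epochs$times_s[tr_idx],
                                              n_trials = n_total),
                 n_trials = n_total),
            class = "cv_decode_result")
}

#' Temporal generalization accuracy matrix
#' @param acc train-times x test-times accuracy matrix in `[0, 1]`.
#' @param train_times_s,test_times_s time axes (s).
#' @param test_condition condition the matrix was tested on.
#' @param subject_id subject id.
#' @export
timegen_matrix <- function(acc, train_times_s, test_times_s,
                           test_condition = NA_character_,
                           subject_id = NA_character_) {
  if (nrow(acc) != length(train_times_s) || ncol(acc) != length(test_times_s)) {
    stop("accuracy matrix dimensions do not match the time axes")
  }
  if (any(acc < -1e-12 | acc > 1 + 1e-12)) stop("accuracies outside [0, 1]")
  structure(list(acc = acc, train_times_s = train_times_s,
                 test_times_s = test_times_s, test_condition = test_condition,
                 subject_id = subject_id),
            class = "timegen_matrix")
}

#' Confusion tensor: testing-time x true x predicted counts
#' @param counts n_times x K x K array of counts.
#' @param times_s testing-time axis.
#' @param n_trials trials per testing time (counts must sum to it).
#' @param normalized whether `counts` are already row-normalized rates.
#' @export
confusion_tensor <- function(counts, times_s, n_trials = NULL,
                             normalized = FALSE) {
  structure(list(counts = counts, times_s = times_s, n_trials = n_trials,
                 normalized = normalized),
            class = "confusion_tensor")
}

#' Cross-condition (cross-decoded) temporal generalization
#'
#' Classifiers are fit once per training time on all training-condition trials
#' of `train_epochs` and applied at every testing time of `test_epochs` — no
#' cross-validation, since training and testing data come from different
#' conditions (or, for pre-stimulus testing on the training condition itself,
#' use [cv_decode_random()] which keeps held-out folds). This covers training
#' on the post-stimulus interval and testing on the pre-stimulus interval.
#'
#' @param train_epochs `meg_epochs` supplying the training condition.
#' @param test_epochs `meg_epochs` tested at all requested times.
#' @param cfg a `decoder_config`.
#' @param test_condition condition of `test_epochs` to test on (default: all
#'   non-omission trials).
#' @param train_window_s,test_window_s optional time windows.
#' @return a `timegen_matrix`.
#' @export
cross_decode <- function(train_epochs, test_epochs, cfg = decoder_config(),
                         test_condition = NULL, train_window_s = NULL,
                         test_window_s = NULL) {
  if (dim(train_epochs$data)[2] != dim(test_epochs$data)[2]) {
    stop("channel mismatch between training and testing containers")
  }
  keep_tr <- train_epochs$condition == cfg$train_condition
  if (cfg$exclude_omissions) keep_tr <- keep_tr & !train_epochs$is_omission
  keep_te <- if (is.null(test_condition)) rep(TRUE, length(test_epochs$labels))
             else test_epochs$condition == test_condition
  if (cfg$exclude_omissions) keep_te <- keep_te & !test_epochs$is_omission
  if (!any(keep_tr) || !any(keep_te)) stop("no trials after condition filtering")
  dtr <- train_epochs$data[keep_tr, , , drop = FALSE]
  ytr <- train_epochs$labels[keep_tr]
  dte <- test_epochs$data[keep_te, , , drop = FALSE]
  yte <- test_epochs$labels[keep_te]
  tr_idx <- .time_index(train_epochs$times_s, train_window_s)
  te_idx <- .time_index(test_epochs$times_s, test_window_s)
  acc <- matrix(0, length(tr_idx), length(te_idx))
  for (ti in seq_along(tr_idx)) {
    model <- fit_shrinkage_lda(dtr[, , tr_idx[ti]], ytr, cfg$shrinkage)
    pred <- .predict_all_times(model, dte, te_idx)
    acc[ti, ] <- colMeans(pred == yte)
  }
  timegen_matrix(acc, train_epochs$times_s[tr_idx],
                 test_epochs$times_s[te_idx],
                 test_condition = if (is.null(test_condition)) "all"
                                  else test_condition,
                 subject_id = test_epochs$subject_id)
}

#' Decoding bias toward the ordered-sequence transition direction
#'
#' Per testing time: mean of the row-normalized confusion cells
#' `true i -> predicted successor(i)` minus mean of
#' `true i -> predicted successor(successor(i))`, where the successor follows
#' the designated transition direction of the ordered sequences (cyclic
#' `i -> i+1 mod K` by default; `cyclic = FALSE` restricts to the strictly
#' upper matrix diagonals, i.e. drops the wrapped cells).
#'
#' @param conf a `confusion_tensor`.
#' @param cyclic wrap the diagonals at K (default TRUE).
#' @return numeric bias time course (one value per testing time).
#' @export
bias_score <- function(conf, cyclic = TRUE) {
  dims <- dim(conf$counts)
  K <- dims[2]
  if (K < 3) stop("bias score needs K >= 3")
  if (!conf$normalized && is.null(conf$n_trials)) {
    stop("unnormalized confusion tensor without trial counts")
  }
  vapply(seq_len(dims[1]), function(t) {
    m <- conf$counts[t, , ]
    if (!conf$normalized) {
      rs <- rowSums(m)
      rs[rs == 0] <- 1
      m <- m / rs
    }
    i <- seq_len(K)
    d1 <- cbind(i, (i %% K) + 1L)
    d2 <- cbind(i, ((i + 1L) %% K) + 1L)
    if (!cyclic) {
      d1 <- d1[d1[, 2] > d1[, 1], , drop = FALSE]
      d2 <- d2[d2[, 2] > d2[, 1], , drop = FALSE]
    }
    mean(m[d1]) - mean(m[d2])
  }, numeric(1))
}

#' Element-wise group average of temporal generalization matrices
#' @param matrices list of `timegen_matrix` with identical axes.
#' @return a `timegen_matrix` (subject_id = "group").
#' @export
group_average <- function(matrices) {
  if (length(matrices) == 0) stop("empty list")
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!isTRUE(all.equal(m$train_times_s, ref$train_times_s)) ||
        !isTRUE(all.equal(m$test_times_s, ref$test_times_s))) {
      stop("time axis mismatch across subjects")
    }
  }
  acc <- Reduce(`+`, lapply(matrices, `[[`, "acc")) / length(matrices)
  timegen_matrix(acc, ref$train_times_s, ref$test_times_s,
                 test_condition = ref$test_condition, subject_id = "group")
}

#' Write a temporal generalization matrix as long-format TSV (+ JSON sidecar)
#' @param tg a `timegen_matrix`.
#' @param path TSV path; a `.json` sidecar is written next to it.
#' @export
write_timegen_tsv <- function(tg, path) {
  df <- data.frame(train_time_s = rep(tg$train_times_s,
                                      times = length(tg$test_times_s)),
                   test_time_s = rep(tg$test_times_s,
                                     each = length(tg$train_times_s)),
                   accuracy = as.vector(tg$acc))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(subject_id = tg$subject_id,
                            test_condition = tg$test_condition,
                            n_train_times = length(tg$train_times_s),
                            n_test_times = length(tg$test_times_s)),
                       paste0(sub("\\.tsv$", "", path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
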