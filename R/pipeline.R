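#' Pipeline run configuration
#'
#' A single flat configuration that fully determines every output of
#' [run_all()] given the code version. Defaults mirror the study parameters:
#' 100 Hz epochs, fivefold CV, 1000 permutations, 470-570 ms training and
#' -400-0 ms testing windows.
#'
#' @param study `"study1"` or `"study2"`.
#' @param n_per_group subjects per group.
#' @param n_trials_per_condition stimuli per condition (default the study
#'   preset; smaller values scale the block layout down for pilot runs).
#' @param n_channels sensors in the synthetic array.
#' @param snr evoked-to-noise amplitude ratio (both groups).
#' @param alpha_pre_tinnitus,alpha_pre_control anticipatory gains per group.
#' @param score_mode `"diff"` (ordered minus random) or `"beta"` (slope over
#'   entropy conditions).
#' @param train_window_s,test_window_s inference windows (s).
#' @param n_folds CV folds.
#' @param n_perm cluster permutations.
#' @param cluster_tail tail of the group cluster test (default one-sided
#'   positive: tinnitus > control).
#' @param seed master seed; every per-stage seed derives from it.
#' @param out_dir output directory (NULL = no files written).
#' @export
run_config <- function(study = "study2", n_per_group = 10L,
                       n_trials_per_condition = NULL, n_channels = 102L,
                       snr = 1.5, alpha_pre_tinnitus = 0,
                       alpha_pre_control = -0.3, score_mode = NULL,
                       train_window_s = c(0.470, 0.570),
                       test_window_s = c(-0.400, 0),
                       n_folds = 5L, n_perm = 1000L,
                       cluster_tail = "one_sided_pos", seed = 1L,
                       out_dir = NULL) {
  if (is.null(score_mode)) {
    score_mode <- if (study == "study1") "beta" else "diff"
  }
  structure(list(study = study, n_per_group = n_per_group,
                 n_trials_per_condition = n_trials_per_condition,
                 n_channels = n_channels, snr = snr,
                 alpha_pre_tinnitus = alpha_pre_tinnitus,
                 alpha_pre_control = alpha_pre_control,
                 score_mode = score_mode, train_window_s = train_window_s,
                 test_window_s = test_window_s, n_folds = n_folds,
                 n_perm = n_perm, cluster_tail = cluster_tail,
                 seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Returns a data.frame of problems (level `"error"` or `"warning"`), empty
#' when the configuration is clean. Flags, among others, the known clash of a
#' 470-570 ms training window with epochs ending at +500 ms (clipped
#' downstream with a warning).
#'
#' @param cfg a `run_config`.
#' @export
validate_config <- function(cfg) {
  problems <- data.frame(level = character(0), message = character(0))
  add <- function(level, msg) {
    problems[nrow(problems) + 1L, ] <<- list(level, msg)
  }
  if (!cfg$study %in% c("study1", "study2")) {
    add("error", "unknown study preset")
    return(problems)
  }
  design <- study_design(cfg$study)
  if (cfg$n_per_group < 1) add("error", "n_per_group must be >= 1")
  if (cfg$snr <= 0) add("error", "snr must be positive")
  if (is.null(cfg$seed)) add("error", "a master seed is required")
  if (cfg$n_folds < 2) add("error", "n_folds must be >= 2")
  epoch <- design$epoch_window_s
  if (cfg$train_window_s[2] > epoch[2] + 1e-9) {
    add("warning", sprintf(
      "training window [%g, %g] s exceeds the %s epoch ending at %g s; it will be clipped",
      cfg$train_window_s[1], cfg$train_window_s[2], cfg$study, epoch[2]))
  }
  if (cfg$test_window_s[1] < epoch[1] - 1e-9) {
    add("warning", "testing window starts before the epoch; it will be clipped")
  }
  min_tr <- ceiling(2 * design$K * cfg$n_folds / (1 - design$omission_rate))
  if (!is.null(cfg$n_trials_per_condition) &&
      cfg$n_trials_per_condition < min_tr) {
    add("error", "too few trials per condition for stratified folds")
  }
  if (cfg$score_mode == "beta" && length(design$conditions) < 2) {
    add("error", "beta mode needs at least two conditions")
  }
  problems
}

#' Run the full pipeline: simulate, decode, score, group statistics
#'
#' Stages: (1) simulate a matched cohort under the configured design and
#' group effects; (2) per subject, train classifiers on the random condition
#' in the training window and test across the pre-stimulus window on every
#' condition (CV folds for random, cross-decoding otherwise); (3) collapse to
#' the neural prediction score (ordered-minus-random difference or entropy
#' slope) per testing time; (4) group statistics: one-sample cluster tests
#' within groups, the group-difference cluster permutation test, a two-sample
#' JZS Bayes factor and Welch/TOST on the windowed score, and the logistic
#' model of tinnitus status on score plus PTA-4. Identical configurations
#' reproduce identical outputs (all stage seeds derive from the master seed).
#'
#' @param cfg a `run_config`.
#' @param sensors,kernel optional model overrides (shared across subjects).
#' @return a `run_report` list.
#' @export
run_all <- function(cfg, sensors = NULL, kernel = NULL) {
  problems <- validate_config(cfg)
  if (any(problems$level == "error")) {
    stop("invalid configuration:\n  ",
         paste(problems$message[problems$level == "error"], collapse = "\n  "))
  }
  t0 <- Sys.time()
  design <- study_design(cfg$study,
                         n_trials_per_condition = cfg$n_trials_per_condition)
  if (is.null(kernel)) kernel <- response_kernel(sfreq = design$sfreq)
  group_params <- list(
    tinnitus = list(alpha_pre = cfg$alpha_pre_tinnitus, snr = cfg$snr),
    control = list(alpha_pre = cfg$alpha_pre_control, snr = cfg$snr))
  if (is.null(sensors)) {
    sensors <- make_sensor_model(cfg$n_channels, design$K,
                                 seed = derive_seed(cfg$seed, 1L))
  }
  cohort <- simulate_cohort(design, cfg$n_per_group, group_params,
                            seed = cfg$seed, sensors = sensors,
                            kernel = kernel)
  dec_cfg <- decoder_config(n_folds = cfg$n_folds,
                            fold_seed = derive_seed(cfg$seed, 3L))
  w <- window_spec(cfg$train_window_s, cfg$test_window_s)
  groups <- vapply(cohort$subjects, `[[`, character(1), "group")
  courses <- NULL
  scores <- numeric(length(cohort$subjects))
  for (s in seq_along(cohort$subjects)) {
    ep <- cohort$subjects[[s]]$epochs
    ws <- if (cfg$score_mode == "diff") {
      subject_prediction_score(ep, dec_cfg, w, return_course = TRUE)
    } else {
      accs <- vector("list", length(design$conditions))
      for (ci in seq_along(design$conditions)) {
        cc <- design$conditions[ci]
        accs[[ci]] <- if (cc == dec_cfg$train_condition) {
          cv_random_windowed(ep, dec_cfg,
                             cfg$train_window_s, cfg$test_window_s)
        } else {
          cross_decode(ep, ep, dec_cfg, test_condition = cc,
                       train_window_s = .clip_window(cfg$train_window_s,
                                                     ep$times_s),
                       test_window_s = cfg$test_window_s)
        }
      }
      suppressWarnings(window_score(beta_slopes(accs), w))
    }
    if (is.null(courses)) {
      courses <- matrix(0, length(cohort$subjects), length(ws$time_course))
    }
    courses[s, ] <- ws$time_course
    scores[s] <- ws$window_mean
  }
  test_times <- sort(unique(
    cohort$subjects[[1]]$epochs$times_s[
      .time_index(cohort$subjects[[1]]$epochs$times_s, cfg$test_window_s)]))
  tin <- groups == "tinnitus"
  cluster_group <- cluster_perm_test(courses[tin, , drop = FALSE],
                                     courses[!tin, , drop = FALSE],
                                     tail = cfg$cluster_tail,
                                     n_perm = cfg$n_perm,
                                     seed = derive_seed(cfg$seed, 4L))
  bf_group <- jzs_bf(scores[tin], scores[!tin])
  welch_group <- welch_t(scores[tin], scores[!tin])
  tost_group <- tost_equivalence(scores[tin], scores[!tin])
  pta <- vapply(cohort$subjects,
                function(s) pta4(s$audiogram)$mean, numeric(1))
  logit <- logistic_tinnitus_model(scores, groups, pta)
  distress <- vapply(cohort$subjects, `[[`, numeric(1), "distress")
  distress_cor <- if (sum(is.finite(distress[tin])) >= 4 &&
                      stats::sd(scores[tin][is.finite(distress[tin])]) > 0) {
    spearman_cor(scores[tin], distress[tin])
  } else NULL
  report <- structure(list(
    config = cfg,
    seeds = list(master = cfg$seed, sensors = derive_seed(cfg$seed, 1L),
                 sequences = derive_seed(cfg$seed, 2L),
                 folds = derive_seed(cfg$seed, 3L),
                 permutations = derive_seed(cfg$seed, 4L)),
    groups = groups,
    subject_ids = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
    test_times_s = test_times,
    score_courses = courses,
    scores = scores,
    cluster_group = cluster_group,
    bf_group = bf_group,
    welch_group = welch_group,
    tost_group = tost_group,
    logistic = logit,
    distress_cor = distress_cor,
    duration_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  if (!is.null(cfg$out_dir)) write_run_report(report, cfg$out_dir)
  report
}

#' Write a run report's tables under a directory
#'
#' `scores.tsv` (per-subject windowed scores), `score_courses.tsv`
#' (subject x testing time), `cluster_group.json`, `stats.json`.
#' @param report a `run_report`.
#' @param dir output directory (created).
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(subject_id = report$subject_ids, group = report$groups,
               score = sprintf("%.10g", report$scores)),
    file.path(dir, "scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tc <- as.data.frame(report$score_courses)
  names(tc) <- sprintf("t_%g", report$test_times_s)
  tc <- cbind(subject_id = report$subject_ids, tc)
  utils::write.table(tc, file.path(dir, "score_courses.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cl <- lapply(report$cluster_group$clusters, function(c0) {
    list(n_points = length(c0$members), t_sum = c0$t_sum,
         p_perm = c0$p_perm,
         test_times_s = report$test_times_s[
           ((c0$members - 1) %% length(report$test_times_s)) + 1])
  })
  jsonlite::write_json(
    list(tail = report$cluster_group$tail,
         n_permutations = report$cluster_group$n_permutations,
         clusters = cl),
    file.path(dir, "cluster_group.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(bf10 = report$bf_group$bf10,
         welch = report$welch_group,
         tost = report$tost_group[c("equivalent", "p_lower", "p_upper",
                                    "delta", "units")],
         logistic = list(coefficients = report$logistic$coefficients,
                         or_per_sd = report$logistic$or_per_sd),
         seeds = report$seeds),
    file.path(dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: %s, %d + %d subjects, score mode %s>\n",
              x$config$study, sum(x$groups == "tinnitus"),
              sum(x$groups == "control"), x$config$score_mode))
  cat(sprintf("  group cluster test: %d cluster(s), min p = %.4f\n",
              length(x$cluster_group$clusters), min_cluster_p(x$cluster_group)))
  cat(sprintf("  windowed score BF10 = %.3g, Welch p = %.4f\n",
              x$bf_group$bf10, x$welch_group$p))
  invisible(x)
}
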