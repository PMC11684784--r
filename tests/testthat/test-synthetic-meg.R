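# Synthetic sensor-space generator: topographies, kernels, epochs,
# audiograms.

test_that("sensor models are reproducible and discriminable", {
  s1 <- make_sensor_model(24, 4, seed = 3)
  s2 <- make_sensor_model(24, 4, seed = 3)
  expect_identical(s1$topographies, s2$topographies)
  expect_equal(unname(sqrt(rowSums(s1$topographies^2))), rep(1, 4),
               tolerance = 1e-12)
  cs <- abs(tcrossprod(s1$topographies))
  diag(cs) <- 0
  expect_lt(max(cs), 0.8)
  expect_equal(s1$noise_cov, t(s1$noise_cov))
  expect_true(all(eigen(s1$noise_cov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
  expect_error(make_sensor_model(3, 4), "n_channels")
})

test_that("the response kernel is causal with the stated component peaks", {
  k <- response_kernel()
  expect_equal(predecode:::kernel_at(k, c(-0.5, -0.01)), c(0, 0))
  early <- k$values * (k$times_s < 0.3)
  expect_lt(abs(k$times_s[which.max(early)] - k$latency_early_s), 0.011)
  late <- k$values * (k$times_s > 0.3)
  expect_lt(abs(k$times_s[which.max(late)] - k$latency_late_s), 0.011)
})

test_that("noiseless epochs equal the exact linear superposition", {
  fx <- tiny_subject(seed = 7, alpha_pre = -0.3,
                     n_trials_per_condition = 40, n_channels = 6)
  sp_inf <- subject_spec("x", "control", alpha_pre = -0.3, snr = Inf)
  ep <- simulate_subject(fx$design, fx$blocks, fx$sensors, fx$kernel, sp_inf,
                         seed = 1)
  row <- 0
  for (b in seq_along(fx$blocks)) {
    sq <- fx$blocks[[b]]
    for (i in seq_len(nrow(sq))) {
      row <- row + 1
      tmpl <- predecode:::.epoch_template(
        i, sq$tone_id, sq$is_omission, sq$condition[1], fx$sensors,
        fx$kernel, -0.3, ep$times_s, fx$design$soa_s, -0.38)
      expect_identical(max(abs(ep$data[row, , ] - tmpl)), 0)
    }
  }
  # anticipation only enters ordered trials
  sp0 <- subject_spec("x", "tinnitus", alpha_pre = 0, snr = Inf)
  ep0 <- simulate_subject(fx$design, fx$blocks, fx$sensors, fx$kernel, sp0,
                          seed = 1)
  rnd <- ep$condition == "random"
  expect_identical(ep$data[rnd, , ], ep0$data[rnd, , ])
  expect_gt(max(abs(ep$data[!rnd, , ] - ep0$data[!rnd, , ])), 0)
})

test_that("averaging noisy epochs of one tone recovers its template", {
  d <- tiny_design(12000)  # ~3000 random-condition epochs per tone
  sens <- make_sensor_model(8, 4, seed = 5)
  kern <- response_kernel()
  blocks <- make_study_blocks(d, 31)
  sp <- subject_spec("s", "tinnitus", alpha_pre = 0, snr = 1.5)
  noisy <- simulate_subject(d, blocks, sens, kern, sp, seed = 41)
  clean <- simulate_subject(d, blocks, sens, kern,
                            subject_spec("s", "tinnitus", 0, snr = Inf),
                            seed = 41)
  sel <- noisy$condition == "random" & noisy$labels == 2L
  expect_gte(sum(sel), 2500)
  m_noisy <- apply(noisy$data[sel, , ], c(2, 3), mean)
  m_clean <- apply(clean$data[sel, , ], c(2, 3), mean)
  rel_err <- sqrt(sum((m_noisy - m_clean)^2) / sum(m_clean^2))
  expect_lt(rel_err, 0.1)
})

test_that("decoding accuracy increases with snr", {
  accs <- vapply(c(0.5, 1.5, 4), function(snr) {
    fx <- tiny_subject(seed = 13, snr = snr, n_trials_per_condition = 120,
                       n_channels = 12)
    res <- cv_decode_random(fx$epochs, decoder_config(fold_seed = 2),
                            train_window_s = c(0.09, 0.13),
                            test_window_s = c(0.09, 0.13), timegen = FALSE)
    mean(res$accuracy)
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
  # even nearly noise-free decoding stays well below 1: the overlapping
  # neighbouring tones (SOA 333 ms) interfere at the early peak by design
  expect_gt(accs[3], 0.45)
})

test_that("pure-tone averages and the hearing-loss flag follow audiometry", {
  expect_equal(pta4(flat_audiogram(20))$mean, 20)
  ag <- flat_audiogram(0)
  ag[, c("500", "1000", "2000", "4000")] <- rep(c(10, 20, 30, 40), each = 2)
  expect_equal(pta4(ag)$mean, 25)
  expect_equal(unname(pta4(ag)$per_ear), c(25, 25))
  ag[, c("6000", "8000")] <- 85
  expect_equal(pta4(ag, extended = TRUE)$mean, (10 + 20 + 30 + 40 + 85 + 85) / 6)
  expect_error(pta4(ag[, 1:3, drop = FALSE]), "missing required")

  expect_false(hearing_loss_flag(flat_audiogram(20)))
  expect_false(hearing_loss_flag(flat_audiogram(30)))  # strictly above 30
  hf <- flat_audiogram(20); hf[1, "8000"] <- 35
  expect_true(hearing_loss_flag(hf))
  expect_error(hearing_loss_flag(numeric(0)), "empty")
})

test_that("cohorts are balanced, matched, and reproducible", {
  d <- tiny_design(40)
  co1 <- simulate_cohort(d, 2, seed = 9,
                         sensors = make_sensor_model(6, 4, seed = 1))
  co2 <- simulate_cohort(d, 2, seed = 9,
                         sensors = make_sensor_model(6, 4, seed = 1))
  expect_length(co1$subjects, 4)
  grp <- vapply(co1$subjects, `[[`, character(1), "group")
  expect_identical(sum(grp == "tinnitus"), 2L)
  expect_identical(co1$subjects[[1]]$epochs$data, co2$subjects[[1]]$epochs$data)
  distress <- vapply(co1$subjects, `[[`, numeric(1), "distress")
  expect_true(all(is.finite(distress[grp == "tinnitus"])))
  expect_true(all(is.na(distress[grp == "control"])))
  ags <- lapply(co1$subjects, `[[`, "audiogram")
  expect_true(all(vapply(ags, function(a) all(a >= -10 & a <= 120),
                         logical(1))))
  # default group effect: deactivation in controls, none in tinnitus
  expect_identical(co1$subjects[[1]]$alpha_pre, 0)
  expect_lt(co1$subjects[[3]]$alpha_pre, 0)
})

test_that("epochs containers round-trip through the on-disk format", {
  fx <- tiny_subject(n_trials_per_condition = 20, n_channels = 5)
  dir <- withr::local_tempdir()
  write_epochs_dir(fx$epochs, dir)
  back <- read_epochs_dir(dir)
  expect_identical(back$labels, fx$epochs$labels)
  expect_identical(back$condition, fx$epochs$condition)
  expect_equal(back$times_s, fx$epochs$times_s, tolerance = 1e-9)
  expect_equal(back$data, fx$epochs$data, tolerance = 1e-5)  # float32
})
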