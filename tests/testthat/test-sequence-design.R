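# Entropy-graded transition matrices and Markov tone sequences.

test_that("transition matrices reproduce the designed structure", {
  ord <- build_transition_matrix("ordered", K = 4, order_strength = 0.75)
  expect_equal(ord$probs[1, ], c(0.25, 0.75, 0, 0))
  expect_equal(ord$probs[4, ], c(0.75, 0, 0, 0.25))
  rnd <- build_transition_matrix("random")
  expect_true(all(rnd$probs == 0.25))
  for (cc in entropy_conditions()) {
    m <- build_transition_matrix(cc)
    expect_equal(rowSums(m$probs), rep(1, 4), tolerance = 1e-14)
    expect_equal(diag(m$probs), rep(0.25, 4))
    expect_true(all(m$probs >= 0 & m$probs <= 1))
  }
  expect_error(build_transition_matrix("bogus"), "unknown condition")
  expect_error(build_transition_matrix("ordered", order_strength = 0.9),
               "order_strength")
  expect_error(build_transition_matrix("ordered", K = 1), "K must be")
})

test_that("row entropies follow the closed form and order the conditions", {
  expect_equal(matrix_entropy(build_transition_matrix("random"))$per_row,
               rep(2, 4))
  # -0.25 log2 0.25 - 0.75 log2 0.75 evaluated numerically
  expect_equal(matrix_entropy(build_transition_matrix("ordered"))$mean,
               0.25 * 2 + 0.75 * log2(1 / 0.75), tolerance = 1e-12)
  expect_equal(matrix_entropy(build_transition_matrix("ordered"))$mean,
               0.8112781, tolerance = 1e-6)
  # degenerate rows have zero entropy
  det <- structure(list(probs = diag(4)[c(2, 3, 4, 1), ],
                        condition_label = "ordered", K = 4L),
                   class = "transition_matrix")
  expect_equal(matrix_entropy(det)$per_row, rep(0, 4))
  h <- vapply(entropy_conditions(),
              function(cc) matrix_entropy(build_transition_matrix(cc))$mean,
              numeric(1))
  expect_true(all(diff(h) < 0))  # random > midminus > midplus > ordered
})

test_that("sampled sequences follow the generating matrix", {
  m <- build_transition_matrix("midplus")
  s1 <- generate_sequence(m, 5000, seed = 11)
  s2 <- generate_sequence(m, 5000, seed = 11)
  expect_identical(s1$tone_id, s2$tone_id)
  expect_true(all(s1$tone_id %in% 0:3))
  expect_equal(diff(s1$onset_s), rep(1 / 3, 4999), tolerance = 1e-12)

  # long-run transition frequencies match the matrix (chi-square GOF per row)
  s <- generate_sequence(m, 50000, seed = 3)
  from <- s$tone_id[-nrow(s)]
  to <- s$tone_id[-1]
  for (k in 0:3) {
    obs <- tabulate(to[from == k] + 1L, nbins = 4)
    expect_gt(stats::chisq.test(obs, p = m$probs[k + 1, ])$p.value, 0.01)
  }
  # uniform stationary tone distribution
  expect_equal(unname(tabulate(s$tone_id + 1L, 4) / nrow(s)), rep(0.25, 4),
               tolerance = 0.02)

  # deterministic cyclic chain is exactly periodic
  det <- structure(list(probs = diag(4)[c(2, 3, 4, 1), ],
                        condition_label = "ordered", K = 4L),
                   class = "transition_matrix")
  sd0 <- generate_sequence(det, 40, seed = 5)
  expect_identical(sd0$tone_id[-1], (sd0$tone_id[-40] + 1L) %% 4L)
})

test_that("omission flagging is exact in count and random in position", {
  m <- build_transition_matrix("random")
  s <- generate_sequence(m, 1000, seed = 1)
  for (seed in 1:3) {
    so <- insert_omissions(s, 0.10, seed = seed)
    expect_identical(sum(so$is_omission), 100L)
    expect_identical(so$tone_id, s$tone_id)  # identities retained
  }
  expect_false(identical(which(insert_omissions(s, 0.1, 1)$is_omission),
                         which(insert_omissions(s, 0.1, 2)$is_omission)))
  expect_identical(sum(insert_omissions(s, 0, 1)$is_omission), 0L)
  expect_error(insert_omissions(s, 1, 1), "rate")
})

test_that("study presets produce the stated trial economies", {
  b1 <- make_study_blocks(study_design("study1"), seed = 21)
  expect_length(b1, 4)
  expect_identical(sum(vapply(b1, function(b) sum(!b$is_omission), integer(1))),
                   3600L)
  expect_identical(sum(vapply(b1, function(b) sum(b$is_omission), integer(1))),
                   400L)
  expect_setequal(vapply(b1, function(b) b$condition[1], character(1)),
                  entropy_conditions())

  d2 <- study_design("study2")
  b2 <- make_study_blocks(d2, seed = 21)
  expect_length(b2, 6)
  expect_true(all(vapply(b2, nrow, integer(1)) == 500L))
  n_per_cond <- vapply(c("random", "ordered"), function(cc)
    sum(vapply(b2, function(b) sum(b$condition == cc), integer(1))),
    integer(1))
  expect_identical(unname(n_per_cond), c(1500L, 1500L))
  expect_true(all(vapply(b2, function(b) !any(b$is_omission), logical(1))))

  expect_length(make_study_blocks(study_design("study2",
                                               n_trials_per_condition = 0),
                                  seed = 1), 0)
})

test_that("carrier frequencies are geometrically spaced and rounded", {
  expect_identical(log_spaced_freqs(200, 2000, 4), c(200, 431, 928, 2000))
  expect_identical(log_spaced_freqs(440, 1043, 4), c(440, 587, 782, 1043))
  expect_identical(log_spaced_freqs(100, 200, 2), c(100, 200))
  expect_error(log_spaced_freqs(-1, 10, 4), "f_lo")
  expect_identical(study_design("study1")$carrier_freqs_hz,
                   c(200, 431, 928, 2000))
  expect_identical(study_design("study2")$carrier_freqs_hz,
                   c(440, 587, 782, 1043))
})

test_that("event tables round-trip through TSV", {
  d <- study_design("study2", n_trials_per_condition = 20)
  b <- make_study_blocks(d, seed = 2)[[1]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(b, d, path)
  back <- read_events_tsv(path)
  expect_equal(back$tone_id, b$tone_id)
  expect_equal(back$carrier_freq_hz, d$carrier_freqs_hz[b$tone_id + 1L])
  expect_equal(back$onset_s, b$onset_s, tolerance = 1e-9)
})
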