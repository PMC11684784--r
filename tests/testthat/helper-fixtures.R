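# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# a scaled-down two-condition design (random + ordered)
tiny_design <- function(n_trials_per_condition = 100) {
  study_design("study2", n_trials_per_condition = n_trials_per_condition)
}

# noiseless, perfectly separable epochs: class k has mean pattern mu_k at
# every time point, scaled by a per-time gain so time points differ
separable_epochs <- function(n_per_class = 10, n_channels = 6, n_times = 5,
                             K = 4, noise_sd = 0, seed = 1,
                             condition = "random") {
  n <- n_per_class * K
  labels <- rep(seq_len(K) - 1L, each = n_per_class)
  mu <- diag(1, K, n_channels)  # orthogonal class means
  gain <- seq(1, 2, length.out = n_times)
  dat <- array(0, c(n, n_channels, n_times))
  for (t in seq_len(n_times)) {
    dat[, , t] <- mu[labels + 1L, ] * gain[t]
  }
  if (noise_sd > 0) {
    dat <- dat + withr::with_seed(seed,
      array(stats::rnorm(length(dat), 0, noise_sd), dim(dat)))
  }
  meg_epochs(dat, times_s = (seq_len(n_times) - 1L) / 100, labels = labels,
             condition = rep(condition, n), sfreq = 100, subject_id = "fix")
}

# one simulated subject under the default generator at reduced size
tiny_subject <- function(seed = 7, alpha_pre = 0, snr = 1.5,
                         n_trials_per_condition = 100, n_channels = 8,
                         design = NULL) {
  if (is.null(design)) design <- tiny_design(n_trials_per_condition)
  sens <- make_sensor_model(n_channels, design$K, seed = derive_seed(seed, 1))
  kern <- response_kernel(sfreq = design$sfreq)
  blocks <- make_study_blocks(design, derive_seed(seed, 2))
  sp <- subject_spec("t01", "tinnitus", alpha_pre = alpha_pre, snr = snr)
  list(design = design, sensors = sens, kernel = kern, blocks = blocks,
       spec = sp,
       epochs = simulate_subject(design, blocks, sens, kern, sp,
                                 seed = derive_seed(seed, 3)))
}

# an audiogram matrix with given thresholds at the standard frequencies
flat_audiogram <- function(level = 20) {
  freqs <- c(125, 250, 500, 1000, 2000, 4000, 6000, 8000)
  ag <- matrix(level, 2, 8, dimnames = list(c("left", "right"),
                                            as.character(freqs)))
  ag
}
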