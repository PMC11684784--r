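#' Derive a per-stage random seed from a master seed
#'
#' All stochastic stages of the pipeline take an explicit integer seed. To keep
#' a whole run reproducible from a single master seed, per-stage/per-subject
#' seeds are derived with a fixed affine splitting rule modulo the Mersenne
#' prime 2^31 - 1, so every derived seed fits a 32-bit R integer and distinct
#' streams never collide for |stream| < 2^31.
#'
#' @param master integer master seed.
#' @param stream non-negative integer stream index (0 = the master stream).
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, stream = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(stream) * 8191 + 1
  as.integer(s %% m)
}

#' Condition labels of the entropy manipulation
#' @export
entropy_conditions <- function() c("random", "midminus", "midplus", "ordered")

# Successor-probability mass placed on the designated cyclic successor, per
# condition, for K = 4 with the diagonal fixed at 1/K. Random puts 1/K on the
# successor (flat row); ordered puts 0.75; the mid levels interpolate the
# concentration linearly.
.default_p_next <- c(random = 0.25, midminus = 0.416, midplus = 0.583,
                     ordered = 0.75)

#' Build an entropy-graded transition matrix
#'
#' Rows index the current tone, columns the next tone. The diagonal
#' (self-repetition) probability is fixed at 1/K for every condition, so the
#' regularity manipulation never changes the repetition rate. The remaining
#' (K-1)/K mass is concentrated on one designated successor per tone (the
#' cyclic neighbour, tone i -> i+1 mod K) with strength depending on the
#' condition, and the remainder spread evenly over the other tones.
#'
#' @param condition_label one of `entropy_conditions()`.
#' @param K number of tone classes (default 4).
#' @param order_strength successor mass for the `ordered` condition, in
#'   `[1/K, (K-1)/K]`; the mid conditions interpolate between `1/K` and this
#'   value. Default 0.75.
#' @return an object of class `transition_matrix`: list with `probs` (K x K),
#'   `condition_label`, `K`.
#' @export
build_transition_matrix <- function(condition_label, K = 4L,
                                    order_strength = 0.75) {
  if (!condition_label %in% entropy_conditions()) {
    stop("unknown condition label: ", condition_label)
  }
  if (K < 2) stop("K must be >= 2")
  if (order_strength < 0 || order_strength > (K - 1) / K) {
    stop("order_strength must lie in [0, (K-1)/K]")
  }
  diag_p <- 1 / K
  # interpolate successor concentration between flat (1/K) and order_strength
  frac <- switch(condition_label,
                 random   = 0,
                 midminus = (.default_p_next[["midminus"]] - 0.25) / 0.5,
                 midplus  = (.default_p_next[["midplus"]] - 0.25) / 0.5,
                 ordered  = 1)
  p_next <- diag_p + frac * (order_strength - diag_p)
  p_rest <- if (K > 2) (1 - diag_p - p_next) / (K - 2) else 0
  probs <- matrix(p_rest, K, K)
  diag(probs) <- diag_p
  for (i in seq_len(K)) probs[i, (i %% K) + 1L] <- p_next
  m <- structure(list(probs = probs, condition_label = condition_label, K = K),
                 class = "transition_matrix")
  validate_transition_matrix(m)
  m
}

#' @export
validate_transition_matrix <- function(m) {
  p <- m$probs
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) stop("entries outside [0, 1]")
  if (any(abs(rowSums(p) - 1) > 1e-12)) stop("rows must sum to 1")
  invisible(m)
}

#' Per-row and mean Shannon entropy of a transition matrix
#'
#' @param m a `transition_matrix`.
#' @return list with `per_row` (bits) and `mean` (bits).
#' @export
matrix_entropy <- function(m) {
  validate_transition_matrix(m)
  h <- apply(m$probs, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  list(per_row = h, mean = mean(h))
}

#' Sample a tone sequence from a transition matrix
#'
#' The first tone is drawn uniformly (the stationary distribution of every
#' condition matrix is uniform because rows are permutation-symmetric with a
#' fixed diagonal); each subsequent tone is drawn from the row of the previous
#' tone. Onsets are a fixed stimulus-onset asynchrony apart (3 Hz by default).
#'
#' @param m a `transition_matrix`.
#' @param n number of tones.
#' @param seed integer seed.
#' @param soa_s stimulus-onset asynchrony in seconds (default 1/3).
#' @return a `tone_sequence`: data.frame with columns `trial_index`, `onset_s`,
#'   `tone_id` (0-based), `condition`, `is_omission`, plus attribute `soa_s`.
#' @export
generate_sequence <- function(m, n, seed, soa_s = 1 / 3) {
  validate_transition_matrix(m)
  if (n < 1) stop("n must be >= 1")
  K <- m$K
  tones <- integer(n)
  withr::with_seed(seed, {
    tones[1L] <- sample.int(K, 1L)
    if (n > 1L) {
      # one uniform per step, inverted through the row CDFs
      u <- stats::runif(n - 1L)
      cum <- t(apply(m$probs, 1, cumsum))
      for (i in 2L:n) {
        tones[i] <- findInterval(u[i - 1L], cum[tones[i - 1L], ]) + 1L
      }
    }
  })
  seq_df <- data.frame(trial_index = seq_len(n),
                       onset_s = (seq_len(n) - 1L) * soa_s,
                       tone_id = tones - 1L,
                       condition = m$condition_label,
                       is_omission = FALSE)
  structure(seq_df, soa_s = soa_s, class = c("tone_sequence", "data.frame"))
}

#' Flag a fixed fraction of events as omissions
#'
#' Exactly `round(rate * n)` events are flagged, at positions drawn uniformly
#' without replacement; tone identities are retained on omitted events (an
#' omission is a silent gap where a specific tone was expected).
#'
#' @param seq_df a `tone_sequence`.
#' @param rate omission fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return the sequence with `is_omission` set.
#' @export
insert_omissions <- function(seq_df, rate, seed) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  n <- nrow(seq_df)
  n_om <- round(rate * n)
  seq_df$is_omission <- FALSE
  if (n_om > 0) {
    idx <- withr::with_seed(seed, sample.int(n, n_om))
    seq_df$is_omission[idx] <- TRUE
  }
  seq_df
}

#' Logarithmically spaced carrier frequencies
#'
#' @param f_lo,f_hi endpoints in Hz (inclusive).
#' @param K number of frequencies.
#' @return integer vector of K frequencies, geometric spacing rounded to Hz.
#' @export
log_spaced_freqs <- function(f_lo, f_hi, K = 4L) {
  if (f_lo <= 0 || f_hi <= f_lo) stop("need 0 < f_lo < f_hi")
  if (K < 2) stop("K must be >= 2")
  round(exp(seq(log(f_lo), log(f_hi), length.out = K)))
}

#' Study design presets
#'
#' `study1`: four entropy conditions, carriers 200-2000 Hz, 1000 stimuli per
#' condition-block with a 10% omission rate (900 sounds + 100 omissions per
#' block; 3600 sounds + 400 omissions in total), epochs (-1, 1) s.
#' `study2`: random and ordered only, carriers 440-1043 Hz, 1500 stimuli per
#' condition arranged in two blocks of alternating 500-stimulus segments
#' (random-ordered-random and ordered-random-ordered), no omissions, epochs
#' (-0.4, 0.5) s.
#'
#' @param study_id `"study1"` or `"study2"`.
#' @param n_trials_per_condition override the preset trial count (scaled-down
#'   simulations); segment layouts are scaled proportionally.
#' @return a `study_design` list.
#' @export
study_design <- function(study_id = c("study1", "study2"),
                         n_trials_per_condition = NULL) {
  study_id <- match.arg(study_id)
  d <- if (study_id == "study1") {
    list(study_id = "study1",
         K = 4L,
         carrier_freqs_hz = log_spaced_freqs(200, 2000, 4L),
         conditions = entropy_conditions(),
         n_trials_per_condition = 1000L,
         omission_rate = 0.10,
         soa_s = 1 / 3,
         sfreq = 100,
         epoch_window_s = c(-1, 1),
         block_layout = lapply(entropy_conditions(), function(cc)
           list(condition = cc, n_stimuli = 1000L)))
  } else {
    list(study_id = "study2",
         K = 4L,
         carrier_freqs_hz = log_spaced_freqs(440, 1043, 4L),
         conditions = c("random", "ordered"),
         n_trials_per_condition = 1500L,
         omission_rate = 0,
         soa_s = 1 / 3,
         sfreq = 100,
         epoch_window_s = c(-0.4, 0.5),
         block_layout = list(
           list(condition = "random",  n_stimuli = 500L),
           list(condition = "ordered", n_stimuli = 500L),
           list(condition = "random",  n_stimuli = 500L),
           list(condition = "ordered", n_stimuli = 500L),
           list(condition = "random",  n_stimuli = 500L),
           list(condition = "ordered", n_stimuli = 500L)))
  }
  if (!is.null(n_trials_per_condition)) {
    n_new <- as.integer(n_trials_per_condition)
    d$n_trials_per_condition <- n_new
    # split each condition's total over its segments, exactly
    for (cc in d$conditions) {
      seg <- which(vapply(d$block_layout, function(b) b$condition == cc,
                          logical(1)))
      sizes <- rep(n_new %/% length(seg), length(seg))
      extra <- n_new %% length(seg)
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      for (i in seq_along(seg)) {
        d$block_layout[[seg[i]]]$n_stimuli <- sizes[i]
      }
    }
  }
  per_cond <- vapply(d$conditions, function(cc)
    sum(vapply(d$block_layout,
               function(b) if (b$condition == cc) b$n_stimuli else 0L,
               integer(1))), integer(1))
  if (any(per_cond != d$n_trials_per_condition)) {
    stop("block layout segment sums do not match n_trials_per_condition")
  }
  structure(d, class = "study_design")
}

#' Generate all condition blocks of a study design
#'
#' One Markov tone sequence per block segment (per-condition transition
#' matrix), with omissions inserted at the design's rate within each
#' condition-block. Per-block seeds are derived from `seed` with
#' [derive_seed()].
#'
#' @param design a `study_design`.
#' @param seed integer master seed.
#' @param order_strength successor mass of the ordered condition (default
#'   0.75).
#' @return list of `tone_sequence`, one per block segment, each with a `block`
#'   column.
#' @export
make_study_blocks <- function(design, seed, order_strength = 0.75) {
  if (length(design$block_layout) == 0 || design$n_trials_per_condition == 0) {
    return(list())
  }
  mats <- lapply(stats::setNames(design$conditions, design$conditions),
                 build_transition_matrix, K = design$K,
                 order_strength = order_strength)
  blocks <- vector("list", length(design$block_layout))
  for (b in seq_along(design$block_layout)) {
    lay <- design$block_layout[[b]]
    s <- generate_sequence(mats[[lay$condition]], lay$n_stimuli,
                           seed = derive_seed(seed, b),
                           soa_s = design$soa_s)
    if (design$omission_rate > 0) {
      s <- insert_omissions(s, design$omission_rate,
                            seed = derive_seed(seed, 1000L + b))
    }
    s$block <- b
    blocks[[b]] <- s
  }
  blocks
}

#' Write / read a tone-sequence event table as TSV
#'
#' Columns: trial_index, onset_s, tone_id, carrier_freq_hz, condition, block,
#' is_omission.
#' @param seq_df a `tone_sequence` (with `block` column, else block = 1).
#' @param design the study design providing carrier frequencies.
#' @param path output TSV path.
#' @export
write_events_tsv <- function(seq_df, design, path) {
  df <- as.data.frame(seq_df)
  if (is.null(df$block)) df$block <- 1L
  df$carrier_freq_hz <- design$carrier_freqs_hz[df$tone_id + 1L]
  df <- df[, c("trial_index", "onset_s", "tone_id", "carrier_freq_hz",
               "condition", "block", "is_omission")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(df, class = c("tone_sequence", "data.frame"))
}

#' Write a transition matrix as TSV (row label = current tone id)
#' @export
write_transition_tsv <- function(m, path) {
  p <- m$probs
  dimnames(p) <- list(seq_len(m$K) - 1L, seq_len(m$K) - 1L)
  utils::write.table(p, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
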