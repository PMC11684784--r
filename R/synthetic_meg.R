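#' Sensor model: tone topographies and spatially correlated noise
#'
#' Emulates a magnetometer array: one unit-norm spatial pattern per tone class
#' and a smooth spatial noise covariance. Channels are placed on a virtual
#' line; noise covariance decays as a squared-exponential of channel distance
#' with correlation length `smoothness` (in channel units), which yields a
#' symmetric positive semi-definite matrix. Topographies are drawn as smoothed
#' Gaussian vectors and redrawn (up to `max_tries`) until every pairwise
#' absolute cosine similarity is below `max_abs_cos`, so the classes are
#' discriminable but not orthogonal.
#'
#' @param n_channels number of sensors (default 102, a magnetometer count).
#' @param K number of tone classes.
#' @param smoothness spatial correlation length in channel units (default
#'   `min(5, max(1, n_channels / 3))`, i.e. 5 for the 102-channel array,
#'   shrinking with smaller arrays so classes stay discriminable).
#' @param seed integer seed.
#' @param max_abs_cos upper bound on pairwise |cosine| between topographies
#'   (default 0.8).
#' @param max_tries redraw budget before giving up.
#' @return a `sensor_model`: list with `topographies` (K x n_channels,
#'   unit-norm rows), `noise_cov`, `noise_chol`, `n_channels`, `K`.
#' @export
make_sensor_model <- function(n_channels = 102L, K = 4L, smoothness = NULL,
                              seed = 1L, max_abs_cos = 0.8,
                              max_tries = 50L) {
  if (n_channels < K) stop("need n_channels >= K")
  if (is.null(smoothness)) {
    # correlation length of 5 channel units for full-size arrays, shrinking
    # for small arrays so the topography draw can satisfy the cosine bound
    smoothness <- min(5, max(1, n_channels / 3))
  }
  d <- abs(outer(seq_len(n_channels), seq_len(n_channels), "-"))
  noise_cov <- exp(-0.5 * (d / smoothness)^2)
  # tiny ridge keeps the Cholesky stable for long correlation lengths
  noise_chol <- chol(noise_cov + 1e-8 * diag(n_channels))
  smooth_cov_chol <- noise_chol  # topographies share the spatial smoothness
  topo <- withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      z <- matrix(stats::rnorm(K * n_channels), K, n_channels)
      tp <- z %*% smooth_cov_chol
      tp <- tp / sqrt(rowSums(tp^2))
      cs <- abs(tcrossprod(tp))
      diag(cs) <- 0
      if (max(cs) < max_abs_cos) break
      tp <- NULL
    }
    if (is.null(tp)) stop("could not draw topographies under the cosine bound")
    tp
  })
  structure(list(topographies = topo, noise_cov = noise_cov,
                 noise_chol = noise_chol, n_channels = as.integer(n_channels),
                 K = as.integer(K), smoothness = smoothness),
            class = "sensor_model")
}

#' Evoked response kernel with early and late components
#'
#' A causal temporal kernel: two smooth Gaussian bumps, an early component
#' (default peak 100 ms) and a late component (default peak 450 ms), zero for
#' t < 0. The late component carries the carrier-frequency-specific
#' reactivation that the late training windows pick up.
#'
#' @param latency_early_s,latency_late_s component peak latencies (s).
#' @param a_early,a_late component amplitudes (arbitrary field units).
#' @param width_s Gaussian sd of each bump (s).
#' @param sfreq sampling rate (Hz).
#' @param support_s kernel duration (s).
#' @return a `response_kernel`: list with `times_s`, `values`, and the
#'   component parameters.
#' @export
response_kernel <- function(latency_early_s = 0.10, latency_late_s = 0.45,
                            a_early = 1, a_late = 1, width_s = 0.03,
                            sfreq = 100, support_s = 0.6) {
  times <- seq(0, support_s, by = 1 / sfreq)
  v <- a_early * exp(-0.5 * ((times - latency_early_s) / width_s)^2) +
    a_late * exp(-0.5 * ((times - latency_late_s) / width_s)^2)
  structure(list(times_s = times, values = v,
                 latency_early_s = latency_early_s,
                 latency_late_s = latency_late_s,
                 a_early = a_early, a_late = a_late, width_s = width_s,
                 sfreq = sfreq),
            class = "response_kernel")
}

#' Evaluate a response kernel at arbitrary lags (zero outside support / t < 0)
#' @keywords internal
kernel_at <- function(kernel, t) {
  v <- numeric(length(t))
  inside <- t >= 0 & t <= max(kernel$times_s)
  if (any(inside)) {
    v[inside] <- stats::approx(kernel$times_s, kernel$values, t[inside],
                               rule = 2)$y
  }
  v
}

#' Subject specification for the synthetic cohort
#'
#' @param subject_id character id.
#' @param group `"tinnitus"` or `"control"`.
#' @param alpha_pre signed gain of the pre-stimulus (de)activation of the
#'   predicted tone's late pattern in ordered sequences; 0 = no anticipatory
#'   effect, negative = deactivation (control-like).
#' @param snr evoked-to-noise amplitude ratio (per-channel evoked peak over
#'   per-channel noise sd).
#' @param audiogram named numeric vector of thresholds (dB HL) at the standard
#'   frequencies, or a two-row matrix (left/right ears).
#' @param distress Mini-TQ distress score (NA for controls).
#' @return a `subject_spec` list.
#' @export
subject_spec <- function(subject_id, group = c("tinnitus", "control"),
                         alpha_pre = 0, snr = 1.5, audiogram = NULL,
                         distress = NA_real_) {
  group <- match.arg(group)
  structure(list(subject_id = subject_id, group = group,
                 alpha_pre = alpha_pre, snr = snr, audiogram = audiogram,
                 distress = distress),
            class = "subject_spec")
}

#' Epochs container
#'
#' Per-subject epoched sensor data: trials x channels x time, a uniform time
#' grid, and per-trial tone labels and condition labels.
#'
#' @param data numeric array, trials x channels x time.
#' @param times_s time grid (s), uniform at 1/sfreq.
#' @param labels integer tone ids (0-based), length = n trials.
#' @param condition character condition per trial.
#' @param sfreq sampling rate (Hz).
#' @param subject_id subject id.
#' @param is_omission logical per trial (optional).
#' @return a `meg_epochs` object.
#' @export
meg_epochs <- function(data, times_s, labels, condition, sfreq = 100,
                       subject_id = "s01", is_omission = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != length(labels) || dim(data)[3] != length(times_s)) {
    stop("data dimensions inconsistent with labels/times")
  }
  dt <- diff(times_s)
  if (max(abs(dt - 1 / sfreq)) > 1e-9) stop("time grid not uniform at 1/sfreq")
  if (is.null(is_omission)) is_omission <- rep(FALSE, length(labels))
  structure(list(data = data, times_s = times_s, labels = as.integer(labels),
                 condition = as.character(condition), sfreq = sfreq,
                 subject_id = subject_id, is_omission = is_omission),
            class = "meg_epochs")
}

#' @export
print.meg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<meg_epochs %s: %d trials x %d channels x %d samples, %g-%g s>\n",
              x$subject_id, d[1], d[2], d[3], min(x$times_s), max(x$times_s)))
  invisible(x)
}

# Deterministic signal template for one epoch: sum over the decoded tone and
# its sequence neighbours of topography x kernel, plus (ordered trials) the
# anticipatory term on the predicted tone's late pattern. Returns channels x
# time. Exposed for the exactness tests; simulate_subject uses the same sums
# through precomputed per-offset building blocks.
.epoch_template <- function(i, tones, omitted, condition, sensors, kernel,
                            alpha_pre, times, soa_s, pre_center_s,
                            pre_width_s = 0.07) {
  n <- length(tones)
  tmpl <- matrix(0, sensors$n_channels, length(times))
  support <- max(kernel$times_s)
  # tone at offset j (onset j*soa) contributes iff its causal kernel support
  # [j*soa, j*soa + support] overlaps the epoch window
  j_lo <- ceiling((min(times) - support) / soa_s)
  j_hi <- floor(max(times) / soa_s)
  for (j in j_lo:j_hi) {
    k <- i + j
    if (k < 1 || k > n) next
    if (omitted[k]) next
    kv <- kernel_at(kernel, times - j * soa_s)
    if (all(kv == 0)) next
    tmpl <- tmpl + tcrossprod(sensors$topographies[tones[k] + 1L, ], kv)
  }
  if (alpha_pre != 0 && condition == "ordered" && i > 1L) {
    # the learned regularity predicts the cyclic successor of the previous tone
    pred <- (tones[i - 1L] + 1L) %% sensors$K
    bump <- kernel$a_late *
      exp(-0.5 * ((times - pre_center_s) / pre_width_s)^2)
    tmpl <- tmpl + alpha_pre *
      tcrossprod(sensors$topographies[pred + 1L, ], bump)
  }
  tmpl
}

#' Simulate one subject's epoched sensor data
#'
#' Each epoch is the linear superposition of topography-by-kernel responses of
#' every non-omitted tone whose kernel support overlaps the epoch window
#' (neighbouring tones at multiples of the SOA overlap by design), plus, on
#' ordered-condition trials, `alpha_pre` times the predicted (cyclic successor
#' of the previous) tone's late pattern as a bump centred in the pre-stimulus
#' interval, plus spatially correlated Gaussian noise with per-channel sd
#' `1/snr` (the evoked early peak has unit amplitude, so `snr` is the
#' evoked-to-noise amplitude ratio). `snr = Inf` gives the noiseless template.
#'
#' @param design a `study_design`.
#' @param sequences list of `tone_sequence` blocks (from [make_study_blocks()]).
#' @param sensors a `sensor_model`.
#' @param kernel a `response_kernel`.
#' @param spec a `subject_spec`.
#' @param seed integer seed for the noise.
#' @param pre_center_s centre of the anticipatory bump (default -0.38 s).
#' @param noise_tsmooth_s temporal Gaussian smoothing sd applied to the noise
#'   (default 0.01 s), mimicking low-pass-filtered sensor noise.
#' @return a `meg_epochs` object covering all trials of all blocks.
#' @export
simulate_subject <- function(design, sequences, sensors, kernel, spec, seed,
                             pre_center_s = -0.38, pre_width_s = 0.07,
                             noise_tsmooth_s = 0.01) {
  if (length(sequences) != length(design$block_layout)) {
    stop("sequences do not match the design's block layout")
  }
  times <- seq(design$epoch_window_s[1], design$epoch_window_s[2],
               by = 1 / design$sfreq)
  n_t <- length(times)
  nch <- sensors$n_channels
  K <- sensors$K
  n_trials <- sum(vapply(sequences, nrow, integer(1)))
  dat <- array(0, c(n_trials, nch, n_t))
  labels <- integer(n_trials)
  condition <- character(n_trials)
  omission <- logical(n_trials)
  support <- max(kernel$times_s)
  offsets <- ceiling((min(times) - support) / design$soa_s):
    floor(max(times) / design$soa_s)
  # building blocks: topography x kernel outer product per (tone, offset),
  # and topography x anticipatory bump per tone
  kv <- lapply(offsets, function(j) kernel_at(kernel, times - j * design$soa_s))
  blockmat <- lapply(seq_len(K), function(k)
    lapply(kv, function(v) tcrossprod(sensors$topographies[k, ], v)))
  bump <- kernel$a_late * exp(-0.5 * ((times - pre_center_s) / pre_width_s)^2)
  bumpmat <- lapply(seq_len(K), function(k)
    tcrossprod(sensors$topographies[k, ], bump))
  row0 <- 0L
  for (b in seq_along(sequences)) {
    sq <- sequences[[b]]
    if (sq$condition[1] != design$block_layout[[b]]$condition) {
      stop("sequence condition does not match the design block")
    }
    n <- nrow(sq)
    tones <- sq$tone_id
    omit <- sq$is_omission
    cond_b <- sq$condition[1]
    # context tone per (trial, offset): -1 where out of range or omitted
    ctx <- matrix(-1L, n, length(offsets))
    for (oi in seq_along(offsets)) {
      k <- seq_len(n) + offsets[oi]
      ok <- k >= 1L & k <= n
      kk <- pmax(pmin(k, n), 1L)
      ctx[, oi] <- ifelse(ok & !omit[kk], tones[kk], -1L)
    }
    pred <- rep(-1L, n)
    if (spec$alpha_pre != 0 && cond_b == "ordered" && n > 1L) {
      pred[-1L] <- (tones[-n] + 1L) %% K
    }
    # encode each trial's context as an integer key; identical keys share an
    # identical deterministic template
    base <- K + 2
    key <- (pred + 2)
    for (oi in seq_along(offsets)) key <- key * base + (ctx[, oi] + 2)
    for (u in unique(key)) {
      idx <- which(key == u)
      i0 <- idx[1L]
      tmpl <- matrix(0, nch, n_t)
      for (oi in seq_along(offsets)) {
        tk <- ctx[i0, oi]
        if (tk >= 0L) tmpl <- tmpl + blockmat[[tk + 1L]][[oi]]
      }
      if (pred[i0] >= 0L) {
        tmpl <- tmpl + spec$alpha_pre * bumpmat[[pred[i0] + 1L]]
      }
      dat[row0 + idx, , ] <- rep(tmpl, each = length(idx))
    }
    labels[row0 + seq_len(n)] <- tones
    condition[row0 + seq_len(n)] <- cond_b
    omission[row0 + seq_len(n)] <- omit
    row0 <- row0 + n
  }
  if (is.finite(spec$snr)) {
    noise <- withr::with_seed(seed, {
      # rows ordered time-fastest within trial so temporal smoothing is a
      # block-wise row shift on one big matrix
      z <- matrix(stats::rnorm(n_trials * n_t * nch), n_trials * n_t, nch)
      z <- z %*% sensors$noise_chol
      if (noise_tsmooth_s > 0) {
        w <- exp(-0.5 * seq(-3, 3, length.out = 7)^2)
        tpos <- rep(seq_len(n_t), n_trials)
        troff <- rep(seq(0L, n_trials - 1L) * n_t, each = n_t)
        sm <- matrix(0, nrow(z), ncol(z))
        for (s in seq_along(w)) {
          src <- pmin(pmax(tpos + (s - 4L), 1L), n_t) + troff
          sm <- sm + w[s] * z[src, , drop = FALSE]
        }
        z <- sm / sqrt(sum(w^2))  # keep per-channel sd at 1
      }
      aperm(array(z, c(n_t, n_trials, nch)), c(2, 3, 1))
    })
    dat <- dat + noise / spec$snr
  }
  meg_epochs(dat, times, labels, condition, sfreq = design$sfreq,
             subject_id = spec$subject_id, is_omission = omission)
}

#' Draw a synthetic audiogram
#'
#' Thresholds (dB HL) at 125-8000 Hz for both ears: a gently sloping base
#' audiogram with age-like high-frequency loss, clipped to [-10, 120] dB HL.
#' Both groups draw from the same distribution (hearing-matched by
#' construction).
#'
#' @param seed integer seed.
#' @param hf_loss_mean mean additional high-frequency loss (dB) at 8 kHz.
#' @return matrix 2 x 8 (ears x frequencies), dimnames set.
#' @export
simulate_audiogram <- function(seed, hf_loss_mean = 25) {
  freqs <- c(125, 250, 500, 1000, 2000, 4000, 6000, 8000)
  withr::with_seed(seed, {
    base <- stats::rnorm(1, 10, 5)
    hf <- pmax(stats::rnorm(1, hf_loss_mean, 12), 0)
    slope <- hf * pmax(log2(freqs / 1000), 0) / 3  # ramps from 1 kHz to 8 kHz
    ag <- rbind(left = base + slope + stats::rnorm(8, 0, 3),
                right = base + slope + stats::rnorm(8, 0, 3))
    colnames(ag) <- as.character(freqs)
    pmin(pmax(round(ag / 5) * 5, -10), 120)
  })
}

#' Pure-tone average (PTA) of an audiogram
#'
#' Arithmetic mean of thresholds at 500, 1000, 2000 and 4000 Hz (PTA-4), per
#' ear and averaged over ears; the extended variant also includes 6000 and
#' 8000 Hz for high-frequency sensitivity analyses.
#'
#' @param audiogram named vector or ears x frequencies matrix of dB HL.
#' @param extended include 6000 and 8000 Hz.
#' @return list with `per_ear` and `mean` (dB HL).
#' @export
pta4 <- function(audiogram, extended = FALSE) {
  want <- c("500", "1000", "2000", "4000")
  if (extended) want <- c(want, "6000", "8000")
  ag <- if (is.matrix(audiogram)) audiogram else rbind(audiogram)
  if (!all(want %in% colnames(ag))) {
    stop("audiogram is missing required frequencies: ",
         paste(setdiff(want, colnames(ag)), collapse = ", "))
  }
  per_ear <- rowMeans(ag[, want, drop = FALSE])
  list(per_ear = per_ear, mean = mean(per_ear))
}

#' Hearing-loss flag: any threshold strictly above 30 dB HL
#' @param audiogram named vector or matrix of dB HL.
#' @return logical.
#' @export
hearing_loss_flag <- function(audiogram) {
  if (length(audiogram) == 0) stop("empty audiogram")
  any(audiogram > 30)
}

#' Simulate a matched two-group cohort
#'
#' Per-subject seeds (sequences, noise, audiograms, distress) derive from the
#' master seed. Audiograms come from one shared distribution for both groups
#' (hearing-matched by construction); distress scores are drawn only for
#' tinnitus-like subjects.
#'
#' @param design a `study_design`.
#' @param n_per_group subjects per group.
#' @param group_params list with elements `tinnitus` and `control`, each a
#'   list with `alpha_pre` and `snr`.
#' @param seed master seed.
#' @param sensors optional shared `sensor_model` (default built from the
#'   design at 102 channels).
#' @param kernel optional `response_kernel`.
#' @param shared_sequences if TRUE (default) all subjects hear the same tone
#'   sequences (as in a fixed stimulus protocol); if FALSE, sequences are
#'   redrawn per subject.
#' @return list with `subjects` (list of `subject_spec`, with `$epochs`
#'   attached) and `sensors`, `kernel`, `design`.
#' @export
simulate_cohort <- function(design, n_per_group,
                            group_params = default_group_params(),
                            seed = 1L, sensors = NULL, kernel = NULL,
                            shared_sequences = TRUE) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (is.null(kernel)) kernel <- response_kernel(sfreq = design$sfreq)
  if (is.null(sensors)) {
    sensors <- make_sensor_model(102L, design$K, seed = derive_seed(seed, 1L))
  }
  seqs_shared <- if (shared_sequences) {
    make_study_blocks(design, seed = derive_seed(seed, 2L))
  } else NULL
  groups <- rep(c("tinnitus", "control"), each = n_per_group)
  subjects <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    g <- groups[s]
    gp <- group_params[[g]]
    ag <- simulate_audiogram(derive_seed(seed, 100L + s))
    distress <- if (g == "tinnitus") {
      withr::with_seed(derive_seed(seed, 200L + s),
                       min(max(round(stats::rnorm(1, 11, 5)), 0), 24))
    } else NA_real_
    spec <- subject_spec(sprintf("%s_%02d", substr(g, 1, 3), s), group = g,
                         alpha_pre = gp$alpha_pre, snr = gp$snr,
                         audiogram = ag, distress = distress)
    seqs <- if (shared_sequences) seqs_shared else {
      make_study_blocks(design, seed = derive_seed(seed, 300L + s))
    }
    spec$epochs <- simulate_subject(design, seqs, sensors, kernel, spec,
                                    seed = derive_seed(seed, 400L + s))
    subjects[[s]] <- spec
  }
  list(subjects = subjects, sensors = sensors, kernel = kernel,
       design = design)
}

#' Default group parameters of the synthetic effect
#'
#' Controls deactivate the predicted tone's late pattern before onset
#' (`alpha_pre = -0.3 * a_late`); tinnitus-like subjects show no anticipatory
#' modulation (`alpha_pre = 0`), mirroring the below-chance control decoding
#' that drives the group difference. Both groups share the same snr.
#'
#' @param a_late late-component amplitude the deactivation is scaled to.
#' @param snr evoked-to-noise amplitude ratio for both groups.
#' @export
default_group_params <- function(a_late = 1, snr = 1.5) {
  list(tinnitus = list(alpha_pre = 0, snr = snr),
       control = list(alpha_pre = -0.3 * a_late, snr = snr))
}

#' Write / read an epochs container as a directory
#'
#' `metadata.json` holds subject id, group label (optional), sfreq, tmin,
#' dimensions, channel names, per-trial condition and tone label;
#' `data.bin` holds float32 little-endian C-order `[trial][channel][time]`.
#'
#' @param epochs a `meg_epochs`.
#' @param dir output directory (created).
#' @export
write_epochs_dir <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  meta <- list(subject_id = epochs$subject_id, sfreq = epochs$sfreq,
               tmin = min(epochs$times_s), n_trials = d[1], n_channels = d[2],
               n_times = d[3],
               channel_names = sprintf("MEG%03d", seq_len(d[2])),
               condition = epochs$condition, tone_label = epochs$labels,
               is_omission = epochs$is_omission)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  # C-order [trial][channel][time]: time fastest -> reverse R's column-major
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con, size = 4,
           endian = "little")
  invisible(dir)
}

#' @rdname write_epochs_dir
#' @param dir directory written by [write_epochs_dir()].
#' @export
read_epochs_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  n <- meta$n_trials * meta$n_channels * meta$n_times
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  dat <- aperm(array(v, c(meta$n_times, meta$n_channels, meta$n_trials)),
               c(3, 2, 1))
  times <- meta$tmin + (seq_len(meta$n_times) - 1L) / meta$sfreq
  meg_epochs(dat, times, meta$tone_label, meta$condition, sfreq = meta$sfreq,
             subject_id = meta$subject_id, is_omission = meta$is_omission)
}
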