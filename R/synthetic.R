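#' Analytic archetype template maps
#'
#' Four canonical resting-state microstate topographies built analytically
#' from electrode positions (x right, y nasion, z up): A and B are the
#' mirror-image diagonal gradients (left-occipital to right-frontal and
#' right-occipital to left-frontal), C is the occipital-to-frontal axial
#' gradient, and D a fronto-central focal maximum. Each map is zero-mean
#' and unit-norm. Any fixed, documented template set makes the A-D labels
#' reproducible; these are synthetic stand-ins, not empirical grand-average
#' maps.
#'
#' @param mont an \code{ms_montage} with positions.
#' @return an \code{ms_maps} with labels A, B, C, D.
#' @export
template_maps <- function(mont = study_montage()) {
  if (n_channels(mont) < 4) stop("need at least 4 channels")
  p <- mont$positions
  d0 <- c(0, 0.3, sqrt(1 - 0.3^2))       # fronto-central focus

  A <- 1.2 * p[, "x"] + 0.8 * p[, "y"]
  B <- -1.2 * p[, "x"] + 0.8 * p[, "y"]
  C <- p[, "y"]
  D <- exp(-colSums((t(p) - d0)^2) / (2 * 0.5^2))
  microstate_maps(rbind(A, B, C, D), c("A", "B", "C", "D"))
}

#' Specification for the semi-Markov microstate EEG simulator
#'
#' Defaults emulate eyes-closed resting EEG with the four-state structure
#' reported for healthy adults: mean dwell times of roughly 78-92 ms
#' (gamma-distributed, shape 4), a 10 Hz amplitude envelope so GFP peaks
#' arrive at realistic alpha-band rates, and spatially white sensor noise
#' at signal-to-noise ratio 2 (RMS/RMS).
#'
#' @param K number of states.
#' @param mean_durations_ms per-state mean dwell time (ms).
#' @param transition K x K matrix with zero diagonal and rows summing to 1,
#'   or NULL for uniform switching.
#' @param carrier_hz centre of the amplitude-carrier band (alpha, 10 Hz).
#' @param depth modulation depth in (0, 1]: the instantaneous amplitude is
#'   floored at (1 - depth) of its scale, so at depth 1 the carrier is pure
#'   band-limited noise and at smaller depths it never collapses to zero.
#' @param snr signal RMS / noise RMS; \code{Inf} disables noise.
#' @param n_epochs,epoch_length_s,fs epoching and rate.
#' @param seed integer RNG seed.
#' @return a list of class \code{ms_simspec}.
#' @export
sim_spec <- function(K = 4, mean_durations_ms = c(78, 77, 83, 92),
                     transition = NULL, carrier_hz = 10, depth = 0.8,
                     snr = 2, n_epochs = 50, epoch_length_s = 3, fs = 200,
                     seed = 1) {
  if (length(mean_durations_ms) != K) stop("need one mean duration per state")
  if (any(mean_durations_ms <= 0)) stop("mean durations must be > 0")
  if (any(mean_durations_ms * fs / 1000 < 2))
    stop("duration mean below 2 samples at fs")
  if (snr <= 0) stop("snr must be > 0")
  if (is.null(transition)) {
    transition <- matrix(1 / (K - 1), K, K)
    diag(transition) <- 0
  }
  transition <- as.matrix(transition)
  if (any(diag(transition) != 0) ||
      any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must sum to 1 with zero diagonal")
  structure(list(K = K, mean_durations_ms = mean_durations_ms,
                 transition = transition, carrier_hz = carrier_hz,
                 depth = depth, snr = snr, n_epochs = n_epochs,
                 epoch_length_s = epoch_length_s, fs = fs, seed = seed),
            class = "ms_simspec")
}

#' Simulate EEG with known microstate structure
#'
#' Per epoch a semi-Markov state sequence is drawn (gamma dwell times,
#' shape 4, specified means, rounded to samples with a 2-sample floor) and
#' the signal is the active state's map scaled by an oscillatory
#' alpha-band amplitude carrier (band-limited noise around
#' \code{carrier_hz} with a sign-preserving floor, see \code{sim_spec}).
#' Spatially white Gaussian noise is added at the specified SNR and the
#' result average-referenced. Pure function of the spec (seeded).
#'
#' @param spec an \code{ms_simspec}.
#' @param M an \code{ms_maps} with \code{M$K == spec$K}.
#' @param mont montage for the output (channel count must match M).
#' @return list with \code{epochs} (an \code{ms_epochs}) and
#'   \code{labels} (ground-truth per-sample state, epoch-major order).
#' @export
simulate_microstate_eeg <- function(spec, M = template_maps(),
                                    mont = study_montage()) {
  if (M$K != spec$K) stop("M$K != spec$K")
  if (ncol(M$maps) != n_channels(mont)) stop("map/montage channel mismatch")
  set.seed(spec$seed)
  fs <- spec$fs
  L <- round(spec$epoch_length_s * fs)
  C <- ncol(M$maps)
  labels <- integer(0)
  signal <- vector("list", spec$n_epochs)
  for (ep in seq_len(spec$n_epochs)) {
    lab <- draw_state_sequence(spec, L)
    env <- amplitude_envelope(L, fs, spec$carrier_hz, spec$depth)
    signal[[ep]] <- t(M$maps[lab, , drop = FALSE] * env)
    labels <- c(labels, lab)
  }
  sig_rms <- sqrt(mean(unlist(signal)^2))
  noise_sd <- if (is.finite(spec$snr)) sig_rms / spec$snr else 0
  eps <- lapply(signal, function(mat) {
    if (noise_sd > 0)
      mat <- mat + matrix(stats::rnorm(C * L, sd = noise_sd), C, L)
    sweep(mat, 2, colMeans(mat))
  })
  list(epochs = epoched_recording(eps, fs, mont, spec$epoch_length_s),
       labels = labels)
}

draw_state_sequence <- function(spec, L) {
  fs <- spec$fs
  lab <- integer(L)
  pos <- 0L
  state <- sample.int(spec$K, 1)
  while (pos < L) {
    mean_samp <- spec$mean_durations_ms[state] * fs / 1000
    dur <- max(2L, round(stats::rgamma(1, shape = 4, scale = mean_samp / 4)))
    take <- min(dur, L - pos)
    lab[(pos + 1L):(pos + take)] <- state
    pos <- pos + take
    state <- sample.int(spec$K, 1, prob = spec$transition[state, ])
  }
  lab
}

# amplitude carrier: band-limited noise around carrier_hz whose magnitude
# is floored at (1 - depth) of its scale, carried with the noise's own
# alternating polarity: a = depth * b + (1 - depth) * sign(b), unit RMS.
# The polarity reversals are unobservable downstream (every microstate
# computation is polarity-blind) but keep the scalp signal oscillatory, so
# the 1 Hz high-pass edge does not eat the envelope; the floor keeps the
# instantaneous amplitude away from zero, where back-fitting is undefined.
amplitude_envelope <- function(L, fs, carrier_hz, depth) {
  b <- band_limited_noise(L, fs, carrier_hz - 2, carrier_hz + 2)
  a <- depth * b + (1 - depth) * sign(b)
  a / sqrt(mean(a^2))
}

# unit-variance Gaussian noise restricted to [lo, hi) Hz via FFT masking
band_limited_noise <- function(L, fs, lo, hi) {
  x <- stats::rnorm(L)
  X <- stats::fft(x)
  f <- (seq_len(L) - 1) * fs / L
  f_fold <- pmin(f, fs - f)
  keep <- f_fold >= lo & f_fold < hi
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / L
  s <- stats::sd(y)
  if (s == 0) stop("band too narrow for signal length")
  y / s
}

#' Simulate a multichannel signal with prescribed band-power fractions
#'
#' Each channel is an independent sum of four band-limited Gaussian noise
#' components, one per canonical band, built by FIR-bandpass-filtering
#' continuous white noise. The filter edges are inset by half a transition
#' width so each component's energy lies strictly inside its nominal band
#' (a component spilling over the shared band edge would be attributed to
#' the neighbouring band by any binned spectral estimator). Components are
#' normalized to unit sample variance and scaled by the square root of
#' their fraction, so the realized variance fractions equal the
#' prescription by construction.
#'
#' @param fractions length-4 non-negative vector summing to 1
#'   (delta, theta, alpha, beta).
#' @param n_epochs number of 3-s epochs.
#' @param fs sampling rate.
#' @param seed integer RNG seed.
#' @param mont montage.
#' @param epoch_length_s epoch length in seconds.
#' @return an \code{ms_epochs}.
#' @export
simulate_band_signal <- function(fractions, n_epochs = 60, fs = 200,
                                 seed = 1, mont = study_montage(),
                                 epoch_length_s = 3) {
  if (any(fractions < 0)) stop("negative fraction")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  set.seed(seed)
  bands <- canonical_bands()
  L <- round(epoch_length_s * fs)
  n <- n_epochs * L
  pad <- 1000L
  tw <- 1
  kerns <- lapply(seq_len(4), function(b)
    design_fir("bandpass", c(bands$lo[b] + tw / 2, bands$hi[b] - tw / 2),
               fs, ripple = 0.01, transition_width = tw))
  C <- n_channels(mont)
  X <- matrix(0, C, n)
  for (ch in seq_len(C)) {
    x <- numeric(n)
    for (b in seq_len(4)) {
      if (fractions[b] == 0) next
      w <- stats::rnorm(n + 2L * pad)
      y <- filter_matrix(matrix(w, 1), kerns[[b]]$taps)[1, pad + seq_len(n)]
      x <- x + sqrt(fractions[b]) * y / stats::sd(y)
    }
    X[ch, ] <- x
  }
  eps <- lapply(seq_len(n_epochs), function(i)
    X[, ((i - 1L) * L + 1L):(i * L), drop = FALSE])
  epoched_recording(eps, fs, mont, epoch_length_s)
}

#' Specification for a simulated cohort
#'
#' Group sizes, age and gender distributions default to the study design:
#' 6 controls, 5 presymptomatic mutation carriers and 5 patients, the
#' patients split 2 early (< 1 year of symptoms) / 3 late (> 2 years).
#' Per-group feature means and SDs default to the reported group-level
#' microstate statistics, with the early/late patient split carrying the
#' qualitative biphasic pattern on microstate D (early up, late down).
#'
#' @param groups named list; each element a list with \code{n},
#'   \code{age_mean}, \code{age_sd}, \code{female_ratio},
#'   \code{features} (named vector of means) and \code{feature_sds}
#'   (named vector of SDs), and optionally \code{mean_durations_ms} for
#'   EEG-level simulation.
#' @param seed integer RNG seed.
#' @return a list of class \code{ms_cohortspec}.
#' @export
cohort_spec <- function(groups = NULL, seed = 1) {
  if (is.null(groups)) groups <- default_cohort_groups()
  for (g in groups) {
    if (g$n < 0 || g$age_sd < 0 || any(g$feature_sds < 0))
      stop("n and SDs must be >= 0")
  }
  structure(list(groups = groups, seed = seed), class = "ms_cohortspec")
}

default_cohort_groups <- function() {
  feat_names <- c(t(outer(c("duration", "occurrence", "coverage"),
                          c("A", "B", "C", "D"), paste, sep = "_")))
  grp <- function(n, age_mean, age_sd, female_ratio, means, sds, durs) {
    list(n = n, age_mean = age_mean, age_sd = age_sd,
         female_ratio = female_ratio,
         features = stats::setNames(means, feat_names),
         feature_sds = stats::setNames(sds, feat_names),
         mean_durations_ms = durs)
  }
  # duration_A..D, occurrence_A..D, coverage_A..D (group-level moments)
  ctrl_m <- c(77.75, 77.48, 82.91, 91.92, 2.80, 2.73, 3.14, 3.36,
              21.76, 21.25, 26.13, 30.86)
  ctrl_s <- c(4.56, 4.97, 8.27, 10.86, 0.46, 0.40, 0.51, 0.16,
              3.54, 4.02, 5.85, 3.67)
  pre_m <- c(86.11, 94.83, 81.95, 100.48, 2.52, 2.86, 2.53, 3.05,
             21.55, 27.01, 21.24, 30.21)
  pre_s <- c(11.05, 16.83, 16.44, 27.15, 0.50, 0.23, 0.72, 0.40,
             4.01, 5.03, 9.35, 6.51)
  pat_m <- c(89.85, 79.67, 84.90, 98.90, 2.79, 2.72, 2.79, 2.88,
             25.75, 21.40, 23.85, 28.99)
  pat_s <- c(19.44, 8.65, 9.61, 38.15, 0.91, 0.52, 0.60, 0.73,
             12.15, 3.44, 6.40, 13.54)
  # biphasic qualitative pattern on microstate D for the duration split
  d_idx <- c(4, 8, 12)
  early_m <- pat_m; early_m[d_idx] <- pat_m[d_idx] * 1.15
  late_m <- pat_m; late_m[d_idx] <- pat_m[d_idx] * 0.90
  list(
    control = grp(6, 55.17, 10.34, 3 / 6, ctrl_m, ctrl_s,
                  c(78, 77, 83, 92)),
    presymptomatic = grp(5, 42.40, 16.86, 3 / 5, pre_m, pre_s,
                         c(86, 95, 82, 100)),
    patient_early = grp(2, 63.80, 9.01, 2 / 5, early_m, pat_s,
                        c(90, 80, 85, 114)),
    patient_late = grp(3, 63.80, 9.01, 2 / 5, late_m, pat_s,
                       c(90, 80, 85, 89))
  )
}

#' Simulate a cohort feature table (and optionally EEG recordings)
#'
#' Per subject: group membership, age ~ Normal, gender ~ Bernoulli, and
#' features drawn from the group's normal distributions (truncated at a
#' small positive floor). With \code{eeg = TRUE}, a per-subject epoched
#' recording is also simulated through \code{simulate_microstate_eeg}
#' using the group's mean dwell times.
#'
#' @param spec an \code{ms_cohortspec}.
#' @param eeg also simulate per-subject EEG (slower).
#' @param sim_args named list of \code{sim_spec} overrides for the EEG
#'   route (e.g. \code{n_epochs}).
#' @return an \code{ms_feature_table}; with \code{eeg = TRUE}, attribute
#'   \code{recordings} holds the per-subject \code{ms_epochs} list.
#' @export
simulate_cohort <- function(spec, eeg = FALSE, sim_args = list()) {
  if (!sum(vapply(spec$groups, function(g) g$n, 0))) stop("empty cohort")
  set.seed(spec$seed)
  rows <- list()
  recs <- list()
  sid <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    if (!g$n) next
    canonical <- if (grepl("^patient", gname)) "patient" else gname
    dur_years <- switch(gname, patient_early = 0.5, patient_late = 3.5,
                        NA_real_)
    for (i in seq_len(g$n)) {
      sid <- sid + 1L
      feats <- pmax(0.01, stats::rnorm(length(g$features),
                                       g$features, g$feature_sds))
      row <- data.frame(
        subject_id = sprintf("S%02d", sid),
        group = canonical,
        age = round(stats::rnorm(1, g$age_mean, g$age_sd), 1),
        gender = if (stats::runif(1) < g$female_ratio) "female" else "male",
        disease_duration_years = dur_years,
        stringsAsFactors = FALSE)
      row[names(g$features)] <- as.list(feats)
      rows[[sid]] <- row
      if (eeg) {
        args <- utils::modifyList(
          list(mean_durations_ms = g$mean_durations_ms,
               seed = spec$seed + 1000L + sid),
          sim_args)
        recs[[sid]] <- simulate_microstate_eeg(do.call(sim_spec, args))$epochs
      }
    }
  }
  tab <- feature_table(do.call(rbind, rows))
  if (eeg) attr(tab, "recordings") <- recs
  tab
}
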