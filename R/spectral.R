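#' Canonical EEG frequency bands
#'
#' Half-open bands at 1 Hz resolution: delta [1, 4), theta [4, 8),
#' alpha [8, 13), beta [13, 30) — so "x.99" printed upper edges mean "the
#' next band's lower bin excluded".
#'
#' @return data.frame with columns name, lo, hi.
#' @export
canonical_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             lo = c(1, 4, 8, 13), hi = c(4, 8, 13, 30),
             stringsAsFactors = FALSE)
}

#' Welch power spectral density of an epoched recording
#'
#' Per channel: Hamming-windowed periodograms of \code{window_len}-sample
#' segments (default one sampling rate's worth, i.e. 1 Hz resolution) with
#' 50\% overlap within each epoch, averaged over all windows of all epochs.
#' One-sided density in uV^2/Hz.
#'
#' @param e an \code{ms_epochs}.
#' @param window_len window length in samples; default \code{e$fs}.
#' @return an \code{ms_spectrum}: list with \code{freqs} (Hz) and
#'   \code{psd} (channels x freqs).
#' @export
power_spectrum <- function(e, window_len = NULL) {
  fs <- e$fs
  if (is.null(window_len)) window_len <- round(fs)
  L <- ncol(e$epochs[[1]])
  if (L < window_len) stop("epoch shorter than one window")
  step <- window_len %/% 2
  starts <- seq(1L, L - window_len + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(window_len) - 1) / (window_len - 1))
  scale <- fs * sum(w^2)
  nf <- window_len %/% 2 + 1L
  C <- nrow(e$epochs[[1]])
  acc <- matrix(0, C, nf)
  n_win <- 0L
  for (ep in e$epochs) {
    for (s in starts) {
      seg <- ep[, s:(s + window_len - 1L), drop = FALSE] *
        rep(w, each = C)
      X <- stats::mvfft(t(seg))
      P <- (Mod(X[seq_len(nf), , drop = FALSE])^2) / scale
      P[2:(nf - 1L), ] <- 2 * P[2:(nf - 1L), ]   # one-sided
      acc <- acc + t(P)
      n_win <- n_win + 1L
    }
  }
  psd <- acc / n_win
  dimnames(psd) <- list(e$montage$channel_names, NULL)
  structure(list(freqs = (seq_len(nf) - 1) * fs / window_len, psd = psd),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat("<ms_spectrum> ", nrow(x$psd), " channels, ", length(x$freqs),
      " bins (", min(x$freqs), "-", max(x$freqs), " Hz, df=",
      x$freqs[2] - x$freqs[1], " Hz)\n", sep = "")
  invisible(x)
}

#' Relative band power per channel
#'
#' Band power is the sum of PSD bins with lo <= f < hi; the total-power
#' denominator is the union of the supplied bands (for the canonical four,
#' 1-30 Hz), so the relative powers of each channel partition 1.
#'
#' @param s an \code{ms_spectrum}.
#' @param bands data.frame as from \code{canonical_bands()}.
#' @return channels x bands matrix of relative powers (rows sum to 1).
#' @export
relative_band_power <- function(s, bands = canonical_bands()) {
  if (any(bands$lo < min(s$freqs) - 1e-9) || any(bands$hi > max(s$freqs) + 1e-9))
    stop("band outside computed frequency range")
  bp <- vapply(seq_len(nrow(bands)), function(b) {
    sel <- s$freqs >= bands$lo[b] - 1e-9 & s$freqs < bands$hi[b] - 1e-9
    rowSums(s$psd[, sel, drop = FALSE])
  }, numeric(nrow(s$psd)))
  bp <- matrix(bp, nrow = nrow(s$psd),
               dimnames = list(rownames(s$psd), bands$name))
  bp / rowSums(bp)
}

#' Global relative power
#'
#' Unweighted mean of per-channel relative band powers.
#'
#' @param rel channels x bands matrix from \code{relative_band_power}.
#' @return named numeric vector, one value per band.
#' @export
global_relative_power <- function(rel) {
  if (!nrow(rel)) stop("empty input")
  colMeans(rel)
}
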