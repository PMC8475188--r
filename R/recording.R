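#' Construct a continuous EEG recording
#'
#' @param data channels x samples numeric matrix, microvolts.
#' @param fs sampling rate in Hz.
#' @param montage an \code{ms_montage} whose channel count matches
#'   \code{nrow(data)}.
#' @param annotations data.frame with columns \code{onset_s},
#'   \code{duration_s}, \code{label} (condition markers), or NULL.
#' @return an object of class \code{ms_recording}.
#' @export
recording <- function(data, fs, montage, annotations = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!inherits(montage, "ms_montage")) stop("montage must be an ms_montage")
  if (nrow(data) != n_channels(montage))
    stop("data has ", nrow(data), " rows but montage has ",
         n_channels(montage), " channels")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (is.null(annotations))
    annotations <- data.frame(onset_s = numeric(), duration_s = numeric(),
                              label = character(), stringsAsFactors = FALSE)
  annotations <- as.data.frame(annotations)
  stopifnot(all(c("onset_s", "duration_s", "label") %in% names(annotations)))
  t_end <- ncol(data) / fs
  if (nrow(annotations)) {
    if (any(annotations$onset_s < 0) ||
        any(annotations$onset_s + annotations$duration_s > t_end + 1e-9))
      stop("annotation interval outside [0, ", t_end, "] s")
  }
  rownames(data) <- montage$channel_names
  structure(list(data = data, fs = fs, montage = montage,
                 annotations = annotations),
            class = "ms_recording")
}

#' @export
print.ms_recording <- function(x, ...) {
  cat("<ms_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 2), " s), ",
      nrow(x$annotations), " annotations\n", sep = "")
  invisible(x)
}

#' Construct an epoched recording
#'
#' @param epochs list of channels x L matrices with identical L.
#' @param fs sampling rate in Hz.
#' @param montage an \code{ms_montage}.
#' @param epoch_length_s epoch length in seconds; L must equal
#'   \code{round(epoch_length_s * fs)}.
#' @return an object of class \code{ms_epochs}.
#' @export
epoched_recording <- function(epochs, fs, montage, epoch_length_s) {
  if (!length(epochs)) stop("no epochs")
  L <- round(epoch_length_s * fs)
  epochs <- lapply(epochs, function(e) {
    e <- as.matrix(e); storage.mode(e) <- "double"
    if (nrow(e) != n_channels(montage)) stop("epoch channel count mismatch")
    if (ncol(e) != L) stop("epoch length ", ncol(e), " != ", L)
    rownames(e) <- montage$channel_names
    e
  })
  structure(list(epochs = epochs, fs = fs, montage = montage,
                 epoch_length_s = epoch_length_s),
            class = "ms_epochs")
}

#' @export
print.ms_epochs <- function(x, ...) {
  cat("<ms_epochs> ", length(x$epochs), " epochs of ", x$epoch_length_s,
      " s (", nrow(x$epochs[[1]]), " channels @ ", x$fs, " Hz)\n", sep = "")
  invisible(x)
}

#' Extract all samples belonging to one annotated condition
#'
#' Concatenates, in temporal order, the samples of every annotation interval
#' carrying \code{label} (half-open \code{[onset, onset+duration)} in
#' seconds). The retained intervals are re-based onto the new time axis so a
#' later \code{epoch()} can avoid spanning interval boundaries.
#'
#' @param rec an \code{ms_recording}.
#' @param label condition label, e.g. \code{"eyes_closed"}.
#' @return an \code{ms_recording} containing only the matching samples.
#' @export
select_condition <- function(rec, label) {
  ann <- rec$annotations
  hit <- ann$label == label
  if (!any(hit))
    stop("condition label '", label, "' not found; available: ",
         paste(unique(ann$label), collapse = ", "))
  iv <- ann[hit, , drop = FALSE]
  iv <- iv[order(iv$onset_s), , drop = FALSE]
  pieces <- vector("list", nrow(iv))
  new_ann <- iv
  t0 <- 0
  for (i in seq_len(nrow(iv))) {
    from <- floor(iv$onset_s[i] * rec$fs) + 1L
    to <- floor((iv$onset_s[i] + iv$duration_s[i]) * rec$fs)
    to <- min(to, ncol(rec$data))
    pieces[[i]] <- rec$data[, from:to, drop = FALSE]
    new_ann$onset_s[i] <- t0
    new_ann$duration_s[i] <- (to - from + 1L) / rec$fs
    t0 <- t0 + new_ann$duration_s[i]
  }
  recording(do.call(cbind, pieces), rec$fs, rec$montage, new_ann)
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' Consecutive epochs of \code{epoch_length_s} seconds; a trailing partial
#' epoch is discarded. If the recording carries condition annotations
#' (e.g. after \code{select_condition}), each annotated interval is epoched
#' separately and the epochs pooled, so no epoch spans a splice point
#' between intervals.
#'
#' @param rec an \code{ms_recording}.
#' @param epoch_length_s epoch length in seconds; must be a whole number of
#'   samples at \code{rec$fs}.
#' @return an \code{ms_epochs}.
#' @export
epoch <- function(rec, epoch_length_s = 3) {
  L_exact <- epoch_length_s * rec$fs
  L <- round(L_exact)
  if (abs(L_exact - L) > 1e-9)
    stop("epoch_length_s * fs must be a whole number of samples")
  cut_piece <- function(mat) {
    k <- floor(ncol(mat) / L)
    lapply(seq_len(k), function(i) mat[, ((i - 1L) * L + 1L):(i * L), drop = FALSE])
  }
  if (nrow(rec$annotations)) {
    eps <- list()
    iv <- rec$annotations[order(rec$annotations$onset_s), , drop = FALSE]
    for (i in seq_len(nrow(iv))) {
      from <- floor(iv$onset_s[i] * rec$fs) + 1L
      to <- min(floor((iv$onset_s[i] + iv$duration_s[i]) * rec$fs), ncol(rec$data))
      eps <- c(eps, cut_piece(rec$data[, from:to, drop = FALSE]))
    }
  } else {
    eps <- cut_piece(rec$data)
  }
  if (!length(eps)) stop("recording shorter than one epoch")
  epoched_recording(eps, rec$fs, rec$montage, epoch_length_s)
}

# all epochs bound into one channels x (n*L) matrix
flatten_epochs <- function(e) do.call(cbind, e$epochs)
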