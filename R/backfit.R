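#' Back-fit microstate maps to an epoched recording
#'
#' Labels every sample with the map maximizing the squared spatial
#' correlation between its (zero-mean) topography and the map, polarity
#' ignored. Samples with zero GFP get fit 0 and the first label.
#'
#' @param e an \code{ms_epochs}, average-referenced (and typically 40 Hz
#'   low-passed before microstate analysis).
#' @param M an \code{ms_maps}.
#' @return an \code{ms_segmentation}: per-sample \code{labels} (integer,
#'   indexing \code{M$labels_order}), \code{fit} (winning squared spatial
#'   correlation), the full \code{corr2} matrix (samples x K, kept for
#'   segment smoothing), \code{epoch_index}, \code{sample_index}, \code{fs}.
#' @export
backfit <- function(e, M) {
  if (ncol(M$maps) != n_channels(e$montage)) stop("channel mismatch")
  flat <- flatten_epochs(e)
  U <- t(flat)                       # samples x channels
  U <- U - rowMeans(U)
  nrm2 <- rowSums(U^2)
  proj <- (U %*% t(M$maps))^2        # maps are unit-norm zero-mean
  corr2 <- proj / ifelse(nrm2 > 0, nrm2, 1)
  corr2[nrm2 == 0, ] <- 0
  labels <- max.col(corr2, ties.method = "first")
  L <- ncol(e$epochs[[1]])
  n_ep <- length(e$epochs)
  structure(list(labels = labels,
                 fit = corr2[cbind(seq_len(nrow(U)), labels)],
                 corr2 = corr2,
                 epoch_index = rep(seq_len(n_ep), each = L),
                 sample_index = rep(seq_len(L), n_ep),
                 fs = e$fs, K = M$K, labels_order = M$labels_order),
            class = "ms_segmentation")
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat("<ms_segmentation> ", length(x$labels), " samples, K=", x$K,
      ", mean fit ", round(mean(x$fit), 3), "\n", sep = "")
  invisible(x)
}

#' Reject microstate segments shorter than a minimum duration
#'
#' Noise smoothing by reassignment: interior same-label runs shorter than
#' \code{min_dur_ms} (in samples, ceiling) are absorbed by their two
#' neighbouring runs, shortest run first. The absorbed run is split at the
#' cut maximizing the summed squared correlation of its samples with the
#' two neighbour maps, so samples join the neighbour whose map fits them
#' better, no new label value ever appears, and the number of runs strictly
#' decreases. Runs truncated by epoch boundaries (first/last run of an
#' epoch) are exempt, and runs never span epoch boundaries. Repeats until
#' no interior run is below threshold.
#'
#' @param s an \code{ms_segmentation} carrying its \code{corr2} matrix.
#' @param min_dur_ms minimum segment duration in milliseconds.
#' @return an \code{ms_segmentation}.
#' @export
reject_short_segments <- function(s, min_dur_ms = 30) {
  if (min_dur_ms < 0) stop("min_dur_ms must be >= 0")
  thr <- ceiling(min_dur_ms * s$fs / 1000)
  labels <- s$labels
  for (ep in unique(s$epoch_index)) {
    idx <- which(s$epoch_index == ep)
    lab <- labels[idx]
    c2 <- s$corr2[idx, , drop = FALSE]
    repeat {
      r <- rle(lab)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      interior <- seq_along(r$lengths)
      interior <- interior[interior != 1L & interior != length(r$lengths)]
      short <- interior[r$lengths[interior] < thr]
      if (!length(short)) break
      j <- short[order(r$lengths[short], starts[short])][1]
      left_lab <- r$values[j - 1L]
      right_lab <- r$values[j + 1L]
      span <- starts[j]:ends[j]
      lcum <- cumsum(c2[span, left_lab])
      rcum <- rev(cumsum(rev(c2[span, right_lab])))
      len <- length(span)
      # cut after position m (0..len): samples 1..m -> left, rest -> right
      score <- c(rcum[1], lcum + c(rcum[-1], 0))
      m <- which.max(score) - 1L
      lab[span] <- c(rep(left_lab, m), rep(right_lab, len - m))
    }
    labels[idx] <- lab
  }
  out <- s
  out$labels <- labels
  out$fit <- s$corr2[cbind(seq_along(labels), labels)]
  out
}

#' Microstate temporal statistics
#'
#' Per map k over all epochs: duration d_k = mean length (ms) of maximal
#' same-label runs (runs truncated at epoch boundaries included);
#' occurrence o_k = runs per second of labeled time; coverage c_k = percent
#' of samples labeled k; gev_k = percent of GFP-squared-weighted variance
#' explained, gev_k = 100 sum_{t: L(t)=k} GFP(t)^2 fit(t) / sum_t GFP(t)^2.
#' Total GEV is the sum over maps. A map that never occurs gets d_k = NA,
#' o_k = c_k = gev_k = 0.
#'
#' @param s an \code{ms_segmentation}.
#' @param g the aligned \code{ms_gfp}.
#' @return an \code{ms_features}: data.frame (one row per map: label,
#'   duration_ms, occurrence_hz, coverage_pct, gev_pct) with attribute
#'   \code{total_gev_pct}.
#' @export
compute_features <- function(s, g) {
  if (length(g$values) != length(s$labels)) stop("s and g not aligned")
  K <- s$K
  run_lengths <- vector("list", K)
  for (ep in unique(s$epoch_index)) {
    r <- rle(s$labels[s$epoch_index == ep])
    for (k in seq_len(K))
      run_lengths[[k]] <- c(run_lengths[[k]], r$lengths[r$values == k])
  }
  total_s <- length(s$labels) / s$fs
  denom <- sum(g$values^2)
  out <- data.frame(
    label = s$labels_order,
    duration_ms = vapply(run_lengths, function(x)
      if (length(x)) mean(x) / s$fs * 1000 else NA_real_, 0),
    occurrence_hz = vapply(run_lengths, length, 0L) / total_s,
    coverage_pct = 100 * tabulate(s$labels, K) / length(s$labels),
    gev_pct = vapply(seq_len(K), function(k) {
      sel <- s$labels == k
      100 * sum(g$values[sel]^2 * s$fit[sel]) / denom
    }, 0),
    stringsAsFactors = FALSE)
  class(out) <- c("ms_features", "data.frame")
  attr(out, "total_gev_pct") <- sum(out$gev_pct)
  out
}

#' Order estimated maps against archetype templates
#'
#' Finds the one-to-one assignment of estimated maps to the template
#' archetypes (A-D) maximizing the total absolute spatial correlation
#' (exhaustive over the K! permutations; K is 4 here), relabels the maps
#' accordingly, and flips signs so each map correlates positively with its
#' template.
#'
#' @param M an \code{ms_maps} to reorder.
#' @param templates an \code{ms_maps} of archetypes with the same K and
#'   channel count.
#' @return an \code{ms_maps} ordered and signed as the templates, with a
#'   \code{template_corr} attribute (per-map absolute correlation).
#' @export
order_maps <- function(M, templates) {
  if (M$K != templates$K) stop("K mismatch")
  if (ncol(M$maps) != ncol(templates$maps)) stop("channel mismatch")
  C <- templates$maps %*% t(M$maps)     # templates x estimates, corr
  perms <- permutations(M$K)
  scores <- apply(perms, 1, function(p) sum(abs(C[cbind(seq_len(M$K), p)])))
  p <- perms[which.max(scores), ]
  maps <- M$maps[p, , drop = FALSE]
  signs <- sign(C[cbind(seq_len(M$K), p)])
  signs[signs == 0] <- 1
  maps <- maps * signs
  out <- microstate_maps(maps, templates$labels_order)
  attr(out, "template_corr") <- abs(C[cbind(seq_len(M$K), p)])
  out
}

permutations <- function(k) {
  if (k == 1) return(matrix(1L))
  sub <- permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}
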