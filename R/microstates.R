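#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the average-referenced
#' topography: sqrt(mean(v_c(t)^2)) over channels for zero-mean v
#' (population normalization, 1/C). Computed per epoch. Input that is not
#' average-referenced (channel mean above 1e-6 anywhere) triggers a warning
#' and an internal re-reference.
#'
#' @param e an \code{ms_epochs}.
#' @return an \code{ms_gfp}: list with \code{values} (one per sample),
#'   \code{epoch_index}, \code{sample_index}, \code{fs}.
#' @export
gfp <- function(e) {
  mats <- e$epochs
  worst <- max(vapply(mats, function(m) max(abs(colMeans(m))), 0))
  if (worst > 1e-6) {
    warning("input not average-referenced (channel mean up to ",
            signif(worst, 3), "); re-referencing internally")
    mats <- lapply(mats, function(m) sweep(m, 2, colMeans(m)))
  }
  vals <- lapply(mats, function(m) sqrt(colMeans(m^2)))
  L <- ncol(mats[[1]])
  structure(list(values = unlist(vals, use.names = FALSE),
                 epoch_index = rep(seq_along(mats), each = L),
                 sample_index = rep(seq_len(L), length(mats)),
                 fs = e$fs),
            class = "ms_gfp")
}

#' Locate GFP peaks
#'
#' Strict local maxima within each epoch (greater than both neighbours, so
#' never at an epoch boundary). Among peaks closer than
#' \code{min_distance_ms} (converted to samples with ceiling), the larger
#' wins, eliminating greedily from the largest peak down.
#'
#' @param g an \code{ms_gfp}.
#' @param min_distance_ms minimum peak separation in milliseconds.
#' @return integer vector of global sample indices into \code{g$values}.
#' @export
find_gfp_peaks <- function(g, min_distance_ms = 10) {
  if (min_distance_ms < 0) stop("min_distance_ms must be >= 0")
  min_dist <- ceiling(min_distance_ms * g$fs / 1000)
  v <- g$values
  out <- integer()
  for (ep in unique(g$epoch_index)) {
    idx <- which(g$epoch_index == ep)
    x <- v[idx]
    n <- length(x)
    if (n < 3) next
    cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
    if (!length(cand)) next
    # greedy elimination from the largest peak
    keep <- logical(length(cand))
    alive <- rep(TRUE, length(cand))
    ord <- order(x[cand], decreasing = TRUE)
    for (j in ord) {
      if (!alive[j]) next
      keep[j] <- TRUE
      alive[abs(cand - cand[j]) < min_dist & seq_along(cand) != j] <- FALSE
    }
    out <- c(out, idx[cand[keep]])
  }
  out
}

#' Select peak topographies for clustering
#'
#' Takes the chronologically first \code{n_max} GFP-peak topographies, then
#' excludes those whose GFP exceeds mean + \code{sd_mult} x SD of the GFPs
#' of the selected set (one-sided high-outlier rejection).
#'
#' @param e an \code{ms_epochs} (average-referenced).
#' @param peaks global sample indices from \code{find_gfp_peaks}.
#' @param n_max cap on the number of maps considered (chronological).
#' @param sd_mult outlier threshold multiplier.
#' @return samples x channels matrix of retained topographies.
#' @export
select_peak_maps <- function(e, peaks, n_max = 2500, sd_mult = 2) {
  if (!length(peaks)) stop("no peaks")
  peaks <- sort(peaks)[seq_len(min(n_max, length(peaks)))]
  flat <- flatten_epochs(e)
  U <- t(flat[, peaks, drop = FALSE])
  U <- U - rowMeans(U)
  gfps <- sqrt(rowMeans(U^2))
  thr <- mean(gfps) + sd_mult * stats::sd(gfps)
  U[gfps <= thr, , drop = FALSE]
}

#' Construct a set of microstate maps
#'
#' @param maps K x channels matrix; each row is forced zero-mean and unit
#'   L2 norm.
#' @param labels_order archetype names, default LETTERS[1:K].
#' @return an object of class \code{ms_maps}.
#' @export
microstate_maps <- function(maps, labels_order = NULL) {
  maps <- as.matrix(maps)
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stop("degenerate (constant) map")
  maps <- maps / nrm
  if (is.null(labels_order)) labels_order <- LETTERS[seq_len(nrow(maps))]
  rownames(maps) <- labels_order
  structure(list(K = nrow(maps), maps = maps, labels_order = labels_order),
            class = "ms_maps")
}

#' @export
print.ms_maps <- function(x, ...) {
  cat("<ms_maps> K=", x$K, " (", paste(x$labels_order, collapse = ", "),
      "), ", ncol(x$maps), " channels\n", sep = "")
  invisible(x)
}

#' Polarity-invariant modified K-means clustering of topographies
#'
#' The microstate flavour of K-means: a sample u is assigned to the
#' prototype maximizing the squared spatial projection (u . M_k)^2 (sign
#' ignored), and each prototype is updated as the dominant eigenvector of
#' the cluster's outer-product sum - the direction maximizing explained
#' topographic variance under polarity invariance. Restart r uses seed
#' seed + r; the restart with the highest training GEV wins. Empty clusters
#' are reseeded from the worst-fitted sample.
#'
#' @param U samples x channels matrix of (zero-mean) topographies.
#' @param K number of clusters.
#' @param restarts number of random restarts.
#' @param seed integer RNG seed.
#' @param tol relative GEV change convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @return list with \code{maps} (an \code{ms_maps}), \code{gev} (training
#'   global explained variance, percent), \code{labels} (training
#'   assignment).
#' @export
modified_kmeans <- function(U, K = 4, restarts = 300, seed = 1,
                            tol = 1e-6, max_iter = 100) {
  U <- as.matrix(U)
  n <- nrow(U)
  if (K > n) stop("K (", K, ") exceeds number of samples (", n, ")")
  U <- U - rowMeans(U)
  denom <- sum(U^2)
  best <- list(gev = -Inf)
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    res <- kmeans_once(U, K, denom, tol, max_iter)
    if (res$gev > best$gev) best <- res
  }
  list(maps = microstate_maps(best$M), gev = 100 * best$gev,
       labels = best$labels)
}

kmeans_once <- function(U, K, denom, tol, max_iter) {
  n <- nrow(U)
  M <- U[sample.int(n, K), , drop = FALSE]
  M <- M / sqrt(rowSums(M^2))
  gev_old <- -Inf
  labels <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    P <- (U %*% t(M))^2               # n x K squared projections
    labels <- max.col(P, ties.method = "first")
    # reseed empty clusters from the worst-fit sample
    for (k in which(tabulate(labels, K) == 0L)) {
      fitn <- P[cbind(seq_len(n), labels)] / rowSums(U^2)
      worst <- which.min(fitn)
      labels[worst] <- k
    }
    for (k in seq_len(K)) {
      Uk <- U[labels == k, , drop = FALSE]
      S <- crossprod(Uk)
      M[k, ] <- eigen(S, symmetric = TRUE)$vectors[, 1]
    }
    gev <- sum((U %*% t(M))[cbind(seq_len(n), labels)]^2) / denom
    if (is.finite(gev_old) && abs(gev - gev_old) <= tol * max(gev_old, .Machine$double.eps))
      break
    gev_old <- gev
  }
  P <- (U %*% t(M))^2
  labels <- max.col(P, ties.method = "first")
  gev <- sum(P[cbind(seq_len(n), labels)]) / denom
  list(M = M, gev = gev, labels = labels)
}

#' Group-level microstate maps
#'
#' Pools every subject's retained peak topographies into one matrix and
#' runs \code{modified_kmeans} once on the pooled data - group maps only,
#' no individual-subject maps.
#'
#' @param per_subject_maps list of samples x channels matrices.
#' @param K,restarts,seed,tol,max_iter passed to \code{modified_kmeans}.
#' @return as \code{modified_kmeans}, plus \code{n_pooled}.
#' @export
group_maps <- function(per_subject_maps, K = 4, restarts = 300, seed = 1,
                       tol = 1e-6, max_iter = 100) {
  if (!length(per_subject_maps)) stop("no subjects")
  ncols <- vapply(per_subject_maps, ncol, 0L)
  if (length(unique(ncols)) != 1L)
    stop("channel-count mismatch across subjects")
  pooled <- do.call(rbind, per_subject_maps)
  res <- modified_kmeans(pooled, K = K, restarts = restarts, seed = seed,
                         tol = tol, max_iter = max_iter)
  res$n_pooled <- nrow(pooled)
  res
}
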