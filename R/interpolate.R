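#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels with Perrin spherical-spline estimates from
#' the remaining good channels: splines of order m = 4 on the unit sphere,
#' Legendre series truncated at 7 terms, with a small ridge (1e-5) on the
#' spline matrix diagonal for conditioning. Good channels are returned
#' untouched. More than three bad channels triggers a warning (the montage
#' has only 18 electrodes, so heavier interpolation degrades topographies).
#'
#' @param e an \code{ms_epochs}.
#' @param bad character vector of channel names to reconstruct.
#' @param m spline order (stiffness), default 4.
#' @param n_terms Legendre series truncation, default 7.
#' @param reg ridge added to the spline matrix diagonal, default 1e-5.
#' @return an \code{ms_epochs} with bad channels replaced.
#' @export
interpolate_channels <- function(e, bad, m = 4, n_terms = 7, reg = 1e-5) {
  ch <- e$montage$channel_names
  unknown <- setdiff(bad, ch)
  if (length(unknown))
    stop("bad label not in montage: ", paste(unknown, collapse = ", "))
  if (!length(bad)) return(e)
  good <- setdiff(ch, bad)
  if (!length(good)) stop("all channels marked bad")
  if (length(bad) > 3)
    warning(length(bad), " channels interpolated; more than 3 is unreliable ",
            "on an 18-channel montage")
  pos <- e$montage$positions
  gi <- match(good, ch); bi <- match(bad, ch)
  W <- spline_weights(pos[gi, , drop = FALSE], pos[bi, , drop = FALSE],
                      m, n_terms, reg)
  out <- e
  out$epochs <- lapply(e$epochs, function(ep) {
    ep[bi, ] <- W %*% ep[gi, , drop = FALSE]
    ep
  })
  out
}

# Perrin g(x): (1/4pi) sum_n (2n+1) / (n(n+1))^m P_n(x)
spline_g <- function(x, m, n_terms) {
  P_prev <- rep(1, length(x))   # P_0
  P_cur <- x                    # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * P_cur
  for (n in 2:n_terms) {
    P_new <- ((2 * n - 1) * x * P_cur - (n - 1) * P_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * P_new
    P_prev <- P_cur; P_cur <- P_new
  }
  acc / (4 * pi)
}

# linear operator mapping good-channel values to bad-channel estimates
spline_weights <- function(good_pos, bad_pos, m, n_terms, reg) {
  ng <- nrow(good_pos)
  G <- spline_g(tcrossprod(good_pos), m, n_terms)
  dim(G) <- c(ng, ng)
  A <- rbind(cbind(G + diag(reg, ng), rep(1, ng)), c(rep(1, ng), 0))
  # columns of solve(A) give [c; c0] as linear functions of [v; 0]
  Ainv <- solve(A)
  Gb <- spline_g(tcrossprod(bad_pos, good_pos), m, n_terms)
  dim(Gb) <- c(nrow(bad_pos), ng)
  cbind(Gb, rep(1, nrow(bad_pos))) %*% Ainv[, seq_len(ng), drop = FALSE]
}
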