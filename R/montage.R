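#' Built-in 10-20 electrode positions
#'
#' Unit-sphere Cartesian coordinates (head-centered, right-handed: x toward
#' the right ear, y toward the nasion, z up) for the 18 electrodes of the
#' study montage, using the legacy 10-20 names T3/T4/T5/T6.
#'
#' Positions follow the 10-20 construction: the circumferential ring
#' (Fp1/2, F7/8, T3/4, T5/6, O1/2) sits at 72 degrees inclination from the
#' vertex; midline and central electrodes (Fz, Pz, C3, C4) at 36 degrees;
#' F3/F4 and P3/P4 are great-circle midpoints of their ring/midline
#' neighbours (F7-Fz, F8-Fz, T5-Pz, T6-Pz), which is how the system defines
#' them on the scalp.
#'
#' @return named list mapping channel label to a length-3 unit vector.
#' @export
ten_twenty_positions <- function() {
  sph <- function(incl_deg, az_deg) {
    # inclination from +z; azimuth from nasion (+y), positive toward right ear
    th <- incl_deg * pi / 180
    az <- az_deg * pi / 180
    c(x = sin(th) * sin(az), y = sin(th) * cos(az), z = cos(th))
  }
  mid <- function(a, b) {
    m <- (a + b) / 2
    m / sqrt(sum(m^2))
  }
  pos <- list(
    Fp1 = sph(72, -18), Fp2 = sph(72, 18),
    F7  = sph(72, -54), F8  = sph(72, 54),
    T3  = sph(72, -90), T4  = sph(72, 90),
    T5  = sph(72, -126), T6 = sph(72, 126),
    O1  = sph(72, -162), O2 = sph(72, 162),
    Fz  = sph(36, 0), Pz = sph(36, 180),
    C3  = sph(36, -90), C4 = sph(36, 90)
  )
  pos$F3 <- mid(pos$F7, pos$Fz)
  pos$F4 <- mid(pos$F8, pos$Fz)
  pos$P3 <- mid(pos$T5, pos$Pz)
  pos$P4 <- mid(pos$T6, pos$Pz)
  order <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "C3", "C4",
             "T3", "T5", "T4", "T6", "P3", "Pz", "P4", "O1", "O2")
  pos[order]
}

#' Construct an EEG montage
#'
#' @param channel_names character vector of unique 10-20 labels.
#' @param positions channels x 3 numeric matrix of unit-sphere coordinates,
#'   or NULL to look the labels up in the built-in 10-20 table.
#' @return an object of class \code{ms_montage}.
#' @export
montage <- function(channel_names, positions = NULL) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stop("duplicate channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (is.null(positions)) {
    tab <- ten_twenty_positions()
    unknown <- setdiff(channel_names, names(tab))
    if (length(unknown))
      stop("unknown channel: ", paste(unknown, collapse = ", "))
    positions <- do.call(rbind, tab[channel_names])
  }
  positions <- as.matrix(positions)
  if (nrow(positions) != length(channel_names))
    stop("length(channel_names) must equal nrow(positions)")
  nrm <- sqrt(rowSums(positions^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("positions must lie on the unit sphere")
  dimnames(positions) <- list(channel_names, c("x", "y", "z"))
  structure(list(channel_names = channel_names, positions = positions),
            class = "ms_montage")
}

#' The 18-channel study montage
#' @return an \code{ms_montage} with the 18 legacy 10-20 labels.
#' @export
study_montage <- function() {
  montage(names(ten_twenty_positions()))
}

#' @export
print.ms_montage <- function(x, ...) {
  cat("<ms_montage> ", length(x$channel_names), " channels: ",
      paste(x$channel_names, collapse = " "), "\n", sep = "")
  invisible(x)
}

n_channels <- function(m) length(m$channel_names)
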