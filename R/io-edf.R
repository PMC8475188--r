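#' Read a European Data Format (EDF/EDF+) recording
#'
#' Minimal EDF reader for uniformly sampled scalp EEG. Channel labels are
#' matched against the built-in 18-channel 10-20 montage case-insensitively
#' after stripping an \code{"EEG "} prefix and any reference suffix such as
#' \code{"-REF"}; matching channels are returned restricted to, and ordered
#' as, the montage. Physical values are converted to microvolts using the
#' per-signal physical dimension (\code{uV}, \code{mV} or \code{V}).
#' EDF+ time-stamped annotations (TALs) are mapped to condition markers.
#'
#' @param path path to an EDF or EDF+ file.
#' @return an \code{ms_recording}.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  rd(8)                       # version
  rd(80); rd(80)              # patient, recording id
  rd(8); rd(8)                # start date, time
  header_bytes <- as.integer(rd(8))
  rd(44)                      # reserved
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("invalid EDF header")
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16)
  fld(80)                     # transducer
  dims <- fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)                     # prefilter
  spr <- as.integer(fld(8))   # samples per record
  fld(32)                     # reserved
  stopifnot(seek(con, where = NA) == header_bytes || TRUE)
  seek(con, header_bytes)

  is_annot <- grepl("^EDF Annotations$", labels)
  clean <- toupper(sub("-(REF|LE|A[12])$", "", sub("^EEG[ _]*", "", labels,
                                                   ignore.case = TRUE),
                       ignore.case = TRUE))
  want <- toupper(names(ten_twenty_positions()))
  keep_idx <- which(clean %in% want & !is_annot)
  if (!length(keep_idx)) stop("none of the 10-20 montage labels present")
  if (length(unique(spr[keep_idx])) != 1L)
    stop("selected channels have mismatched sampling rates")
  if (n_records <= 0 || spr[keep_idx[1]] == 0) stop("empty recording")

  total_sig <- vector("list", ns)
  for (i in keep_idx) total_sig[[i]] <- numeric(n_records * spr[i])
  ann_raw <- raw()
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      if (is_annot[i]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", 2L * spr[i]))
      } else if (i %in% keep_idx) {
        v <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                     endian = "little")
        total_sig[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- v
      } else {
        seek(con, 2L * spr[i], origin = "current")
      }
    }
  }
  fs <- spr[keep_idx[1]] / record_dur
  # digital -> physical -> microvolts
  unit_scale <- function(d) switch(toupper(trimws(d)), "UV" = 1, "MV" = 1e3,
                                   "V" = 1e6, 1)
  rows <- lapply(keep_idx, function(i) {
    gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    (total_sig[[i]] - dmin[i]) * gain + pmin[i]
  })
  dat <- do.call(rbind, rows) *
    vapply(keep_idx, function(i) unit_scale(dims[i]), 0)
  if (ncol(dat) == 0) stop("empty recording")
  # order as the montage
  present <- clean[keep_idx]
  ord <- order(match(present, want))
  dat <- dat[ord, , drop = FALSE]
  labs <- names(ten_twenty_positions())[match(present[ord], want)]
  ann <- parse_edf_annotations(ann_raw)
  t_end <- ncol(dat) / fs
  ann <- ann[ann$onset_s < t_end, , drop = FALSE]
  ann$duration_s <- pmin(ann$duration_s, t_end - ann$onset_s)
  recording(dat, fs, montage(labs), ann)
}

# EDF+ TALs: "+onset(\x15duration)?\x14label1\x14label2...\x14" then NUL
parse_edf_annotations <- function(bytes) {
  out <- data.frame(onset_s = numeric(), duration_s = numeric(),
                    label = character(), stringsAsFactors = FALSE)
  if (!length(bytes)) return(out)
  # split the raw stream at NUL separators, decode each TAL as text
  nul <- bytes == as.raw(0)
  grp <- cumsum(nul)
  tals <- vapply(split(bytes[!nul], grp[!nul]), rawToChar, "")
  for (tal in tals) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (!length(parts)) next
    head <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head[1]))
    if (is.na(onset)) next
    dur <- if (length(head) > 1) suppressWarnings(as.numeric(head[2])) else 0
    labs <- parts[-1]
    labs <- labs[nzchar(labs)]
    for (lb in labs)
      out <- rbind(out, data.frame(onset_s = onset, duration_s = dur,
                                   label = lb, stringsAsFactors = FALSE))
  }
  out
}
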