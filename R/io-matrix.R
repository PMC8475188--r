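#' Read/write the delimited matrix fixture format
#'
#' Plain-text exchange format for multichannel signals: line 1 is
#' \code{# fs=<Hz>} (optional \code{annotations=} JSON field), line 2 the
#' tab-separated channel names, then one tab-separated row per time point.
#' Channel positions are looked up from the built-in 10-20 table.
#'
#' @param path file path.
#' @return \code{read_matrix}: an \code{ms_recording}.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#\\s*fs=", lines[1]))
    stop("missing '# fs=<Hz>' header")
  fs <- as.numeric(sub("^#\\s*fs=([0-9.eE+-]+).*$", "\\1", lines[1]))
  if (is.na(fs)) stop("missing '# fs=<Hz>' header")
  ann <- NULL
  if (grepl("annotations=", lines[1])) {
    js <- sub("^.*annotations=", "", lines[1])
    a <- jsonlite::fromJSON(js)
    if (length(a)) ann <- as.data.frame(a)
  }
  ch <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body)) {
    cells <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(cells) != length(ch))) stop("ragged row in matrix file")
    vals <- suppressWarnings(as.numeric(unlist(cells)))
    if (anyNA(vals)) stop("non-numeric cell in matrix file")
    dat <- matrix(vals, nrow = length(ch), ncol = length(body))
  } else {
    dat <- matrix(numeric(), nrow = length(ch), ncol = 0)
  }
  recording(dat, fs, montage(ch), ann)
}

#' @param rec an \code{ms_recording} to write.
#' @rdname read_matrix
#' @export
write_matrix <- function(rec, path) {
  hdr <- sprintf("# fs=%.10g", rec$fs)
  if (nrow(rec$annotations))
    hdr <- paste0(hdr, " annotations=",
                  jsonlite::toJSON(rec$annotations, digits = NA))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(rec$montage$channel_names, collapse = "\t"), con)
  if (ncol(rec$data))
    writeLines(apply(rec$data, 2, function(col)
      paste(formatC(col, format = "g", digits = 15), collapse = "\t")), con)
  invisible(NULL)
}
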