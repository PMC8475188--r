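# shared fixtures: built in code, no stored binaries

# small montage with arbitrary labels at valid unit-sphere positions
toy_montage <- function(C = 3) {
  th <- seq(0, pi / 3, length.out = C)
  ph <- seq(0, 2 * pi * (1 - 1 / C), length.out = C)
  pos <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  montage(paste0("ch", seq_len(C)), pos)
}

# zero-mean random topographies (rows), fixed seed outside
random_topographies <- function(n, C) {
  U <- matrix(stats::rnorm(n * C), n, C)
  U - rowMeans(U)
}

# minimal EDF+ writer (test-side oracle for read_edf); 1-s records,
# 16-bit signals scaled 0.1 uV/unit, optional annotation channel
write_edf_fixture <- function(path, data, fs, labels,
                              annotations = NULL) {
  stopifnot(nrow(data) == length(labels))
  n_records <- ceiling(ncol(data) / fs)
  pad <- n_records * fs - ncol(data)
  if (pad > 0) data <- cbind(data, matrix(0, nrow(data), pad))
  ns <- nrow(data) + as.integer(!is.null(annotations))
  ann_spr <- 64L                       # 128 bytes of TAL space per record

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) {
    s <- sprintf("%-*s", w, substr(as.character(x), 1, w))
    writeBin(charToRaw(s), con)
  }
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr(if (is.null(annotations)) "" else "EDF+C", 44)
  wr(n_records, 8); wr("1", 8); wr(ns, 4)
  all_labels <- c(paste0("EEG ", labels),
                  if (!is.null(annotations)) "EDF Annotations")
  for (l in all_labels) wr(l, 16)
  for (i in seq_len(ns)) wr("AgAgCl", 80)
  for (i in seq_len(ns)) wr(if (i <= nrow(data)) "uV" else "", 8)
  for (i in seq_len(ns)) wr("-3276.8", 8)
  for (i in seq_len(ns)) wr("3276.7", 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  sprs <- c(rep(fs, nrow(data)), if (!is.null(annotations)) ann_spr)
  for (s in sprs) wr(s, 8)
  for (i in seq_len(ns)) wr("", 32)

  tal_bytes <- function(rec_idx) {
    # record timestamp TAL, then any annotations starting in this record
    b <- c(charToRaw(sprintf("+%d", rec_idx - 1L)), as.raw(c(0x14, 0x14)),
           as.raw(0))
    if (!is.null(annotations)) {
      sel <- floor(annotations$onset_s) == (rec_idx - 1L)
      for (j in which(sel)) {
        b <- c(b, charToRaw(sprintf("+%g", annotations$onset_s[j])),
               as.raw(0x15), charToRaw(sprintf("%g",
                                               annotations$duration_s[j])),
               as.raw(0x14), charToRaw(annotations$label[j]),
               as.raw(0x14), as.raw(0))
      }
    }
    stopifnot(length(b) <= 2L * ann_spr)
    c(b, raw(2L * ann_spr - length(b)))
  }
  for (r in seq_len(n_records)) {
    sl <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nrow(data))) {
      dig <- as.integer(round(data[i, sl] * 10))   # 0.1 uV per unit
      writeBin(dig, con, size = 2L, endian = "little")
    }
    if (!is.null(annotations)) writeBin(tal_bytes(r), con)
  }
  invisible(path)
}

# exhaustive polarity-invariant clustering oracle on a 3-channel montage:
# zero-mean topographies live in a 2-D subspace, so each cluster's dominant
# eigenvalue has a closed 2x2 form and all K^n labelings can be scored
# vectorized
exhaustive_best_gev <- function(U, K) {
  stopifnot(ncol(U) == 3)
  B <- qr.Q(qr(cbind(c(1, -1, 0), c(1, 1, -2))))
  V <- U %*% B
  n <- nrow(V)
  asg <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  comp <- cbind(V[, 1]^2, V[, 1] * V[, 2], V[, 2]^2)
  tot <- 0
  for (k in seq_len(K)) {
    S <- ((asg == k) * 1) %*% comp
    tot <- tot + (S[, 1] + S[, 3] + sqrt((S[, 1] - S[, 3])^2 +
                                           4 * S[, 2]^2)) / 2
  }
  100 * max(tot) / sum(V^2)
}
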