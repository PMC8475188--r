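#' Pipeline configuration
#'
#' All defaults equal the study's stated analysis parameters: 1-70 Hz
#' band-pass and 45-55 Hz band-stop (Kaiser, ripple 0.001), 3-s epochs,
#' average reference, 40 Hz low-pass before microstate analysis, the first
#' 2500 GFP-peak maps per subject at >= 10 ms separation with mean + 2 SD
#' GFP outlier exclusion, K = 4 maps from 300 modified K-means restarts,
#' 30 ms short-segment rejection, and log-transformed ANCOVA with age and
#' gender covariates. Serializes losslessly to/from JSON.
#'
#' @param ... overrides of the default fields (see the default list in the
#'   function body; nested lists are merged).
#' @return a list of class \code{ms_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    preprocessing = list(bandpass_hz = c(1, 70), bandstop_hz = c(45, 55),
                         ripple = 0.001,
                         transition_width_hz = list(bandpass = c(1, 2),
                                                    bandstop = 2,
                                                    lowpass = 2),
                         epoch_length_s = 3,
                         bad_channels = list()),
    spectral = list(bands = canonical_bands(), window_policy = "fs"),
    microstates = list(K = 4, n_max_peaks = 2500, sd_mult = 2,
                       min_peak_distance_ms = 10, min_segment_ms = 30,
                       restarts = 300, seed = 1, lowpass_hz = 40),
    stats = list(covariates = c("age", "gender"), transform = "log"),
    io = list(condition_label = "eyes_closed")
  )
  over <- list(...)
  cfg <- utils::modifyList(cfg, over)
  validate_config(cfg)
  structure(cfg, class = c("ms_config", "list"))
}

validate_config <- function(cfg) {
  ms <- cfg$microstates
  stopifnot(ms$K >= 1, ms$n_max_peaks >= 1, ms$sd_mult > 0,
            ms$min_peak_distance_ms >= 0, ms$min_segment_ms >= 0,
            ms$restarts >= 1, ms$lowpass_hz > 0,
            cfg$preprocessing$ripple > 0, cfg$preprocessing$ripple < 0.5,
            cfg$preprocessing$epoch_length_s > 0)
  invisible(cfg)
}

#' @param cfg an \code{ms_config}.
#' @param path JSON file path.
#' @rdname pipeline_config
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(NULL)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$spectral$bands <- as.data.frame(raw$spectral$bands)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable polynomial rolling hash; no digest dependency
  h <- 5381
  for (b in utf8ToInt(as.character(js)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Stages per subject: read -> select eyes-closed -> band-pass ->
#' band-stop -> epoch -> interpolate bad channels -> average reference ->
#' [Welch spectral branch | 40 Hz low-pass -> GFP-peak map extraction].
#' Then group-level modified K-means over all subjects' pooled peak maps,
#' archetype ordering against the analytic templates, per-subject
#' back-fitting with short-segment rejection and feature computation, and
#' finally the covariate-adjusted group statistics. Deterministic given
#' the config (including its seed); every output carries a provenance
#' header (config hash + parameters).
#'
#' @param config an \code{ms_config}.
#' @param subjects data.frame with columns subject_id, group, age, gender,
#'   optional disease_duration_years, and either a \code{path} column
#'   (matrix/EDF files) or an \code{epochs} list-column of ready
#'   \code{ms_epochs}.
#' @param out_dir output directory (created if missing).
#' @param verbose print stage progress.
#' @return invisibly, a list with \code{features} (ms_feature_table),
#'   \code{maps}, \code{stats}, \code{out_dir}.
#' @export
run_pipeline <- function(config, subjects, out_dir, verbose = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  hash <- config_hash(config)
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logf, append = TRUE)
    if (verbose) message(msg)
  }
  log_line("config hash ", hash)
  log_line("parameters: ", jsonlite::toJSON(unclass(config),
                                            auto_unbox = TRUE, digits = NA))
  write_config(config, file.path(out_dir, "config.json"))

  pp <- config$preprocessing
  msc <- config$microstates
  stage <- function(name, sid, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for subject ", sid, ": ",
           conditionMessage(e), call. = FALSE))
  }

  per_subject <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    log_line("subject ", sid)
    if (!is.null(subjects$epochs)) {
      e <- subjects$epochs[[i]]
      e <- stage("reference", sid, average_reference(e))
    } else {
      path <- subjects$path[i]
      rec <- stage("read", sid, {
        if (grepl("\\.edf$", path, ignore.case = TRUE)) read_edf(path)
        else read_matrix(path)
      })
      if (nrow(rec$annotations))
        rec <- stage("select_condition", sid,
                     select_condition(rec, config$io$condition_label))
      rec <- stage("bandpass", sid, apply_filter(rec,
        design_fir("bandpass", pp$bandpass_hz, rec$fs, pp$ripple,
                   pp$transition_width_hz$bandpass)))
      rec <- stage("bandstop", sid, apply_filter(rec,
        design_fir("bandstop", pp$bandstop_hz, rec$fs, pp$ripple,
                   pp$transition_width_hz$bandstop)))
      e <- stage("epoch", sid, epoch(rec, pp$epoch_length_s))
      bad <- pp$bad_channels[[sid]]
      if (!is.null(bad) && length(bad))
        e <- stage("interpolate", sid, interpolate_channels(e, bad))
      e <- stage("reference", sid, average_reference(e))
    }
    # spectral branch
    spec <- stage("spectral", sid, {
      s <- power_spectrum(e)
      global_relative_power(relative_band_power(s, config$spectral$bands))
    })
    # microstate branch: 40 Hz low-pass on epochs
    elp <- stage("lowpass", sid, average_reference(apply_filter(e,
      design_fir("lowpass", msc$lowpass_hz, e$fs, pp$ripple,
                 pp$transition_width_hz$lowpass))))
    gser <- stage("gfp", sid, gfp(elp))
    pk <- stage("gfp_peaks", sid,
                find_gfp_peaks(gser, msc$min_peak_distance_ms))
    maps_i <- stage("peak_maps", sid,
                    select_peak_maps(elp, pk, msc$n_max_peaks, msc$sd_mult))
    per_subject[[sid]] <- list(epochs_lp = elp, gfp = gser,
                               peak_maps = maps_i, relpow = spec)
  }

  log_line("group clustering: ", length(per_subject), " subjects, K=",
           msc$K, ", restarts=", msc$restarts, ", seed=", msc$seed)
  gm <- group_maps(lapply(per_subject, `[[`, "peak_maps"),
                   K = msc$K, restarts = msc$restarts, seed = msc$seed)
  maps <- if (msc$K == 4 &&
              ncol(gm$maps$maps) == n_channels(study_montage())) {
    order_maps(gm$maps, template_maps())
  } else gm$maps
  write_maps(maps, file.path(out_dir, "group_maps.tsv"), hash)

  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    ps <- per_subject[[sid]]
    seg <- stage("backfit", sid, backfit(ps$epochs_lp, maps))
    seg <- stage("reject_short", sid,
                 reject_short_segments(seg, msc$min_segment_ms))
    write_segmentation(seg, file.path(out_dir,
                                      paste0("segmentation_", sid, ".tsv")),
                       hash)
    ft <- stage("features", sid, compute_features(seg, ps$gfp))
    row <- subjects[i, intersect(c("subject_id", "group", "age", "gender",
                                   "disease_duration_years"),
                                 names(subjects))]
    for (k in seq_len(nrow(ft))) {
      row[[paste0("duration_", ft$label[k])]] <- ft$duration_ms[k]
      row[[paste0("occurrence_", ft$label[k])]] <- ft$occurrence_hz[k]
      row[[paste0("coverage_", ft$label[k])]] <- ft$coverage_pct[k]
      row[[paste0("gev_", ft$label[k])]] <- ft$gev_pct[k]
    }
    row$gev_total <- attr(ft, "total_gev_pct")
    for (b in names(ps$relpow))
      row[[paste0("relpow_", b, "_global")]] <- ps$relpow[[b]]
    rows[[i]] <- row
  }
  feats <- feature_table(do.call(rbind, rows))
  ft_path <- file.path(out_dir, "features.tsv")
  writeLines(paste0("# config=", hash), ft_path)
  suppressWarnings(utils::write.table(
    format_numeric_cols(feats), ft_path, sep = "\t", quote = FALSE,
    row.names = FALSE, append = TRUE))

  stats_tab <- stage("stats", "-", group_statistics(feats, config))
  st_path <- file.path(out_dir, "stats.tsv")
  writeLines(paste0("# config=", hash), st_path)
  suppressWarnings(utils::write.table(
    stats_tab, st_path, sep = "\t", quote = FALSE, row.names = FALSE,
    append = TRUE))
  log_line("done")
  invisible(list(features = feats, maps = maps, stats = stats_tab,
                 out_dir = out_dir))
}

#' Group statistics over a feature table
#'
#' For every feature column: the three-group covariate-adjusted ANCOVA on
#' (by default) log-transformed values, mirroring the study's layout, plus
#' the patients-vs-controls effect size (Cohen's d, untransformed) for
#' microstate D occurrence.
#'
#' @param feats an \code{ms_feature_table}.
#' @param config an \code{ms_config}.
#' @return data.frame (feature, test, statistic, df1, df2, p).
#' @export
group_statistics <- function(feats, config = pipeline_config()) {
  skip <- c("subject_id", "group", "age", "gender",
            "disease_duration_years")
  fcols <- setdiff(names(feats), skip)
  fcols <- fcols[vapply(feats[fcols], is.numeric, TRUE)]
  out <- list()
  for (f in fcols) {
    y <- feats[[f]]
    ok <- all(is.finite(y)) && all(y > 0)
    yv <- if (identical(config$stats$transform, "log") && ok)
      log_transform(y) else y
    res <- tryCatch(
      ancova_group_test(yv, feats$group, feats$age, feats$gender),
      error = function(e) NULL)
    if (is.null(res)) next
    out[[f]] <- data.frame(feature = f, test = res$method,
                           statistic = res$statistic,
                           df1 = res$df[1], df2 = res$df[2], p = res$p,
                           stringsAsFactors = FALSE)
  }
  tab <- if (length(out))
    do.call(rbind, c(out, list(make.row.names = FALSE))) else NULL
  if ("occurrence_D" %in% names(feats) &&
      all(c("patient", "control") %in% feats$group)) {
    d <- cohens_d(feats$occurrence_D[feats$group == "control"],
                  feats$occurrence_D[feats$group == "patient"])
    tab <- rbind(tab, data.frame(
      feature = "occurrence_D", test = "Cohen's d (control - patient)",
      statistic = d, df1 = NA_real_, df2 = NA_real_, p = NA_real_,
      stringsAsFactors = FALSE))
  }
  tab
}

write_maps <- function(maps, path, hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(hash)) writeLines(paste0("# config=", hash), con)
  writeLines(paste(c("label", colnames(maps$maps)), collapse = "\t"), con)
  for (k in seq_len(maps$K))
    writeLines(paste(c(maps$labels_order[k],
                       formatC(maps$maps[k, ], format = "g", digits = 15)),
                     collapse = "\t"), con)
  # JSON sidecar with ordering metadata
  jsonlite::write_json(list(K = maps$K, labels_order = maps$labels_order),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(NULL)
}

#' Read microstate maps written by \code{write_maps}
#' @param path TSV path (expects the \code{.json} sidecar next to it).
#' @return an \code{ms_maps}.
#' @export
read_maps <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- cells[[1]][-1]
  body <- cells[-1]
  maps <- do.call(rbind, lapply(body, function(x) as.numeric(x[-1])))
  colnames(maps) <- hdr
  labs <- vapply(body, `[[`, "", 1)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    labs <- meta$labels_order
  }
  microstate_maps(maps, labs)
}

write_segmentation <- function(seg, path, hash = "") {
  df <- data.frame(epoch = seg$epoch_index, sample = seg$sample_index,
                   label = seg$labels_order[seg$labels],
                   fit = formatC(seg$fit, format = "g", digits = 15))
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(hash)) writeLines(paste0("# config=", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
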