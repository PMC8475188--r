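#' Cohort feature tables
#'
#' A feature table is a data.frame keyed by \code{subject_id} with the
#' grouping columns \code{group} (control / presymptomatic / patient),
#' \code{age}, \code{gender} (female / male), an optional
#' \code{disease_duration_years}, and any number of named numeric feature
#' columns (relative band powers, microstate statistics, ...).
#'
#' @param df data.frame with at least subject_id, group, age, gender.
#' @return the validated data.frame with class \code{ms_feature_table}.
#' @export
feature_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "gender")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  df$group <- normalize_level(df$group,
    c("control", "presymptomatic", "patient"))
  df$gender <- normalize_level(df$gender, c("female", "male"))
  class(df) <- c("ms_feature_table", "data.frame")
  df
}

# trim/lower-case and validate a categorical column
normalize_level <- function(x, levels) {
  x <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(x), levels)
  if (length(bad))
    stop("invalid level(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(levels, collapse = "/"), ")")
  x
}

#' @param tab an \code{ms_feature_table}.
#' @param path file path (tab-separated values with header).
#' @rdname feature_table
#' @export
write_feature_table <- function(tab, path) {
  utils::write.table(format_numeric_cols(tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(NULL)
}

format_numeric_cols <- function(df) {
  df[] <- lapply(df, function(col)
    if (is.numeric(col))
      ifelse(is.na(col), NA, formatC(col, format = "g", digits = 17))
    else col)
  df
}

#' @rdname feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  feature_table(df)
}
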