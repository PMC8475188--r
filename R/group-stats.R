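#' Two-sided Fisher exact test for a 2 x m contingency table
#'
#' Full enumeration: all tables with the observed margins are generated,
#' their multivariate hypergeometric probabilities computed, and the
#' two-sided p-value is the sum of the probabilities not exceeding the
#' observed table's (with a 1e-12 slack for floating-point ties). For
#' m = 2 this is the classic two-sided Fisher test.
#'
#' @param tab 2 x m matrix of non-negative integer counts.
#' @return an \code{ms_test}: list with statistic (NA), p, df (NULL),
#'   method.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2 || ncol(tab) < 2) stop("need a 2 x m table, m >= 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) < 1) stop("empty table")
  col_tot <- colSums(tab)
  row1 <- sum(tab[1, ])
  N <- sum(tab)
  # log-probability of a table given first-row counts a (margins fixed)
  logp <- function(a) sum(lchoose(col_tot, a)) - lchoose(N, row1)
  p_obs <- logp(tab[1, ])
  # enumerate first-row count vectors with the right margins
  total <- 0
  rec <- function(j, remaining, acc) {
    if (j > length(col_tot)) {
      if (remaining == 0) {
        lp <- sum(lchoose(col_tot, acc)) - lchoose(N, row1)
        if (lp <= p_obs + 1e-12) total <<- total + exp(lp)
      }
      return(invisible())
    }
    lo <- max(0, remaining - sum(col_tot[j:length(col_tot)]) + col_tot[j])
    hi <- min(col_tot[j], remaining)
    if (hi < lo) return(invisible())
    for (a in lo:hi) rec(j + 1L, remaining - a, c(acc, a))
  }
  rec(1L, row1, integer())
  ms_test(NA_real_, min(1, total), NULL,
          sprintf("Fisher exact (2 x %d, enumeration)", ncol(tab)))
}

ms_test <- function(statistic, p, df, method) {
  structure(list(statistic = statistic, p = p, df = df, method = method),
            class = "ms_test")
}

#' @export
print.ms_test <- function(x, ...) {
  cat("<ms_test> ", x$method, ": ", sep = "")
  if (!is.na(x$statistic)) cat("statistic=", signif(x$statistic, 5), " ", sep = "")
  if (!is.null(x$df)) cat("df=(", paste(x$df, collapse = ","), ") ", sep = "")
  cat("p=", signif(x$p, 5), "\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' H statistic on mid-ranks with the tie correction, p from the chi-square
#' distribution with (groups - 1) degrees of freedom.
#'
#' @param groups list of (non-empty) numeric vectors.
#' @return an \code{ms_test}.
#' @export
kruskal_wallis <- function(groups) {
  if (any(!lengths(groups))) stop("empty group")
  g <- length(groups)
  if (g < 2) stop("need >= 2 groups")
  x <- unlist(groups)
  n <- length(x)
  if (n < 3) stop("need total n >= 3")
  r <- rank(x)
  idx <- rep(seq_len(g), lengths(groups))
  Rbar <- tapply(r, idx, sum)^2 / lengths(groups)
  H <- 12 / (n * (n + 1)) * sum(Rbar) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H <- H / corr
  ms_test(H, stats::pchisq(H, g - 1, lower.tail = FALSE), g - 1L,
          "Kruskal-Wallis")
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p by enumeration of the rank-sum distribution when the
#' combined sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections. Two-sided p
#' is twice the smaller tail, capped at 1.
#'
#' @param x,y numeric vectors.
#' @return an \code{ms_test} (statistic is the rank sum W of \code{x}).
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(nx)])
  has_ties <- any(duplicated(pooled))
  if (n <= 12 && !has_ties) {
    combos <- utils::combn(n, nx)
    sums <- colSums(matrix(seq_len(n)[combos], nrow = nx))
    p_lo <- mean(sums <= W)
    p_hi <- mean(sums >= W)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "Wilcoxon rank sum (exact)"
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(pooled)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon rank sum (normal approximation)"
  }
  ms_test(W, p, NULL, method)
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Least-squares fit of the full model (intercept + group indicators +
#' age + gender) against the reduced model (intercept + age + gender);
#' the group main effect is the incremental F with (g - 1, n - g - 2)
#' degrees of freedom. Gender is coded 0/1. Computed from explicit design
#' matrices via QR.
#'
#' @param y numeric response.
#' @param group factor or character with g >= 2 levels.
#' @param age numeric covariate.
#' @param gender factor/character/0-1 covariate with two levels.
#' @return an \code{ms_test} with \code{df = c(g - 1, n - g - 2)}.
#' @export
ancova_group_test <- function(y, group, age, gender) {
  group <- factor(group)
  g <- nlevels(group)
  n <- length(y)
  if (g < 2) stop("group needs >= 2 non-empty levels")
  if (n <= g + 2) stop("too few observations for the covariate model")
  gender_num <- if (is.numeric(gender)) gender
                else as.numeric(factor(gender)) - 1
  Xr <- cbind(1, age, gender_num)
  Xf <- cbind(Xr, stats::model.matrix(~group)[, -1, drop = FALSE])
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf)) {
    # name the offending columns for the error message
    bad <- colnames(Xf)[qf$pivot[seq(qf$rank + 1, ncol(Xf))]]
    stop("rank-deficient design (collinear: ",
         paste(bad, collapse = ", "), ")")
  }
  rss_full <- sum(qr.resid(qf, y)^2)
  rss_red <- sum(qr.resid(qr(Xr), y)^2)
  df1 <- g - 1
  df2 <- n - g - 2
  if (rss_full <= 1e-24 && rss_red <= 1e-24) {
    Fv <- 0
  } else {
    Fv <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  }
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  ms_test(Fv, p, c(df1, df2), "ANCOVA (group, adjusted for age + gender)")
}

#' Natural log transform for positive features
#'
#' Errors on non-positive values: structural zeros (e.g. a microstate that
#' never occurred) must be handled by the caller, not hidden by an offset.
#'
#' @param values positive numeric vector.
#' @return log(values).
#' @export
log_transform <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("log_transform requires strictly positive finite values")
  log(values)
}

#' Cohen's d with pooled SD
#'
#' (mean(x) - mean(y)) / s_pooled, s_pooled the (n-1)-weighted pooled
#' standard deviation; the sign follows the first argument.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return numeric effect size.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need >= 2 values per sample")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  if (sp2 == 0) stop("zero pooled SD")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Descriptive stratified summaries
#'
#' Mean and SD per stratum per feature. Intentionally emits no test
#' statistics: the disease-duration strata are too small to test, so this
#' summary is descriptive only.
#'
#' @param tab an \code{ms_feature_table} (or data.frame).
#' @param strata vector assigning every row to a stratum, or the name of a
#'   column of \code{tab}.
#' @param features character vector of feature columns; default all
#'   numeric columns except age.
#' @return data.frame with stratum, n, and per-feature mean/sd columns.
#' @export
stratified_summary <- function(tab, strata, features = NULL) {
  if (length(strata) == 1 && is.character(strata) && strata %in% names(tab))
    strata <- tab[[strata]]
  if (length(strata) != nrow(tab)) stop("strata must assign every row")
  if (anyNA(strata)) stop("strata must assign every row (NA found)")
  if (is.null(features)) {
    num <- vapply(tab, is.numeric, TRUE)
    features <- setdiff(names(tab)[num], c("age", "disease_duration_years"))
  }
  lev <- unique(strata)
  out <- data.frame(stratum = lev,
                    n = vapply(lev, function(s) sum(strata == s), 0L),
                    stringsAsFactors = FALSE)
  for (f in features) {
    out[[paste0(f, "_mean")]] <- vapply(lev, function(s) {
      v <- tab[[f]][strata == s]
      if (length(v)) mean(v) else NA_real_
    }, 0)
    out[[paste0(f, "_sd")]] <- vapply(lev, function(s) {
      v <- tab[[f]][strata == s]
      if (length(v) > 1) stats::sd(v) else NA_real_
    }, 0)
  }
  out
}
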