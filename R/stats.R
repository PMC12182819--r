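# Group comparisons used in the study: paired and unpaired t-tests, and
# one-way repeated-measures ANOVA with Greenhouse-Geisser correction.

#' Paired and unpaired two-sided t-tests
#'
#' Thin wrappers around [stats::t.test()] returning the statistic and
#' two-sided p-value. The paired version requires the two samples to be
#' aligned by subject; pass `ids` to have the alignment checked.
#'
#' @param a,b numeric vectors of per-subject values.
#' @param ids optional list with `a` and `b` subject-id vectors; the paired
#'   test errors if they do not match element-wise.
#' @return list with `t`, `p`, `df`, `estimate`.
#' @export
paired_t <- function(a, b, ids = NULL) {
  if (length(a) != length(b))
    stop_lungecv("paired samples must have equal length")
  if (length(a) < 2L) stop_lungecv("need at least 2 pairs")
  if (!is.null(ids) && !identical(ids$a, ids$b))
    stop_lungecv("paired samples are not aligned by subject id")
  if (isTRUE(all.equal(a, b))) {
    # degenerate zero-difference case: t = 0, p = 1 by convention
    return(list(t = 0, p = 1, df = length(a) - 1L, estimate = 0))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       estimate = unname(ht$estimate))
}

#' @rdname paired_t
#' @export
unpaired_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_lungecv("need at least 2 values per group")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       estimate = unname(diff(rev(ht$estimate))))
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard within-subject F from the subject x condition decomposition;
#' the Greenhouse-Geisser epsilon is estimated from the sample covariance of
#' the conditions (via the double-centered covariance matrix) and scales the
#' degrees of freedom of the F reference distribution. With two conditions
#' epsilon is 1 by construction.
#'
#' @param y numeric matrix, subjects in rows, conditions in columns
#'   (complete; missing cells are an error).
#' @return list with `F`, `df1`, `df2`, `epsilon`, `p_gg` (corrected),
#'   `p_uncorrected`.
#' @export
rm_anova_gg <- function(y) {
  y <- as.matrix(y)
  if (anyNA(y)) stop_lungecv("repeated-measures ANOVA requires complete data")
  n <- nrow(y); k <- ncol(y)
  if (n < 2L || k < 2L) stop_lungecv("need >= 2 subjects and >= 2 conditions")
  grand <- mean(y)
  cond_m <- colMeans(y)
  subj_m <- rowMeans(y)
  ss_cond <- n * sum((cond_m - grand)^2)
  resid <- y - outer(subj_m, cond_m, `+`) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  # Greenhouse-Geisser epsilon from the double-centered covariance
  s <- stats::cov(y)
  cmat <- diag(k) - 1 / k
  sc <- cmat %*% s %*% cmat
  eps <- sum(diag(sc))^2 / ((k - 1) * sum(sc * sc))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  list(F = f, df1 = df1, df2 = df2, epsilon = eps,
       p_gg = stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE),
       p_uncorrected = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Mean +/- SD summary table
#'
#' Formats per-group values the way the study tabulates them: one row per
#' measure, one column per condition, cells as `mean +/- SD`. Percentages
#' are rounded to the nearest integer using R's round-half-even rule;
#' other units keep `digits` significant decimals.
#'
#' @param data data frame with columns `measure`, `condition`, `value`
#'   (one row per subject and measure).
#' @param percent character vector of measures whose values are fractions to
#'   be reported as integer percentages.
#' @param digits decimals for non-percentage measures.
#' @return data frame, measures in rows and conditions in columns.
#' @export
summary_table <- function(data, percent = character(), digits = 0) {
  stopifnot(all(c("measure", "condition", "value") %in% names(data)))
  measures <- unique(data$measure)
  conditions <- unique(data$condition)
  fmt <- function(v, as_pct) {
    if (as_pct) v <- 100 * v
    m <- round(mean(v), if (as_pct) 0 else digits)
    s <- signif(stats::sd(v), 2)
    if (is.na(s)) s <- 0
    sprintf("%s ± %s", format(m, trim = TRUE), format(s, trim = TRUE))
  }
  out <- sapply(conditions, function(cn) {
    vapply(measures, function(ms) {
      v <- data$value[data$measure == ms & data$condition == cn]
      if (length(v) == 0L) return(NA_character_)
      fmt(v, ms %in% percent)
    }, character(1))
  })
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  names(out) <- conditions
  cbind(data.frame(measure = measures, stringsAsFactors = FALSE), out)
}
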