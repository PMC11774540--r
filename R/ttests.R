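#' Cohen's d for paired or one-sample designs
#'
#' `method = "dz"` (default) is the standardised mean difference of the
#' paired differences, `mean(d) / sd(d)`, which equals `t / sqrt(n)`.
#' `method = "pooled"` divides the mean difference by the root mean square
#' of the two condition SDs instead, an alternative paired convention.
#'
#' @param x Numeric vector (first condition, or differences if `y` is NULL).
#' @param y Optional second condition, paired with `x`.
#' @param mu Null value subtracted from the (difference) scores.
#' @param method `"dz"` or `"pooled"` (`"pooled"` requires `y`).
#' @return Effect size (numeric scalar).
#' @export
cohens_d <- function(x, y = NULL, mu = 0, method = c("dz", "pooled")) {
  method <- match.arg(method)
  if (method == "pooled") {
    if (is.null(y)) stop("method = 'pooled' requires two paired vectors",
                         call. = FALSE)
    return((mean(x) - mean(y) - mu) / sqrt((var(x) + var(y)) / 2))
  }
  d <- if (is.null(y)) x else x - y
  (mean(d) - mu) / sd(d)
}

.t_row <- function(diffs, mu, label) {
  n <- length(diffs)
  s <- sd(diffs)
  if (s == 0) {
    if (isTRUE(all.equal(mean(diffs), mu))) {
      tv <- 0; p <- 1
    } else {
      warning(sprintf("%s: zero variance with mean != mu; t is infinite",
                      label), call. = FALSE)
      tv <- sign(mean(diffs) - mu) * Inf; p <- 0
    }
    d <- tv / sqrt(n)
  } else {
    tv <- (mean(diffs) - mu) / (s / sqrt(n))
    p <- 2 * pt(abs(tv), n - 1, lower.tail = FALSE)
    d <- tv / sqrt(n)
  }
  lbf <- if (is.finite(tv)) jzs_bf_ttest(tv, n) else Inf
  tibble::tibble(comparison = label, n = n, df = n - 1, t = tv, p = p,
                 d = d, lbf = lbf)
}

#' Bonferroni-corrected post-hoc paired t tests
#'
#' Two-tailed paired t tests between condition columns, with
#' `p_bonf = min(1, m * p)`, Cohen's d_z and the default JZS log10 Bayes
#' factor ([jzs_bf_ttest()]).
#'
#' @param data Data frame or matrix with one column per condition and one
#'   row per subject (pairing by row).
#' @param comparisons List of length-2 character vectors naming the column
#'   pairs to compare; all pairs by default.
#' @param m Bonferroni family size; defaults to the number of comparisons.
#' @return A tibble with `comparison`, `n`, `df`, `t`, `p`, `p_bonf`, `d`,
#'   `lbf`.
#' @export
posthoc_paired_t <- function(data, comparisons = NULL, m = NULL) {
  data <- as.data.frame(data)
  if (is.null(comparisons))
    comparisons <- utils::combn(names(data), 2, simplify = FALSE)
  if (is.null(m)) m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2)
    a <- data[[cmp[1]]]; b <- data[[cmp[2]]]
    if (is.null(a) || is.null(b))
      stop(sprintf("unknown condition '%s'",
                   cmp[!(cmp %in% names(data))][1]), call. = FALSE)
    if (length(a) != length(b))
      stop("paired vectors must have equal length", call. = FALSE)
    .t_row(a - b, 0, paste(cmp, collapse = " vs. "))
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonf <- pmin(1, m * out$p)
  out[, c("comparison", "n", "df", "t", "p", "p_bonf", "d", "lbf")]
}

#' One-sample t test with adjusted alpha
#'
#' Two-tailed one-sample t test against `mu`, reporting Cohen's
#' `d_z = t / sqrt(n)`, the JZS log10 Bayes factor, the Bonferroni-adjusted
#' p (`min(1, m p)`) and whether the test is significant at the supplied
#' (already adjusted) alpha level. A zero-variance sample with mean
#' different from `mu` yields an infinite t with a warning.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param mu Null value (default 0).
#' @param alpha Adjusted significance level used for the `significant` flag.
#' @param m Bonferroni family size for `p_bonf`.
#' @param label Comparison label carried into the result.
#' @return A one-row tibble with `comparison`, `mean`, `sem`, `n`, `df`,
#'   `t`, `p`, `p_bonf`, `d`, `lbf`, `alpha`, `significant`.
#' @export
one_sample_t <- function(values, mu = 0, alpha = 0.05, m = 1,
                         label = "values") {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  row <- .t_row(values, mu, label)
  tibble::tibble(
    comparison = label,
    mean = mean(values),
    sem = sd(values) / sqrt(length(values)),
    n = row$n, df = row$df, t = row$t, p = row$p,
    p_bonf = pmin(1, m * row$p), d = row$d, lbf = row$lbf,
    alpha = alpha, significant = row$p < alpha
  )
}
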