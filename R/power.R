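#' Power of a paired (one-sample) t test
#'
#' Exact power via the noncentral t distribution, for effect size
#' `d` (standardised mean difference of the paired differences) and `n`
#' pairs.
#'
#' @param n Number of pairs (>= 2).
#' @param d Effect size (Cohen's d_z).
#' @param alpha Significance level.
#' @param tails 2 (default) or 1.
#' @return Power (probability of rejecting the null).
#' @export
paired_t_power <- function(n, d, alpha = 0.05, tails = 2) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, tails %in% c(1, 2))
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 2) {
    tc <- qt(1 - alpha / 2, df)
    pt(tc, df, ncp, lower.tail = FALSE) + pt(-tc, df, ncp)
  } else {
    tc <- qt(1 - alpha, df)
    pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Required sample size for a paired t test
#'
#' Smallest `n` whose noncentral-t power reaches the target.
#'
#' @param d Effect size (> 0).
#' @param alpha Significance level.
#' @param power Target power, in (0, 1).
#' @param tails 2 (default) or 1.
#' @param max_n Search cap.
#' @return Integer sample size.
#' @examples
#' required_sample_size(1, 0.05, 0.8) # 10
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.95, tails = 2,
                                 max_n = 1e6) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2
  while (paired_t_power(n, d, alpha, tails) < power) {
    n <- n + 1
    if (n > max_n) stop("target power not reachable within max_n",
                        call. = FALSE)
  }
  as.integer(n)
}

#' Smallest detectable effect size at given n, alpha and power
#'
#' Solves the noncentral-t power equation for `d` by root finding; the
#' complement of [required_sample_size()], useful when a design reports its
#' n but not the effect size it was powered for.
#'
#' @param n Number of pairs.
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails 2 (default) or 1.
#' @return Effect size `d` such that `paired_t_power(n, d, ...) == power`.
#' @export
detectable_effect_size <- function(n, alpha = 0.05, power = 0.95,
                                   tails = 2) {
  stopifnot(n >= 2)
  uniroot(function(d) paired_t_power(n, d, alpha, tails) - power,
          c(1e-8, 50), tol = 1e-9)$root
}
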