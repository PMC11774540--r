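#' Default (JZS) Bayes factor for a one-sample or paired t statistic
#'
#' Computes the Jeffreys-Zellner-Siow Bayes factor comparing the alternative
#' (Cauchy prior with scale `r` on the standardised effect size) against the
#' point null, from the t statistic and sample size, by numerical
#' integration of the marginal likelihood over the prior on the variance
#' scaling factor g (inverse-gamma(1/2, r^2/2)). Returned on the log10
#' scale: positive values favour the alternative.
#'
#' @param t Observed t statistic (finite).
#' @param n Number of (paired) observations, >= 2.
#' @param r Cauchy prior scale; default `sqrt(2)/2`, the conventional
#'   "medium" width.
#' @return `log10(BF10)` (numeric, vectorised over `t`).
#' @examples
#' jzs_bf_ttest(2.09, 28) # ~0.12
#' @export
jzs_bf_ttest <- function(t, n, r = sqrt(2) / 2) {
  if (length(t) > 1)
    return(vapply(t, jzs_bf_ttest, numeric(1), n = n, r = r))
  if (!is.finite(t)) stop("t must be finite", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  stopifnot(r > 0)
  nu <- n - 1
  log_h0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  # integrand is the ratio of marginal likelihoods times the prior on g,
  # keeping everything relative to the null for numerical stability
  f <- function(g) {
    exp(-0.5 * log1p(n * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) - log_h0) *
      r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g))
  }
  bf <- integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  log10(bf)
}

#' BIC-approximated inclusion Bayes factors for within-subject designs
#'
#' For each effect of a fully within-subject factorial design, compares the
#' set of models that include the effect against the matched set without it.
#' The model family consists of all sub-models of the full factorial model
#' that respect marginality (an interaction is only included together with
#' its main effects); each is fitted as a fixed-effects linear model on the
#' subject x cell means with a subject blocking factor, and its marginal
#' likelihood is approximated by `exp(-BIC / 2)`. The inclusion Bayes
#' factor for effect T is the ratio of summed (equal-prior) marginal
#' likelihoods over matched pairs (M + T vs. M), reported as log10. For a
#' single-factor design this reduces to the simple model-vs-null Bayes
#' factor.
#'
#' @inheritParams rm_anova
#' @return A tibble with `effect` and `lbf_inclusion`.
#' @export
bic_inclusion_bf <- function(data, dv, within, subject) {
  data <- as.data.frame(data)
  for (v in c(dv, within, subject)) {
    if (!v %in% names(data))
      stop(sprintf("column '%s' not found in data", v), call. = FALSE)
  }
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  agg <- stats::aggregate(data[[dv]],
                          by = c(list(data[[subject]]),
                                 lapply(within, function(w) data[[w]])),
                          FUN = mean)
  names(agg) <- c(subject, within, dv)

  terms_all <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  labels <- vapply(terms_all, paste, character(1), collapse = ":")

  contains <- function(model, i) i %in% model
  legal <- function(model) {
    # marginality: every sub-term of an included term is included
    for (i in model) {
      parts <- terms_all[[i]]
      for (k in seq_len(length(parts) - 1)) {
        subs <- utils::combn(parts, k, simplify = FALSE)
        for (s in subs) {
          j <- match(paste(s, collapse = ":"), labels)
          if (!j %in% model) return(FALSE)
        }
      }
    }
    TRUE
  }
  all_models <- Filter(legal, unlist(lapply(0:length(labels), function(k)
    utils::combn(seq_along(labels), k, simplify = FALSE)),
    recursive = FALSE))

  bic_of <- vapply(all_models, function(model) {
    rhs <- paste(c(subject, labels[model]), collapse = " + ")
    fit <- stats::lm(stats::as.formula(paste(dv, "~", rhs)), data = agg)
    BIC(fit)
  }, numeric(1))
  bic_of <- bic_of - min(bic_of)  # common shift cancels in ratios
  w <- exp(-bic_of / 2)

  model_sets <- lapply(all_models, sort)
  key <- vapply(model_sets, paste, character(1), collapse = ",")
  rows <- lapply(seq_along(labels), function(i) {
    num <- 0; den <- 0
    for (mi in seq_along(model_sets)) {
      model <- model_sets[[mi]]
      if (!contains(model, i) && legal(sort(c(model, i)))) {
        plus <- match(paste(sort(c(model, i)), collapse = ","), key)
        if (!is.na(plus)) {
          num <- num + w[plus]
          den <- den + w[mi]
        }
      }
    }
    tibble::tibble(effect = labels[i], lbf_inclusion = log10(num / den))
  })
  dplyr::bind_rows(rows)
}
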