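#' Repeated-measures ANOVA with sphericity handling
#'
#' Univariate repeated-measures ANOVA for balanced, complete, fully
#' within-subject designs, computed by projecting each subject's cell means
#' onto orthonormal contrast bases (one basis per effect). For every effect
#' with more than one numerator degree of freedom the function reports
#' Mauchly's sphericity test and the Greenhouse-Geisser corrected p value;
#' following common practice the correction is considered "applied" when
#' Mauchly's p < .05. Effect sizes are classical eta squared
#' (SS_effect / SS_total). Replicated observations within a subject x cell
#' are averaged first.
#'
#' @param data Data frame in long format.
#' @param dv Name of the numeric dependent variable column.
#' @param within Character vector of within-subject factor column names.
#' @param subject Name of the subject identifier column.
#' @return A tibble of class `rm_anova` with columns `effect`, `df_num`,
#'   `df_den`, `F`, `p`, `mauchly_p`, `gg_epsilon`, `p_gg`,
#'   `sphericity_violated`, `eta_sq`.
#' @examples
#' d <- expand.grid(subj = factor(1:8), cond = factor(1:3))
#' d$y <- rnorm(nrow(d)) + as.numeric(d$cond)
#' rm_anova(d, "y", "cond", "subj")
#' @export
rm_anova <- function(data, dv, within, subject) {
  data <- as.data.frame(data)
  for (v in c(dv, within, subject)) {
    if (!v %in% names(data))
      stop(sprintf("column '%s' not found in data", v), call. = FALSE)
  }
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  if (nlevels(data[[subject]]) < 2)
    stop("at least 2 subjects are required", call. = FALSE)

  # cell means per subject
  agg <- stats::aggregate(data[[dv]],
                          by = c(list(data[[subject]]),
                                 lapply(within, function(w) data[[w]])),
                          FUN = mean)
  names(agg) <- c(subject, within, dv)

  lev <- lapply(within, function(w) levels(data[[w]]))
  names(lev) <- within
  cells <- expand.grid(lev, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  n_cells <- nrow(cells)
  subj_levels <- levels(data[[subject]])
  n <- length(subj_levels)

  cell_key <- function(df) do.call(paste, c(df[within], sep = "\r"))
  agg$.cell <- cell_key(agg)
  full_keys <- cell_key(cells)
  Y <- matrix(NA_real_, n, n_cells,
              dimnames = list(subj_levels, full_keys))
  Y[cbind(as.character(agg[[subject]]), agg$.cell)] <- agg[[dv]]
  if (anyNA(Y)) {
    miss <- which(is.na(Y), arr.ind = TRUE)[1, ]
    stop(sprintf("missing cell: subject %s lacks %s",
                 rownames(Y)[miss[1]],
                 gsub("\r", ":", colnames(Y)[miss[2]])), call. = FALSE)
  }

  # orthonormal contrast basis per factor, unit mean vector otherwise
  qmat <- lapply(lev, function(lv) {
    k <- length(lv)
    Q <- stats::contr.helmert(k)
    sweep(Q, 2, sqrt(colSums(Q^2)), "/")
  })
  umat <- lapply(lev, function(lv) matrix(1 / sqrt(length(lv)),
                                          length(lv), 1))

  effects <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  ss_total <- sum((Y - mean(Y))^2)

  rows <- lapply(effects, function(eff) {
    mats <- lapply(within, function(w)
      if (w %in% eff) qmat[[w]] else umat[[w]])
    # expand.grid varies the first factor fastest -> kronecker in reverse
    C <- Reduce(kronecker, rev(mats))
    D <- Y %*% C
    mbar <- colMeans(D)
    d1 <- ncol(C)
    d2 <- (n - 1) * d1
    ss_eff <- n * sum(mbar^2)
    resid <- sweep(D, 2, mbar)
    ss_err <- sum(resid^2)
    scale <- sum(Y^2) + .Machine$double.xmin
    if (ss_eff < 1e-20 * scale) ss_eff <- 0
    if (ss_err < 1e-20 * scale) ss_err <- 0
    Fval <- if (ss_eff == 0) 0
            else if (ss_err == 0) Inf
            else (ss_eff / d1) / (ss_err / d2)
    p <- pf(Fval, d1, d2, lower.tail = FALSE)
    if (d1 > 1) {
      S <- crossprod(resid) / (n - 1)
      eps <- sum(diag(S))^2 / (d1 * sum(S * S))
      mauchly_p <- .mauchly_p(S, n, d1)
    } else {
      eps <- 1
      mauchly_p <- NA_real_
    }
    p_gg <- pf(Fval, eps * d1, eps * d2, lower.tail = FALSE)
    tibble::tibble(
      effect = paste(eff, collapse = ":"),
      df_num = d1, df_den = d2, F = Fval, p = p,
      mauchly_p = mauchly_p, gg_epsilon = eps, p_gg = p_gg,
      sphericity_violated = !is.na(mauchly_p) & mauchly_p < 0.05,
      eta_sq = if (ss_total > 0) ss_eff / ss_total else 0
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rm_anova", class(out))
  out
}

# Mauchly's test for sphericity of the contrast covariance matrix S (d x d),
# chi-square approximation.
.mauchly_p <- function(S, n, d) {
  if (n - 1 < d) return(NA_real_)
  detS <- det(S)
  if (!is.finite(detS) || detS <= 0) return(0)
  W <- detS / (sum(diag(S)) / d)^d
  f <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
  chi <- -(n - 1) * f * log(W)
  df <- d * (d + 1) / 2 - 1
  pchisq(chi, df, lower.tail = FALSE)
}
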