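#' Principal component analysis with oblimin rotation
#'
#' Eigen-decomposes the correlation matrix, retains components with
#' eigenvalue > 1 (Kaiser criterion) and obliquely rotates the retained
#' loadings with the quartimin (oblimin, gamma = 0) criterion via the
#' gradient projection algorithm. Percent variance is that of the retained
#' unrotated components. Rotated components are ordered by decreasing sum of
#' squared loadings and sign-aligned so each column's dominant loadings are
#' positive.
#'
#' @param x Numeric matrix or data frame, observations x variables
#'   (>= 2 variables, more observations than variables).
#' @param rotate Rotate when 2 or more components are retained
#'   (default TRUE).
#' @return An object of class `pca_oblimin`: `eigenvalues`,
#'   `n_components`, `loadings` (rotated if applicable), `Phi` (factor
#'   correlation matrix), `rotmat`, `pct_variance`, `rotated`.
#' @export
pca_oblimin <- function(x, rotate = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 variables", call. = FALSE)
  if (nrow(x) <= ncol(x))
    stop("need more observations than variables", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("constant variable(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  R <- cor(x)
  e <- eigen(R, symmetric = TRUE)
  k <- sum(e$values > 1)
  if (k == 0) k <- 1  # always retain the leading component
  pct <- 100 * sum(e$values[seq_len(k)]) / ncol(x)
  A <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  rownames(A) <- colnames(x)
  rotated <- FALSE
  Tmat <- diag(k)
  L <- A
  Phi <- diag(k)
  if (k >= 2 && rotate) {
    rot <- .gpa_quartimin(A)
    L <- rot$loadings
    Phi <- rot$Phi
    Tmat <- rot$Tmat
    rotated <- TRUE
  }
  # sign-align and order by explained SS
  signs <- ifelse(colSums(L^3) < 0, -1, 1)
  L <- sweep(L, 2, signs, "*")
  Tmat <- sweep(Tmat, 2, signs, "*")
  Phi <- diag(signs, k) %*% Phi %*% diag(signs, k)
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Tmat <- Tmat[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  colnames(L) <- paste0("PC", seq_len(k))
  structure(
    list(eigenvalues = e$values, n_components = k, loadings = L,
         Phi = Phi, rotmat = Tmat, pct_variance = pct, rotated = rotated),
    class = "pca_oblimin"
  )
}

#' @export
print.pca_oblimin <- function(x, ...) {
  cat(sprintf(
    "<pca_oblimin> %d component(s) retained (eigenvalue > 1), %.1f%% of variance%s\n",
    x$n_components, x$pct_variance,
    if (x$rotated) ", oblimin-rotated" else ""))
  print(round(x$loadings, 3))
  invisible(x)
}

# Gradient projection algorithm for oblique quartimin rotation
# (Jennrich-style GPFoblq with the quartimin criterion).
.gpa_quartimin <- function(A, maxit = 1000, tol = 1e-6) {
  k <- ncol(A)
  N <- matrix(1, k, k) - diag(k)
  vgQ <- function(L) {
    L2 <- L^2
    list(f = sum(L2 * (L2 %*% N)) / 4, G = L * (L2 %*% N))
  }
  Tmat <- diag(k)
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  v <- vgQ(L)
  f <- v$f
  G <- -t(t(L) %*% v$G %*% Ti)
  al <- 1
  s <- Inf
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (i in 1:25) {
      X <- Tmat - al * Gp
      X <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti2 <- tryCatch(solve(X), error = function(e) NULL)
      if (!is.null(Ti2)) {
        L2m <- A %*% t(Ti2)
        v2 <- vgQ(L2m)
        if (v2$f < f - 0.5 * s^2 * al) break
      }
      al <- al / 2
    }
    Tmat <- X
    f <- v2$f
    L <- L2m
    G <- -t(t(L) %*% v2$G %*% solve(Tmat))
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, Tmat = Tmat, f = f,
       iterations = iter, converged = s < tol)
}
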