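# Tetrachoric correlation ----------------------------------------------------

# Vectorized standard bivariate normal CDF P(X <= h, Y <= k; rho), via the
# single-integral identity
#   Phi2(h, k, rho) = Phi(h) Phi(k) +
#     (1 / 2*pi) * int_0^asin(rho) exp(-(h^2 + k^2 - 2 h k sin t) / (2 cos^2 t)) dt
# evaluated with 48-node Gauss-Legendre quadrature. Vectorization over
# thousands of (h, k, rho) triples is what makes whole-matrix tetrachoric
# estimation and binary parallel analysis affordable; accuracy is checked
# against mvtnorm::pmvnorm in the test suite.
.gl48 <- local({
  # Golub-Welsch: Gauss-Legendre nodes/weights on [-1, 1] from the
  # eigendecomposition of the Jacobi matrix
  n <- 48L
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
})

#' Bivariate standard normal CDF
#'
#' `P(X <= h, Y <= k)` for a standard bivariate normal with correlation
#' `rho`; vectorized over all three arguments.
#'
#' @param h,k upper limits.
#' @param rho correlation(s) in `[-1, 1]`.
#' @return numeric vector of probabilities.
#' @export
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(h, n); k <- rep_len(k, n); rho <- rep_len(rho, n)
  rho <- pmin(pmax(rho, -1), 1)
  out <- stats::pnorm(h) * stats::pnorm(k)
  nz <- which(rho != 0 & is.finite(h) & is.finite(k))
  if (length(nz)) {
    a <- asin(rho[nz])
    # map GL nodes from [-1,1] to [0, a]
    tn <- outer(a / 2, .gl48$nodes + 1)            # n x 48
    hh <- h[nz]; kk <- k[nz]
    s <- sin(tn); c2 <- cos(tn)^2
    f <- exp(-(hh^2 + kk^2 - 2 * hh * kk * s) / (2 * c2))
    out[nz] <- out[nz] + (a / 2) * drop(f %*% .gl48$weights) / (2 * pi)
  }
  # exact limits
  hit <- rho == 1; out[hit] <- stats::pnorm(pmin(h, k))[hit]
  hit <- rho == -1; out[hit] <- pmax(stats::pnorm(h) + stats::pnorm(k) - 1, 0)[hit]
  pmin(pmax(out, 0), 1)
}

# Solve Phi2(h, k, rho) = p11 for rho, vectorized bisection. With the
# thresholds fixed at the marginal inverse-normal estimates this is the
# maximum-likelihood tetrachoric estimate: the model margins match the
# observed margins by construction, so the multinomial likelihood of the
# four cells is maximized exactly when the model p11 equals the observed
# proportion (Phi2 is strictly increasing in rho).
.solve_tetra <- function(h, k, p11, tol = 1e-10, maxit = 60L) {
  n <- max(length(h), length(k), length(p11))
  h <- rep_len(h, n); k <- rep_len(k, n); p11 <- rep_len(p11, n)
  lo <- rep(-1, n); hi <- rep(1, n)
  # clamp targets into the attainable range
  p11 <- pmin(pmax(p11, pbvnorm(h, k, -1)), pbvnorm(h, k, 1))
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    up <- pbvnorm(h, k, mid) < p11
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
    if (max(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

#' Tetrachoric correlation of two dichotomous variables
#'
#' Maximum-likelihood estimate under the latent bivariate-normal model:
#' thresholds are set from the marginals via the inverse normal and `rho`
#' maximizes the bivariate-normal likelihood of the four cell counts. If
#' exactly one cell of the 2x2 table is empty, a continuity correction
#' (adding 0.5 to all cells) is applied and the result is flagged; a
#' perfectly concordant (or discordant) table returns +/-(1 - 1e-6),
#' flagged.
#'
#' @param x,y binary vectors (0/1), each with both levels present.
#' @return correlation in `(-1, 1)`, with attribute `corrected` (logical:
#'   degenerate-table handling applied).
#' @examples
#' set.seed(1)
#' z <- mvtnorm::rmvnorm(5000, sigma = matrix(c(1, .5, .5, 1), 2))
#' tetrachoric(z[, 1] > 0, z[, 2] > 0)
#' @export
tetrachoric <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined correlation: a variable is constant")
  n11 <- sum(x & y); n10 <- sum(x & !y); n01 <- sum(!x & y)
  n00 <- sum(!x & !y)
  corrected <- FALSE
  if (n10 == 0L && n01 == 0L) {
    rho <- 1 - 1e-6; corrected <- TRUE
  } else if (n11 == 0L && n00 == 0L) {
    rho <- -(1 - 1e-6); corrected <- TRUE
  } else {
    if (min(n11, n10, n01, n00) == 0L) {
      n11 <- n11 + 0.5; n10 <- n10 + 0.5; n01 <- n01 + 0.5; n00 <- n00 + 0.5
      corrected <- TRUE
    }
    n <- n11 + n10 + n01 + n00
    h <- stats::qnorm((n11 + n10) / n)   # P(x = 1) threshold, as upper limit
    k <- stats::qnorm((n11 + n01) / n)
    rho <- .solve_tetra(h, k, n11 / n)
  }
  structure(rho, corrected = corrected)
}

#' Pairwise tetrachoric correlation matrix
#'
#' All pairwise 2x2 cell counts are obtained in one cross-product of the
#' binary matrix, then every pair's maximum-likelihood `rho` is solved in a
#' single vectorized pass. Degenerate tables are handled as in
#' [tetrachoric()].
#'
#' @param x subjects x items binary matrix (no missing values).
#' @return correlation matrix with unit diagonal and attribute `corrected`
#'   (count of pairs needing degenerate-table handling).
#' @export
tetrachoric_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("tetrachoric_matrix() requires complete responses")
  p <- ncol(x); n <- nrow(x)
  cm <- colMeans(x)
  if (any(cm == 0 | cm == 1))
    stop("undefined correlation: constant item(s) ",
         paste(colnames(x)[cm == 0 | cm == 1], collapse = ", "))
  n1 <- colSums(x)
  n11 <- crossprod(x)
  iu <- which(upper.tri(n11), arr.ind = TRUE)
  a11 <- n11[iu]
  a10 <- n1[iu[, 1]] - a11
  a01 <- n1[iu[, 2]] - a11
  a00 <- n - a11 - a10 - a01
  conc <- a10 == 0 & a01 == 0
  disc <- a11 == 0 & a00 == 0
  zero <- !conc & !disc & pmin(a11, a10, a01, a00) == 0
  add <- ifelse(zero, 0.5, 0)
  tot <- n + 4 * add
  h <- stats::qnorm((a11 + a10 + 2 * add) / tot)
  k <- stats::qnorm((a11 + a01 + 2 * add) / tot)
  rho <- .solve_tetra(h, k, (a11 + add) / tot)
  rho[conc] <- 1 - 1e-6
  rho[disc] <- -(1 - 1e-6)
  R <- diag(p)
  R[iu] <- rho
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  dimnames(R) <- list(colnames(x), colnames(x))
  structure(R, corrected = sum(conc | disc | zero))
}

#' Smooth a correlation matrix to positive semi-definiteness
#'
#' Pairwise tetrachoric matrices need not be PSD. Eigenvalues below
#' `eps = 1e-6` are clipped to `eps`, the matrix is reassembled and
#' rescaled to unit diagonal; an already-PSD input is returned unchanged.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param eps clipping floor for eigenvalues.
#' @return PSD correlation matrix.
#' @export
smooth_to_psd <- function(R, eps = 1e-6) {
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop("smooth_to_psd() expects a symmetric matrix")
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) return(R)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- 1 / sqrt(diag(out))
  out <- out * tcrossprod(d)
  dimnames(out) <- dimnames(R)
  out
}
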