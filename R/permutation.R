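# Permutation QQ envelope ----------------------------------------------------
#
# A permutation null for the grid of covariate-adjusted rank correlations:
# subject rows of the sleep block are shuffled as whole rows while the
# personality block and the covariates stay fixed, so all correlations
# *within* each domain are preserved exactly while every *cross-domain*
# association is destroyed. Each replicate's p values are sorted in
# descending order; rank-wise means and the 5th/95th percentiles across
# replicates form the expected line and the envelope.

# Precompute, per complete-case group of sleep columns, everything that is
# fixed across replicates: ranked/residualized/standardized personality
# residuals, the orthonormal covariate basis, and the ranked sleep columns.
.qq_precompute <- function(personality, sleep, covariates) {
  P <- as.matrix(personality); S <- as.matrix(sleep)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (nrow(P) != nrow(S) || (!is.null(C) && nrow(C) != nrow(P)))
    stop("misaligned rows: blocks must be row-aligned on subjects")
  base_ok <- apply(is.finite(P), 1, all) &
    (if (is.null(C)) TRUE else apply(is.finite(C), 1, all))
  # freeze complete-case masks per sleep column; group columns sharing one
  pat <- apply(is.finite(S) & base_ok, 2, paste, collapse = "")
  groups <- split(seq_len(ncol(S)), pat)
  lapply(groups, function(cols) {
    rows <- which(is.finite(S[, cols[1]]) & base_ok)
    n <- length(rows)
    rs <- apply(S[rows, cols, drop = FALSE], 2, rank)
    rp <- apply(P[rows, , drop = FALSE], 2, rank)
    k <- 0L
    if (!is.null(C)) {
      rc <- apply(C[rows, , drop = FALSE], 2, rank)
      rc <- rc[, apply(rc, 2, stats::sd) > 0, drop = FALSE]
      k <- ncol(rc)
      Q <- qr.Q(qr(cbind(1, rc)))
    } else {
      Q <- matrix(1 / sqrt(n), n, 1)
    }
    presid <- rp - Q %*% crossprod(Q, rp)
    list(cols = cols, n = n, k = k, Q = Q,
         presid = sweep(presid, 2, sqrt(colSums(presid^2)), "/"),
         ranked_sleep = rs, df = n - 2L - k)
  })
}

# correlations -> two-sided p via the t approximation on df degrees of freedom
.rho_to_p <- function(rho, df) {
  rho <- pmin(pmax(rho, -1), 1)
  2 * stats::pt(abs(rho) * sqrt(df / pmax(1 - rho^2, 1e-300)),
                df, lower.tail = FALSE)
}

#' Permutation null p values for the association grid
#'
#' Per replicate, the subject rows of the sleep block are shuffled as whole
#' rows (within each frozen complete-case group), all
#' `ncol(personality) * ncol(sleep)` partial Spearman p values are
#' recomputed against the fixed personality block and covariates, and the
#' vector is sorted in descending order. Because whole rows move together,
#' the rank-correlation structure within the sleep domain (and trivially
#' within the personality domain) is preserved exactly in every replicate.
#'
#' @param personality subjects x scores matrix (complete).
#' @param sleep subjects x sleep-variable matrix (NA allowed; complete-case
#'   masks are frozen before permutation so each test's n is constant
#'   across replicates).
#' @param covariates subjects x covariates matrix or NULL.
#' @param n_replicates number of permutation replicates (warns below 100).
#' @param seed RNG seed.
#' @return `n_replicates x m` matrix of descending-sorted p values,
#'   `m = ncol(personality) * ncol(sleep)`.
#' @export
permute_and_score <- function(personality, sleep, covariates = NULL,
                              n_replicates = 10000L, seed = 1L) {
  if (n_replicates < 100L)
    warning("fewer than 100 replicates: envelope will be unstable")
  pre <- .qq_precompute(personality, sleep, covariates)
  m <- sum(vapply(pre, function(g) length(g$cols), integer(1))) *
    ncol(as.matrix(personality))
  set.seed(seed)
  out <- matrix(NA_real_, n_replicates, m)
  for (r in seq_len(n_replicates)) {
    ps <- unlist(lapply(pre, function(g) {
      sp <- g$ranked_sleep[sample.int(g$n), , drop = FALSE]
      sr <- sp - g$Q %*% crossprod(g$Q, sp)
      sr <- sweep(sr, 2, sqrt(colSums(sr^2)), "/")
      .rho_to_p(crossprod(g$presid, sr), g$df)
    }), use.names = FALSE)
    out[r, ] <- sort(ps, decreasing = TRUE)
  }
  out
}

#' Build the rank-wise permutation envelope
#'
#' Column-wise mean and 5th/95th percentiles (linear-interpolation
#' percentile rule) of the descending-sorted permutation p values.
#'
#' @param p_matrix replicates x ranks matrix from [permute_and_score()].
#' @return data.frame: `rank`, `mean_expected`, `p5`, `p95`.
#' @export
build_envelope <- function(p_matrix) {
  data.frame(
    rank = seq_len(ncol(p_matrix)),
    mean_expected = colMeans(p_matrix),
    p5 = apply(p_matrix, 2, stats::quantile, probs = 0.05, names = FALSE),
    p95 = apply(p_matrix, 2, stats::quantile, probs = 0.95, names = FALSE)
  )
}

#' Pair observed p values with the permutation envelope
#'
#' Sorts the observed p values in descending order, pairs them rank-wise
#' with the mean expected p values, and flags ranks where the observed
#' value leaves the envelope (`below` = smaller than the 5th percentile,
#' excess signal; `above` = larger than the 95th).
#'
#' @param observed_p vector of observed p values (same length as the
#'   envelope).
#' @param envelope data.frame from [build_envelope()].
#' @return data.frame: `rank`, `expected` (mean), `observed`, `p5`, `p95`,
#'   `flag` (`"inside"`, `"below"`, `"above"`).
#' @export
qq_points <- function(observed_p, envelope) {
  if (length(observed_p) != nrow(envelope))
    stop("length mismatch between observed p values and envelope")
  obs <- sort(observed_p, decreasing = TRUE)
  flag <- ifelse(obs < envelope$p5, "below",
                 ifelse(obs > envelope$p95, "above", "inside"))
  data.frame(rank = envelope$rank, expected = envelope$mean_expected,
             observed = obs, p5 = envelope$p5, p95 = envelope$p95,
             flag = flag, stringsAsFactors = FALSE)
}

#' Render the permutation QQ plot
#'
#' Diagonal identity line, gray 5th-95th percentile band, observed p values
#' as circles — all against the mean expected p value per rank.
#'
#' @param points data.frame from [qq_points()].
#' @param path output file; the extension selects the device (`.png` or
#'   `.svg`).
#' @param log_scale plot on -log10 axes (default FALSE).
#' @return `path`, invisibly.
#' @export
plot_qq <- function(points, path, log_scale = FALSE) {
  open_dev(path)
  on.exit(grDevices::dev.off())
  tr <- if (log_scale) function(p) -log10(pmax(p, 1e-300)) else identity
  xlab <- if (log_scale) "-log10 mean expected p" else "mean expected p"
  ylab <- if (log_scale) "-log10 p" else "p value"
  x <- tr(points$expected)
  graphics::plot(range(x), range(tr(c(points$observed, points$p5, points$p95))),
                 type = "n", xlab = xlab, ylab = ylab,
                 main = "Observed vs permutation-expected p values")
  graphics::polygon(c(x, rev(x)), c(tr(points$p5), rev(tr(points$p95))),
                    col = "gray85", border = NA)
  graphics::abline(0, 1)
  graphics::points(x, tr(points$observed), pch = 21, bg = "steelblue")
  invisible(path)
}

open_dev <- function(path, width = 7, height = 7) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         svg = grDevices::svg(path, width = width, height = height),
         stop("unsupported figure format: ", ext))
}
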