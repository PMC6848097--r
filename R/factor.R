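# Factor analysis of dichotomous items --------------------------------------
#
# The subscale machinery: tetrachoric correlation matrix -> parallel-analysis
# retention -> iterated principal-axis extraction -> promax rotation ->
# Thurstone regression factor scores, with factor labeling via marker items.

#' Parallel-analysis factor retention
#'
#' Horn's rule: the number of leading eigenvalues of `R` that exceed the
#' 95th percentile of the corresponding eigenvalue from `n_sims` random-data
#' correlation matrices of the same dimension and sample size. When the
#' observed matrix is tetrachoric, random data are simulated as independent
#' binary items matching the observed marginals and correlated with the
#' same tetrachoric estimator, so the null eigenvalue dispersion reflects
#' the (larger) sampling noise of tetrachoric estimates; for a Pearson
#' matrix, standard-normal data are used.
#'
#' @param R observed correlation matrix (PSD; smooth first if needed).
#' @param n sample size the matrix was estimated from.
#' @param n_sims number of random-data replicates (default 100).
#' @param seed RNG seed.
#' @param marginals optional vector of binary item means (length
#'   `ncol(R)`); if supplied, the binary/tetrachoric null is used.
#' @param quantile percentile of the null eigenvalue distribution
#'   (default 0.95).
#' @return integer `k`, with attribute `thresholds` (the per-position null
#'   percentiles) and `eigenvalues`.
#' @export
retain_k <- function(R, n, n_sims = 100L, seed = 1L, marginals = NULL,
                     quantile = 0.95) {
  p <- ncol(R)
  obs <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  sims <- matrix(NA_real_, n_sims, p)
  for (s in seq_len(n_sims)) {
    Rs <- if (is.null(marginals)) {
      stats::cor(matrix(stats::rnorm(n * p), n, p))
    } else {
      x <- sweep(matrix(stats::runif(n * p), n, p), 2, marginals, "<") + 0
      # guard against constant simulated items at extreme marginals
      const <- colMeans(x) %in% c(0, 1)
      if (any(const)) x[1, const] <- 1 - x[1, const]
      tetrachoric_matrix(x)
    }
    sims[s, ] <- eigen(Rs, symmetric = TRUE, only.values = TRUE)$values
  }
  thr <- apply(sims, 2, stats::quantile, probs = quantile, names = FALSE)
  exceeds <- obs > thr
  k <- if (exceeds[1]) which.min(c(exceeds, FALSE)) - 1L else 0L
  structure(as.integer(k), thresholds = thr, eigenvalues = obs)
}

#' Iterated principal-axis factor extraction
#'
#' Eigendecomposition of `R` with communalities on the diagonal, iterated
#' to convergence of the communalities (starting from squared multiple
#' correlations). Columns are ordered by explained variance. Heywood cases
#' (communalities above 1) are clipped to 1 and flagged.
#'
#' @param R PSD correlation matrix.
#' @param k number of factors (>= 1).
#' @param tol convergence tolerance on the communalities (default 1e-6).
#' @param max_iter iteration cap (default 1000); non-convergence is an
#'   error carrying the iteration trace.
#' @return unrotated loading matrix (items x k) with attributes
#'   `communalities`, `iterations`, `heywood` (logical).
#' @export
extract_paf <- function(R, k, tol = 1e-6, max_iter = 1000L) {
  p <- ncol(R)
  if (k < 1L || k >= p) stop("k must be in [1, p - 1]")
  # squared multiple correlations as starting communalities
  h <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) {
    r2 <- R; diag(r2) <- 0; apply(abs(r2), 1, max)
  })
  h <- pmin(pmax(h, 0), 0.995)
  heywood <- FALSE
  trace <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h
    e <- eigen(Rh, symmetric = TRUE)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
    h_new <- rowSums(L^2)
    if (any(h_new > 1)) {
      heywood <- TRUE
      h_new <- pmin(h_new, 1)
    }
    trace[it] <- max(abs(h_new - h))
    h <- h_new
    if (trace[it] < tol) {
      rownames(L) <- rownames(R)
      colnames(L) <- paste0("F", seq_len(k))
      return(structure(L, communalities = h, iterations = it,
                       heywood = heywood))
    }
  }
  stop(structure(class = c("paf_nonconvergence", "error", "condition"),
                 list(message = paste0("principal-axis iteration did not converge in ",
                                       max_iter, " iterations"),
                      call = sys.call(-1), trace = trace)))
}

#' Promax (oblique) rotation
#'
#' Varimax followed by a target-power-4 oblique transformation
#' (`stats::promax`). Column signs are fixed so each factor's
#' largest-magnitude pattern loading is positive, and columns are ordered
#' by decreasing sum of squared pattern loadings. `k = 1` returns the
#' input unchanged with a 1x1 factor correlation.
#'
#' @param loadings unrotated loading matrix from [extract_paf()].
#' @param m promax power (default 4).
#' @return list with `pattern` (items x k), `factor_corr` (k x k),
#'   `rotation` (method name).
#' @export
rotate_oblique <- function(loadings, m = 4) {
  k <- ncol(loadings)
  if (k == 1L) {
    s <- if (loadings[which.max(abs(loadings)), 1] < 0) -1 else 1
    return(list(pattern = loadings * s,
                factor_corr = matrix(1, 1, 1), rotation = "none"))
  }
  v <- stats::varimax(loadings, normalize = TRUE)
  pm <- tryCatch(stats::promax(unclass(v$loadings), m = m),
                 error = function(e) stop("singular promax transformation: ",
                                          conditionMessage(e)))
  P <- unclass(pm$loadings)
  U <- pm$rotmat
  phi <- solve(crossprod(U))
  # sign convention: largest-|loading| item of each factor loads positively
  sgn <- vapply(seq_len(k), function(j) {
    ifelse(P[which.max(abs(P[, j])), j] < 0, -1, 1)
  }, numeric(1))
  P <- sweep(P, 2, sgn, "*")
  phi <- phi * tcrossprod(sgn)
  ord <- order(colSums(P^2), decreasing = TRUE)
  P <- P[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  diag(phi) <- 1
  colnames(P) <- paste0("F", seq_len(k))
  dimnames(phi) <- list(colnames(P), colnames(P))
  list(pattern = P, factor_corr = phi, rotation = "promax")
}

# Assign subscale labels to rotated factors via marker items: greedy
# bijection maximizing the mean structure loading of each subscale's
# markers on its factor.
.label_factors <- function(structure_loadings, markers) {
  k <- ncol(structure_loadings)
  M <- vapply(markers, function(items) {
    colMeans(structure_loadings[intersect(items, rownames(structure_loadings)), ,
                                drop = FALSE])
  }, numeric(k))                     # k x n_labels
  labels <- character(k)
  M_work <- t(M)                     # labels x factors
  for (i in seq_len(min(k, nrow(M_work)))) {
    idx <- which(M_work == max(M_work), arr.ind = TRUE)[1, ]
    labels[idx[2]] <- rownames(M_work)[idx[1]]
    M_work[idx[1], ] <- -Inf
    M_work[, idx[2]] <- -Inf
  }
  labels[labels == ""] <- paste0("F", which(labels == ""))
  labels
}

#' Thurstone regression factor scores
#'
#' `scores = Z %*% solve(R) %*% S` where `Z` are the standardized item
#' responses and `S = pattern %*% factor_corr` the structure loadings;
#' columns are standardized to unit sample SD. Subjects with missing
#' responses are excluded (complete-response policy, consistent with the
#' sum-score functions).
#'
#' @param responses subjects x items binary matrix (same item set the
#'   solution was fitted on).
#' @param solution list with `pattern` and `factor_corr` ([rotate_oblique()]).
#' @param R the (smoothed) item correlation matrix used for fitting.
#' @return data.frame `subject_id` plus one standardized score column per
#'   factor (named by the solution's labels when present).
#' @export
factor_scores <- function(responses, solution, R) {
  if (!identical(rownames(R), colnames(responses)))
    stop("solution/response item sets differ")
  complete <- stats::complete.cases(responses)
  if (any(!complete))
    hp_log("factor_scores: excluded ", sum(!complete),
           " subject(s) with incomplete responses")
  r <- responses[complete, , drop = FALSE]
  Z <- scale(r)
  S <- solution$pattern %*% solution$factor_corr
  W <- solve(R, S)
  sc <- Z %*% W
  sc <- scale(sc, center = TRUE, scale = apply(sc, 2, stats::sd))
  labels <- solution$labels %||% colnames(solution$pattern)
  out <- data.frame(subject_id = rownames(r), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(sc))) out[[paste0("score_", labels[j])]] <- sc[, j]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the full factor model to dichotomous item responses
#'
#' Tetrachoric matrix, PSD smoothing, parallel-analysis retention (or a
#' fixed `k`), principal-axis extraction, promax rotation, marker-item
#' labeling, and Thurstone regression scores.
#'
#' @param responses subjects x items binary matrix.
#' @param k `"auto"` (parallel analysis) or a fixed integer.
#' @param markers named list of marker item ids per subscale label
#'   (defaults to the assignments of [default_scoring_key()]); used only
#'   to attach labels.
#' @param n_sims,seed parallel-analysis settings.
#' @return list of class `hps_factor_fit`: `R` (smoothed tetrachorics),
#'   `k`, `solution` (pattern, factor_corr, rotation, communalities,
#'   labels), `scores` (data.frame), `retention` (diagnostics or NULL).
#' @export
fit_hps_factors <- function(responses, k = "auto",
                            markers = split(default_scoring_key()$item,
                                            default_scoring_key()$subscale),
                            n_sims = 100L, seed = 1L) {
  complete <- stats::complete.cases(responses)
  resp <- responses[complete, , drop = FALSE]
  R0 <- tetrachoric_matrix(resp)
  R <- smooth_to_psd(R0)
  retention <- NULL
  if (identical(k, "auto")) {
    retention <- retain_k(R, n = nrow(resp), n_sims = n_sims, seed = seed,
                          marginals = colMeans(resp))
    k <- max(as.integer(retention), 1L)
  }
  L <- extract_paf(R, k)
  sol <- rotate_oblique(L)
  sol$communalities <- attr(L, "communalities")
  sol$labels <- if (k == length(markers))
    .label_factors(sol$pattern %*% sol$factor_corr, markers) else
      colnames(sol$pattern)
  fit <- list(R = R, k = as.integer(k), solution = sol,
              scores = factor_scores(resp, sol, R), retention = retention)
  class(fit) <- "hps_factor_fit"
  fit
}

#' @export
print.hps_factor_fit <- function(x, ...) {
  cat("Tetrachoric factor analysis:", nrow(x$solution$pattern), "items,",
      x$k, "factors (", x$solution$rotation, ")\n")
  cat("Labels:", paste(x$solution$labels, collapse = ", "), "\n")
  cat("Factor correlations:\n")
  print(round(x$solution$factor_corr, 3))
  invisible(x)
}
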