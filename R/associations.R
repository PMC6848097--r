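# Covariate-adjusted rank correlations and extreme-group tests ---------------

#' Partial Spearman correlation
#'
#' Rank -> residualize -> Pearson: `x`, `y` and each covariate are
#' average-rank transformed; ranked `x` and ranked `y` are residualized on
#' the ranked covariates plus an intercept by least squares; `rho` is the
#' Pearson correlation of the residuals. The two-sided p value uses
#' `t = rho * sqrt((n - 2 - k) / (1 - rho^2))` on `n - 2 - k` degrees of
#' freedom, with `k` the number of (non-constant) covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame of covariates (or NULL).
#' @return list `rho`, `p`, `n`, `k`.
#' @examples
#' partial_spearman(1:10, (1:10)^2)$rho  # 1: monotone, no adjustment
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  cov <- if (is.null(covariates)) NULL else as.matrix(covariates)
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(cov)) ok <- ok & apply(is.finite(cov), 1, all)
  x <- x[ok]; y <- y[ok]
  cov <- if (!is.null(cov)) cov[ok, , drop = FALSE]
  n <- length(x)
  if (!is.null(cov)) {
    const <- apply(cov, 2, function(v) length(unique(v)) < 2L)
    if (any(const)) {
      hp_log("partial_spearman: dropped constant covariate(s) ",
             paste(colnames(cov)[const], collapse = ", "))
      cov <- cov[, !const, drop = FALSE]
    }
    if (ncol(cov) == 0L) cov <- NULL
  }
  k <- if (is.null(cov)) 0L else ncol(cov)
  if (n < k + 4L) stop("too few complete observations (need >= k + 4)")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: constant variable after ranking")
  if (!is.null(cov)) {
    rc <- apply(cov, 2, rank)
    fit <- stats::lm.fit(cbind(1, rc), cbind(rx, ry))
    rx <- fit$residuals[, 1]; ry <- fit$residuals[, 2]
  } else {
    rx <- rx - mean(rx); ry <- ry - mean(ry)
  }
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - k
  p <- if (abs(rho) >= 1) 0 else
    2 * stats::pt(abs(rho) * sqrt(df / (1 - rho^2)), df, lower.tail = FALSE)
  list(rho = rho, p = p, n = n, k = k)
}

#' Grid of partial Spearman correlations
#'
#' One association record per (personality score, sleep variable) pair, in
#' deterministic score-major order with the sleep variables in the order
#' given. Complete cases are determined per pair, so instrument subsamples
#' of different sizes (e.g. actigraphy vs PSQI) are handled naturally.
#'
#' @param scores data.frame: `subject_id` + one column per personality score.
#' @param sleep data.frame: `subject_id` + one column per sleep variable
#'   (missing values allowed; e.g. subjects without actigraphy).
#' @param covariates data.frame: `subject_id` + covariate columns
#'   (default: adjust for nothing if NULL).
#' @param adjust_method multiple-test correction applied jointly across the
#'   grid (default `"BH"`; see [adjust_pvalues()]).
#' @return data.frame of association records: `personality_score`,
#'   `sleep_variable`, `rho`, `p`, `p_adj`, `n`.
#' @export
correlate_grid <- function(scores, sleep, covariates = NULL,
                           adjust_method = "BH") {
  score_cols <- setdiff(names(scores), "subject_id")
  sleep_cols <- setdiff(names(sleep), "subject_id")
  if (!length(score_cols) || !length(sleep_cols))
    stop("configuration error: scores and sleep tables need data columns")
  ids <- scores$subject_id
  sl <- sleep[match(ids, sleep$subject_id), sleep_cols, drop = FALSE]
  cv <- if (!is.null(covariates)) {
    as.matrix(covariates[match(ids, covariates$subject_id),
                         setdiff(names(covariates), "subject_id"), drop = FALSE])
  }
  rec <- vector("list", length(score_cols) * length(sleep_cols))
  i <- 0L
  for (sc in score_cols) {
    for (sv in sleep_cols) {
      i <- i + 1L
      r <- partial_spearman(scores[[sc]], sl[[sv]], cv)
      rec[[i]] <- data.frame(personality_score = sc, sleep_variable = sv,
                             rho = r$rho, p = r$p, n = r$n,
                             stringsAsFactors = FALSE)
    }
  }
  adjust_pvalues(do.call(rbind, rec), method = adjust_method)
}

#' Multiple-test correction across association records
#'
#' Applies [stats::p.adjust()] jointly across all records (one family);
#' default Benjamini-Hochberg, swappable to `"holm"` or `"bonferroni"`.
#'
#' @param records data.frame with a `p` column.
#' @param method correction method name.
#' @return `records` with a `p_adj` column.
#' @export
adjust_pvalues <- function(records, method = "BH") {
  records$p_adj <- stats::p.adjust(records$p, method = method)
  records
}

#' Compare two dependent (overlapping) correlations
#'
#' Steiger's Z for H0: `cor(x, a) = cor(x, b)` when `a` and `b` are
#' themselves correlated: Fisher-z difference scaled with the covariance
#' term for overlapping correlations.
#'
#' @param r_xa,r_xb the two correlations sharing variable `x`.
#' @param r_ab correlation between `a` and `b`.
#' @param n sample size (> 10).
#' @return list `z`, `p` (two-sided).
#' @export
compare_dependent_correlations <- function(r_xa, r_xb, r_ab, n) {
  if (any(abs(c(r_xa, r_xb, r_ab)) >= 1))
    stop("degenerate input: |r| must be < 1")
  if (n <= 10) stop("n must exceed 10")
  z1 <- atanh(r_xa); z2 <- atanh(r_xb)
  rbar <- (r_xa + r_xb) / 2
  s <- (r_ab * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_ab^2)) /
    (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - s)))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Top/bottom decile extreme groups
#'
#' Bottom group: scores at or below the 10th percentile (nearest-rank rule,
#' the `ceiling(decile * n)`-th order statistic); top group: at or above
#' the mirrored upper cut (the `n + 1 - ceiling(decile * n)`-th order
#' statistic). Boundary ties are all included, so group sizes can be
#' unequal.
#'
#' @param score numeric vector (>= 20 subjects).
#' @param decile tail fraction (default 0.1).
#' @return factor with levels `bottom`, `excluded`, `top`; attributes
#'   `cut_low`, `cut_high`.
#' @export
extreme_deciles <- function(score, decile = 0.1) {
  n <- length(score)
  if (n < 20L) stop("need at least 20 subjects for decile groups")
  if (length(unique(score)) < 2L)
    stop("degenerate score distribution: all values equal")
  srt <- sort(score)
  lo <- srt[ceiling(decile * n)]
  hi <- srt[n + 1L - ceiling(decile * n)]   # symmetric nearest rank from above
  g <- rep("excluded", n)
  g[score <= lo] <- "bottom"
  g[score >= hi] <- "top"
  if (lo >= hi) stop("degenerate score distribution: decile cutoffs overlap")
  structure(factor(g, levels = c("bottom", "excluded", "top")),
            cut_low = lo, cut_high = hi)
}

#' Kruskal-Wallis rank-sum test
#'
#' Average ranks with tie correction, chi-square reference with
#' `groups - 1` degrees of freedom (delegates to [stats::kruskal.test()]).
#' A response with all values identical gives `H = 0`, `p = 1`.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 nonempty groups).
#' @return list `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 nonempty groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = nlevels(groups) - 1L))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Extreme-group comparison over a panel of sleep variables
#'
#' Splits subjects into top/bottom decile groups of a personality score and
#' compares every sleep variable between the groups with Kruskal-Wallis
#' tests.
#'
#' @param score_table data.frame `subject_id` + the score column.
#' @param score_col name of the score column.
#' @param sleep data.frame `subject_id` + sleep variables.
#' @param decile tail fraction (default 0.1).
#' @return data.frame: `sleep_variable`, `H`, `p`, `n_top`, `n_bottom`,
#'   `median_top`, `median_bottom`.
#' @export
extreme_group_tests <- function(score_table, score_col, sleep, decile = 0.1) {
  g <- extreme_deciles(score_table[[score_col]], decile)
  ids <- score_table$subject_id
  sl <- sleep[match(ids, sleep$subject_id), , drop = FALSE]
  keep <- g != "excluded"
  out <- lapply(setdiff(names(sleep), "subject_id"), function(sv) {
    v <- sl[[sv]][keep]
    gg <- droplevels(g[keep])
    ok <- is.finite(v)
    kt <- kruskal_wallis(v[ok], gg[ok])
    data.frame(sleep_variable = sv, H = kt$H, p = kt$p,
               n_top = sum(gg[ok] == "top"), n_bottom = sum(gg[ok] == "bottom"),
               median_top = stats::median(v[ok][gg[ok] == "top"]),
               median_bottom = stats::median(v[ok][gg[ok] == "bottom"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
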