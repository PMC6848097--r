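# Cross-validated incremental prediction -------------------------------------

#' Assign subjects to k folds
#'
#' Seeded random partition into `k` folds whose sizes differ by at most one.
#'
#' @param n number of subjects (>= k).
#' @param k number of folds (>= 2; default 10).
#' @param seed RNG seed.
#' @return integer vector of fold labels in `1..k`.
#' @export
kfold_assign <- function(n, k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("n must be at least k")
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# OLS with training-fold standardization and rank-deficiency handling:
# returns held-out predictions. Columns that are (near-)linearly dependent
# on earlier ones within the training fold — sleep panels contain exact
# accounting identities such as offset = onset + duration + WASO, blurred
# only by storage rounding — are treated as rank-deficient and dropped
# (pivoted QR with a 1e-2 relative tolerance), since they would otherwise
# receive exploding, non-generalizing coefficients.
.cv_predict_ols <- function(y, X, folds, tol = 1e-2) {
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    keep <- sd_ > 0
    Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], "/")
    fit <- stats::lm.fit(cbind(1, Z[tr, , drop = FALSE]), y[tr], tol = tol)
    beta <- fit$coefficients
    if (anyNA(beta)) {
      hp_log("cv: dropped ", sum(is.na(beta)),
             " rank-deficient predictor(s) in fold ", f)
      beta[is.na(beta)] <- 0
    }
    pred[!tr] <- drop(cbind(1, Z[!tr, , drop = FALSE]) %*% beta)
  }
  pred
}

#' Cross-validated incremental out-of-sample R-squared
#'
#' Fits, on identical folds, a covariate-only model and a covariates +
#' extra-predictors model by OLS; predictors are standardized on each
#' training fold only (no leakage). Out-of-sample R-squared is pooled over
#' all held-out predictions as `1 - SSE/SST`, with SST about the
#' full-sample mean of `y`; the incremental value is the difference of the
#' two R-squared values.
#'
#' @param y response vector.
#' @param base_predictors matrix/data.frame of covariates.
#' @param extra_predictors matrix/data.frame of additional predictors.
#' @param folds fold labels from [kfold_assign()] (or `NULL` to draw
#'   ten folds with `seed`).
#' @param seed seed used when `folds` is NULL.
#' @param target name to attach to the result.
#' @return list of class `cv_result`: `target`, `r2_base`, `r2_full`,
#'   `incremental`, `folds`, `seed`.
#' @export
cv_incremental_r2 <- function(y, base_predictors, extra_predictors,
                              folds = NULL, seed = 1L, target = "y") {
  Xb <- as.matrix(base_predictors)
  Xe <- as.matrix(extra_predictors)
  ok <- is.finite(y) & apply(is.finite(Xb), 1, all) & apply(is.finite(Xe), 1, all)
  y <- y[ok]; Xb <- Xb[ok, , drop = FALSE]; Xe <- Xe[ok, , drop = FALSE]
  if (is.null(folds)) folds <- kfold_assign(length(y), 10L, seed)
  else folds <- folds[ok]
  sst <- sum((y - mean(y))^2)
  r2 <- function(pred) 1 - sum((y - pred)^2) / sst
  res <- list(
    target = target,
    r2_base = r2(.cv_predict_ols(y, Xb, folds)),
    r2_full = r2(.cv_predict_ols(y, cbind(Xb, Xe), folds)),
    folds = folds, seed = seed
  )
  res$incremental <- res$r2_full - res$r2_base
  class(res) <- "cv_result"
  res
}

#' Incremental predictive value of sleep for each personality score
#'
#' For every target score, contrasts out-of-sample R-squared of
#' covariates-only vs covariates + sleep variables under shared ten-fold
#' assignments.
#'
#' @param scores data.frame `subject_id` + target score columns.
#' @param sleep data.frame `subject_id` + sleep variables.
#' @param covariates data.frame `subject_id` + covariate columns
#'   (e.g. age, sex, SES).
#' @param targets character vector of score columns (default: all).
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return data.frame: `target`, `r2_base`, `r2_full`, `incremental`, `n`.
#' @export
cv_predict_scores <- function(scores, sleep, covariates,
                              targets = setdiff(names(scores), "subject_id"),
                              k = 10L, seed = 1L) {
  ids <- scores$subject_id
  Xe <- as.matrix(sleep[match(ids, sleep$subject_id),
                        setdiff(names(sleep), "subject_id"), drop = FALSE])
  Xb <- as.matrix(covariates[match(ids, covariates$subject_id),
                             setdiff(names(covariates), "subject_id"),
                             drop = FALSE])
  out <- lapply(targets, function(tg) {
    y <- scores[[tg]]
    ok <- is.finite(y) & apply(is.finite(Xb), 1, all) & apply(is.finite(Xe), 1, all)
    folds <- kfold_assign(sum(ok), k, seed)
    r <- cv_incremental_r2(y[ok], Xb[ok, , drop = FALSE], Xe[ok, , drop = FALSE],
                           folds = folds, target = tg)
    data.frame(target = tg, r2_base = r$r2_base, r2_full = r$r2_full,
               incremental = r$incremental, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
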