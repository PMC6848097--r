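test_that("parallel analysis retains no factors in pure noise", {
  set.seed(6)
  R <- cor(matrix(rnorm(1500 * 8), 1500, 8))
  k <- retain_k(R, n = 1500, n_sims = 60, seed = 1)
  expect_lte(as.integer(k), 1L)
})

test_that("parallel analysis finds one factor in a rank-one structure", {
  R <- matrix(0.5, 10, 10); diag(R) <- 1
  expect_equal(as.integer(retain_k(R, n = 2000, n_sims = 60, seed = 2)), 1L)
})

test_that("three factors are retained on the default synthetic item model", {
  cfg <- cohort_config(n_subjects = 2861, n_actigraphy = 10, seed = 77)
  x <- generate_item_responses(generate_subjects(cfg), cfg)
  R <- smooth_to_psd(tetrachoric_matrix(x))
  k <- retain_k(R, n = nrow(x), n_sims = 100, seed = 3,
                marginals = colMeans(x))
  expect_equal(as.integer(k), 3L)
})

test_that("principal-axis extraction solves the closed-form one-factor model", {
  expect_true(all(abs(extract_paf(diag(8) + 0, 1)) < 1e-8))
  lam <- rep(0.8, 6)
  R <- tcrossprod(lam); diag(R) <- 1
  L <- extract_paf(R, 1)
  expect_lt(max(abs(abs(L) - 0.8)), 1e-3)
  expect_equal(attr(L, "communalities"), rep(0.64, 6), tolerance = 1e-3)
})

test_that("the factor model reproduces the synthetic tetrachoric matrix", {
  cfg <- cohort_config(n_subjects = 2000, n_actigraphy = 10, seed = 78)
  x <- generate_item_responses(generate_subjects(cfg), cfg)
  R <- smooth_to_psd(tetrachoric_matrix(x))
  L <- extract_paf(R, 3)
  sol <- rotate_oblique(L)
  Rhat <- sol$pattern %*% sol$factor_corr %*% t(sol$pattern)
  resid <- (R - Rhat)[upper.tri(R)]
  expect_lt(sqrt(mean(resid^2)), 0.05)   # RMSR of the off-diagonals
})

test_that("promax rotation respects simple structure, signs, and ordering", {
  # one factor: rotation is the identity up to sign
  lam <- matrix(seq(0.4, 0.9, length.out = 6), ncol = 1)
  sol1 <- rotate_oblique(lam)
  expect_equal(sol1$pattern, lam)
  expect_equal(sol1$factor_corr, matrix(1, 1, 1))
  # orthogonal block structure: factor correlations near identity
  L <- rbind(cbind(runif(6, 0.6, 0.8), 0), cbind(0, runif(6, 0.6, 0.8)))
  # rotate by a random orthogonal matrix to hide the structure
  set.seed(8)
  Q <- qr.Q(qr(matrix(rnorm(4), 2)))
  sol <- rotate_oblique(L %*% Q)
  expect_lt(max(abs(sol$factor_corr[upper.tri(sol$factor_corr)])), 0.05)
  for (j in 1:2)
    expect_gt(sol$pattern[which.max(abs(sol$pattern[, j])), j], 0)
  expect_true(diff(colSums(sol$pattern^2)) <= 0)
})

test_that("rotated factors align with the generating item blocks", {
  cfg <- cohort_config(n_subjects = 2861, n_actigraphy = 10, seed = 79)
  x <- generate_item_responses(generate_subjects(cfg), cfg)
  fit <- fit_hps_factors(x, k = 3)
  it <- cfg$item_table
  # Tucker congruence of each rotated factor with its generating block
  gen <- vapply(c("core", "vitality", "ordinariness"), function(f)
    ifelse(it$factor == f, it$loading, 0), numeric(44))
  congr <- abs(crossprod(gen, fit$solution$pattern)) /
    outer(sqrt(colSums(gen^2)), sqrt(colSums(fit$solution$pattern^2)))
  best <- apply(congr, 1, max)
  expect_true(all(best > 0.95))
  # marker-item labels form a bijection onto the three subscales
  expect_setequal(fit$solution$labels, c("core", "vitality", "ordinariness"))
})

test_that("factor scores are standardized and recover the latent truth", {
  cfg <- cohort_config(n_subjects = 2861, n_actigraphy = 10, seed = 80)
  s <- generate_subjects(cfg)
  x <- generate_item_responses(s, cfg)
  fit <- fit_hps_factors(x, k = 3)
  for (col in grep("^score_", names(fit$scores), value = TRUE)) {
    expect_lt(abs(mean(fit$scores[[col]])), 1e-6)
    expect_lt(abs(sd(fit$scores[[col]]) - 1), 0.05)
  }
  m <- match(fit$scores$subject_id, s$subject_id)
  expect_gt(cor(fit$scores$score_core, s$latent_core[m]), 0.8)
  expect_gt(cor(fit$scores$score_vitality, s$latent_vitality[m]), 0.8)
  expect_gt(cor(fit$scores$score_ordinariness, s$latent_ordinariness[m]), 0.8)
})

test_that("item order does not change the labeled subscale scores", {
  cfg <- cohort_config(n_subjects = 1500, n_actigraphy = 10, seed = 81)
  x <- generate_item_responses(generate_subjects(cfg), cfg)
  fit1 <- fit_hps_factors(x, k = 3)
  set.seed(10)
  perm <- sample(ncol(x))
  fit2 <- fit_hps_factors(x[, perm], k = 3)
  for (col in c("score_core", "score_vitality", "score_ordinariness"))
    expect_equal(fit2$scores[[col]], fit1$scores[[col]], tolerance = 1e-10)
})

test_that("sum-scores track factor scores with slightly weaker associations", {
  cfg <- cohort_config(n_subjects = 20000, n_actigraphy = 20000, seed = 82)
  tb <- cohort_tables(cfg)
  key <- default_scoring_key(cfg$item_table)
  sums <- score_hps_subscales_sum(tb$cohort$items, key)
  ids <- tb$scores$subject_id
  m <- match(ids, tb$panel$subject_id)
  cv <- qq_blocks(tb)$C
  for (v in c("isd_waso", "isd_duration")) {
    y <- tb$panel[[v]][m]
    rho_f <- partial_spearman(tb$scores$score_core, y, cv)$rho
    rho_s <- partial_spearman(sums$sum_core[match(ids, sums$subject_id)], y, cv)$rho
    expect_equal(sign(rho_s), sign(rho_f))
    expect_lte(abs(rho_s), abs(rho_f) + 0.02)
  }
})
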