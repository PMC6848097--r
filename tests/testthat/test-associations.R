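test_that("partial Spearman reduces to Spearman and handles monotone signals", {
  r <- partial_spearman(1:10, (1:10)^2, covariates = cbind(rep(1, 10)))
  expect_equal(r$rho, 1)
  expect_equal(r$k, 0L)    # constant covariate dropped
  # invariance under strictly increasing transforms
  set.seed(14)
  x <- rnorm(60); y <- 0.4 * x + rnorm(60); cv <- cbind(rnorm(60))
  a <- partial_spearman(x, y, cv)
  b <- partial_spearman(exp(x), y^3 + 2 * y, cv)
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
  expect_error(partial_spearman(rep(1, 30), rnorm(30)), "constant")
})

test_that("partial Spearman equals an independently composed oracle", {
  set.seed(15)
  for (i in 1:50) {
    x <- rnorm(30); y <- rnorm(30); cv <- cbind(a = rnorm(30), b = rnorm(30))
    got <- partial_spearman(x, y, cv)
    rx <- resid(lm(rank(x) ~ apply(cv, 2, rank)))
    ry <- resid(lm(rank(y) ~ apply(cv, 2, rank)))
    rho <- cor(rx, ry)
    tt <- rho * sqrt((30 - 2 - 2) / (1 - rho^2))
    expect_equal(got$rho, rho, tolerance = 1e-10)
    expect_equal(got$p, 2 * pt(abs(tt), 26, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("covariate adjustment holds the type-I error at its nominal level", {
  set.seed(16)
  n <- 771
  nsim <- 2000
  rej <- logical(nsim)
  for (i in seq_len(nsim)) {
    age <- runif(n, 60, 82)
    x <- rnorm(n)                      # independent of y given age
    y <- age + rnorm(n, 0, 5)
    rej[i] <- partial_spearman(x, y, cbind(age))$p < 0.05
  }
  bound <- 2.576 * sqrt(0.05 * 0.95 / nsim)
  expect_lt(abs(mean(rej) - 0.05), bound)
})

test_that("the association grid yields one record per pair in fixed order", {
  cfg <- small_config(n = 250, seed = 17)
  tb <- cohort_tables(cfg)
  g <- correlate_grid(tb$scores, tb$panel, tb$covars)
  expect_equal(nrow(g), 84)
  expect_equal(length(unique(g$personality_score)), 4)
  expect_equal(length(unique(g$sleep_variable)), 21)
  # score-major deterministic ordering
  expect_equal(g$personality_score,
               rep(setdiff(names(tb$scores), "subject_id"), each = 21))
  expect_true(all(g$p_adj >= g$p))
  expect_true(all(g$rho >= -1 & g$rho <= 1))
  # 1 x 1 grid reduces to partial_spearman
  one <- correlate_grid(tb$scores[, c("subject_id", "hps_total")],
                        tb$panel[, c("subject_id", "isd_waso")], tb$covars)
  m <- match(tb$scores$subject_id, tb$panel$subject_id)
  ref <- partial_spearman(tb$scores$hps_total, tb$panel$isd_waso[m],
                          qq_blocks(tb)$C)
  expect_equal(one$rho, ref$rho)
  expect_equal(one$n, ref$n)
  # duplicated sleep column duplicates the record exactly
  dup <- tb$panel[, c("subject_id", "isd_waso", "isd_waso")]
  names(dup) <- c("subject_id", "v1", "v2")
  two <- correlate_grid(tb$scores[, c("subject_id", "hps_total")], dup, tb$covars)
  expect_equal(two$rho[1], two$rho[2])
  expect_equal(two$p[1], two$p[2])
})

test_that("Benjamini-Hochberg adjustment follows the step-up procedure", {
  rec <- data.frame(p = rep(0.01, 84))
  expect_equal(adjust_pvalues(rec)$p_adj, rep(0.01, 84))
  expect_equal(adjust_pvalues(data.frame(p = 0.03))$p_adj, 0.03)
  out <- adjust_pvalues(data.frame(p = c(0.01, 0.02, 0.04, 0.8)))
  expect_equal(out$p_adj, c(0.04, 0.04, 4 * 0.04 / 3, 0.8), tolerance = 1e-12)
  holm <- adjust_pvalues(data.frame(p = c(0.01, 0.04)), method = "holm")
  expect_equal(holm$p_adj, c(0.02, 0.04))
})

test_that("Steiger's Z is symmetric, antisymmetric, and correctly scaled", {
  expect_equal(compare_dependent_correlations(0.3, 0.3, 0.5, 500)$z, 0)
  expect_equal(compare_dependent_correlations(0.3, 0.3, 0.5, 500)$p, 1)
  a <- compare_dependent_correlations(0.3, 0.1, 0.7, 1766)
  b <- compare_dependent_correlations(0.1, 0.3, 0.7, 1766)
  expect_equal(a$z, -b$z)
  expect_error(compare_dependent_correlations(1, 0.5, 0.2, 100), "degenerate")
  # Monte Carlo check of the null scaling: empirical SD of the Fisher-z
  # difference under matching trivariate structure vs Steiger's term
  set.seed(18)
  n <- 500; reps <- 4000
  rho_x <- 0.2; r_ab <- 0.7
  Sig <- matrix(c(1, rho_x, rho_x, rho_x, 1, r_ab, rho_x, r_ab, 1), 3)
  d <- replicate(reps, {
    z <- matrix(rnorm(n * 3), n) %*% chol(Sig)
    atanh(cor(z[, 1], z[, 2])) - atanh(cor(z[, 1], z[, 3]))
  })
  rbar <- rho_x
  s <- (r_ab * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_ab^2)) /
    (1 - rbar^2)^2
  theory <- sqrt(2 * (1 - s) / (n - 3))
  expect_lt(abs(sd(d) / theory - 1), 0.1)
})

test_that("decile extreme groups follow the nearest-rank rule with ties", {
  g <- extreme_deciles(1:100)
  expect_equal(sum(g == "bottom"), 10)
  expect_equal(sum(g == "top"), 10)
  expect_equal(which(g == "top"), 91:100)
  # heavy ties at the upper cut: every tied subject joins the top group
  x <- c(1:80, rep(90, 20))
  g2 <- extreme_deciles(x)
  expect_equal(sum(g2 == "top"), 20)
  expect_error(extreme_deciles(rep(5, 50)), "degenerate")
  expect_error(extreme_deciles(1:10), "20 subjects")
  # integer-valued scores at the study scale give tie-inflated groups
  cfg <- cohort_config(n_subjects = 771, n_actigraphy = 10, seed = 19)
  tot <- score_hps_total(generate_item_responses(generate_subjects(cfg), cfg),
                         default_scoring_key(cfg$item_table))
  g3 <- extreme_deciles(tot$hps_total)
  expect_gte(sum(g3 == "top"), 58); expect_lte(sum(g3 == "top"), 97)
  expect_gte(sum(g3 == "bottom"), 58); expect_lte(sum(g3 == "bottom"), 97)
})

test_that("Kruskal-Wallis matches the rank-sum formula and rank invariance", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # direct formula: 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1)
  expect_equal(kw$H, 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7,
               tolerance = 1e-12)
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)
  same <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$H, 0)
  expect_equal(kruskal_wallis(rep(4, 9), rep(c("a", "b", "c"), 3))$p, 1)
  set.seed(20)
  v <- rnorm(40); gr <- rep(c("a", "b"), 20)
  expect_equal(kruskal_wallis(v, gr)$H, kruskal_wallis(exp(v), gr)$H,
               tolerance = 1e-12)
})

test_that("extreme-group tests report sizes and medians per variable", {
  cfg <- small_config(n = 300, seed = 21)
  tb <- cohort_tables(cfg)
  ext <- extreme_group_tests(tb$scores, "hps_total", tb$panel)
  expect_equal(nrow(ext), 21)
  expect_true(all(ext$H >= 0))
  expect_true(all(ext$n_top > 0 & ext$n_bottom > 0))
})
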