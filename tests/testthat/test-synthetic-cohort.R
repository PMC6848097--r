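test_that("generation is deterministic given the seed", {
  cfg <- small_config(n = 120, seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$items, b$items)
  expect_identical(a$nights, b$nights)
  expect_identical(a$psqi, b$psqi)
})

test_that("latent factors follow the configured correlation structure", {
  cfg <- cohort_config(n_subjects = 50000, n_actigraphy = 10, seed = 21,
                       factor_corr = diag(3))
  dimnames(cfg$factor_corr) <- list(c("core", "vitality", "ordinariness"),
                                    c("core", "vitality", "ordinariness"))
  s <- generate_subjects(cfg)
  z <- as.matrix(s[, c("latent_core", "latent_vitality", "latent_ordinariness")])
  cc <- cor(z)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.02)
  expect_lt(max(abs(colMeans(z))), 0.02)

  cfg2 <- cohort_config(n_subjects = 50000, n_actigraphy = 10, seed = 22)
  cfg2$factor_corr["core", "vitality"] <- 0.4
  cfg2$factor_corr["vitality", "core"] <- 0.4
  s2 <- generate_subjects(cfg2)
  expect_lt(abs(cor(s2$latent_core, s2$latent_vitality) - 0.4), 0.02)
})

test_that("non-positive-definite factor correlations are rejected", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  dimnames(bad) <- list(c("core", "vitality", "ordinariness"),
                        c("core", "vitality", "ordinariness"))
  expect_error(cohort_config(factor_corr = bad), "positive definite")
  it <- default_item_table(); it$loading[1] <- 1.2
  expect_error(cohort_config(item_table = it), "loadings")
  expect_error(cohort_config(nights_dist = c("5" = 0.5, "7" = 0.6)),
               "probability")
})

test_that("item responses obey the probit threshold model", {
  # null model: loadings 0, thresholds 0 -> means 1/2, tetrachorics ~ 0
  it <- default_item_table()
  it$loading <- 0; it$threshold <- 0
  cfg <- cohort_config(n_subjects = 50000, n_actigraphy = 10, seed = 31,
                       item_table = it)
  x <- generate_item_responses(generate_subjects(cfg), cfg)
  expect_lt(max(abs(colMeans(x) - 0.5)), 0.02)
  R <- tetrachoric_matrix(x[, 1:10])
  expect_lt(max(abs(R[upper.tri(R)])), 0.025)

  # closed form: same-factor items with loadings a1 = a2 = 0.8 imply
  # tetrachoric a1 * a2 = 0.64
  it2 <- default_item_table()
  it2$loading[1:2] <- 0.8
  cfg2 <- cohort_config(n_subjects = 50000, n_actigraphy = 10, seed = 32,
                        item_table = it2)
  x2 <- generate_item_responses(generate_subjects(cfg2), cfg2)
  expect_lt(abs(tetrachoric(x2[, 1], x2[, 2]) - 0.64), 0.03)

  # degenerate threshold: b very large -> nothing endorsed
  it3 <- default_item_table(); it3$threshold <- 20
  cfg3 <- small_config(n = 200, seed = 33, item_table = it3)
  x3 <- generate_item_responses(generate_subjects(cfg3), cfg3)
  expect_true(all(x3 == 0L))
})

test_that("nights distribution and point masses behave as configured", {
  cfg <- cohort_config(n_subjects = 10000, n_actigraphy = 10000, seed = 41)
  ng <- generate_nights(generate_subjects(cfg), cfg)
  nn <- table(ng$subject_id)
  expect_true(all(nn >= 5 & nn <= 7))
  expect_lt(abs(mean(nn) - 6.9), 0.05)

  cfg7 <- small_config(n = 150, seed = 42, nights_dist = c("7" = 1.0))
  ng7 <- generate_nights(generate_subjects(cfg7), cfg7)
  expect_true(all(table(ng7$subject_id) == 7))
})

test_that("night records satisfy the domain invariants", {
  cfg <- small_config(n = 500, seed = 43)
  ng <- generate_nights(generate_subjects(cfg), cfg)
  expect_true(all(ng$sleep_duration > 0))
  expect_true(all(ng$waso >= 0))
  expect_true(all(ng$sleep_onset_latency >= 0))
  expect_true(all(ng$nwak >= 0 & ng$nwak == round(ng$nwak)))
  # stored offset - onset equals duration + WASO up to clock rounding
  ons <- linearize_clock_time(ng$sleep_onset_time)
  off <- linearize_clock_time(ng$sleep_offset_time)
  expect_lt(max(abs((off - ons) - (ng$sleep_duration + ng$waso))), 1.5)
})

test_that("zeroed cross-domain effects leave sleep independent of the traits", {
  cfg <- null_config(cohort_config(n_subjects = 20000, n_actigraphy = 20000,
                                   seed = 51))
  s <- generate_subjects(cfg)
  ss <- summarize_sleep(generate_nights(s, cfg))
  m <- match(ss$subject_id, s$subject_id)
  cv <- cbind(age = s$age[m], sex = s$sex[m])
  for (v in c("isd_duration", "isd_waso", "mean_waso"))
    expect_lt(abs(partial_spearman(s$latent_core[m], ss[[v]], cv)$rho), 0.025)
  ps <- score_psqi(generate_psqi(s, cfg))
  m2 <- match(ps$subject_id, s$subject_id)
  cv2 <- cbind(age = s$age[m2], sex = s$sex[m2])
  for (v in c("psqi_total", "psqi_duration"))
    expect_lt(abs(partial_spearman(s$latent_core[m2], ps[[v]], cv2)$rho), 0.025)
})

test_that("configured variability and PSQI effects are recovered in sign and size", {
  # population value of the configured (core, ISD WASO) association is 0.12;
  # a single n = 20,000 cohort must land within +/- 0.03
  cfg <- cohort_config(n_subjects = 20000, n_actigraphy = 20000, seed = 52)
  s <- generate_subjects(cfg)
  ss <- summarize_sleep(generate_nights(s, cfg))
  m <- match(ss$subject_id, s$subject_id)
  cv <- cbind(age = s$age[m], sex = s$sex[m])
  rho_waso <- partial_spearman(s$latent_core[m], ss$isd_waso, cv)$rho
  expect_lt(abs(rho_waso - 0.12), 0.03)
  # positive core effect on log night SD of duration shows up in ISD(duration)
  expect_gt(partial_spearman(s$latent_core[m], ss$isd_duration, cv)$rho, 0.05)
  # negative configured core -> reported duration effect recovers its sign
  ps <- score_psqi(generate_psqi(s, cfg))
  m2 <- match(ps$subject_id, s$subject_id)
  expect_lt(partial_spearman(s$latent_core[m2], ps$psqi_duration,
                             cbind(s$age[m2], s$sex[m2]))$rho, 0)
})

test_that("written cohort files round-trip and keep truth separate", {
  dir <- withr::local_tempdir()
  cfg <- small_config(n = 60, seed = 61)
  co <- generate_cohort(cfg)
  paths <- write_cohort(co, dir)
  subj <- read_table_csv(file.path(dir, "subjects.csv"))
  expect_false(any(grepl("latent", names(subj))))
  truth <- read_table_csv(file.path(dir, "truth.csv"))
  expect_equal(truth$latent_core, co$subjects$latent_core, tolerance = 1e-12)
  ng <- read_table_csv(file.path(dir, "nights.csv"))
  expect_equal(nrow(ng), nrow(co$nights))
  expect_match(ng$sleep_onset_time[1], "^[0-2][0-9]:[0-5][0-9]$")
})
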