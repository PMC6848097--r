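test_that("HPS total is the keyed sum with floors and ceilings", {
  key <- default_scoring_key()
  items <- key$item
  none <- matrix(0L, 2, 44, dimnames = list(c("a", "b"), items))
  # all zero: positively keyed items contribute 0, reverse-keyed contribute 1
  tot0 <- score_hps_total(none, key)
  expect_equal(tot0$hps_total, rep(sum(key$direction == -1), 2))
  # key everything positive: 0 -> 0, all-ones -> 44
  key_pos <- key; key_pos$direction <- 1L
  expect_equal(score_hps_total(none, key_pos)$hps_total, c(0, 0))
  all1 <- matrix(1L, 1, 44, dimnames = list("c", items))
  expect_equal(score_hps_total(all1, key_pos)$hps_total, 44)
})

test_that("scores match a brute-force keyed sum on random matrices", {
  key <- default_scoring_key()
  set.seed(13)
  for (i in 1:5) {
    x <- matrix(rbinom(20 * 44, 1, 0.4), 20, 44,
                dimnames = list(sprintf("s%02d", 1:20), key$item))
    got <- score_hps_total(x, key)$hps_total
    want <- apply(x, 1, function(r)
      sum(ifelse(key$direction[match(colnames(x), key$item)] == 1, r, 1 - r)))
    expect_equal(got, unname(want))
    # subscale sums via an independent groupby oracle (hypomanic pole)
    sub <- score_hps_subscales_sum(x, key, pole = "hypomanic")
    for (sc in c("core", "vitality", "ordinariness")) {
      cols <- key$item[key$subscale == sc]
      w <- apply(x[, cols, drop = FALSE], 1, function(r)
        sum(ifelse(key$direction[match(cols, key$item)] == 1, r, 1 - r)))
      expect_equal(sub[[paste0("sum_", sc)]], unname(w))
    }
    # consistent-key decomposition: total = sum of subscale sums
    expect_equal(got, sub$sum_core + sub$sum_vitality + sub$sum_ordinariness)
    # native pole flips ordinariness to its own direction
    nat <- score_hps_subscales_sum(x, key, pole = "native")
    expect_equal(nat$sum_ordinariness,
                 sum(key$subscale == "ordinariness") - sub$sum_ordinariness)
  }
})

test_that("subjects with missing items are excluded and unknown items rejected", {
  key <- default_scoring_key()
  x <- matrix(1L, 3, 44, dimnames = list(c("a", "b", "c"), key$item))
  x[2, 5] <- NA
  expect_equal(score_hps_total(x, key)$subject_id, c("a", "c"))
  colnames(x)[1] <- "mystery"
  expect_error(score_hps_total(x, key), "key mismatch")
})

psqi_row <- function(quality = 0, latency_min = 5, latency_freq = 0,
                     duration_h = 8, bedtime = "22:30", getup_time = "07:00",
                     d = 0, medication = 0, sleepiness = 0, enthusiasm = 0) {
  out <- data.frame(subject_id = "p1", bedtime = bedtime,
                    getup_time = getup_time, latency_min = latency_min,
                    latency_freq = latency_freq, duration_h = duration_h,
                    quality = quality, medication = medication,
                    sleepiness = sleepiness, enthusiasm = enthusiasm,
                    stringsAsFactors = FALSE)
  for (j in 1:9) out[[paste0("d", j)]] <- d
  out
}

test_that("PSQI components apply the shipped cut-points", {
  # reported efficiency 0.90 -> efficiency component 0 (>= 85 % band)
  r <- psqi_row(duration_h = 7.65, bedtime = "22:30", getup_time = "07:00")
  s <- score_psqi(r)
  expect_equal(s$psqi_efficiency, 7.65 * 60 / 510, tolerance = 1e-12)  # 0.9
  expect_equal(s$comp_efficiency, 0L)
  # all components at the worst band -> total 21
  worst <- psqi_row(quality = 3, latency_min = 90, latency_freq = 3,
                    duration_h = 4, bedtime = "21:00", getup_time = "07:00",
                    d = 3, medication = 3, sleepiness = 3, enthusiasm = 3)
  expect_equal(score_psqi(worst)$psqi_total, 21)
  # all components at the best band -> total 0
  expect_equal(score_psqi(psqi_row())$psqi_total, 0)
})

test_that("worsening any single PSQI item never decreases the total", {
  base <- psqi_row(quality = 1, latency_min = 20, latency_freq = 1,
                   duration_h = 6.5, d = 1, medication = 1, sleepiness = 1,
                   enthusiasm = 1)
  t0 <- score_psqi(base)$psqi_total
  worsen <- list(quality = 2, latency_min = 70, latency_freq = 3,
                 duration_h = 4.5, d1 = 3, medication = 3, sleepiness = 3,
                 enthusiasm = 3)
  for (nm in names(worsen)) {
    mod <- base
    mod[[nm]] <- worsen[[nm]]
    expect_gte(score_psqi(mod)$psqi_total, t0)
  }
})

test_that("scores stay within instrument ranges on generated cohorts", {
  cfg <- small_config(n = 400, seed = 81)
  co <- generate_cohort(cfg)
  tot <- score_hps_total(co$items, default_scoring_key(cfg$item_table))
  expect_true(all(tot$hps_total >= 0 & tot$hps_total <= 44))
  ps <- score_psqi(co$psqi)
  expect_true(all(ps$psqi_total >= 0 & ps$psqi_total <= 21))
  comp <- as.matrix(ps[, grep("^comp_", names(ps))])
  expect_true(all(comp >= 0 & comp <= 3))
  expect_equal(ps$psqi_total, unname(rowSums(comp)))
  expect_length(psqi_variables(), 7)
})

test_that("PSQI subjects with missing items are excluded with a log entry", {
  r <- rbind(psqi_row(), psqi_row())
  r$subject_id <- c("p1", "p2")
  r$latency_min[2] <- NA
  expect_message(s <- score_psqi(r), "excluded 1")
  expect_equal(s$subject_id, "p1")
})
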