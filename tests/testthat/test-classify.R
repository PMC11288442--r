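test_that("trial summaries reproduce closed-form and oracle statistics", {
  one <- summarize_trials(tibble::tibble(
    duration_s = 0.68, hd_min_mm = 3, hd_max_mm = -2, pd_min_mm = 1,
    pd_max_mm = 0.5
  ))
  expect_equal(one$n_strides, 1L)
  expect_equal(one$mean_hd_min_mm, 3)
  expect_equal(one$sd_hd_min_mm, 0)

  two <- summarize_trials(tibble::tibble(
    duration_s = c(0.7, 0.7), hd_min_mm = c(5, -5), hd_max_mm = 0,
    pd_min_mm = 0, pd_max_mm = 0
  ))
  expect_equal(two$mean_hd_min_mm, 0)
  expect_equal(two$sd_hd_min_mm, 7.0710678, tolerance = 1e-7)

  set.seed(406)
  st <- tibble::tibble(
    duration_s = rnorm(50, 0.7, 0.02), hd_min_mm = rnorm(50, 4, 2),
    hd_max_mm = rnorm(50, -1, 1), pd_min_mm = rnorm(50), pd_max_mm = rnorm(50)
  )
  sm <- summarize_trials(st)
  o <- oracle_mean_sd(st$hd_min_mm)
  expect_equal(sm$mean_hd_min_mm, o$mean)
  expect_equal(sm$sd_hd_min_mm, o$sd)
  expect_equal(sm$mean_stride_duration_s, mean(st$duration_s))
  expect_error(summarize_trials(st[0, ]), class = "equisym_input_error")
})

test_that("threshold rule with SD condition drives the classification", {
  asym <- classify_trials(summary_row(hd_min = 7, sd_hd_min = 3))
  expect_equal(asym$classification, "asymmetric")
  expect_equal(asym$triggered_parameters, "hd_min")
  expect_false(asym$high_variability)

  highvar <- classify_trials(summary_row(pd_min = 4, sd_pd_min = 5))
  expect_equal(highvar$classification, "symmetric")
  expect_true(highvar$high_variability)

  boundary <- classify_trials(summary_row(hd_min = 6, sd_hd_min = 1))
  expect_equal(boundary$classification, "symmetric")
  expect_false(boundary$high_variability)

  # negative means classify on absolute value
  left <- classify_trials(summary_row(pd_max = -3.5, sd_pd_max = 2))
  expect_equal(left$classification, "asymmetric")
  expect_equal(left$triggered_parameters, "pd_max")
})

test_that("classification is monotone in |mean| and antitone in SD", {
  set.seed(407)
  for (i in 1:50) {
    mu <- runif(1, 0, 12)
    s <- runif(1, 0, 8)
    base <- classify_trials(summary_row(hd_min = mu, sd_hd_min = s))
    bigger <- classify_trials(summary_row(hd_min = mu + runif(1, 0, 5),
                                          sd_hd_min = s))
    noisier <- classify_trials(summary_row(hd_min = mu,
                                           sd_hd_min = s + runif(1, 0, 5)))
    if (base$classification == "asymmetric") {
      expect_equal(bigger$classification, "asymmetric")
    }
    if (noisier$classification == "asymmetric") {
      expect_equal(base$classification, "asymmetric")
    }
  }
})

test_that("double-threshold flag uses strict doubled cutoffs", {
  expect_true(classify_trials(summary_row(hd_min = 12.5, sd_hd_min = 4))$double_threshold)
  expect_false(classify_trials(summary_row(hd_min = 12, sd_hd_min = 4))$double_threshold)
  expect_true(classify_trials(summary_row(pd_max = 6.1, sd_pd_max = 2))$double_threshold)
  # SD condition inherited by default, reported without it separately
  wide <- classify_trials(summary_row(hd_min = 13, sd_hd_min = 14))
  expect_false(wide$double_threshold)
  expect_true(wide$double_threshold_any)
})

test_that("TAS halves head terms and is sign-invariant", {
  expect_equal(compute_tas(summary_row())$tas_mm, 0)
  expect_equal(
    compute_tas(summary_row(hd_min = -12, hd_max = 6, pd_min = 4, pd_max = 2))$tas_mm,
    15
  )
  # exactly at all four thresholds: equal contributions, 12 mm total
  expect_equal(
    compute_tas(summary_row(hd_min = 6, hd_max = -6, pd_min = 3, pd_max = 3))$tas_mm,
    12
  )
  set.seed(408)
  for (i in 1:20) {
    m <- runif(4, -15, 15)
    t1 <- compute_tas(summary_row(m[1], m[2], m[3], m[4]))$tas_mm
    s <- sample(c(-1, 1), 4, replace = TRUE)
    t2 <- compute_tas(summary_row(m[1] * s[1], m[2] * s[2], m[3] * s[3],
                                  m[4] * s[4]))$tas_mm
    expect_equal(t1, t2)
    expect_equal(t1, abs(m[1]) / 2 + abs(m[2]) / 2 + abs(m[3]) + abs(m[4]))
    expect_true(t1 > 0 || all(m == 0))
  }
})

lunge_pair <- function(left, right) {
  dplyr::bind_rows(
    dplyr::mutate(summary_row(left[1], left[2], left[3], left[4],
                              condition = "lunge_left")),
    dplyr::mutate(summary_row(right[1], right[2], right[3], right[4],
                              condition = "lunge_right"))
  )
}

test_that("lunge TAS sums signed parameters across directions first", {
  cancel <- compute_tas_lunge(lunge_pair(c(5, 0, 0, 0), c(-5, 0, 0, 0)))
  expect_equal(cancel$tas_lunge_mm, 0)

  oneside <- compute_tas_lunge(lunge_pair(c(0, 0, 0, 0), c(-12, 6, 4, 2)))
  expect_equal(oneside$tas_lunge_mm, 15)

  set.seed(409)
  for (i in 1:20) {
    l <- runif(4, -10, 10)
    r <- runif(4, -10, 10)
    got <- compute_tas_lunge(lunge_pair(l, r))$tas_lunge_mm
    s <- l + r
    expect_equal(got, abs(s[1]) / 2 + abs(s[2]) / 2 + abs(s[3]) + abs(s[4]))
  }

  only_left <- summary_row(condition = "lunge_left")
  expect_true(is.na(compute_tas_lunge(only_left)$tas_lunge_mm))
})

test_that("population summary reproduces direct counting", {
  flags <- tibble::tibble(
    horse_id = sprintf("H%03d", 1:114),
    discipline = rep(c("show_jumping", "dressage", "eventing"), c(53, 46, 15)),
    classification = rep(c("asymmetric", "symmetric"), c(79, 35)),
    high_variability = c(rep(FALSE, 104), rep(TRUE, 10)),
    double_threshold = rep(c(TRUE, FALSE), c(42, 72))
  )
  ps <- population_summary(flags)
  overall <- ps[ps$group == "overall", ]
  expect_equal(overall$n, 114L)
  expect_equal(overall$pct_asymmetric, round(100 * 79 / 114, 1))
  expect_equal(overall$pct_double_threshold, round(100 * 42 / 114, 1))
  expect_equal(overall$n_high_variability, 10L)
  sj <- ps[ps$group == "show_jumping", ]
  expect_equal(sj$n_asymmetric, sum(flags$classification == "asymmetric" &
                                      flags$discipline == "show_jumping"))

  set.seed(410)
  rnd <- tibble::tibble(
    classification = sample(c("asymmetric", "symmetric"), 200, TRUE),
    high_variability = sample(c(TRUE, FALSE), 200, TRUE),
    double_threshold = sample(c(TRUE, FALSE), 200, TRUE)
  )
  ps2 <- population_summary(rnd)
  expect_equal(ps2$n_asymmetric, sum(rnd$classification == "asymmetric"))
  expect_equal(ps2$pct_asymmetric,
               round(100 * mean(rnd$classification == "asymmetric"), 1))
})

test_that("surface concordance partitions horses into three disjoint groups", {
  set.seed(411)
  d <- tibble::tibble(
    classification_hard = sample(c("asymmetric", "symmetric", NA), 150, TRUE),
    classification_soft = sample(c("asymmetric", "symmetric", NA), 150, TRUE)
  )
  cs <- concordance_summary(d)
  eligible <- sum(stats::complete.cases(d))
  expect_equal(sum(cs$n), eligible)
  tab <- table(d$classification_hard, d$classification_soft)
  expect_equal(cs$n[cs$category == "both_asymmetric"],
               as.integer(tab["asymmetric", "asymmetric"]))
  expect_equal(cs$n[cs$category == "both_symmetric"],
               as.integer(tab["symmetric", "symmetric"]))

  same <- tibble::tibble(classification_hard = rep("asymmetric", 10),
                         classification_soft = rep("asymmetric", 10))
  expect_equal(concordance_summary(same)$n[3], 0L)
})

test_that("top-quartile summaries match the sort-and-slice oracle", {
  four <- quartile_summary(rep(7.5, 4))
  expect_equal(four$mean_top_quartile, 7.5)

  set.seed(412)
  for (n in c(11, 37, 39, 80)) {
    v <- round(runif(n, 6, 25), 3)
    qs <- quartile_summary(v)
    o <- oracle_top_quartile(v)
    expect_equal(qs$n_top_quartile, o$k)
    expect_equal(qs$mean_top_quartile, o$mean)
    expect_equal(qs$min_top_quartile, o$min)
    expect_equal(qs$max_top_quartile, o$max)
  }
  # counting convention on distinct values: 39 -> 10, 37 -> 9
  expect_equal(quartile_summary(seq_len(39) + 6)$n_top_quartile, 10L)
  expect_equal(quartile_summary(seq_len(37) + 6)$n_top_quartile, 9L)

  small <- quartile_summary(c(7, 8, 9))
  expect_true(is.na(small$n_top_quartile))
})
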