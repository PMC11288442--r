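test_that("symmetric noiseless trial yields zero differences everywhere", {
  trial <- simulate_trial_traces(gait_config(n_strides = 12))
  strides <- segment_strides(trial$traces)
  sa <- stride_asymmetries(trial$traces, strides)
  expect_equal(nrow(sa), 12)
  expect_false(any(sa$flagged))
  expect_true(all(abs(as.matrix(sa[, c("hd_min_mm", "hd_max_mm",
                                       "pd_min_mm", "pd_max_mm")])) < 1e-9))
})

test_that("noiseless extraction recovers injected asymmetries exactly, all sign patterns", {
  signs <- expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1), s4 = c(-1, 1))
  for (i in seq_len(nrow(signs))) {
    a <- c(6, 4, 2.5, 1.5) * as.numeric(signs[i, ])
    trial <- simulate_trial_traces(gait_config(
      n_strides = 5, asym_hdmin = a[1], asym_hdmax = a[2],
      asym_pdmin = a[3], asym_pdmax = a[4]
    ))
    sa <- stride_asymmetries(trial$traces, segment_strides(trial$traces))
    got <- as.matrix(sa[, c("hd_min_mm", "hd_max_mm", "pd_min_mm", "pd_max_mm")])
    expect_equal(got, matrix(a, 5, 4, byrow = TRUE), ignore_attr = TRUE,
                 tolerance = 1e-9)
  }
})

test_that("brute-force extrema search confirms the injected per-stride differences", {
  trial <- simulate_trial_traces(gait_config(n_strides = 8, asym_hdmin = 6))
  strides <- segment_strides(trial$traces)
  d <- oracle_stride_diffs(trial$traces$head_z_mm, strides$start_idx,
                           strides$end_idx)
  expect_equal(d[, 1], rep(6, 8), tolerance = 1e-9)
  expect_equal(d[, 2], rep(0, 8), tolerance = 1e-9)
})

test_that("sign-flipping the configuration flips every extracted difference", {
  base <- list(n_strides = 6, asym_hdmin = 5, asym_hdmax = -3,
               asym_pdmin = 2, asym_pdmax = -1.2)
  flip <- purrr::map(base, ~ if (is.numeric(.x) && abs(.x) < 10) -.x else .x)
  flip$n_strides <- base$n_strides
  t1 <- simulate_trial_traces(do.call(gait_config, base))
  t2 <- simulate_trial_traces(do.call(gait_config, flip))
  s1 <- stride_asymmetries(t1$traces, segment_strides(t1$traces))
  s2 <- stride_asymmetries(t2$traces, segment_strides(t2$traces))
  cols <- c("hd_min_mm", "hd_max_mm", "pd_min_mm", "pd_max_mm")
  expect_equal(as.matrix(s1[, cols]), -as.matrix(s2[, cols]),
               tolerance = 1e-9)
})

test_that("recovery is exact across random sign patterns and stride counts", {
  set.seed(401)
  for (rep in 1:20) {
    a <- round(runif(4, 0.5, 8), 2) * sample(c(-1, 1), 4, replace = TRUE)
    ns <- sample(3:25, 1)
    trial <- simulate_trial_traces(gait_config(
      n_strides = ns, asym_hdmin = a[1], asym_hdmax = a[2],
      asym_pdmin = a[3], asym_pdmax = a[4],
      stride_duration_cv = runif(1, 0, 0.08), seed = rep
    ))
    sa <- stride_asymmetries(trial$traces, segment_strides(trial$traces))
    got <- as.matrix(sa[, c("hd_min_mm", "hd_max_mm", "pd_min_mm", "pd_max_mm")])
    expect_equal(got, matrix(a, ns, 4, byrow = TRUE), ignore_attr = TRUE,
                 tolerance = 1e-9)
  }
})

test_that("sensor noise perturbs trial means within the expected envelope", {
  n_strides <- 30
  noise_sd <- 0.8
  bound <- 4 * noise_sd / sqrt(n_strides)
  ok <- 0L
  total <- 0L
  for (seed in 1:50) {
    trial <- simulate_trial_traces(gait_config(
      n_strides = n_strides, asym_hdmin = 6, asym_pdmax = -2,
      noise_sd = noise_sd, seed = seed
    ))
    sa <- stride_asymmetries(trial$traces, segment_strides(trial$traces),
                             smooth_window = 7)
    sa <- sa[!sa$flagged, ]
    dev <- abs(c(mean(sa$hd_min_mm) - 6, mean(sa$hd_max_mm),
                 mean(sa$pd_min_mm), mean(sa$pd_max_mm) + 2))
    ok <- ok + sum(dev <= bound)
    total <- total + 4L
  }
  expect_gte(ok / total, 0.99)
})

test_that("outlier strides occur at the configured rate and are marked in truth", {
  trial <- simulate_trial_traces(gait_config(
    n_strides = 400, outlier_stride_prob = 0.1, seed = 99
  ))
  n_out <- sum(trial$truth$outlier)
  ci <- qbinom(c(0.005, 0.995), 400, 0.1)
  expect_gte(n_out, ci[1])
  expect_lte(n_out, ci[2])
  expect_true(all(trial$truth$hd_min_mm[trial$truth$outlier] == 40))
})

test_that("trace simulation is reproducible under a fixed seed", {
  cfg <- gait_config(n_strides = 10, noise_sd = 1, stride_duration_cv = 0.05,
                     seed = 12)
  t1 <- simulate_trial_traces(cfg)
  t2 <- simulate_trial_traces(cfg)
  expect_identical(t1, t2)
})

test_that("invalid configurations are rejected", {
  expect_error(gait_config(n_strides = 0), class = "equisym_config_error")
  expect_error(gait_config(sample_rate = 20), class = "equisym_config_error")
  expect_error(gait_config(head_amplitude = -1), class = "equisym_config_error")
  expect_error(gait_config(outlier_stride_prob = 1.5),
               class = "equisym_config_error")
  expect_error(gait_config(noise_sd = -0.1), class = "equisym_config_error")
})
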