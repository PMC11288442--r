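make_responses <- function(n = 100) {
  set.seed(413)
  tibble::tibble(
    horse_id = sprintf("H%03d", 1:n),
    q_a = sample(c("no", "left", "right"), n, TRUE, prob = c(0.6, 0.2, 0.2)),
    q_b = sample(c("no", "left", "right", "na"), n, TRUE,
                 prob = c(0.3, 0.3, 0.3, 0.1)),
    q_c = sample(c("no", "left", "right", "na"), n, TRUE,
                 prob = c(0.3, 0.25, 0.25, 0.2)),
    q_d = sample(c("no", "left", "right"), n, TRUE, prob = c(0.45, 0.3, 0.25))
  )
}

test_that("question reduction keeps the best-answered member and drops no-sidedness questions", {
  r <- make_responses()
  red <- reduce_questions(r, groups = list(c("q_b", "q_c")))
  expect_true(red$selected[red$question == "q_b"])   # fewer na than q_c
  expect_false(red$selected[red$question == "q_c"])
  expect_false(red$retained[red$question == "q_a"])  # 60% "no"
  expect_match(red$reason[red$question == "q_a"], "no sidedness")
  expect_true(red$retained[red$question == "q_d"])   # 45% "no", singleton

  # tie in na counts goes to the first in declared order
  tie <- tibble::tibble(horse_id = c("a", "b"), q_x = c("no", "left"),
                        q_y = c("left", "no"))
  red_tie <- reduce_questions(tie, groups = list(c("q_y", "q_x")))
  expect_true(red_tie$selected[red_tie$question == "q_y"])
  expect_error(reduce_questions(r, groups = list("not_a_question")),
               class = "equisym_input_error")
})

test_that("responses binarize and grades merge as specified", {
  expect_equal(as.character(binarize_response(c("left", "no", "right", "na"))),
               c("yes", "no", "yes", NA))
  expect_error(binarize_response("maybe"), class = "equisym_input_error")
  merged <- merge_sidedness_grades(c("no", "mild", "severe", "moderate", "na"))
  expect_equal(as.character(merged), c("no", "mild", "moderate", "moderate", NA))
  expect_equal(levels(merged), c("no", "mild", "moderate"))
})

test_that("association fit returns a complete, tidy-able result", {
  d <- assoc_data()
  f <- fit_association(d, tas_lunge_mm, sidedness, mean_stride_duration_s,
                       rider_id)
  expect_s3_class(f, "equisym_assoc")
  expect_setequal(f$anova$term, c("predictor", "stride_duration"))
  expect_true(all(f$anova$p.value >= 0 & f$anova$p.value <= 1))
  expect_equal(nrow(pairwise_contrasts(f)), 3)  # 3 groups -> 3 contrasts
  expect_equal(f$n_obs, nrow(tidyr::drop_na(d, tas_lunge_mm, sidedness)))
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$n_obs, f$n_obs)
  expect_output(print(f), "Type III")
})

test_that("results are invariant to flipping the sign of every asymmetry", {
  pop <- simulate_population(lunge_only_config(29, 0))
  flipped <- pop
  cols <- c("hd_min_mm", "hd_max_mm", "pd_min_mm", "pd_max_mm")
  flipped$strides[cols] <- -flipped$strides[cols]
  build <- function(p) {
    sm <- summarize_trials(p$strides, horse_id, condition)
    compute_tas_lunge(sm) |>
      dplyr::inner_join(p$questionnaire, by = "horse_id") |>
      dplyr::mutate(sidedness = merge_sidedness_grades(q1_sidedness))
  }
  f1 <- fit_association(build(pop), tas_lunge_mm, sidedness,
                        mean_stride_duration_s, rider_id, contrasts = FALSE)
  f2 <- fit_association(build(flipped), tas_lunge_mm, sidedness,
                        mean_stride_duration_s, rider_id, contrasts = FALSE)
  expect_equal(f1$anova, f2$anova, tolerance = 1e-10)
})

test_that("one horse per rider reduces to ordinary least squares", {
  set.seed(414)
  n <- 40
  d <- tibble::tibble(
    value = abs(rnorm(n, 10, 4)),
    group = factor(sample(c("no", "yes"), n, TRUE)),
    dur = rnorm(n, 0.7, 0.03),
    rider = sprintf("R%02d", 1:n)
  )
  f <- fit_association(d, value, group, dur, rider, skew_threshold = Inf)
  expect_equal(f$fallback, "fixed-only")
  ols <- stats::lm(value ~ group + dur, data = d)
  expect_equal(unname(coef(f$model)), unname(coef(ols)), tolerance = 1e-10)
})

test_that("degenerate zero-variance responses are flagged, not significant", {
  d <- tibble::tibble(
    value = rep(5, 30),
    group = factor(rep(c("no", "yes"), 15)),
    dur = rnorm(30, 0.7, 0.02),
    rider = rep(sprintf("R%02d", 1:10), 3)
  )
  f <- fit_association(d, value, group, dur, rider)
  expect_true(f$degenerate)
  p <- f$anova$p.value[f$anova$term == "predictor"]
  expect_true(is.na(p) || p > 0.05)
})

test_that("skewed residuals trigger a Box-Cox refit with a recorded lambda", {
  set.seed(415)
  n <- 80
  d <- tibble::tibble(
    value = stats::rlnorm(n, 1, 1.6),
    group = factor(sample(c("no", "yes"), n, TRUE)),
    dur = rnorm(n, 0.7, 0.03),
    rider = sample(sprintf("R%02d", 1:30), n, TRUE)
  )
  f <- fit_association(d, value, group, dur, rider)
  expect_equal(f$transformation, "boxcox")
  expect_true(is.finite(f$lambda))
  expect_true(abs(e1071::skewness(residuals(f$model), type = 2)) < 1)
})

test_that("a large injected lunge shift is detected, equal groups are not", {
  p_alt <- sidedness_pvalue(seed = 30, effect = 6)
  expect_lt(p_alt, 0.05)

  # two identical groups: contrast estimate near zero relative to its SE
  set.seed(416)
  n <- 120
  d <- tibble::tibble(
    value = abs(rnorm(n, 12, 3)),
    group = factor(rep(c("no", "yes"), each = n / 2)),
    dur = rnorm(n, 0.7, 0.03),
    rider = sample(sprintf("R%02d", 1:40), n, TRUE)
  )
  f <- fit_association(d, value, group, dur, rider, skew_threshold = Inf)
  ct <- pairwise_contrasts(f)
  expect_equal(nrow(ct), 1)
  expect_lt(abs(ct$estimate / ct$SE), 3)
})

test_that("input validation rejects unusable model data", {
  d <- tibble::tibble(value = c(1, 2), group = factor(c("a", "a")),
                      dur = c(0.7, 0.7), rider = c("r1", "r2"))
  expect_error(fit_association(d, value, group, dur, rider),
               class = "equisym_input_error")
  d2 <- tibble::tibble(value = c(1, -2, 3, 4), group = factor(c("a", "b", "a", "b")),
                       dur = 0.7, rider = c("r1", "r2", "r1", "r2"))
  expect_error(fit_association(d2, value, group, dur, rider),
               class = "equisym_input_error")
})
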