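# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and textbook formulas, not the package's
# own code paths.

# exhaustive 3-point local-extrema scan (plateaus: earliest sample)
oracle_extrema <- function(z) {
  minima <- integer(0)
  maxima <- integer(0)
  n <- length(z)
  i <- 2
  while (i <= n - 1) {
    # find the end of any plateau starting at i
    j <- i
    while (j < n && z[j + 1] == z[j]) j <- j + 1
    if (j <= n - 1) {
      before <- z[i - 1]
      after <- z[j + 1]
      if (z[i] > before && z[i] > after) maxima <- c(maxima, i)
      if (z[i] < before && z[i] < after) minima <- c(minima, i)
    }
    i <- j + 1
  }
  list(minima = minima, maxima = maxima)
}

# per-stride right-minus-left differences by exhaustive scan
oracle_stride_diffs <- function(z, start_idx, end_idx) {
  t(vapply(seq_along(start_idx), function(k) {
    seg <- z[start_idx[k]:end_idx[k]]
    ext <- oracle_extrema(seg)
    if (length(ext$minima) != 2 || length(ext$maxima) != 2) {
      return(c(NA_real_, NA_real_))
    }
    c(seg[ext$minima[1]] - seg[ext$minima[2]],
      seg[ext$maxima[1]] - seg[ext$maxima[2]])
  }, numeric(2)))
}

# iterative outlier removal: explicit quadratic-form Mahalanobis distance,
# recompute mean/covariance each pass, drop distance >= threshold, repeat
oracle_outlier_removal <- function(X, threshold = 3) {
  keep <- seq_len(nrow(X))
  repeat {
    if (length(keep) < 2) break
    M <- X[keep, , drop = FALSE]
    mu <- colMeans(M)
    S <- cov(M)
    inv <- try(solve(S), silent = TRUE)
    if (inherits(inv, "try-error")) break
    d2 <- numeric(nrow(M))
    for (i in seq_len(nrow(M))) {
      v <- M[i, ] - mu
      d2[i] <- drop(t(v) %*% inv %*% v)
    }
    out <- d2 >= threshold^2
    if (!any(out)) break
    keep <- keep[!out]
  }
  keep
}

# textbook sample mean / SD
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

# top quartile by sort-and-count against the interpolated 75th percentile
oracle_top_quartile <- function(values) {
  n <- length(values)
  s <- sort(values)
  h <- (n - 1) * 0.75 + 1
  lo <- floor(h)
  q75 <- s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  top <- s[s > q75]
  list(k = length(top), mean = mean(top), min = min(top), max = max(top))
}

# minimal lunge-condition-only population for association simulations
lunge_only_config <- function(seed, effect = 0, n_horses = 71, n_riders = 51) {
  population_config(
    n_horses = n_horses, n_riders = n_riders, questionnaire_coverage = 1,
    missing_prob = c(straight_hard = 1, straight_soft = 1, lunge = 0),
    sidedness_association_effect = effect, seed = seed
  )
}

# one null/alternative replicate: p-value of the sidedness term for TAS_lunge
sidedness_pvalue <- function(seed, effect = 0) {
  pop <- simulate_population(lunge_only_config(seed, effect))
  sm <- summarize_trials(pop$strides, horse_id, condition)
  tas <- compute_tas_lunge(sm) |>
    dplyr::inner_join(pop$questionnaire, by = "horse_id") |>
    dplyr::mutate(sidedness = merge_sidedness_grades(q1_sidedness))
  f <- fit_association(tas, tas_lunge_mm, sidedness, mean_stride_duration_s,
                       rider_id, contrasts = FALSE)
  f$anova$p.value[f$anova$term == "predictor"]
}

# trial summary row constructor for classification tests
summary_row <- function(hd_min = 0, hd_max = 0, pd_min = 0, pd_max = 0,
                        sd_hd_min = 0, sd_hd_max = 0, sd_pd_min = 0,
                        sd_pd_max = 0, condition = "straight_hard",
                        n_strides = 30) {
  tibble::tibble(
    horse_id = "H001", condition = condition, n_strides = n_strides,
    mean_stride_duration_s = 0.7,
    mean_hd_min_mm = hd_min, sd_hd_min_mm = sd_hd_min,
    mean_hd_max_mm = hd_max, sd_hd_max_mm = sd_hd_max,
    mean_pd_min_mm = pd_min, sd_pd_min_mm = sd_pd_min,
    mean_pd_max_mm = pd_max, sd_pd_max_mm = sd_pd_max
  )
}

# TAS_lunge + questionnaire analysis table from a lunge-only population
assoc_data <- function(seed = 28, effect = 0, n_horses = 71, n_riders = 51) {
  pop <- simulate_population(lunge_only_config(seed, effect, n_horses, n_riders))
  sm <- summarize_trials(pop$strides, horse_id, condition)
  compute_tas_lunge(sm) |>
    dplyr::inner_join(pop$questionnaire, by = "horse_id") |>
    dplyr::mutate(sidedness = merge_sidedness_grades(q1_sidedness))
}

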