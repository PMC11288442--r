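#' Summarize strides into trial-level asymmetry parameters
#'
#' Computes, per trial, the arithmetic mean and sample SD of the four
#' stride-level asymmetry differences, the stride count and the mean stride
#' duration. These trial means are the quantities the classification
#' thresholds apply to.
#'
#' @param strides Stride table with columns `duration_s`, `hd_min_mm`,
#'   `hd_max_mm`, `pd_min_mm`, `pd_max_mm`; flagged strides (if a `flagged`
#'   column is present) are excluded first.
#' @param ... Grouping columns (tidy-eval), e.g. `horse_id, condition`; omit
#'   for a single trial.
#' @return A tibble with one row per group: `n_strides`,
#'   `mean_stride_duration_s`, and `mean_*_mm` / `sd_*_mm` for each of
#'   `hd_min`, `hd_max`, `pd_min`, `pd_max`. Single-stride groups get SD 0.
#' @export
#' @examples
#' trial <- simulate_trial_traces(gait_config(n_strides = 20, asym_hdmin = 8))
#' sa <- stride_asymmetries(trial$traces, segment_strides(trial$traces))
#' summarize_trials(sa)
summarize_trials <- function(strides, ...) {
  if ("flagged" %in% names(strides)) {
    strides <- dplyr::filter(strides, !.data$flagged)
  }
  if (nrow(strides) == 0) {
    abort("no strides to summarize", class = "equisym_input_error")
  }
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  strides |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n_strides = dplyr::n(),
      mean_stride_duration_s = mean(.data$duration_s),
      dplyr::across(
        dplyr::all_of(c("hd_min_mm", "hd_max_mm", "pd_min_mm", "pd_max_mm")),
        list(mean = mean, sd = sd0),
        .names = "{.fn}_{.col}"
      ),
      .groups = "drop"
    )
}

# |mean| and sd matrices (rows = trials, cols = asym_params() order)
summary_matrices <- function(summaries) {
  list(
    absmean = abs(cbind(summaries$mean_hd_min_mm, summaries$mean_hd_max_mm,
                        summaries$mean_pd_min_mm, summaries$mean_pd_max_mm)),
    sd = cbind(summaries$sd_hd_min_mm, summaries$sd_hd_max_mm,
               summaries$sd_pd_min_mm, summaries$sd_pd_max_mm)
  )
}

#' Classify trials as asymmetric or symmetric
#'
#' A trial is asymmetric when at least one parameter's mean absolute value
#' strictly exceeds its threshold (6 mm for head differences, 3 mm for
#' pelvic differences by default) *and* the stride-level SD is strictly
#' below that absolute mean. Trials with an above-threshold mean whose SD is
#' not below the mean are classified symmetric but flagged as
#' high-variability. The double-threshold flag marks trials with a parameter
#' beyond twice its threshold; by default it inherits the SD condition from
#' the parent rule (`double_any` reports the count without it).
#'
#' @param summaries Trial summary table from [summarize_trials()].
#' @param thresholds An [asym_thresholds()].
#' @return The input with appended columns: `classification`
#'   (`"asymmetric"`/`"symmetric"`), `triggered_parameters` (comma-separated,
#'   empty when symmetric), `high_variability` (logical), `double_threshold`
#'   (logical, SD condition applied) and `double_threshold_any` (logical, SD
#'   condition ignored).
#' @export
classify_trials <- function(summaries, thresholds = asym_thresholds()) {
  m <- summary_matrices(summaries)
  thr <- threshold_vector(thresholds)
  thr_mat <- matrix(thr, nrow(m$absmean), 4, byrow = TRUE)

  exceeds <- m$absmean > thr_mat
  stable <- m$sd < m$absmean
  triggered <- exceeds & stable
  dbl <- m$absmean > thresholds$double_factor * thr_mat

  param_names <- asym_params()$parameter
  summaries |>
    dplyr::mutate(
      classification = ifelse(rowSums(triggered) > 0, "asymmetric", "symmetric"),
      triggered_parameters = apply(triggered, 1, function(r) {
        paste(param_names[r], collapse = ",")
      }),
      high_variability = rowSums(triggered) == 0 & rowSums(exceeds & !stable) > 0,
      double_threshold = rowSums(dbl & stable) > 0,
      double_threshold_any = rowSums(dbl) > 0
    )
}

#' Total Asymmetry Score
#'
#' Combines the four trial-mean asymmetry parameters into one magnitude:
#' half the absolute head differences plus the absolute pelvic differences,
#' `TAS = |HDmin|/2 + |HDmax|/2 + |PDmin| + |PDmax|` (mm). Halving the head
#' terms equalizes the parameter contributions, since the head threshold
#' (6 mm) is twice the pelvic one (3 mm): a trial sitting exactly at all
#' four thresholds scores 12 mm.
#'
#' @param summaries Trial summary table (needs the four `mean_*_mm` columns).
#' @param column Name of the output column (default `"tas_mm"`).
#' @return The input with the TAS column appended.
#' @export
#' @examples
#' compute_tas(tibble::tibble(
#'   mean_hd_min_mm = -12, mean_hd_max_mm = 6,
#'   mean_pd_min_mm = 4, mean_pd_max_mm = 2
#' ))  # 6 + 3 + 4 + 2 = 15 mm
compute_tas <- function(summaries, column = "tas_mm") {
  dplyr::mutate(
    summaries,
    !!column := abs(.data$mean_hd_min_mm) / 2 + abs(.data$mean_hd_max_mm) / 2 +
      abs(.data$mean_pd_min_mm) + abs(.data$mean_pd_max_mm)
  )
}

#' Combined lunge Total Asymmetry Score
#'
#' The two lunge directions are combined by summing each parameter's signed
#' trial mean across the left and right circle and applying the TAS formula
#' to the sums, so opposite-signed asymmetries in the two directions cancel.
#' Horses missing either direction get `NA`, never a silent zero.
#'
#' @param summaries Trial summary table containing (at most) one
#'   `lunge_left` and one `lunge_right` row per horse in `condition`.
#' @param id Grouping column identifying the horse (tidy-eval, default
#'   `horse_id`).
#' @return A tibble with the id column, the per-parameter signed sums
#'   (`sum_*_mm`), the mean of the two trials' mean stride durations
#'   (`mean_stride_duration_s`) and `tas_lunge_mm`.
#' @export
compute_tas_lunge <- function(summaries, id = horse_id) {
  lunge <- dplyr::filter(summaries, .data$condition %in% c("lunge_left", "lunge_right"))
  both <- lunge |>
    dplyr::group_by({{ id }}) |>
    dplyr::summarise(
      n_directions = dplyr::n_distinct(.data$condition),
      sum_hd_min_mm = sum(.data$mean_hd_min_mm),
      sum_hd_max_mm = sum(.data$mean_hd_max_mm),
      sum_pd_min_mm = sum(.data$mean_pd_min_mm),
      sum_pd_max_mm = sum(.data$mean_pd_max_mm),
      mean_stride_duration_s = mean(.data$mean_stride_duration_s),
      .groups = "drop"
    )
  both |>
    dplyr::mutate(
      tas_lunge_mm = ifelse(
        .data$n_directions == 2,
        abs(.data$sum_hd_min_mm) / 2 + abs(.data$sum_hd_max_mm) / 2 +
          abs(.data$sum_pd_min_mm) + abs(.data$sum_pd_max_mm),
        NA_real_
      )
    ) |>
    dplyr::select(-"n_directions")
}

# one-decimal percentage as printed in prevalence reports
pct1 <- function(num, den) round(100 * num / den, 1)

#' Prevalence and double-threshold summary of classified horses
#'
#' Counts asymmetric horses overall and per discipline, the proportion of
#' horses beyond double thresholds (of all classified horses), and the
#' high-variability count. Percentages are reported to one decimal.
#'
#' @param assessments Classified table from [classify_trials()], one row per
#'   horse for a given surface; a `discipline` column adds per-discipline
#'   rows.
#' @return A tibble with rows `overall` plus one per discipline: `group`,
#'   `n`, `n_asymmetric`, `pct_asymmetric`, `n_double_threshold`,
#'   `pct_double_threshold`, `n_high_variability`.
#' @export
population_summary <- function(assessments) {
  if (nrow(assessments) == 0) {
    abort("no assessed horses", class = "equisym_input_error")
  }
  one <- function(d, label) {
    tibble::tibble(
      group = label,
      n = nrow(d),
      n_asymmetric = sum(d$classification == "asymmetric"),
      pct_asymmetric = pct1(sum(d$classification == "asymmetric"), nrow(d)),
      n_double_threshold = sum(d$double_threshold),
      pct_double_threshold = pct1(sum(d$double_threshold), nrow(d)),
      n_high_variability = sum(d$high_variability)
    )
  }
  out <- one(assessments, "overall")
  if ("discipline" %in% names(assessments)) {
    by_disc <- assessments |>
      dplyr::group_by(.data$discipline) |>
      dplyr::group_map(~ one(.x, .y$discipline))
    out <- dplyr::bind_rows(out, by_disc)
  }
  out
}

#' Concordance of classification between two surfaces
#'
#' Partitions horses assessed on both straight-line surfaces into three
#' exhaustive, disjoint categories: asymmetric on both, symmetric on both,
#' or discordant.
#'
#' @param assessments Data frame with one row per horse and the two
#'   classifications in `classification_hard` and `classification_soft`
#'   (`NA` rows are dropped: only horses with both surfaces count).
#' @return A tibble: `category`, `n`, `pct` (one decimal, of eligible
#'   horses).
#' @export
concordance_summary <- function(assessments) {
  d <- dplyr::filter(assessments,
                     !is.na(.data$classification_hard),
                     !is.na(.data$classification_soft))
  category <- dplyr::case_when(
    d$classification_hard == "asymmetric" & d$classification_soft == "asymmetric" ~ "both_asymmetric",
    d$classification_hard == "symmetric" & d$classification_soft == "symmetric" ~ "both_symmetric",
    TRUE ~ "discordant"
  )
  counts <- table(factor(category, levels = c("both_asymmetric", "both_symmetric", "discordant")))
  tibble::tibble(
    category = names(counts),
    n = as.integer(counts),
    pct = pct1(as.integer(counts), nrow(d))
  )
}

#' Descriptive summary with upper-quartile statistics
#'
#' Summarizes a set of above-threshold absolute asymmetry values the way the
#' study's descriptive tables do: n, mean and SD of all values, then the
#' size, mean and range of the top quartile. The top quartile is the set of
#' values strictly greater than the 75th percentile; the percentile is
#' computed by linear interpolation (quantile type 7) by default, with
#' `type = "ceiling"` / `"floor"` selecting fixed top-k conventions
#' (k = ceiling(n/4) or floor(n/4)) instead.
#'
#' @param values Numeric vector (absolute trial means, mm).
#' @param type Top-quartile convention; `"strict_above"` (default),
#'   `"ceiling"` or `"floor"`.
#' @return One-row tibble: `n`, `mean`, `sd`, `n_top_quartile`,
#'   `mean_top_quartile`, `min_top_quartile`, `max_top_quartile`. With fewer
#'   than 4 values the quartile fields are `NA`.
#' @export
quartile_summary <- function(values, type = c("strict_above", "ceiling", "floor")) {
  type <- match.arg(type)
  values <- values[!is.na(values)]
  n <- length(values)
  base <- tibble::tibble(n = n, mean = mean(values), sd = if (n > 1) sd(values) else NA_real_)
  if (n < 4) {
    return(dplyr::mutate(base,
      n_top_quartile = NA_integer_, mean_top_quartile = NA_real_,
      min_top_quartile = NA_real_, max_top_quartile = NA_real_
    ))
  }
  sorted <- sort(values, decreasing = TRUE)
  k <- switch(type,
    strict_above = sum(values > quantile(values, 0.75, type = 7)),
    ceiling = ceiling(n / 4),
    floor = floor(n / 4)
  )
  top <- sorted[seq_len(max(k, 1))]
  dplyr::mutate(base,
    n_top_quartile = as.integer(k),
    mean_top_quartile = mean(top),
    min_top_quartile = min(top),
    max_top_quartile = max(top)
  )
}

#' Per-parameter exceedance report (descriptive table of asymmetric values)
#'
#' For each asymmetry parameter, summarizes the absolute trial means of the
#' horses exceeding that parameter's threshold with SD below the mean, plus
#' a TAS row over the asymmetric horses — the layout of the study-style
#' descriptive tables for a straight-line surface.
#'
#' @inheritParams classify_trials
#' @param quartile_type Passed to [quartile_summary()].
#' @return A tibble with one row per parameter (`|hd_min|`, ..., `|pd_max|`)
#'   and one `tas` row, each with the [quartile_summary()] columns.
#' @export
exceedance_report <- function(summaries, thresholds = asym_thresholds(),
                              quartile_type = "strict_above") {
  m <- summary_matrices(summaries)
  thr <- threshold_vector(thresholds)
  cls <- classify_trials(summaries, thresholds)
  rows <- purrr::map(1:4, function(j) {
    sel <- m$absmean[, j] > thr[j] & m$sd[, j] < m$absmean[, j]
    quartile_summary(m$absmean[sel, j], type = quartile_type)
  })
  tas <- compute_tas(cls) |> dplyr::filter(.data$classification == "asymmetric")
  dplyr::bind_rows(
    dplyr::bind_cols(
      tibble::tibble(variable = paste0("|", asym_params()$parameter, "|")),
      dplyr::bind_rows(rows)
    ),
    dplyr::bind_cols(tibble::tibble(variable = "tas"),
                     quartile_summary(tas$tas_mm, type = quartile_type))
  )
}
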