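#' Segment trot strides from a periodic reference signal
#'
#' Splits a displacement trace into strides using rising midline crossings of
#' a periodic reference (one cycle per stride), e.g. the right-pastern
#' sensor. Crossing times are linearly interpolated between samples, so on a
#' clean periodic signal the reported durations equal the true cycle lengths.
#'
#' @param data Data frame with a uniform time column and the reference signal.
#' @param time,z Column names (tidy-eval) of time in seconds and the
#'   reference signal. Defaults `time_s`, `pastern_z_mm`.
#' @param min_cycles Minimum number of complete cycles required (default 2).
#' @return A tibble with one row per stride: `stride_index`, `start_s`,
#'   `end_s`, `duration_s`, `start_idx`, `end_idx` (sample indices covering
#'   the stride, end exclusive of the next stride's start).
#' @export
#' @examples
#' trial <- simulate_trial_traces(gait_config(n_strides = 4))
#' segment_strides(trial$traces)
segment_strides <- function(data, time = time_s, z = pastern_z_mm,
                            min_cycles = 2) {
  t <- dplyr::pull(data, {{ time }})
  x <- dplyr::pull(data, {{ z }})
  if (length(t) < 3 || anyNA(t) || anyNA(x) || any(!is.finite(x))) {
    abort("reference trace must be finite and have at least 3 samples",
          class = "equisym_segmentation_error")
  }
  dt <- diff(t)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-12) {
    abort("time must be a strictly increasing uniform grid",
          class = "equisym_segmentation_error")
  }

  midline <- (max(x) + min(x)) / 2
  y <- x - midline
  n <- length(y)
  # rising crossing between i and i+1: y[i] < 0 <= y[i+1]; a signal starting
  # exactly on the rising midline counts as a crossing at its first sample
  i <- which(y[-n] < 0 & y[-1] >= 0)
  t_cross <- t[i] + (0 - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
  if (y[1] == 0 && y[2] > 0) t_cross <- c(t[1], t_cross)
  if (length(t_cross) < min_cycles + 1) {
    abort(sprintf(
      "reference contains %d complete cycle(s); at least %d required",
      max(0L, length(t_cross) - 1L), min_cycles
    ), class = "equisym_segmentation_error")
  }

  durations <- diff(t_cross)
  med <- stats::median(durations)
  if (any(durations < 0.25 * med) || any(durations > 4 * med)) {
    abort("reference appears aperiodic: cycle lengths vary more than 4-fold",
          class = "equisym_segmentation_error")
  }

  # stride samples: first sample at/after the crossing, up to the one before
  # the next stride's first sample
  start_idx <- findInterval(t_cross - 1e-9, t) + 1L
  start_idx[t_cross <= t[1]] <- 1L
  n_strides <- length(t_cross) - 1L
  first_idx <- start_idx[-length(start_idx)]
  last_idx <- start_idx[-1] - 1L
  tibble::tibble(
    stride_index = seq_len(n_strides),
    start_s = t_cross[-length(t_cross)],
    end_s = t_cross[-1],
    duration_s = durations,
    start_idx = first_idx,
    end_idx = last_idx
  )
}

# Local extrema on a sampled signal by 3-point comparison; plateaus break the
# tie to the earliest sample. Returns indices relative to the input vector.
local_extrema <- function(z) {
  s <- sign(diff(z))
  # backfill flats with the following trend so a plateau's first sample is
  # the turning point
  s_filled <- s
  for (k in rev(seq_along(s)[-length(s)])) {
    if (s_filled[k] == 0) s_filled[k] <- s_filled[k + 1]
  }
  turn <- which(s_filled[-length(s_filled)] != 0 &
                  s_filled[-1] != 0 &
                  s_filled[-length(s_filled)] != s_filled[-1]) + 1L
  list(
    minima = turn[s_filled[turn - 1] < 0],
    maxima = turn[s_filled[turn - 1] > 0]
  )
}

# moving-average smoother (odd window), edges padded by replication
smooth_ma <- function(z, window) {
  if (window <= 1) return(z)
  if (window %% 2 == 0) window <- window + 1
  half <- (window - 1) / 2
  zp <- c(rep(z[1], half), z, rep(z[length(z)], half))
  as.numeric(stats::filter(zp, rep(1 / window, window), sides = 2))[
    (half + 1):(half + length(z))
  ]
}

#' Per-stride asymmetry differences from head and pelvis traces
#'
#' For each segmented stride, locates the two minima and two maxima of the
#' head and pelvis vertical displacement and computes the four asymmetry
#' parameters as right-minus-left differences: `hd_min_mm` and `hd_max_mm`
#' (head), `pd_min_mm` and `pd_max_mm` (pelvis). Strides start at the
#' right-pastern reference event, so the first extremum of each kind within a
#' stride belongs to the right diagonal step. Positive values indicate
#' asymmetry associated with the right fore/hind limb under this convention.
#' Strides that do not show exactly two extrema of each kind in both traces
#' are flagged (`flagged = TRUE`, parameter values `NA`), not dropped.
#'
#' @param data Data frame with time and the head and pelvis signals.
#' @param strides Stride table from [segment_strides()].
#' @param head,pelvis Column names (tidy-eval) of the two traces.
#' @param smooth_window Optional moving-average window (samples) applied to
#'   both traces before extrema detection; 1 (default) disables smoothing.
#'   Use an odd window of roughly 1/10 stride for noisy signals.
#' @return A tibble, one row per stride: `stride_index`, `duration_s`,
#'   `hd_min_mm`, `hd_max_mm`, `pd_min_mm`, `pd_max_mm`, `flagged`.
#' @export
#' @examples
#' trial <- simulate_trial_traces(gait_config(n_strides = 4, asym_hdmin = 6))
#' strides <- segment_strides(trial$traces)
#' stride_asymmetries(trial$traces, strides)
stride_asymmetries <- function(data, strides, head = head_z_mm,
                               pelvis = pelvis_z_mm, smooth_window = 1) {
  zh <- dplyr::pull(data, {{ head }})
  zp <- dplyr::pull(data, {{ pelvis }})
  if (max(strides$end_idx) > length(zh) || max(strides$end_idx) > length(zp)) {
    abort("traces do not cover all stride intervals", class = "equisym_input_error")
  }
  zh <- smooth_ma(zh, smooth_window)
  zp <- smooth_ma(zp, smooth_window)

  one_trace <- function(z, from, to) {
    ext <- local_extrema(z[from:to])
    if (length(ext$minima) != 2 || length(ext$maxima) != 2) {
      return(c(NA_real_, NA_real_))
    }
    seg <- z[from:to]
    # first extremum of each kind after stride start = right diagonal step
    c(seg[ext$minima[1]] - seg[ext$minima[2]],
      seg[ext$maxima[1]] - seg[ext$maxima[2]])
  }

  vals <- purrr::map(seq_len(nrow(strides)), function(k) {
    from <- strides$start_idx[k]
    to <- strides$end_idx[k]
    c(one_trace(zh, from, to), one_trace(zp, from, to))
  })
  m <- do.call(rbind, vals)
  tibble::tibble(
    stride_index = strides$stride_index,
    duration_s = strides$duration_s,
    hd_min_mm = m[, 1], hd_max_mm = m[, 2],
    pd_min_mm = m[, 3], pd_max_mm = m[, 4],
    flagged = !complete.cases(m)
  )
}
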