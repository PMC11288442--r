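#' Configuration for simulating one gait-analysis trial
#'
#' Describes a trot trial at the signal level: vertical displacement of the
#' head and pelvis sampled on a uniform grid, plus a pastern reference signal
#' with one cycle per stride used for stride segmentation. At trot each body
#' landmark oscillates twice per stride (once per diagonal step), so the
#' simulated waveform has two minima and two maxima per stride; the `asym_*`
#' parameters inject a signed right-minus-left offset at the corresponding
#' pair of extrema, which is exactly the quantity the downstream parameters
#' HDmin/HDmax/PDmin/PDmax measure.
#'
#' @param n_strides Number of strides to simulate.
#' @param stride_duration_mean Mean stride duration, seconds.
#' @param stride_duration_cv Coefficient of variation of stride durations.
#' @param sample_rate Sampling rate, Hz. Must give at least 20 samples per
#'   stride.
#' @param head_amplitude,pelvis_amplitude Peak vertical oscillation
#'   amplitude, mm (must be positive).
#' @param asym_hdmin,asym_hdmax,asym_pdmin,asym_pdmax Injected trial-level
#'   asymmetry, mm. Signed: positive values lower/raise the right-step
#'   extremum relative to the left so that the extracted per-stride
#'   difference (right minus left) equals the configured value.
#' @param noise_sd Gaussian sensor noise SD on head and pelvis traces, mm.
#'   The pastern reference is left noise-free (it is a timing reference).
#' @param outlier_stride_prob Probability that a stride is an outlier stride.
#' @param outlier_magnitude Extra head-minimum offset applied to outlier
#'   strides, mm.
#' @param seed Optional integer seed; when given the trial is reproducible.
#' @return A validated list of class `gait_config`.
#' @export
#' @examples
#' cfg <- gait_config(n_strides = 5, asym_hdmin = 6)
gait_config <- function(n_strides = 25,
                        stride_duration_mean = 0.7,
                        stride_duration_cv = 0,
                        sample_rate = 200,
                        head_amplitude = 40,
                        pelvis_amplitude = 30,
                        asym_hdmin = 0, asym_hdmax = 0,
                        asym_pdmin = 0, asym_pdmax = 0,
                        noise_sd = 0,
                        outlier_stride_prob = 0,
                        outlier_magnitude = 40,
                        seed = NULL) {
  cfg <- list(
    n_strides = n_strides, stride_duration_mean = stride_duration_mean,
    stride_duration_cv = stride_duration_cv, sample_rate = sample_rate,
    head_amplitude = head_amplitude, pelvis_amplitude = pelvis_amplitude,
    asym_hdmin = asym_hdmin, asym_hdmax = asym_hdmax,
    asym_pdmin = asym_pdmin, asym_pdmax = asym_pdmax,
    noise_sd = noise_sd, outlier_stride_prob = outlier_stride_prob,
    outlier_magnitude = outlier_magnitude, seed = seed
  )
  if (n_strides < 1) abort("`n_strides` must be >= 1", class = "equisym_config_error")
  if (sample_rate <= 0 || stride_duration_mean <= 0 ||
      sample_rate * stride_duration_mean < 20) {
    abort("`sample_rate` must give at least 20 samples per stride",
          class = "equisym_config_error")
  }
  if (head_amplitude <= 0 || pelvis_amplitude <= 0) {
    abort("amplitudes must be positive", class = "equisym_config_error")
  }
  if (stride_duration_cv < 0 || noise_sd < 0) {
    abort("`stride_duration_cv` and `noise_sd` must be non-negative",
          class = "equisym_config_error")
  }
  if (outlier_stride_prob < 0 || outlier_stride_prob > 1) {
    abort("`outlier_stride_prob` must be in [0, 1]", class = "equisym_config_error")
  }
  structure(cfg, class = "gait_config")
}

# Periodic Gaussian bump (period 1 stride) centred at phase `centre`. The
# periodic wrapping makes each bump's tail contributions identical at the two
# extrema of the other kind, so they cancel exactly in the right-minus-left
# differences; the width (sd = 0.06 stride) is broad enough to survive mild
# low-pass smoothing without attenuating the injected offset.
phase_bump <- function(phase, centre, width = 0.06) {
  exp(-(phase - centre)^2 / (2 * width^2)) +
    exp(-(phase - centre + 1)^2 / (2 * width^2)) +
    exp(-(phase - centre - 1)^2 / (2 * width^2))
}

# Two-oscillation stride waveform with per-extremum offsets. Phase in [0, 1);
# the right diagonal step occupies [0, 0.5): max at 0.125, min at 0.375; the
# left step mirrors them at 0.625 / 0.875. Offsetting the right and left
# extrema by +a/2 and -a/2 makes the right-minus-left difference exactly `a`:
# the construction is antisymmetric under a half-stride shift, so with an
# even sample count per half-stride the sampled extrema sit at identical
# grid offsets in the two halves and every residual term cancels.
stride_waveform <- function(phase, amplitude, a_min, a_max) {
  amplitude * sin(4 * pi * phase) +
    (a_max / 2) * (phase_bump(phase, 0.125) - phase_bump(phase, 0.625)) +
    (a_min / 2) * (phase_bump(phase, 0.375) - phase_bump(phase, 0.875))
}

#' Simulate head, pelvis and pastern displacement traces for one trial
#'
#' Generates a uniformly sampled trot trial from a [gait_config()]: the head
#' and pelvis traces carry two vertical oscillations per stride with the
#' configured right-minus-left extremum offsets, Gaussian sensor noise and
#' sporadic outlier strides; the pastern reference carries one clean cycle
#' per stride (it stands in for the right-pastern sensor that marks stride
#' starts). Each stride spans a multiple of eight samples so the sampled
#' extrema coincide with the waveform's true extrema and, without noise, the
#' extracted differences equal the injected values exactly.
#'
#' @param config A [gait_config()].
#' @return A list with components
#'   \describe{
#'     \item{traces}{tibble with columns `time_s`, `head_z_mm`,
#'       `pelvis_z_mm`, `pastern_z_mm`, `pastern_phase`.}
#'     \item{truth}{tibble of ground truth per stride: `stride_index`,
#'       `duration_s`, the four injected differences (`hd_min_mm`, ...,
#'       `pd_max_mm`) and `outlier`.}
#'   }
#' @export
#' @examples
#' trial <- simulate_trial_traces(gait_config(n_strides = 3, seed = 1))
#' head(trial$traces)
#' trial$truth
simulate_trial_traces <- function(config) {
  if (!inherits(config, "gait_config")) config <- do.call(gait_config, config)
  if (!is.null(config$seed)) set.seed(config$seed)

  fs <- config$sample_rate
  # samples per stride snap to a multiple of 8 so the four extremum phases
  # (1/8, 3/8, 5/8, 7/8 stride) fall exactly on the sample grid and the
  # noiseless extraction is exact; durations snap with them
  n_samp <- 8 * pmax(3, round(
    config$stride_duration_mean *
      (1 + config$stride_duration_cv * rnorm(config$n_strides)) * fs / 8
  ))
  durations <- n_samp / fs

  is_outlier <- runif(config$n_strides) < config$outlier_stride_prob
  truth <- tibble::tibble(
    stride_index = seq_len(config$n_strides),
    duration_s = durations,
    hd_min_mm = config$asym_hdmin + ifelse(is_outlier, config$outlier_magnitude, 0),
    hd_max_mm = config$asym_hdmax,
    pd_min_mm = config$asym_pdmin,
    pd_max_mm = config$asym_pdmax,
    outlier = is_outlier
  )

  phase <- unlist(lapply(n_samp, function(n) (seq_len(n) - 1) / n))
  stride_of <- rep(seq_len(config$n_strides), n_samp)
  head_z <- stride_waveform(phase, config$head_amplitude,
                            truth$hd_min_mm[stride_of], truth$hd_max_mm[stride_of])
  pelvis_z <- stride_waveform(phase, config$pelvis_amplitude,
                              truth$pd_min_mm[stride_of], truth$pd_max_mm[stride_of])
  n_total <- length(phase)
  if (config$noise_sd > 0) {
    head_z <- head_z + rnorm(n_total, 0, config$noise_sd)
    pelvis_z <- pelvis_z + rnorm(n_total, 0, config$noise_sd)
  }

  # terminal boundary sample (phase 0 of the cycle after the last stride) so
  # that segmentation can close the final stride
  closing_noise <- if (config$noise_sd > 0) rnorm(2, 0, config$noise_sd) else c(0, 0)
  traces <- tibble::tibble(
    time_s = (seq_len(n_total + 1) - 1) / fs,
    head_z_mm = c(head_z, stride_waveform(0, config$head_amplitude,
                                          truth$hd_min_mm[config$n_strides],
                                          truth$hd_max_mm[config$n_strides]) +
                    closing_noise[1]),
    pelvis_z_mm = c(pelvis_z, stride_waveform(0, config$pelvis_amplitude,
                                              truth$pd_min_mm[config$n_strides],
                                              truth$pd_max_mm[config$n_strides]) +
                      closing_noise[2]),
    pastern_z_mm = 10 * sin(2 * pi * c(phase, 0)),
    pastern_phase = c(phase, 0)
  )
  list(traces = traces, truth = truth)
}
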