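#' Schema describing a deposited trial-summary workbook
#'
#' The study's deposited data ship as a workbook with one sheet per
#' condition ('Straight-line Hard Surface', 'Straight-line Soft Surface',
#' 'Lunge'); this package reads each sheet as a CSV file of the same name.
#' The schema maps the external column headers onto the internal trial
#' summary fields and declares the condition labels, so a differently
#' labelled export can be ingested by editing the schema rather than the
#' data. Units are millimetres for parameters and seconds for durations;
#' signs are right-positive.
#'
#' @param sheets Named character vector mapping condition groups
#'   (`straight_hard`, `straight_soft`, `lunge`) to file base names.
#' @param columns Named character vector mapping external column names to
#'   internal field names.
#' @param direction_labels Named character vector mapping the Lunge sheet's
#'   direction codes to `lunge_left`/`lunge_right`.
#' @return A list of class `sheet_schema`.
#' @export
sheet_schema <- function(sheets = c(straight_hard = "Straight-line Hard Surface",
                                    straight_soft = "Straight-line Soft Surface",
                                    lunge = "Lunge"),
                         columns = c(
                           "Horse" = "horse_id",
                           "Discipline" = "discipline",
                           "Strides (n)" = "n_strides",
                           "Stride duration (s)" = "mean_stride_duration_s",
                           "HDmin mean (mm)" = "mean_hd_min_mm",
                           "HDmin SD (mm)" = "sd_hd_min_mm",
                           "HDmax mean (mm)" = "mean_hd_max_mm",
                           "HDmax SD (mm)" = "sd_hd_max_mm",
                           "PDmin mean (mm)" = "mean_pd_min_mm",
                           "PDmin SD (mm)" = "sd_pd_min_mm",
                           "PDmax mean (mm)" = "mean_pd_max_mm",
                           "PDmax SD (mm)" = "sd_pd_max_mm"
                         ),
                         direction_labels = c("left" = "lunge_left",
                                              "right" = "lunge_right")) {
  required <- c("horse_id", "n_strides", "mean_stride_duration_s",
                paste0(rep(c("mean_", "sd_"), 4),
                       rep(c("hd_min", "hd_max", "pd_min", "pd_max"), each = 2),
                       "_mm"))
  dup <- columns[duplicated(columns)]
  if (length(dup)) {
    abort(paste("internal field mapped more than once:", paste(dup, collapse = ", ")),
          class = "equisym_schema_error")
  }
  missing <- setdiff(required, columns)
  if (length(missing)) {
    abort(paste("schema misses required field(s):", paste(missing, collapse = ", ")),
          class = "equisym_schema_error")
  }
  structure(list(sheets = sheets, columns = columns,
                 direction_labels = direction_labels),
            class = "sheet_schema")
}

#' Write trial summaries as a sheet-per-condition CSV workbook
#'
#' Inverse of [read_trial_sheets()]: splits a trial summary table into the
#' three condition sheets with the schema's external column names. The
#' Lunge sheet carries both directions with a `Direction` column.
#'
#' @param summaries Trial summary table (internal names, `condition`
#'   column).
#' @param dir Output directory (created if needed).
#' @param schema A [sheet_schema()].
#' @return Invisibly, the written file paths.
#' @export
write_trial_sheets <- function(summaries, dir, schema = sheet_schema()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inv_cols <- stats::setNames(names(schema$columns), schema$columns)
  inv_dir <- stats::setNames(names(schema$direction_labels), schema$direction_labels)
  paths <- character(0)
  for (grp in names(schema$sheets)) {
    d <- if (grp == "lunge") {
      summaries |>
        dplyr::filter(.data$condition %in% names(inv_dir)) |>
        dplyr::mutate(Direction = inv_dir[.data$condition])
    } else {
      dplyr::filter(summaries, .data$condition == grp)
    }
    d <- dplyr::select(d, dplyr::any_of(c(unname(schema$columns), "Direction")))
    keep <- intersect(names(d), schema$columns)
    names(d)[match(keep, names(d))] <- inv_cols[keep]
    path <- file.path(dir, paste0(schema$sheets[[grp]], ".csv"))
    readr::write_csv(d, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a sheet-per-condition trial-summary workbook
#'
#' Reads the three condition sheets (CSV files named after the workbook
#' sheets) from `dir`, maps external columns to internal fields via the
#' schema, validates numeric fields row by row and attaches condition
#' labels. Unmapped columns are reported as a message; missing sheets or
#' columns raise a schema error naming the gap; rows with non-numeric
#' values in numeric fields are dropped and reported in the
#' `row_errors` attribute.
#'
#' @param dir Directory containing the sheet CSV files.
#' @param schema A [sheet_schema()].
#' @return A tibble of trial summaries (one row per horse and condition)
#'   with attribute `row_errors`.
#' @export
read_trial_sheets <- function(dir, schema = sheet_schema()) {
  numeric_fields <- setdiff(unname(schema$columns), c("horse_id", "discipline"))
  out <- list()
  errors <- list()
  for (grp in names(schema$sheets)) {
    path <- file.path(dir, paste0(schema$sheets[[grp]], ".csv"))
    if (!file.exists(path)) {
      abort(paste0("missing sheet '", schema$sheets[[grp]], "' (", path, ")"),
            class = "equisym_schema_error")
    }
    d <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
    need_external <- names(schema$columns)[schema$columns %in%
                                             c("horse_id", numeric_fields)]
    miss <- setdiff(need_external, names(d))
    if (length(miss)) {
      abort(paste0("sheet '", schema$sheets[[grp]], "' misses column(s): ",
                   paste(miss, collapse = ", ")),
            class = "equisym_schema_error")
    }
    extra <- setdiff(names(d), c(names(schema$columns), "Direction"))
    if (length(extra)) {
      message("sheet '", schema$sheets[[grp]], "': ignoring unmapped column(s): ",
              paste(extra, collapse = ", "))
    }
    keep <- intersect(names(d), names(schema$columns))
    names(d)[match(keep, names(d))] <- schema$columns[keep]
    if (grp == "lunge") {
      if (!"Direction" %in% names(d)) {
        abort("Lunge sheet misses the 'Direction' column",
              class = "equisym_schema_error")
      }
      bad_dir <- setdiff(unique(d$Direction), names(schema$direction_labels))
      if (length(bad_dir)) {
        abort(paste("unknown lunge direction label(s):",
                    paste(bad_dir, collapse = ", ")),
              class = "equisym_schema_error")
      }
      d$condition <- unname(schema$direction_labels[d$Direction])
      d$Direction <- NULL
    } else {
      d$condition <- grp
    }
    suppressWarnings(converted <- dplyr::mutate(
      d, dplyr::across(dplyr::all_of(numeric_fields), as.numeric)
    ))
    bad <- !complete.cases(converted[numeric_fields])
    if (any(bad)) {
      errors[[grp]] <- tibble::tibble(
        sheet = schema$sheets[[grp]],
        row = which(bad),
        horse_id = d$horse_id[bad]
      )
    }
    out[[grp]] <- converted[!bad, ]
  }
  res <- dplyr::bind_rows(out)
  attr(res, "row_errors") <- dplyr::bind_rows(errors)
  res
}

# hard/soft assessments side by side for concordance and reporting
widen_assessments <- function(assessed) {
  assessed |>
    dplyr::filter(.data$condition %in% c("straight_hard", "straight_soft")) |>
    dplyr::mutate(surface = sub("straight_", "", .data$condition)) |>
    dplyr::select(dplyr::any_of(c("horse_id", "discipline")), "surface",
                  "classification", "high_variability", "double_threshold") |>
    tidyr::pivot_wider(names_from = "surface",
                       values_from = c("classification", "high_variability",
                                       "double_threshold"))
}

#' Run the full asymmetry pipeline
#'
#' Orchestrates the package end to end: simulate a population (or take a
#' trial-summary table read from deposited sheets), apply stride-level QC
#' and trial inclusion rules, classify horses per straight-line surface,
#' compute Total Asymmetry Scores, produce prevalence / double-threshold /
#' concordance / exceedance reports and, when questionnaire data are
#' present, fit the sidedness association models for the graded sidedness
#' question against straight-line and lunge TAS. When `out_dir` is given,
#' all tables plus a JSON run manifest (package version, seed, stage
#' settings) are written there as CSV.
#'
#' @param population A [population_config()] used to simulate input data;
#'   ignored when `summaries` is supplied.
#' @param summaries Optional pre-computed trial summary table (e.g. from
#'   [read_trial_sheets()]); skips simulation and stride-level QC.
#' @param thresholds An [asym_thresholds()].
#' @param associate Fit the association models (needs questionnaire data).
#' @param quartile_type Top-quartile convention for [exceedance_report()].
#' @param out_dir Optional output directory.
#' @return A list: `summaries`, `assessments` (per condition), `wide`
#'   (hard/soft side by side), `population_hard`, `population_soft`,
#'   `concordance`, `exceedance_hard`, `exceedance_soft`, `tas_straight`,
#'   `tas_lunge`, `qc_reports`, `associations` (list or `NULL`),
#'   `manifest`.
#' @export
run_pipeline <- function(population = population_config(),
                         summaries = NULL,
                         thresholds = asym_thresholds(),
                         associate = TRUE,
                         quartile_type = "strict_above",
                         out_dir = NULL) {
  questionnaire <- NULL
  qc_reports <- NULL
  simulated <- is.null(summaries)
  if (simulated) {
    pop <- simulate_population(population, thresholds)
    questionnaire <- pop$questionnaire
    grouped <- dplyr::group_by(pop$strides, .data$horse_id, .data$condition)
    cleaned <- dplyr::ungroup(
      dplyr::group_modify(grouped, ~ remove_stride_outliers(.x)$strides)
    )
    qc_reports <- dplyr::ungroup(
      dplyr::group_modify(grouped, ~ remove_stride_outliers(.x)$report)
    )
    summaries <- summarize_trials(cleaned, .data$horse_id, .data$condition) |>
      dplyr::left_join(dplyr::select(pop$horses, "horse_id", "discipline"),
                       by = "horse_id")
  }

  summaries <- apply_inclusion_rules(summaries)
  included <- dplyr::filter(summaries, .data$included)
  assessed <- classify_trials(included, thresholds)

  straight <- dplyr::filter(assessed, .data$condition %in%
                              c("straight_hard", "straight_soft"))
  pop_hard <- population_summary(dplyr::filter(straight, .data$condition == "straight_hard"))
  pop_soft <- population_summary(dplyr::filter(straight, .data$condition == "straight_soft"))
  wide <- widen_assessments(assessed)
  concord <- concordance_summary(wide)
  exc_hard <- exceedance_report(
    dplyr::filter(included, .data$condition == "straight_hard"), thresholds,
    quartile_type)
  exc_soft <- exceedance_report(
    dplyr::filter(included, .data$condition == "straight_soft"), thresholds,
    quartile_type)
  tas_straight <- included |>
    dplyr::filter(.data$condition == "straight_hard") |>
    compute_tas(column = "tas_straight_mm") |>
    dplyr::select(dplyr::any_of(c("horse_id", "discipline")), "tas_straight_mm",
                  "mean_stride_duration_s")
  tas_lunge <- compute_tas_lunge(included)

  associations <- NULL
  if (associate && !is.null(questionnaire) && nrow(questionnaire) >= 10) {
    q <- dplyr::mutate(questionnaire,
                       sidedness = merge_sidedness_grades(.data$q1_sidedness))
    d_straight <- dplyr::inner_join(tas_straight, q, by = "horse_id")
    d_lunge <- dplyr::inner_join(tas_lunge, q, by = "horse_id")
    associations <- list(
      sidedness_tas_straight = try(fit_association(
        d_straight, .data$tas_straight_mm, .data$sidedness,
        .data$mean_stride_duration_s, .data$rider_id), silent = TRUE),
      sidedness_tas_lunge = try(fit_association(
        d_lunge, .data$tas_lunge_mm, .data$sidedness,
        .data$mean_stride_duration_s, .data$rider_id), silent = TRUE)
    )
  }

  manifest <- list(
    package = "equisym",
    version = as.character(utils::packageVersion("equisym")),
    seed = if (simulated) population$seed %||% NA else NA,
    thresholds = unclass(thresholds),
    quartile_type = quartile_type,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  res <- list(
    summaries = summaries, assessments = assessed, wide = wide,
    population_hard = pop_hard, population_soft = pop_soft,
    concordance = concord, exceedance_hard = exc_hard,
    exceedance_soft = exc_soft, tas_straight = tas_straight,
    tas_lunge = tas_lunge, qc_reports = qc_reports,
    associations = associations, manifest = manifest
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tables <- c("summaries", "assessments", "wide", "population_hard",
                "population_soft", "concordance", "exceedance_hard",
                "exceedance_soft", "tas_straight", "tas_lunge", "qc_reports")
    for (nm in tables) {
      if (!is.null(res[[nm]])) {
        readr::write_csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")))
      }
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, null = "null")
    }
  }
  res
}
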