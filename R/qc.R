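#' Iterative outlier removal on stride asymmetry parameters
#'
#' Removes outlier strides the way the commercial processing chain does for
#' the head parameters: each stride is compared with the trial average using
#' the Mahalanobis distance over the selected parameter block, strides lying
#' three or more standard deviations out (squared distance >= 9 for the
#' bivariate head block) are dropped, and the procedure repeats on the
#' remaining strides until no further stride is removed. When the parameter
#' covariance is singular (e.g. a constant parameter) the rule falls back to
#' a per-parameter univariate 3-SD screen, which is recorded in the report.
#' Zero-variance data produce no outliers. The operation is idempotent:
#' applied to its own output it removes nothing.
#'
#' @param strides Stride table as produced by [stride_asymmetries()] (columns
#'   `hd_min_mm`, `hd_max_mm`, `pd_min_mm`, `pd_max_mm`). Flagged strides
#'   (`flagged == TRUE`), if present, are ignored by the distance computation
#'   and dropped from the output.
#' @param parameters `"head"` (default: the bivariate `hd_min`/`hd_max`
#'   block, matching the standard processing) or `"all"` (all four
#'   parameters jointly).
#' @param method `"mahalanobis"` (default) or `"univariate"` for the plain
#'   per-parameter 3-SD rule.
#' @param threshold Distance threshold in SD units; strides at or beyond it
#'   are removed (inclusive, default 3).
#' @param max_iter Safety cap on iterations.
#' @return A list with `strides` (the cleaned tibble) and `report`, a
#'   one-row tibble: `n_strides_in`, `n_removed_auto`, `n_removed_flagged`,
#'   `iterations`, `method`, `qc_fail`.
#' @export
#' @examples
#' sa <- tibble::tibble(
#'   stride_index = 1:31, duration_s = 0.7,
#'   hd_min_mm = c(rep(0, 30), 100) + rnorm(31, 0, 0.5),
#'   hd_max_mm = rnorm(31, 0, 0.5), pd_min_mm = 0, pd_max_mm = 0
#' )
#' remove_stride_outliers(sa)$report
remove_stride_outliers <- function(strides,
                                   parameters = c("head", "all"),
                                   method = c("mahalanobis", "univariate"),
                                   threshold = 3,
                                   max_iter = 100L) {
  parameters <- match.arg(parameters)
  method <- match.arg(method)
  cols <- switch(parameters,
    head = c("hd_min_mm", "hd_max_mm"),
    all = c("hd_min_mm", "hd_max_mm", "pd_min_mm", "pd_max_mm")
  )
  missing_cols <- setdiff(cols, names(strides))
  if (length(missing_cols)) {
    abort(paste("missing parameter columns:", paste(missing_cols, collapse = ", ")),
          class = "equisym_input_error")
  }

  n_in <- nrow(strides)
  if (n_in < 2) abort("need at least 2 strides", class = "equisym_input_error")
  n_flagged <- 0L
  if ("flagged" %in% names(strides)) {
    n_flagged <- sum(strides$flagged)
    strides <- dplyr::filter(strides, !.data$flagged)
  }

  keep <- strides
  iterations <- 0L
  method_used <- method
  repeat {
    iterations <- iterations + 1L
    X <- as.matrix(keep[, cols])
    if (nrow(X) < 2) break
    mu <- colMeans(X)
    S <- cov(X)
    out <- NULL
    if (method == "mahalanobis") {
      singular <- any(diag(S) < 1e-12) ||
        inherits(try(solve(S), silent = TRUE), "try-error") ||
        abs(det(S)) < 1e-12 * prod(pmax(diag(S), 1e-300))
      if (!singular) {
        d2 <- mahalanobis(X, mu, S)
        out <- d2 >= threshold^2
      } else {
        method_used <- "univariate-fallback"
      }
    }
    if (is.null(out)) {
      # univariate screen; constant parameters (sd = 0) yield no outliers
      sds <- apply(X, 2, sd)
      out <- rep(FALSE, nrow(X))
      for (j in seq_along(cols)) {
        if (sds[j] > 0) out <- out | abs(X[, j] - mu[j]) >= threshold * sds[j]
      }
    }
    if (!any(out) || iterations >= max_iter) break
    keep <- keep[!out, , drop = FALSE]
  }

  list(
    strides = tibble::as_tibble(keep),
    report = tibble::tibble(
      n_strides_in = n_in,
      n_removed_auto = (n_in - n_flagged) - nrow(keep),
      n_removed_flagged = n_flagged,
      iterations = iterations,
      method = method_used,
      qc_fail = nrow(keep) == 0
    )
  )
}

#' Drop manually identified stride ranges from a trial
#'
#' Removes contiguous stride sequences identified from trial video (head
#' tossing, biting at the handler, ...) before any further processing.
#'
#' @param strides Stride table with a `stride_index` column.
#' @param ranges Data frame with columns `start` and `end` (inclusive stride
#'   indices), or `NULL`/empty for no exclusions.
#' @return A list with `strides` (remaining rows) and `report` (one-row
#'   tibble: `n_strides_in`, `n_removed_manual`, `qc_fail`).
#' @export
exclude_stride_ranges <- function(strides, ranges = NULL) {
  n_in <- nrow(strides)
  if (is.null(ranges) || nrow(as.data.frame(ranges)) == 0) {
    return(list(
      strides = tibble::as_tibble(strides),
      report = tibble::tibble(n_strides_in = n_in, n_removed_manual = 0L,
                              qc_fail = FALSE)
    ))
  }
  ranges <- dplyr::arrange(tibble::as_tibble(ranges), .data$start)
  if (any(ranges$start > ranges$end)) {
    abort("each range needs start <= end", class = "equisym_input_error")
  }
  if (any(ranges$start < min(strides$stride_index)) ||
      any(ranges$end > max(strides$stride_index))) {
    abort("exclusion range outside trial stride indices",
          class = "equisym_input_error")
  }
  if (nrow(ranges) > 1 && any(ranges$start[-1] <= ranges$end[-nrow(ranges)])) {
    abort("exclusion ranges overlap", class = "equisym_input_error")
  }
  drop_idx <- unlist(purrr::map2(ranges$start, ranges$end, seq))
  out <- dplyr::filter(strides, !(.data$stride_index %in% drop_idx))
  list(
    strides = out,
    report = tibble::tibble(
      n_strides_in = n_in,
      n_removed_manual = n_in - nrow(out),
      qc_fail = nrow(out) == 0
    )
  )
}

#' Trial inclusion rules by condition and stride count
#'
#' After outlier removal, lunge trials need at least 25 strides and
#' straight-line trials at least 20. Straight-line trials with 16-19 strides
#' are still accepted when every asymmetry parameter's SD is below the
#' parameter's absolute mean (a low-variability exception); trials with
#' exactly 20 strides pass the ordinary rule.
#'
#' @param summaries Trial summary table from [summarize_trials()] (needs
#'   `condition`, `n_strides` and the per-parameter mean/SD columns).
#' @return The input with `included` (logical) and `exclusion_reason`
#'   (character, `NA` when included) appended.
#' @export
apply_inclusion_rules <- function(summaries) {
  if (!"condition" %in% names(summaries) || anyNA(summaries$condition)) {
    abort("`condition` column required for inclusion rules",
          class = "equisym_input_error")
  }
  is_lunge <- grepl("^lunge", summaries$condition)
  low_var <- with(summaries,
    sd_hd_min_mm < abs(mean_hd_min_mm) & sd_hd_max_mm < abs(mean_hd_max_mm) &
    sd_pd_min_mm < abs(mean_pd_min_mm) & sd_pd_max_mm < abs(mean_pd_max_mm))
  n <- summaries$n_strides
  included <- ifelse(is_lunge, n >= 25, n >= 20 | (n >= 16 & low_var))
  reason <- dplyr::case_when(
    included ~ NA_character_,
    is_lunge ~ "lunge trial with fewer than 25 strides",
    n < 16 ~ "straight-line trial with fewer than 16 strides",
    TRUE ~ "straight-line trial with 16-19 strides and SD >= |mean| for some parameter"
  )
  dplyr::mutate(summaries, included = included, exclusion_reason = reason)
}
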