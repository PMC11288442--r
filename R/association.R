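#' Reduce overlapping questionnaire questions and drop no-sidedness ones
#'
#' Applies the question-selection procedure: within each declared group of
#' closely related questions the member with the fewest non-answers ("na")
#' is kept (ties go to the first in declared order); any question whose
#' share of "no" responses among answered ones exceeds `no_cutoff` is then
#' excluded, since it records no perceived sidedness. Which questions
#' overlap is a study-design input, not something inferred from the data.
#'
#' @param responses Data frame with one row per horse and one column per
#'   question; values `"na"` count as non-answers.
#' @param groups List of character vectors of column names; singletons may
#'   be omitted (ungrouped questions form their own group).
#' @param no_cutoff Exclusion cutoff on the "no" share (default 0.5,
#'   strictly greater than).
#' @return A tibble, one row per question: `question`, `n_na`, `prop_no`,
#'   `selected` (survived its group), `retained` (selected and below the
#'   cutoff), `reason`.
#' @export
reduce_questions <- function(responses, groups = NULL, no_cutoff = 0.5) {
  qcols <- setdiff(names(responses), c("horse_id", "rider_id"))
  if (length(qcols) == 0) abort("no question columns", class = "equisym_input_error")
  grouped <- unlist(groups)
  if (!all(grouped %in% qcols)) {
    abort("group members must be question columns", class = "equisym_input_error")
  }
  groups <- c(groups, as.list(setdiff(qcols, grouped)))

  stats <- purrr::map_dfr(qcols, function(q) {
    x <- responses[[q]]
    n_na <- sum(is.na(x) | x == "na")
    answered <- x[!is.na(x) & x != "na"]
    tibble::tibble(question = q, n_na = n_na,
                   prop_no = if (length(answered)) mean(answered == "no") else NA_real_)
  })
  winners <- purrr::map_chr(groups, function(g) {
    g[which.min(stats$n_na[match(g, stats$question)])]
  })
  stats |>
    dplyr::mutate(
      selected = .data$question %in% winners,
      retained = .data$selected & !is.na(.data$prop_no) & .data$prop_no <= no_cutoff,
      reason = dplyr::case_when(
        !selected ~ "overlaps with a question having fewer na answers",
        !retained ~ sprintf("over %d%% of responders perceived no sidedness",
                            round(100 * no_cutoff)),
        TRUE ~ NA_character_
      )
    )
}

#' Binarize a left/right questionnaire response
#'
#' Converts directional answers to presence/absence: `"left"` and `"right"`
#' become `"yes"`, `"no"` stays `"no"`, `"na"` (or `NA`) becomes missing.
#'
#' @param x Character vector of responses.
#' @return Factor with levels `no`, `yes`.
#' @export
#' @examples
#' binarize_response(c("left", "no", "right", "na"))
binarize_response <- function(x) {
  known <- c("no", "left", "right", "na", NA)
  if (!all(x %in% known)) {
    abort(paste("unknown response code(s):",
                paste(unique(setdiff(x, known)), collapse = ", ")),
          class = "equisym_input_error")
  }
  out <- dplyr::case_when(
    x %in% c("left", "right") ~ "yes",
    x == "no" ~ "no",
    TRUE ~ NA_character_
  )
  factor(out, levels = c("no", "yes"))
}

#' Merge graded sidedness responses for modelling
#'
#' The graded sidedness question is analysed on three levels; the rare
#' `"severe"` answers are merged into `"moderate"`.
#'
#' @param x Character vector with values in no/mild/moderate/severe/na.
#' @return Ordered-level factor `no < mild < moderate`.
#' @export
#' @examples
#' merge_sidedness_grades(c("no", "severe", "mild"))
merge_sidedness_grades <- function(x) {
  known <- c("no", "mild", "moderate", "severe", "na", NA)
  if (!all(x %in% known)) {
    abort(paste("unknown response code(s):",
                paste(unique(setdiff(x, known)), collapse = ", ")),
          class = "equisym_input_error")
  }
  out <- ifelse(x == "severe", "moderate", x)
  out[out == "na"] <- NA
  factor(out, levels = c("no", "mild", "moderate"))
}

# ML Box-Cox lambda on a fixed grid for the fixed-effects formula
boxcox_lambda <- function(formula, data, grid = seq(-2, 2, by = 0.1)) {
  m <- stats::lm(formula, data = data, y = TRUE, qr = TRUE)
  bc <- MASS::boxcox(m, lambda = grid, plotit = FALSE)
  bc$x[which.max(bc$y)]
}

boxcox_apply <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

#' Mixed-model association between a questionnaire answer and asymmetry
#'
#' Fits the study's association model for one question: the absolute
#' asymmetry magnitude (a parameter's |trial mean| or a Total Asymmetry
#' Score) as response, the questionnaire factor and mean stride duration (a
#' speed proxy) as fixed effects, and a random intercept per rider. One
#' observation per horse. When the residuals of an initial fit are skewed
#' (absolute skewness above `skew_threshold`), the response is Box-Cox
#' transformed (maximum-likelihood lambda on a 0.1-spaced grid, after adding
#' `offset` mm since magnitudes can be zero) and the model refitted. Type
#' III tests use Satterthwaite degrees of freedom; pairwise comparisons of
#' the factor levels use estimated marginal means with Tukey adjustment by
#' default. A singular rider term triggers a fixed-effects-only fallback,
#' which is flagged, not hidden.
#'
#' @param data Data frame, one row per horse.
#' @param response,predictor,duration,rider Column names (tidy-eval) of the
#'   asymmetry magnitude (mm), the questionnaire factor, the stride-duration
#'   covariate (s) and the rider identifier.
#' @param skew_threshold Absolute residual skewness above which the Box-Cox
#'   refit triggers (default 1).
#' @param offset Positive constant (mm) added before the Box-Cox transform.
#' @param adjust Multiplicity adjustment for pairwise contrasts
#'   (`"tukey"` default, `"none"` to disable).
#' @param contrasts Compute marginal means and pairwise contrasts (disable
#'   for speed in simulations).
#' @return An object of class `equisym_assoc`: list with `model`, `anova`
#'   (term, statistic, df, p.value), `emmeans`, `contrasts`,
#'   `transformation` (`"none"` or `"boxcox"`), `lambda`, `offset`,
#'   `fallback` (`"none"` or `"fixed-only"`), `degenerate` (zero-variance
#'   response), `n_obs`, `n_riders`. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' pop <- simulate_population(population_config(n_horses = 40, seed = 2))
#' sm <- summarize_trials(pop$strides, horse_id, condition)
#' tas <- compute_tas_lunge(sm) |>
#'   dplyr::inner_join(pop$questionnaire, by = "horse_id") |>
#'   dplyr::mutate(sidedness = merge_sidedness_grades(q1_sidedness))
#' fit <- fit_association(tas, tas_lunge_mm, sidedness,
#'                        mean_stride_duration_s, rider_id)
#' tidy(fit)
fit_association <- function(data, response, predictor, duration, rider,
                            skew_threshold = 1, offset = 1,
                            adjust = "tukey", contrasts = TRUE) {
  d <- data |>
    dplyr::transmute(
      .value = {{ response }},
      .pred = {{ predictor }},
      .dur = {{ duration }},
      .rider = as.factor({{ rider }})
    ) |>
    dplyr::filter(complete.cases(dplyr::pick(dplyr::everything())))
  if (!is.factor(d$.pred)) d$.pred <- factor(d$.pred)
  d$.pred <- droplevels(d$.pred)
  if (nlevels(d$.pred) < 2) {
    abort("predictor needs at least 2 observed levels", class = "equisym_input_error")
  }
  if (dplyr::n_distinct(d$.rider) < 2) {
    abort("need at least 2 riders", class = "equisym_input_error")
  }
  if (any(d$.value < 0)) {
    abort("response must be a non-negative asymmetry magnitude",
          class = "equisym_input_error")
  }

  degenerate <- stats::var(d$.value) < 1e-12
  transformation <- "none"
  lambda <- NA_real_
  d$.y <- d$.value

  fit_once <- function(dd) {
    m <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(.y ~ .pred + .dur + (1 | .rider), data = dd)
      )),
      error = function(e) NULL
    )
    if (is.null(m) || lme4::isSingular(m, tol = 1e-4)) {
      list(model = stats::lm(.y ~ .pred + .dur, data = dd),
           fallback = "fixed-only")
    } else {
      list(model = m, fallback = "none")
    }
  }

  if (degenerate) {
    f <- list(model = stats::lm(.y ~ .pred + .dur, data = d), fallback = "fixed-only")
  } else {
    f <- fit_once(d)
    skew <- e1071::skewness(residuals(f$model), type = 2)
    if (is.finite(skew) && abs(skew) > skew_threshold) {
      transformation <- "boxcox"
      d$.yoff <- d$.value + offset
      lambda <- boxcox_lambda(.yoff ~ .pred + .dur, d)
      d$.y <- boxcox_apply(d$.yoff, lambda)
      f <- fit_once(d)
    }
  }

  if (inherits(f$model, "lmerModLmerTest")) {
    a <- stats::anova(f$model, type = "III")
    anova_tbl <- tibble::tibble(
      term = c("predictor", "stride_duration")[match(rownames(a), c(".pred", ".dur"))],
      statistic = a[["F value"]], num_df = a$NumDF, den_df = a$DenDF,
      p.value = a[["Pr(>F)"]]
    )
  } else {
    a <- if (degenerate) suppressWarnings(drop1(f$model, test = "F")) else
      drop1(f$model, test = "F")
    keep <- rownames(a) %in% c(".pred", ".dur")
    anova_tbl <- tibble::tibble(
      term = c("predictor", "stride_duration")[match(rownames(a)[keep], c(".pred", ".dur"))],
      statistic = a[["F value"]][keep], num_df = a$Df[keep],
      den_df = stats::df.residual(f$model), p.value = a[["Pr(>F)"]][keep]
    )
  }

  emm_tbl <- contr_tbl <- NULL
  if (contrasts && !degenerate) {
    emm <- emmeans::emmeans(f$model, specs = ".pred")
    emm_tbl <- tibble::as_tibble(emm) |>
      dplyr::rename(group = ".pred")
    pw <- emmeans::contrast(emm, method = "pairwise", adjust = adjust)
    contr_tbl <- tibble::as_tibble(summary(pw))
  }

  structure(
    list(
      model = f$model, anova = anova_tbl, emmeans = emm_tbl,
      contrasts = contr_tbl, transformation = transformation, lambda = lambda,
      offset = offset, fallback = f$fallback, degenerate = degenerate,
      n_obs = nrow(d), n_riders = dplyr::n_distinct(d$.rider),
      adjust = adjust
    ),
    class = "equisym_assoc"
  )
}

#' Pairwise marginal-mean contrasts of a fitted association model
#'
#' @param fit An [fit_association()] result.
#' @return Tibble of all pairwise group comparisons (estimate, SE, p-value),
#'   empty when contrasts were not computed.
#' @export
pairwise_contrasts <- function(fit) {
  stopifnot(inherits(fit, "equisym_assoc"))
  fit$contrasts %||% tibble::tibble()
}

#' @export
print.equisym_assoc <- function(x, ...) {
  cat("Sidedness-asymmetry association model\n")
  cat("  observations:", x$n_obs, " riders:", x$n_riders, "\n")
  cat("  transformation:", x$transformation,
      if (x$transformation == "boxcox") sprintf("(lambda = %.2f)", x$lambda) else "",
      "\n")
  if (x$fallback != "none") cat("  NOTE: fallback =", x$fallback, "\n")
  cat("  Type III tests:\n")
  print(as.data.frame(x$anova), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.equisym_assoc <- function(x, ...) {
  cf <- as.data.frame(coef(summary(x$model)))
  out <- tibble::tibble(
    term = rownames(cf),
    estimate = cf$Estimate,
    std.error = cf[["Std. Error"]],
    statistic = cf[["t value"]]
  )
  if ("df" %in% names(cf)) out$df <- cf$df
  pcol <- intersect(c("Pr(>|t|)"), names(cf))
  if (length(pcol)) out$p.value <- cf[[pcol]]
  out$term <- sub("^\\.pred", "group:", out$term)
  out$term <- sub("^\\.dur$", "stride_duration", out$term)
  out
}

#' @exportS3Method generics::glance
glance.equisym_assoc <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_riders = x$n_riders,
    transformation = x$transformation,
    lambda = x$lambda,
    fallback = x$fallback,
    degenerate = x$degenerate,
    sigma = stats::sigma(x$model),
    logLik = as.numeric(logLik(x$model)),
    AIC = stats::AIC(x$model)
  )
}
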