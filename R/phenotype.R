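# Long-term mean blood-pressure trait: medication adjustment, per-visit
# covariate residualization, per-individual averaging.

#' Adjust systolic blood pressure for antihypertensive treatment
#'
#' Adds a fixed constant (default 15 mmHg) to the measured SBP at visits
#' where the individual was on antihypertensive medication, approximating
#' the untreated pressure. `delta = 0` disables the adjustment.
#'
#' @param sbp Numeric vector of systolic blood pressure (mmHg).
#' @param treated Logical (or 0/1) vector, recycled against `sbp`.
#' @param delta Medication adjustment in mmHg; default 15.
#' @return Adjusted SBP vector (mmHg). Missing values pass through.
#' @export
medication_adjust <- function(sbp, treated, delta = 15) {
  if (!is.numeric(sbp) || any(is.infinite(sbp))) {
    abort("`sbp` must be numeric and finite where present.",
          class = "linkassoc_invalid_input")
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta)) {
    abort("`delta` must be a single finite number.", class = "linkassoc_invalid_input")
  }
  treated <- rep_len(as.logical(treated), length(sbp))
  sbp + ifelse(treated %in% TRUE, delta, 0)
}

#' Residualize visit measurements on age and sex
#'
#' Ordinary least-squares fit of the (medication-adjusted) measurements on
#' an intercept, age and sex; returns the residuals. Rows with any missing
#' value get `NA` residuals and are excluded from the fit.
#'
#' @param values Numeric vector of medication-adjusted SBP (mmHg).
#' @param age Numeric vector of ages (years); must vary.
#' @param sex Binary vector (0/1 or logical).
#' @return Numeric vector of residuals, same length as `values`; the fitted
#'   coefficients are attached as attribute `"coefficients"`.
#' @export
visit_residualize <- function(values, age, sex) {
  n <- length(values)
  if (length(age) != n || length(sex) != n) {
    abort("`values`, `age` and `sex` must have equal length.",
          class = "linkassoc_invalid_input")
  }
  sex <- as.numeric(sex)
  use <- complete.cases(values, age, sex)
  if (sum(use) < 3L) {
    abort("Need at least 3 complete visits to residualize.",
          class = "linkassoc_invalid_input")
  }
  if (sd(age[use]) == 0) {
    abort("Degenerate design: age is constant across visits in the fit.",
          class = "linkassoc_degenerate_design")
  }
  fit <- lm(values ~ age + sex, data = data.frame(values, age, sex)[use, ])
  if (anyNA(coef(fit))) {
    abort("Degenerate (rank-deficient) design in visit residualization.",
          class = "linkassoc_degenerate_design")
  }
  out <- rep(NA_real_, n)
  out[use] <- resid(fit)
  attr(out, "coefficients") <- coef(fit)
  out
}

#' Long-term mean adjusted blood-pressure trait
#'
#' Builds the per-individual quantitative trait from repeated visit
#' measurements: add `delta` mmHg to SBP at treated visits, residualize each
#' visit separately on intercept + age + sex by least squares (ages differ by
#' visit; set `pooled = TRUE` to fit one model across all visits), then
#' average the available residuals within each individual. Individuals with
#' no usable visit are dropped and reported in the `"dropped"` attribute.
#'
#' @param visits Long-format visit table: data frame with columns `id`,
#'   `visit`, `sbp`, `age`, `sex`, `treated`; missing measurements as `NA`.
#' @param delta Medication adjustment in mmHg (default 15).
#' @param pooled If `TRUE`, residualize all visits in one pooled fit instead
#'   of per visit.
#' @return A tibble with columns `id`, `trait` (residual units, mean about
#'   zero), one row per retained individual; dropped ids in
#'   `attr(, "dropped")`.
#' @examples
#' visits <- tibble::tibble(
#'   id = rep(c("a", "b", "c", "d"), each = 2), visit = rep(1:2, 4),
#'   sbp = c(118, 121, 135, 140, 128, NA, 110, 115),
#'   age = c(40, 42, 55, 57, 47, 49, 33, 35),
#'   sex = rep(c(0, 1, 0, 1), each = 2),
#'   treated = c(0, 0, 1, 1, 0, 0, 0, 0)
#' )
#' long_term_mean(visits)
#' @export
long_term_mean <- function(visits, delta = 15, pooled = FALSE) {
  need <- c("id", "visit", "sbp", "age", "sex", "treated")
  if (!is.data.frame(visits) || !all(need %in% names(visits))) {
    abort(sprintf("`visits` needs columns %s.", paste(need, collapse = ", ")),
          class = "linkassoc_invalid_input")
  }
  if (nrow(visits) == 0L) {
    abort("`visits` is empty.", class = "linkassoc_invalid_input")
  }
  if (any(visits$sbp <= 0, na.rm = TRUE)) {
    abort("SBP must be positive where present.", class = "linkassoc_validation_error")
  }
  visits <- visits |>
    tibble::as_tibble() |>
    dplyr::mutate(sbp_adj = medication_adjust(.data$sbp, .data$treated, delta))
  if (pooled) {
    visits$residual <- visit_residualize(visits$sbp_adj, visits$age, visits$sex)
  } else {
    visits <- visits |>
      dplyr::group_by(.data$visit) |>
      dplyr::mutate(residual = visit_residualize(.data$sbp_adj, .data$age, .data$sex)) |>
      dplyr::ungroup()
  }
  trait <- visits |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      trait = mean(.data$residual, na.rm = TRUE),
      n_visits = sum(!is.na(.data$residual)),
      .groups = "drop"
    )
  dropped <- trait$id[trait$n_visits == 0L]
  if (length(dropped) > 0L) {
    warn(sprintf("Dropped %d individual(s) with no usable visit: %s",
                 length(dropped), paste(head(dropped, 5L), collapse = ", ")))
  }
  out <- trait |>
    dplyr::filter(.data$n_visits > 0L) |>
    dplyr::select("id", "trait")
  attr(out, "dropped") <- as.character(dropped)
  out
}
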