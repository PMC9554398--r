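#' Candidate QRCM specifications for the credits analysis
#'
#' Builds the five model specifications compared in the case study, for the
#' covariate layout intercept + X1...X10 (X1 first-semester credits, X2
#' cohort dummy, X3 male dummy, X4 high-school grade, X5...X10 school-type
#' dummies). `poly(p, r)` stands for the shifted Legendre polynomials up to
#' degree r (r+1 terms).
#'
#' * Model 0: every coefficient poly(p, 1) — the linear baseline.
#' * Model 1: intercept poly(p, 5) - log(1-p); X2 poly(p, 5); X1, X3, X4
#'   poly(p, 1); X5...X10 constant.
#' * Model 2: as Model 1 plus the -log(1-p) term on X2 (the selected model).
#' * Model 3: as Model 2 with X1, X3, X4 upgraded to poly(p, 3).
#' * Model 4: as Model 2 with intercept and X2 upgraded to poly(p, 8).
#'
#' School-type coefficients are constant in all models but Model 0
#' (\eqn{\beta_c(p) = \theta_{c0}} for c = 5,...,10): with seven small
#' categories, quantile-dependent school effects would be weakly identified,
#' so only their location is modelled.
#'
#' @param coef_names optional coefficient labels (length 11).
#' @return List of five entries of class `grid_entry`, each with `label`,
#'   `spec` and `n_params`.
#' @export
build_candidate_models <- function(coef_names = NULL) {
  if (is.null(coef_names)) {
    coef_names <- c("(Intercept)", "credits_sem1_std", "cohort2019", "male",
                    "grade_std", "school_humanities", "school_language",
                    "school_human_sciences", "school_art", "school_technical",
                    "school_other")
  }
  if (length(coef_names) != 11) stop("expected 11 coefficient names")
  poly_r <- function(r) lapply(0:r, basis_legendre)
  flexible <- function(r) c(poly_r(r), list(basis_minus_log1mp()))
  const6 <- lapply(1:6, function(i) poly_r(0))

  layouts <- list(
    "Model 0" = c(list(poly_r(1)), list(poly_r(1)), list(poly_r(1)),
                  list(poly_r(1)), list(poly_r(1)),
                  lapply(1:6, function(i) poly_r(1))),
    "Model 1" = c(list(flexible(5)), list(poly_r(1)), list(poly_r(5)),
                  list(poly_r(1)), list(poly_r(1)), const6),
    "Model 2" = c(list(flexible(5)), list(poly_r(1)), list(flexible(5)),
                  list(poly_r(1)), list(poly_r(1)), const6),
    "Model 3" = c(list(flexible(5)), list(poly_r(3)), list(flexible(5)),
                  list(poly_r(3)), list(poly_r(3)), const6),
    "Model 4" = c(list(flexible(8)), list(poly_r(1)), list(flexible(8)),
                  list(poly_r(1)), list(poly_r(1)), const6)
  )
  lapply(names(layouts), function(lab) {
    spec <- model_spec(layouts[[lab]], coef_names = coef_names)
    structure(list(label = lab, spec = spec,
                   n_params = count_free_parameters(spec), fitted = NULL),
              class = "grid_entry")
  })
}

#' Fit every entry of a model grid on one dataset
#'
#' @param entries list of `grid_entry` objects (see [build_candidate_models()]).
#' @param dataset a [qr_dataset].
#' @param ... passed to [fit_qrcm()].
#' @return The entries with their `fitted` slot filled.
#' @export
fit_model_grid <- function(entries, dataset, ...) {
  lapply(entries, function(e) {
    stopifnot(inherits(e, "grid_entry"))
    e$fitted <- fit_qrcm(dataset, e$spec, ...)
    e
  })
}

#' Loss and parameter-count table for a fitted model grid
#'
#' The minimised integrated loss monitors the fit of competing models; it is
#' non-increasing under nesting but carries no complexity penalty, so it
#' cannot select a model on its own.
#'
#' @param entries fitted `grid_entry` list.
#' @return data.frame with `model`, `parameters`, `loss`.
#' @export
loss_table <- function(entries) {
  for (e in entries) {
    if (is.null(e$fitted)) stop("unfitted grid entry: ", e$label)
  }
  data.frame(
    model = vapply(entries, function(e) e$label, ""),
    parameters = vapply(entries, function(e) e$n_params, 0L),
    loss = vapply(entries, function(e) e$fitted$loss, 0)
  )
}

#' Overlay of QRCM and jittering estimates of one coefficient curve
#'
#' Exports, for each quantile level of the jittering grid, the QRCM point
#' estimate with a pointwise 95% confidence band and the average-jittering
#' point estimate — the plain table behind the model-selection overlay plots.
#'
#' @param fit a [qrcm_fit].
#' @param jfit a [jitter_fit] on the same dataset and covariate coding.
#' @param covariate_index theta row (1 = intercept, 2 = first covariate, ...).
#' @param level band level (default 0.95).
#' @return data.frame with `p`, `qrcm`, `lower`, `upper`, `jittering`.
#' @export
beta2_overlay <- function(fit, jfit, covariate_index, level = 0.95) {
  stopifnot(inherits(fit, "qrcm_fit"), inherits(jfit, "jitter_fit"))
  if (ncol(jfit$beta_avg) != fit$spec$n_coef) {
    stop("grid mismatch: jittering fit has ", ncol(jfit$beta_avg),
         " coefficients, QRCM fit has ", fit$spec$n_coef)
  }
  band <- beta_curve_band(fit, covariate_index, jfit$p_grid, level)
  data.frame(p = jfit$p_grid, qrcm = band$estimate, lower = band$lower,
             upper = band$upper, jittering = jfit$beta_avg[, covariate_index])
}
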