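#' Load a student-records CSV
#'
#' Reads and validates the raw records table. Required columns: `id`,
#' `cohort`, `gender`, `school_type`, `grade`, `credits_sem1`,
#' `credits_sem2`. Exams award 6, 9 or 12 credits, so semester totals must be
#' non-negative multiples of 3; violations are reported with their row
#' numbers, as are duplicate ids and unparseable cells.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
load_records <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "cohort", "gender", "school_type", "grade",
                "credits_sem1", "credits_sem2")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$id)) {
    dup <- which(duplicated(raw$id))
    stop("duplicate id at row(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  for (col in c("grade", "credits_sem1", "credits_sem2")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("unparseable ", col, " at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    raw[[col]] <- v
  }
  for (col in c("credits_sem1", "credits_sem2")) {
    bad <- which(raw[[col]] < 0 | raw[[col]] %% 3 != 0)
    if (length(bad)) {
      stop(col, " must be a non-negative multiple of 3; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  bad_cohort <- which(!raw$cohort %in% c(2018, 2019))
  if (length(bad_cohort)) {
    stop("cohort must be 2018 or 2019; offending row(s): ",
         paste(utils::head(bad_cohort, 5), collapse = ", "))
  }
  raw
}

#' Preprocess raw records into an analysis dataset
#'
#' Applies the case-study preparation: students with zero first-semester
#' credits are excluded (their second-semester activity mostly concerns
#' first-semester courses); the response is second-semester credits divided
#' by 3; first-semester credits and high-school grade are centred at their
#' sample means and divided by their sample SDs; dummies are built for cohort
#' 2019, male, and the six school types other than the "Scientific" baseline.
#'
#' @param raw validated records table from [load_records()].
#' @return A [qr_dataset] with attributes `n_excluded` (zero-credit rows
#'   dropped) and `scaling` (centres and SDs used).
#' @export
preprocess <- function(raw) {
  keep <- raw$credits_sem1 > 0
  n_excluded <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0) stop("all rows excluded: no student earned first-semester credits")
  unseen <- setdiff(unique(raw$school_type), school_levels())
  if (length(unseen)) {
    stop("unseen school-type level(s): ", paste(unseen, collapse = ", "))
  }
  y <- raw$credits_sem2 / 3
  tab <- data.frame(
    gender = raw$gender, cohort = raw$cohort, school_type = raw$school_type,
    grade = raw$grade, credits_sem1 = raw$credits_sem1,
    grade_std = as.numeric(scale(raw$grade)),
    credits_sem1_std = as.numeric(scale(raw$credits_sem1))
  )
  X <- design_from_covariates(tab)
  out <- qr_dataset(X, y, names = colnames(X))
  attr(out, "n_excluded") <- n_excluded
  attr(out, "scaling") <- list(
    credits_sem1 = c(mean = mean(raw$credits_sem1), sd = stats::sd(raw$credits_sem1)),
    grade = c(mean = mean(raw$grade), sd = stats::sd(raw$grade)))
  out
}

#' Analysis configuration for the end-to-end pipeline
#'
#' @param input optional path to a records CSV (alternative: pass `records`).
#' @param records optional records data.frame already in memory.
#' @param p_report quantile orders for the coefficient tables (default 0.10,
#'   0.25, 0.50, 0.75, 0.90).
#' @param p_grid quantile grid for the coefficient-curve overlays (default
#'   [percentile_grid()]).
#' @param m jitter replications for point estimates (default 100).
#' @param m_boot jitter replications inside each bootstrap resample (default
#'   20; the bootstrap SD is dominated by resampling noise, so fewer
#'   replications per resample suffice).
#' @param B bootstrap resamples for jittering standard errors (default 100).
#' @param n_mc Monte Carlo replicates of the goodness-of-fit test (default
#'   100).
#' @param models labels of the grid models to fit (default all five).
#' @param selected label of the model used for tables, Wald tests and the
#'   goodness-of-fit test (default "Model 2").
#' @param out_dir output directory for the CSV/JSON report files; `NULL`
#'   skips writing.
#' @param seed master seed; sub-seeds for jittering, bootstrap and the
#'   goodness-of-fit test are derived from it and logged in the manifest.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, records = NULL,
                            p_report = c(0.10, 0.25, 0.50, 0.75, 0.90),
                            p_grid = percentile_grid(),
                            m = 100L, m_boot = 20L, B = 100L, n_mc = 100L,
                            models = paste("Model", 0:4),
                            selected = "Model 2",
                            out_dir = NULL, seed = 1L) {
  check_quantile_level(p_report)
  check_quantile_level(p_grid)
  if (any(p_report < min(p_grid)) || any(p_report > max(p_grid))) {
    stop("`p_report` must lie within the range of `p_grid`")
  }
  if (!selected %in% models) stop("`selected` must be one of `models`")
  structure(list(input = input, records = records, p_report = p_report,
                 p_grid = p_grid, m = as.integer(m), m_boot = as.integer(m_boot),
                 B = as.integer(B), n_mc = as.integer(n_mc), models = models,
                 selected = selected, out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full credits analysis and emit the report bundle
#'
#' End-to-end pipeline: load and preprocess the records, fit the
#' average-jittering estimator (point estimates over the full grid, bootstrap
#' standard errors at the report quantiles), fit the model grid, and produce
#' the report tables: per-coefficient estimates and standard errors for both
#' methods at the report quantiles; average standard errors per method with a
#' QRCM/jittering ratio row; the cohort-coefficient overlay; the
#' loss/parameter table; global Wald tests per covariate; and the
#' goodness-of-fit statistic with its Monte Carlo p-value for the selected
#' model. With `out_dir` set, every table is written as CSV along with a JSON
#' run manifest recording the seeds and settings; outputs are byte-identical
#' across reruns with the same seed.
#'
#' If a stage fails, the bundle is returned with `partial = TRUE` and
#' `failed_stage` naming the stage; completed stages are kept.
#'
#' @param config an [analysis_config].
#' @return List of class `analysis_bundle`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  bundle <- list(partial = FALSE, failed_stage = NULL, config = config)
  seeds <- list(jitter = config$seed + 101L, bootstrap = config$seed + 202L,
                gof = config$seed + 303L)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      bundle$partial <<- TRUE
      if (is.null(bundle$failed_stage)) {
        bundle$failed_stage <<- paste0(name, ": ", conditionMessage(e))
      }
      NULL
    })
  }

  dataset <- run_stage("preprocess", {
    raw <- if (!is.null(config$input)) load_records(config$input) else {
      if (is.null(config$records)) stop("provide `input` or `records`")
      config$records
    }
    preprocess(raw)
  })
  if (is.null(dataset)) {
    bundle$partial <- TRUE
    class(bundle) <- "analysis_bundle"
    return(bundle)
  }
  bundle$dataset <- dataset
  coef_names <- dataset$names

  jfit <- run_stage("jittering", {
    average_jittering_fit(dataset, config$p_grid,
                          jitter_config(m = config$m, seed = seeds$jitter))
  })
  bundle$jitter_fit <- jfit
  jse <- run_stage("bootstrap", {
    bootstrap_se(dataset, config$p_report,
                 jitter_config(m = config$m_boot), B = config$B,
                 m_boot = config$m_boot, seed = seeds$bootstrap)
  })

  grid <- run_stage("model_grid", {
    entries <- build_candidate_models(coef_names = coef_names)
    entries <- entries[vapply(entries, function(e) e$label, "") %in% config$models]
    fit_model_grid(entries, dataset)
  })
  bundle$grid <- grid
  sel_fit <- if (!is.null(grid)) {
    labs <- vapply(grid, function(e) e$label, "")
    grid[[match(config$selected, labs)]]$fitted
  }
  bundle$selected_fit <- sel_fit

  # (a) coefficient/SE table for both methods at the report quantiles
  bundle$coef_table <- run_stage("coef_table", {
    stopifnot(!is.null(jfit), !is.null(sel_fit))
    ridx <- match(config$p_report, config$p_grid)
    if (anyNA(ridx)) {
      jrep <- average_jittering_fit(
        dataset, config$p_report, jitter_config(m = config$m, seed = seeds$jitter))
      jit_est <- jrep$beta_avg
    } else {
      jit_est <- jfit$beta_avg[ridx, , drop = FALSE]
    }
    rows <- list()
    for (ci in seq_along(coef_names)) {
      band <- beta_curve_band(sel_fit, ci, config$p_report)
      rows[[length(rows) + 1]] <- data.frame(
        coefficient = coef_names[ci], method = "jittering",
        p = config$p_report, estimate = jit_est[, ci],
        se = if (!is.null(jse)) jse[, ci] else NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        coefficient = coef_names[ci], method = "qrcm",
        p = config$p_report, estimate = band$estimate, se = band$se)
    }
    do.call(rbind, rows)
  })

  # (b) average-SE table with QRCM/jittering ratio row
  bundle$avg_se_table <- run_stage("avg_se_table", {
    ct <- bundle$coef_table
    stopifnot(!is.null(ct))
    avg <- stats::aggregate(se ~ method + p, data = ct, FUN = mean)
    wide <- data.frame(p = sort(unique(avg$p)))
    wide$jittering <- avg$se[avg$method == "jittering"][order(avg$p[avg$method == "jittering"])]
    wide$qrcm <- avg$se[avg$method == "qrcm"][order(avg$p[avg$method == "qrcm"])]
    wide$ratio <- wide$qrcm / wide$jittering
    wide
  })

  # (c) cohort-coefficient overlay over the full grid
  bundle$overlay <- run_stage("overlay", {
    stopifnot(!is.null(jfit), !is.null(sel_fit))
    beta2_overlay(sel_fit, jfit, covariate_index = 3)
  })

  # (d) loss/parameter table
  bundle$loss_table <- run_stage("loss_table", loss_table(grid))

  # (e) global Wald tests per covariate
  bundle$wald_table <- run_stage("wald", {
    stopifnot(!is.null(sel_fit))
    do.call(rbind, lapply(2:length(coef_names), function(ci) {
      wt <- wald_test_global(sel_fit, ci)
      data.frame(coefficient = wt$coefficient, statistic = wt$statistic,
                 df = wt$df, p_value = wt$p_value)
    }))
  })

  # (f) goodness of fit of the selected model
  bundle$gof <- run_stage("gof", {
    stopifnot(!is.null(sel_fit))
    g <- gof_test(sel_fit, dataset, "KS", n_mc = config$n_mc, seed = seeds$gof)
    g$mc_statistics <- NULL
    g
  })

  bundle$seeds <- seeds
  bundle$n_excluded <- attr(dataset, "n_excluded")
  class(bundle) <- "analysis_bundle"

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# Write the report bundle as plain CSV/JSON files. No timestamps or machine
# state: reruns with the same seed are byte-identical.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) {
    if (!is.null(df)) utils::write.csv(df, file.path(out_dir, file),
                                       row.names = FALSE)
  }
  wr(bundle$coef_table, "coefficients.csv")
  wr(bundle$avg_se_table, "average_se.csv")
  wr(bundle$overlay, "cohort_overlay.csv")
  wr(bundle$loss_table, "model_grid_loss.csv")
  wr(bundle$wald_table, "wald_tests.csv")
  manifest <- list(
    seed = bundle$config$seed, derived_seeds = bundle$seeds,
    m = bundle$config$m, m_boot = bundle$config$m_boot, B = bundle$config$B,
    n_mc = bundle$config$n_mc, models = bundle$config$models,
    selected = bundle$config$selected, p_report = bundle$config$p_report,
    n_excluded = bundle$n_excluded,
    n_used = if (!is.null(bundle$dataset)) nrow(bundle$dataset$design),
    gof = if (!is.null(bundle$gof)) {
      bundle$gof[c("statistic", "value", "p_value", "n_mc_used")]
    },
    partial = bundle$partial, failed_stage = bundle$failed_stage)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("analysis_bundle", if (x$partial) paste0("(PARTIAL - ", x$failed_stage, ")"),
      "\n")
  if (!is.null(x$dataset)) {
    cat(" n =", nrow(x$dataset$design), "(", x$n_excluded, "excluded )\n")
  }
  if (!is.null(x$loss_table)) {
    print(x$loss_table)
  }
  if (!is.null(x$gof)) {
    cat(" GOF", x$gof$statistic, "=", format(x$gof$value, digits = 4),
        ", MC p =", format(x$gof$p_value, digits = 3), "\n")
  }
  invisible(x)
}
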