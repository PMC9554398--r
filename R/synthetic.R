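#' Configuration of the synthetic covariate generator
#'
#' Marginals default to the Psychology cohort of the motivating case study:
#' 79.5% female students, seven high-school types with the observed shares
#' (Scientific 35.1%, Humanities 16.6%, Language 7.2%, Human sciences 22.2%,
#' Art school 2.2%, Technical 12.3%, Other 4.3%), high-school grade with mean
#' 81.17 and SD 11.00 on the Italian 60-100 scale, and first-semester
#' credits with mean 21.6 and SD 6.64 on multiples of 3. Covariates are drawn
#' independently of one another (the joint distribution of the source data is
#' not available; this is a documented simplification).
#'
#' @param n number of students.
#' @param prop_female probability of gender "female" (default 0.795).
#' @param prop_cohort2019 probability of enrollment cohort 2019 (default 0.5).
#' @param school_type_probs named 7-vector of school-type probabilities;
#'   normalised to sum to 1.
#' @param grade_mean,grade_sd target mean and SD of the high-school grade on
#'   the 60-100 scale; the latent normal is moment-matched so the truncated,
#'   integer-rounded draw attains them.
#' @param credits1_mean,credits1_sd target moments of first-semester credits;
#'   draws are rounded to the nearest positive multiple of 3 (capped at 33).
#' @param seed integer seed.
#' @return List of class `covariate_config`.
#' @export
covariate_config <- function(n,
                             prop_female = 0.795,
                             prop_cohort2019 = 0.5,
                             school_type_probs = c(
                               Scientific = 35.1, Humanities = 16.6,
                               Language = 7.24, `Human sciences` = 22.2,
                               `Art school` = 2.16, Technical = 12.3,
                               Other = 4.31),
                             grade_mean = 81.17, grade_sd = 11.00,
                             credits1_mean = 21.6, credits1_sd = 6.64,
                             seed = NULL) {
  if (n < 30) stop("`n` must be at least 30")
  if (prop_female < 0 || prop_female > 1 || prop_cohort2019 < 0 ||
      prop_cohort2019 > 1) {
    stop("proportions must lie in [0, 1]")
  }
  if (length(school_type_probs) != 7 || any(school_type_probs < 0)) {
    stop("`school_type_probs` must be 7 non-negative values")
  }
  if (grade_sd <= 0 || credits1_sd <= 0) stop("standard deviations must be > 0")
  structure(list(n = as.integer(n), prop_female = prop_female,
                 prop_cohort2019 = prop_cohort2019,
                 school_type_probs = school_type_probs / sum(school_type_probs),
                 grade_mean = grade_mean, grade_sd = grade_sd,
                 credits1_mean = credits1_mean, credits1_sd = credits1_sd,
                 seed = seed),
            class = "covariate_config")
}

#' Serialise a covariate configuration to JSON
#'
#' @param config a [covariate_config].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
config_to_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "covariate_config"))
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

# Latent (mu, sigma) of a normal whose truncation to [lo, hi] has the target
# mean and SD; falls back to the targets themselves if unattainable.
truncnorm_latent <- function(target_mean, target_sd, lo, hi) {
  moments <- function(mu, s) {
    a <- (lo - mu) / s; b <- (hi - mu) / s
    Z <- stats::pnorm(b) - stats::pnorm(a)
    if (Z < 1e-12) return(c(NA_real_, NA_real_))
    m <- mu + s * (stats::dnorm(a) - stats::dnorm(b)) / Z
    v <- s^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / Z -
                  ((stats::dnorm(a) - stats::dnorm(b)) / Z)^2)
    c(m, sqrt(max(v, 0)))
  }
  obj <- function(par) {
    mm <- moments(par[1], exp(par[2]))
    if (anyNA(mm)) return(1e6)
    sum((mm - c(target_mean, target_sd))^2)
  }
  opt <- stats::optim(c(target_mean, log(target_sd)), obj)
  if (opt$value > 0.25) return(c(target_mean, target_sd))
  c(opt$par[1], exp(opt$par[2]))
}

school_levels <- function() {
  c("Scientific", "Humanities", "Language", "Human sciences", "Art school",
    "Technical", "Other")
}

#' Draw a synthetic covariate table
#'
#' @param config a [covariate_config].
#' @return data.frame with raw columns (`gender`, `cohort`, `school_type`,
#'   `grade`, `credits_sem1`) and standardised versions of the continuous
#'   covariates (`grade_std`, `credits_sem1_std`; centred at the sample mean,
#'   divided by the sample SD).
#' @export
sample_covariates <- function(config) {
  stopifnot(inherits(config, "covariate_config"))
  n <- config$n
  local_seed(config$seed, {
    gender <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
    cohort <- ifelse(stats::runif(n) < config$prop_cohort2019, 2019L, 2018L)
    school_type <- sample(school_levels(), n, replace = TRUE,
                          prob = config$school_type_probs)
    # grade: normal truncated to the 60-100 grading scale, integer-valued;
    # the latent parameters are moment-matched so the truncated draw hits the
    # configured mean and SD
    lat <- truncnorm_latent(config$grade_mean, config$grade_sd, 60, 100)
    lo <- stats::pnorm(60, lat[1], lat[2])
    hi <- stats::pnorm(100, lat[1], lat[2])
    grade <- round(stats::qnorm(stats::runif(n, lo, hi), lat[1], lat[2]))
    # first-semester credits: positive multiples of 3 (students with zero
    # first-semester credits are excluded from the analysis population)
    credits1 <- 3 * pmin(pmax(round(
      stats::rnorm(n, config$credits1_mean, config$credits1_sd) / 3), 1), 11)
    data.frame(
      gender = gender, cohort = cohort, school_type = school_type,
      grade = grade, credits_sem1 = credits1,
      grade_std = as.numeric(scale(grade)),
      credits_sem1_std = as.numeric(scale(credits1))
    )
  })
}

# Design matrix in the case-study covariate order:
# intercept, X1 credits_sem1 (standardised), X2 cohort-2019 dummy, X3 male
# dummy, X4 grade (standardised), X5..X10 school-type dummies (Scientific
# baseline).
design_from_covariates <- function(tab) {
  lv <- school_levels()
  st <- factor(tab$school_type, levels = lv)
  if (anyNA(st)) stop("unseen school-type level in covariate table")
  dummies <- sapply(lv[-1], function(l) as.numeric(st == l))
  X <- cbind(1, tab$credits_sem1_std, as.numeric(tab$cohort == 2019),
             as.numeric(tab$gender == "male"), tab$grade_std, dummies)
  colnames(X) <- c("(Intercept)", "credits_sem1_std", "cohort2019", "male",
                   "grade_std", "school_humanities", "school_language",
                   "school_human_sciences", "school_art", "school_technical",
                   "school_other")
  X
}

#' Reference data-generating quantile model
#'
#' A known conditional quantile function with the structure of the selected
#' case-study model (intercept and cohort coefficient flexible in p; control
#' coefficients linear in p; school-type coefficients constant), used to
#' generate synthetic responses with recoverable true parameters. The
#' intercept curve spans roughly 8 to 15 across the quantile range, covering
#' the bulk of the 0-21 credit-unit support; the cohort-2019
#' curve is mildly negative with stronger effects in the tails. All values
#' are synthetic choices, not estimates from any real dataset.
#'
#' @param support_cap largest generated count (default 21, the case-study
#'   support).
#' @return Object of class `true_model`: `spec`, `theta` ([theta_matrix]),
#'   `support_cap`.
#' @export
default_true_model <- function(support_cap = 21L) {
  spec <- build_candidate_models()[[3]]$spec     # selected-model structure
  theta <- matrix(0, spec$n_coef, spec$k,
                  dimnames = list(spec$coef_names, spec$basis_labels))
  theta["(Intercept)", ] <- c(10.2, 2.5, 0.3, 0, 0, 0, 0.4)
  theta["cohort2019", ] <- c(-0.2, 0, -0.3, 0, 0, 0, -0.15)
  theta["credits_sem1_std", c("legendre0", "legendre1")] <- c(1.3, -0.4)
  theta["male", c("legendre0", "legendre1")] <- c(-0.1, 0.3)
  theta["grade_std", c("legendre0", "legendre1")] <- c(0.15, 0.1)
  theta[6:11, "legendre0"] <- c(-0.18, -0.30, -0.20, -0.40, -0.35, -0.79)
  structure(list(spec = spec, theta = theta_matrix(theta, spec),
                 support_cap = as.integer(support_cap)),
            class = "true_model")
}

#' Validate monotonicity of a true model over a hull of covariate profiles
#'
#' Checks that the implied conditional quantile function is strictly
#' increasing in p over (0.001, 0.999) for every supplied profile.
#'
#' @param model a `true_model`.
#' @param profiles matrix of covariate rows (intercept first).
#' @param n_check number of p values on the check grid (default 400).
#' @return `TRUE` invisibly; errors naming the first offending profile row.
#' @export
validate_monotone <- function(model, profiles, n_check = 400L) {
  stopifnot(inherits(model, "true_model"))
  pg <- seq(0.001, 0.999, length.out = n_check)
  B <- basis_matrix(model$spec, pg)
  XT <- profiles %*% model$theta$values
  step <- 2000L
  for (start in seq(1, nrow(profiles), by = step)) {
    rows <- start:min(start + step - 1, nrow(profiles))
    eta <- XT[rows, , drop = FALSE] %*% t(B)
    bad <- which(apply(eta, 1, function(e) any(diff(e) <= 0)))
    if (length(bad)) {
      stop("non-monotone quantile function at covariate profile row ",
           rows[bad[1]])
    }
  }
  invisible(TRUE)
}

#' Draw count responses from a known conditional quantile model
#'
#' Inverse-transform sampling: per observation a latent quantile level p is
#' drawn uniformly, the continuous quantile \eqn{y^\circ = x'\beta(p \mid
#' \theta_{true})} is evaluated, and the count is
#' \eqn{\lceil y^\circ - 1 \rceil} clamped to `[0, support_cap]`. The ceiling
#' construction mirrors the estimators' recovery rule, so the generator's
#' true count quantiles are exactly what the estimators target. The latent p
#' values are returned for testing.
#'
#' @param X design matrix (intercept first) of covariate profiles.
#' @param model a `true_model`; monotonicity is validated on the supplied
#'   profiles before sampling.
#' @param seed integer seed.
#' @return List: `y` (integer counts), `latent_p`, `latent_q` (the continuous
#'   quantile values).
#' @export
sample_response <- function(X, model, seed = NULL) {
  stopifnot(inherits(model, "true_model"))
  validate_monotone(model, unique(round(X, 6)))
  n <- nrow(X)
  local_seed(seed, {
    pu <- stats::runif(n)
    Bu <- basis_matrix(model$spec, pmin(pmax(pu, 1e-12), 1 - 1e-12))
    q_lat <- rowSums((X %*% model$theta$values) * Bu)
    y <- pmin(pmax(ceiling(q_lat - 1), 0), model$support_cap)
    list(y = as.integer(y), latent_p = pu, latent_q = q_lat)
  })
}

#' Generate a complete synthetic student-credits dataset
#'
#' Combines [sample_covariates()], the reference quantile model and
#' [sample_response()] into (a) a raw records table in the CSV schema the
#' pipeline reads and (b) the ready-made [qr_dataset] on which the response
#' was generated (standardised design), plus the latent quantile levels and
#' the true model.
#'
#' @param n number of students (default 649, the case-study sample size).
#' @param config optional [covariate_config]; built from `n` and `seed` when
#'   missing.
#' @param model a `true_model` (default [default_true_model()]).
#' @param seed integer seed driving both covariates and response.
#' @return List of class `synthetic_credits`: `records` (raw table with id,
#'   cohort, gender, school_type, grade, credits_sem1, credits_sem2),
#'   `dataset` (a [qr_dataset]), `latent_p`, `model`.
#' @export
generate_credits_data <- function(n = 649L, config = NULL,
                                  model = default_true_model(), seed = NULL) {
  if (is.null(config)) {
    config <- covariate_config(n, seed = if (is.null(seed)) NULL else seed)
  }
  tab <- sample_covariates(config)
  X <- design_from_covariates(tab)
  resp <- sample_response(X, model,
                          seed = if (is.null(seed)) NULL else seed + 1L)
  records <- data.frame(
    id = seq_len(nrow(tab)),
    cohort = tab$cohort, gender = tab$gender, school_type = tab$school_type,
    grade = tab$grade, credits_sem1 = tab$credits_sem1,
    credits_sem2 = 3L * resp$y
  )
  structure(
    list(records = records,
         dataset = qr_dataset(X, resp$y, names = colnames(X)),
         latent_p = resp$latent_p, model = model, config = config),
    class = "synthetic_credits"
  )
}
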