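#' Configuration for the average-jittering estimator
#'
#' @param m number of jitter replications to average over (default 100).
#' @param transform transform of the working variable: `"linear"` is
#'   \eqn{T(Z, p) = Z - p} (the quantile function of Z is bounded below by p);
#'   `"log"` is the original proposal \eqn{\log(Z - p)} when \eqn{Z > p} and
#'   \eqn{\log(\zeta)} otherwise.
#' @param zeta small positive constant used by the log transform when
#'   \eqn{Z \le p} (default 1e-5).
#' @param seed integer seed controlling the jitter noise.
#' @return List of class `jitter_config`.
#' @export
jitter_config <- function(m = 100L, transform = c("linear", "log"),
                          zeta = 1e-5, seed = NULL) {
  transform <- match.arg(transform)
  if (m < 1 || m != round(m)) stop("`m` must be a positive integer")
  if (zeta <= 0 || zeta >= 1) stop("`zeta` must lie in (0, 1)")
  structure(list(m = as.integer(m), transform = transform, zeta = zeta,
                 seed = seed),
            class = "jitter_config")
}

#' Jitter a count response
#'
#' Adds independent Uniform[0,1) noise to each count, producing the
#' continuous working variable \eqn{Z = Y + U} whose conditional quantiles
#' map one-to-one to those of the count.
#'
#' @param response non-negative integer counts.
#' @return Numeric vector `z` with \eqn{y_i \le z_i < y_i + 1}.
#' @export
jitter_sample <- function(response) {
  if (anyNA(response) || any(response < 0) || any(response != round(response))) {
    stop("`response` must be non-negative integer counts")
  }
  response + stats::runif(length(response))
}

#' Transform of the jittered working variable
#'
#' @param z working values (jittered counts).
#' @param p quantile level in (0,1).
#' @param config a [jitter_config] selecting the transform.
#' @return Transformed values: `z - p` (linear) or `log(z - p)` with
#'   `log(zeta)` on the branch `z <= p` (log).
#' @export
transform_working <- function(z, p, config) {
  stopifnot(inherits(config, "jitter_config"))
  check_quantile_level(p)
  if (any(z < 0)) stop("working variable must be non-negative")
  if (config$transform == "linear") {
    z - p
  } else {
    out <- rep(log(config$zeta), length(z))
    ok <- z > p
    out[ok] <- log(z[ok] - p)
    out
  }
}

#' Recover a count quantile from a fitted transformed quantile
#'
#' Inverts the working transform and applies the ceiling recovery rule
#' \eqn{\lceil T^{-1}(v) - 1 \rceil}. With the linear transform the result
#' can be negative; it is reported as-is.
#'
#' @param fitted fitted value(s) \eqn{x'\hat\beta(p)} on the transformed
#'   scale.
#' @param p quantile level used in the transform.
#' @param config a [jitter_config].
#' @return Integer count quantile estimate(s).
#' @export
invert_to_count <- function(fitted, p, config) {
  stopifnot(inherits(config, "jitter_config"))
  if (any(!is.finite(fitted))) stop("`fitted` must be finite")
  tinv <- if (config$transform == "linear") fitted + p else exp(fitted) + p
  as.integer(ceiling(tinv - 1))
}

#' Average-jittering quantile regression over a grid of quantile levels
#'
#' Draws `m` independent jitter samples; within each sample, fits linear
#' quantile regression to the transformed working variable at every quantile
#' level of the grid; averages the `m` coefficient vectors per level. One
#' working sample is drawn per replication and reused across the whole grid.
#'
#' @param dataset a [qr_dataset].
#' @param p_grid quantile levels, strictly inside (0,1); default
#'   [percentile_grid()].
#' @param config a [jitter_config].
#' @return Object of class `jitter_fit`: `p_grid`, `beta_avg` (grid x (q+1)
#'   averaged estimates), `beta_reps` (m x grid x (q+1) array of
#'   per-replication estimates), `config`.
#' @export
average_jittering_fit <- function(dataset, p_grid = percentile_grid(),
                                  config = jitter_config()) {
  stopifnot(inherits(dataset, "qr_dataset"), inherits(config, "jitter_config"))
  check_quantile_level(p_grid)
  X <- dataset$design
  q1 <- ncol(X)
  ng <- length(p_grid)
  beta_reps <- array(NA_real_, c(config$m, ng, q1),
                     dimnames = list(NULL, NULL, dataset$names))
  local_seed(config$seed, {
    for (l in seq_len(config$m)) {
      z <- jitter_sample(dataset$response)
      for (gi in seq_len(ng)) {
        p <- p_grid[gi]
        t_ <- transform_working(z, p, config)
        beta_reps[l, gi, ] <- tryCatch(
          rq_fit_fn(X, t_, p)$beta,
          error = function(e) stop(
            "quantile-regression failure at replication ", l, ", p = ", p,
            ": ", conditionMessage(e)))
      }
    }
  })
  beta_avg <- apply(beta_reps, c(2, 3), mean)
  if (ng == 1) beta_avg <- matrix(beta_avg, 1, q1,
                                  dimnames = list(NULL, dataset$names))
  structure(list(p_grid = p_grid, beta_avg = beta_avg, beta_reps = beta_reps,
                 config = config),
            class = "jitter_fit")
}

#' @export
print.jitter_fit <- function(x, ...) {
  cat("jitter_fit: m =", x$config$m, "replications,",
      length(x$p_grid), "quantile levels,", dim(x$beta_reps)[3],
      "coefficients (", x$config$transform, "transform )\n")
  invisible(x)
}

#' Bootstrap standard errors of the average-jittering estimator
#'
#' Nonparametric bootstrap over observations (cases). Each resample is
#' re-jittered with fresh noise, the average-jittering estimate is recomputed
#' with `m_boot` replications, and the standard error is the standard
#' deviation of the estimates across resamples.
#'
#' @param dataset a [qr_dataset].
#' @param p_grid quantile levels.
#' @param config a [jitter_config]; its `seed` is not consulted here.
#' @param B number of bootstrap resamples (default 100, minimum 2).
#' @param m_boot jitter replications inside each resample (default
#'   `config$m`).
#' @param seed integer seed for resampling and re-jittering.
#' @return Matrix (length(p_grid) x (q+1)) of standard errors.
#' @export
bootstrap_se <- function(dataset, p_grid, config = jitter_config(), B = 100L,
                         m_boot = config$m, seed = NULL) {
  stopifnot(inherits(dataset, "qr_dataset"), inherits(config, "jitter_config"))
  if (B < 2) stop("`B` must be at least 2")
  check_quantile_level(p_grid)
  n <- nrow(dataset$design)
  q1 <- ncol(dataset$design)
  ng <- length(p_grid)
  est <- array(NA_real_, c(B, ng, q1))
  boot_cfg <- jitter_config(m = m_boot, transform = config$transform,
                            zeta = config$zeta, seed = NULL)
  warned <- FALSE
  local_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (!warned && length(unique(dataset$response[idx])) == 1) {
        warning("degenerate bootstrap resample: constant response")
        warned <- TRUE
      }
      ds_b <- structure(list(design = dataset$design[idx, , drop = FALSE],
                             response = dataset$response[idx],
                             names = dataset$names),
                        class = "qr_dataset")
      jf <- average_jittering_fit(ds_b, p_grid, boot_cfg)
      est[b, , ] <- jf$beta_avg
    }
  })
  se <- apply(est, c(2, 3), stats::sd)
  if (ng == 1) se <- matrix(se, 1, q1)
  dimnames(se) <- list(NULL, dataset$names)
  se
}
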