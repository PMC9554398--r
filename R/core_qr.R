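#' Construct a quantile-regression dataset for count responses
#'
#' Bundles a design matrix (first column identically 1) with a non-negative
#' integer response vector. All estimators in the package operate on this
#' container.
#'
#' @param design numeric matrix, n rows by q+1 columns; the first column must
#'   be constant and equal to 1 (the intercept).
#' @param response integer vector of length n; non-negative counts.
#' @param names optional character vector of column labels; defaults to the
#'   column names of `design`.
#' @return An object of class `qr_dataset` with elements `design`,
#'   `response` and `names`.
#' @export
qr_dataset <- function(design, response, names = colnames(design)) {
  design <- as.matrix(design)
  if (!is.numeric(design) || anyNA(design) || any(!is.finite(design))) {
    stop("`design` must be a finite numeric matrix")
  }
  n <- nrow(design)
  q1 <- ncol(design)
  if (any(design[, 1] != 1)) {
    stop("first column of `design` must be identically 1 (intercept)")
  }
  if (n <= q1) {
    stop("need more observations than design columns (n > q+1)")
  }
  response <- as.numeric(response)
  if (length(response) != n) {
    stop("`response` length must equal nrow(design)")
  }
  if (anyNA(response) || any(response < 0) || any(response != round(response))) {
    stop("`response` must be non-negative integer counts")
  }
  if (is.null(names)) {
    names <- c("(Intercept)", if (q1 > 1) paste0("X", seq_len(q1 - 1)))
  }
  structure(
    list(design = design, response = response, names = names),
    class = "qr_dataset"
  )
}

#' @export
print.qr_dataset <- function(x, ...) {
  cat("qr_dataset:", nrow(x$design), "observations,",
      ncol(x$design) - 1, "covariates (+ intercept)\n")
  cat("response range:", min(x$response), "-", max(x$response), "\n")
  invisible(x)
}

check_quantile_level <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1)) {
    stop("quantile level `p` must lie strictly inside (0, 1)")
  }
  p
}

#' Pinball (check) loss of a coefficient vector
#'
#' Evaluates the quantile-regression objective
#' \eqn{L(\beta) = \sum_i (p - \omega_{p,i}) (t_i - x_i'\beta)} with
#' \eqn{\omega_{p,i} = I(t_i \le x_i'\beta)}. Every summand is non-negative,
#' so the loss is zero only when `beta` reproduces every `t` exactly.
#'
#' @param beta coefficient vector, one entry per design column.
#' @param p quantile level in (0,1).
#' @param t numeric vector of (transformed) responses.
#' @param design numeric design matrix.
#' @return A list of class `pinball_evaluation` with `loss`, `indicators`
#'   (the \eqn{\omega_{p,i}}) and `residuals` (\eqn{t_i - x_i'\beta}).
#' @export
pinball_objective <- function(beta, p, t, design) {
  design <- as.matrix(design)
  check_quantile_level(p)
  if (length(beta) != ncol(design)) {
    stop("length(beta) must equal ncol(design)")
  }
  if (length(t) != nrow(design)) {
    stop("length(t) must equal nrow(design)")
  }
  if (anyNA(beta) || any(!is.finite(beta)) ||
      anyNA(t) || any(!is.finite(t)) || any(!is.finite(design))) {
    stop("non-finite inputs to pinball_objective")
  }
  res <- t - drop(design %*% beta)
  omega <- as.numeric(res <= 0)
  loss <- sum((p - omega) * res)
  structure(list(loss = loss, indicators = omega, residuals = res),
            class = "pinball_evaluation")
}

# Frisch-Newton interior-point solver for a single quantile level.
#
# Solves min_beta sum_i rho_p(t_i - x_i' beta) through its dual linear
# program max { t'a : X'a = (1-p) X'1, a in [0,1]^n } with a Mehrotra
# predictor-corrector iteration; the equality-constraint multipliers at the
# optimum are the primal coefficients. Cost per iteration is one (q+1)x(q+1)
# solve, so large n is cheap.
rq_fit_fn <- function(X, t, p, tol = 1e-11, max_iter = 200L) {
  n <- nrow(X)
  k <- ncol(X)
  big <- 0.99995

  safe_solve <- function(M, v) {
    out <- tryCatch(solve(M, v), error = function(e) NULL)
    if (is.null(out)) {
      out <- tryCatch(solve(M + diag(1e-10 * (1 + mean(diag(M))), nrow(M)), v),
                      error = function(e) NULL)
      if (is.null(out)) stop("singular system in interior-point solver")
    }
    out
  }

  # interior start: a strictly inside [0,1], exactly feasible for X'a = rhs
  a <- rep(1 - p, n)
  s <- 1 - a
  XtX <- crossprod(X)
  y <- drop(safe_solve(XtX, crossprod(X, t)))
  r <- drop(X %*% y) - t
  z <- pmax(r, 0) + 1e-4
  w <- z - r                                  # z - w = Xy - t, both > 0

  gap <- sum(z * a) + sum(w * s)
  scale0 <- 1 + sum(abs(t))
  it <- 0L
  while (gap > tol * scale0 && it < max_iter) {
    it <- it + 1L
    q <- 1 / (z / a + w / s)
    r_zw <- z - w                              # = X y - t (dual feasible)

    # affine (predictor) direction
    rhs <- -crossprod(X, q * r_zw)
    dy <- drop(safe_solve(crossprod(X, q * X), rhs))
    da <- -q * (drop(X %*% dy) + r_zw)
    dz <- -z - (z / a) * da
    dw <- -w + (w / s) * da

    alpha_p <- step_len(a, da, s, -da, big)
    alpha_d <- step_len(z, dz, w, dw, big)
    gap_aff <- sum((z + alpha_d * dz) * (a + alpha_p * da)) +
      sum((w + alpha_d * dw) * (s - alpha_p * da))
    mu <- (gap_aff / gap)^3 * gap / (2 * n)

    # corrector + centering
    rz <- (mu - da * dz) / a - z
    rw <- (mu + da * dw) / s - w              # ds = -da
    rhs <- crossprod(X, q * (rz - rw))
    dy <- drop(safe_solve(crossprod(X, q * X), rhs))
    da <- q * (rz - rw - drop(X %*% dy))
    dz <- rz - (z / a) * da
    dw <- rw + (w / s) * da

    alpha_p <- step_len(a, da, s, -da, big)
    alpha_d <- step_len(z, dz, w, dw, big)
    a <- a + alpha_p * da
    s <- s - alpha_p * da
    y <- y + alpha_d * dy
    z <- z + alpha_d * dz
    w <- w + alpha_d * dw
    gap <- sum(z * a) + sum(w * s)
  }
  if (gap > sqrt(tol) * scale0) {
    stop(sprintf(
      "quantile-regression solver failed to converge: gap %.3e after %d iterations (n=%d, p=%.3f)",
      gap, it, n, p))
  }
  list(beta = y, iterations = it, gap = gap)
}

step_len <- function(x1, d1, x2, d2, big) {
  ratio <- c(if (any(d1 < 0)) -x1[d1 < 0] / d1[d1 < 0],
             if (any(d2 < 0)) -x2[d2 < 0] / d2[d2 < 0])
  if (length(ratio) == 0) return(1)
  min(1, big * min(ratio))
}

#' Fit linear quantile regression at a single quantile level
#'
#' Minimises the pinball objective over the coefficient vector by an
#' interior-point method on the dual linear program. When several minimisers
#' exist (the solution set of quantile regression can be an interval or a
#' face), any loss-minimiser is returned; downstream contracts compare
#' achieved losses, never coefficients.
#'
#' @param dataset a [qr_dataset]; only its design matrix is used here.
#' @param t numeric vector of transformed responses to regress (for the
#'   jittering estimator this is a transform of the jittered counts).
#' @param p quantile level in (0,1).
#' @return Object of class `qr_solution`: `beta`, `p`, `achieved_loss`.
#' @export
solve_qr <- function(dataset, t, p) {
  stopifnot(inherits(dataset, "qr_dataset"))
  check_quantile_level(p)
  X <- dataset$design
  if (length(t) != nrow(X)) stop("length(t) must equal nrow(design)")
  if (anyNA(t) || any(!is.finite(t))) stop("non-finite working response")
  if (qr(X)$rank < ncol(X)) {
    warning("rank-deficient design: any loss-minimiser is returned")
  }
  fit <- rq_fit_fn(X, t, p)
  loss <- pinball_objective(fit$beta, p, t, X)$loss
  structure(list(beta = fit$beta, p = p, achieved_loss = loss,
                 iterations = fit$iterations),
            class = "qr_solution")
}

#' Percentile grid 0.01, 0.02, ..., 0.99
#'
#' The quantile orders at which the jittering estimator is evaluated for the
#' coefficient-curve overlays.
#'
#' @return Numeric vector of length 99, strictly increasing.
#' @export
percentile_grid <- function() {
  (1:99) / 100
}
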