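#' Gauss-Legendre nodes on (0,1) for the integrated loss
#'
#' All integrals over the quantile order use a fixed Gauss-Legendre rule
#' mapped to (0,1). The nodes are strictly interior, which keeps basis
#' functions with endpoint singularities (such as \eqn{-\log(1-p)}) finite.
#'
#' @param n_nodes number of quadrature nodes (default 199).
#' @return List with `p` (nodes) and `w` (weights summing to 1).
#' @keywords internal
quad_rule <- function(n_nodes = 199L) {
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  list(p = gl$x, w = gl$w)
}

# Working response: counts are offset by the mean of the implicit jittering
# noise, y_working = y + 0.5.
working_response <- function(dataset) {
  dataset$response + 0.5
}

# Loss, gradient and fitted quantile surface at the quadrature nodes
# (compiled kernel). eta[i, k] = x_i' theta b(p_k); the loss is
# sum_k w_k L_{p_k}(theta) and the gradient is restricted to the free
# entries of theta.
qrcm_loss_parts <- function(par, spec, X, yw, B, pnod, wnod,
                            want_grad = TRUE, want_eta = TRUE) {
  theta <- free_to_theta(par, spec)
  res <- cqr_loss_grad(X, theta, B, pnod, wnod, yw, want_grad, want_eta)
  out <- list(loss = res$loss)
  if (want_eta) out$eta <- res$eta
  if (want_grad) out$grad <- res$grad_full[free_index(spec)]
  out
}

# Reference implementation of the same quantities in plain R, kept as an
# independent cross-check of the compiled kernel. The check loss is
# accumulated as w_k [ p_k * sum_i res+ + (1 - p_k) * sum_i res- ] per node,
# and the gradient as t(X) (omega %*% (w*B)) - colSums(X) (x) colSums(w*p*B).
qrcm_loss_parts_r <- function(par, spec, X, yw, B, pnod, wnod,
                              want_grad = TRUE) {
  theta <- free_to_theta(par, spec)
  eta <- (X %*% theta) %*% t(B)              # n x K
  res <- yw - eta                             # y - fitted, n x K
  pos <- res > 0
  sum_pos <- colSums(res * pos)              # per-node positive residual mass
  sum_neg <- sum_pos - colSums(res)          # per-node |negative| residual mass
  loss <- sum(wnod * (pnod * sum_pos + (1 - pnod) * sum_neg))
  out <- list(loss = loss, eta = eta)
  if (want_grad) {
    WB <- B * wnod                            # K x k, row k scaled by w_k
    wpB <- colSums(B * (wnod * pnod))
    Gfull <- crossprod(X, (!pos) %*% WB) - outer(colSums(X), wpB)
    out$grad <- Gfull[free_index(spec)]
  }
  out
}

#' Integrated pinball loss of a theta matrix
#'
#' The QRCM objective \eqn{\bar L(\theta) = \int_0^1 L(\beta(p\mid\theta))
#' \mathrm{d}p}, approximated by a fixed Gauss-Legendre rule with interior
#' nodes. The count response is offset to the working response
#' \eqn{y^\circ = y + 0.5} internally.
#'
#' @param theta a [theta_matrix] or conforming plain matrix.
#' @param dataset a [qr_dataset].
#' @param spec a [model_spec].
#' @param n_nodes number of quadrature nodes (default 199).
#' @return Non-negative scalar.
#' @export
integrated_loss <- function(theta, dataset, spec, n_nodes = 199L) {
  stopifnot(inherits(dataset, "qr_dataset"), inherits(spec, "qrcm_spec"))
  values <- if (inherits(theta, "theta_matrix")) theta$values else
    theta_matrix(theta, spec)$values
  rule <- quad_rule(n_nodes)
  B <- basis_matrix(spec, rule$p)
  if (any(!is.finite(B))) stop("non-finite basis evaluation at a quadrature node")
  par <- theta_to_free(values, spec)
  qrcm_loss_parts(par, spec, dataset$design, working_response(dataset),
                  B, rule$p, rule$w, want_grad = FALSE)$loss
}

#' Fit a quantile-regression-coefficients model by integrated-loss
#' minimisation
#'
#' Estimates the free entries of the theta matrix by minimising the pinball
#' loss integrated over the quantile order. The optimiser is BFGS with the
#' analytic (almost-everywhere) gradient, followed by Newton polishing steps
#' that use the closed-form curvature of the integrated estimating equation.
#' The default working response is \eqn{y^\circ = y + 0.5}; a jittered or
#' otherwise continuous working response can be supplied instead via
#' `working`, which is how the Monte Carlo goodness-of-fit replicates and the
#' jittered-vs-offset comparison are fitted.
#'
#' @param dataset a [qr_dataset].
#' @param spec a [model_spec].
#' @param init optional [theta_matrix] (or conforming matrix) of starting
#'   values; by default the constant-basis column is initialised from a
#'   single-quantile fit at p = 0.5 and all other entries start at zero.
#' @param n_nodes quadrature nodes (default 199).
#' @param working optional numeric vector overriding the working response.
#' @param control list: `maxit` (BFGS iterations, default 500),
#'   `newton_steps` (default 40), `reltol` (default 1e-12).
#' @return Object of class `qrcm_fit`: `theta` ([theta_matrix]), `spec`,
#'   `loss` (minimised integrated loss), `gradient`, `gradient_norm`,
#'   `covariance` (free-parameter sandwich, see [covariance_sandwich()]),
#'   `se` (theta-shaped standard errors), `converged`, plus the design,
#'   working response and quadrature rule needed by downstream methods.
#' @export
fit_qrcm <- function(dataset, spec, init = NULL, n_nodes = 199L,
                     working = NULL, control = list()) {
  stopifnot(inherits(dataset, "qr_dataset"), inherits(spec, "qrcm_spec"))
  ctl <- list(maxit = 500L, newton_steps = 40L, reltol = 1e-12)
  ctl[names(control)] <- control
  X <- dataset$design
  n <- nrow(X)
  nfree <- count_free_parameters(spec)
  if (nfree >= n) stop("free-parameter count must be below n")
  if (nrow(spec$mask) != ncol(X)) {
    stop("spec has ", nrow(spec$mask), " coefficients but design has ",
         ncol(X), " columns")
  }
  yw <- if (is.null(working)) working_response(dataset) else {
    if (length(working) != n || anyNA(working)) {
      stop("`working` must be a complete numeric vector of length n")
    }
    as.numeric(working)
  }
  rule <- quad_rule(n_nodes)
  B <- basis_matrix(spec, rule$p)
  if (any(!is.finite(B))) stop("non-finite basis evaluation at a quadrature node")

  if (is.null(init)) {
    # constant column from a median fit; linear column from the interquartile
    # spread so the initial quantile curve is increasing in p (a flat start
    # has no usable curvature).
    theta0 <- matrix(0, spec$n_coef, spec$k)
    const_col <- match("legendre0", spec$basis_labels)
    lin_col <- match("legendre1", spec$basis_labels)
    med <- rq_fit_fn(X, yw, 0.5)$beta
    if (!is.na(const_col)) {
      use <- spec$mask[, const_col]
      theta0[use, const_col] <- med[use]
    }
    if (!is.na(lin_col)) {
      b25 <- rq_fit_fn(X, yw, 0.25)$beta
      b75 <- rq_fit_fn(X, yw, 0.75)$beta
      use <- spec$mask[, lin_col]
      theta0[use, lin_col] <- (b75 - b25)[use]   # P1(.75) - P1(.25) = 1
    }
  } else {
    theta0 <- if (inherits(init, "theta_matrix")) init$values else
      theta_matrix(init, spec)$values
  }
  par <- theta_to_free(theta0, spec)

  fn <- function(p_) qrcm_loss_parts(p_, spec, X, yw, B, rule$p, rule$w,
                                     want_grad = FALSE, want_eta = FALSE)$loss
  gr <- function(p_) qrcm_loss_parts(p_, spec, X, yw, B, rule$p, rule$w,
                                     want_eta = FALSE)$grad

  # Newton iteration on the smoothed curvature; the integrated loss is convex
  # and piecewise linear in theta, so descent with the closed-form curvature
  # plus backtracking converges to a kink-point minimiser quickly.
  cur <- qrcm_loss_parts(par, spec, X, yw, B, rule$p, rule$w)
  newton_pass <- function(par, cur, max_steps) {
    for (step in seq_len(max_steps)) {
      H <- qrcm_hessian(par, spec, X, yw, B, rule$p, eta = cur$eta)
      dirn <- tryCatch(
        -solve(H + diag(1e-8 * (1 + mean(diag(H))), nfree), cur$grad),
        error = function(e) -cur$grad / max(1, sqrt(sum(cur$grad^2))))
      improved <- FALSE
      for (alpha in 2^-(0:10)) {
        cand <- par + alpha * dirn
        cand_loss <- fn(cand)
        if (cand_loss < cur$loss - 1e-13 * (1 + abs(cur$loss))) {
          par <- cand
          cur <- qrcm_loss_parts(par, spec, X, yw, B, rule$p, rule$w)
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    list(par = par, cur = cur)
  }
  np <- newton_pass(par, cur, ctl$newton_steps)
  par <- np$par; cur <- np$cur

  # fall back to BFGS only if Newton stalled away from a stationary point,
  # then polish once more
  if (max(abs(cur$grad)) / n > 5e-3) {
    opt <- stats::optim(par, fn, gr, method = "BFGS",
                        control = list(maxit = ctl$maxit, reltol = ctl$reltol))
    if (opt$value < cur$loss) {
      par <- opt$par
      cur <- qrcm_loss_parts(par, spec, X, yw, B, rule$p, rule$w)
      np <- newton_pass(par, cur, ctl$newton_steps)
      par <- np$par; cur <- np$cur
    }
  }

  grad_norm <- max(abs(cur$grad)) / n
  converged <- is.finite(cur$loss)
  if (!converged || grad_norm > 0.1) {
    stop("integrated-loss minimisation failed to converge: |grad|_inf/n = ",
         format(grad_norm), ", loss = ", format(cur$loss))
  }

  # monotonicity of the fitted quantile surface at observed covariate rows is
  # not enforced; warn when the node-grid curves cross.
  n_viol <- sum(apply(cur$eta, 1, function(e) any(diff(e) < -1e-8)))
  if (n_viol > 0) {
    warning(sprintf(
      "fitted quantile function is non-monotone over the node grid for %d of %d observations",
      n_viol, n))
  }

  fit <- structure(
    list(theta = theta_matrix(free_to_theta(par, spec), spec), spec = spec,
         loss = cur$loss, gradient = cur$grad, gradient_norm = grad_norm,
         converged = converged, n = n, n_nodes = n_nodes,
         design = X, working = yw, rule = rule, basis_nodes = B,
         coef_names = spec$coef_names, offset_note = "fitted to y + 0.5"),
    class = "qrcm_fit"
  )
  fit$covariance <- tryCatch(covariance_sandwich(fit, dataset = NULL),
                             error = function(e) NULL)
  if (!is.null(fit$covariance)) {
    se <- free_to_theta(sqrt(pmax(diag(fit$covariance), 0)), spec)
    se[!spec$mask] <- NA_real_
    fit$se <- se
  }
  fit
}

#' @export
print.qrcm_fit <- function(x, ...) {
  cat("qrcm_fit:", sum(x$spec$mask), "free parameters, n =", x$n, "\n")
  cat("integrated loss:", format(x$loss, digits = 8),
      " |grad|_inf/n:", format(x$gradient_norm, digits = 3), "\n")
  invisible(x)
}

# Closed-form curvature of the integrated estimating equation. For monotone
# fitted curves the per-observation score is s_i(theta) =
# x_i (x) int (I(p >= p*_i) - p) b(p) dp, where p*_i solves
# x_i' theta b(p) = yw_i; differentiating through p*_i gives
# H = sum_i [x_i (x) b(p*_i)] [x_i (x) b(p*_i)]' / (x_i' theta b'(p*_i)).
# Observations whose working response falls outside the fitted range
# contribute no curvature. The curve slope is floored to keep H bounded.
qrcm_hessian <- function(par, spec, X, yw, B, pnod, eta = NULL) {
  theta <- free_to_theta(par, spec)
  if (is.null(eta)) eta <- (X %*% theta) %*% t(B)
  cross <- pit_from_eta(eta, yw, pnod)
  keep <- !is.na(cross$p_star) & cross$interior
  fi <- free_index(spec)
  nfree <- nrow(fi)
  if (!any(keep)) return(diag(1e-8, nfree))
  Bstar <- basis_matrix(spec, pmin(pmax(cross$p_star[keep], 1e-6), 1 - 1e-6))
  slope <- pmax(cross$slope[keep], 1e-3)
  V <- X[keep, fi[, "row"], drop = FALSE] * Bstar[, fi[, "col"], drop = FALSE]
  crossprod(V / sqrt(slope))
}

# First upward crossing of eta[i, ] with yw[i] over the node grid, linearly
# interpolated between adjacent nodes (compiled kernel). Returns the crossing
# quantile level (0 when the response is below the whole curve, 1 when
# above), the local slope d eta / d p there, and whether the crossing is
# interior with positive slope.
pit_from_eta <- function(eta, yw, pnod) {
  res <- cqr_first_crossing(eta, yw, pnod)
  list(p_star = as.numeric(res$p_star), slope = as.numeric(res$slope),
       interior = as.logical(res$interior))
}

#' M-estimation sandwich covariance of the free parameters
#'
#' Returns \eqn{H^{-1} G H^{-1}} where G is the outer-product sum of the
#' per-observation integrated gradient contributions and H is the closed-form
#' derivative of the integrated estimating equation (computed through the
#' fitted PIT values; symmetric positive semi-definite by construction).
#'
#' @param fit a [qrcm_fit].
#' @param dataset ignored (the fit stores its design and working response);
#'   kept for call-site symmetry.
#' @return Symmetric PSD matrix over the free parameters, with row/column
#'   labels `coefficient:basis`.
#' @export
covariance_sandwich <- function(fit, dataset = NULL) {
  stopifnot(inherits(fit, "qrcm_fit"))
  if (!fit$converged) stop("fit did not converge")
  spec <- fit$spec
  X <- fit$design
  yw <- fit$working
  B <- fit$basis_nodes
  rule <- fit$rule
  par <- theta_to_free(fit$theta$values, spec)
  fi <- free_index(spec)

  eta <- (X %*% fit$theta$values) %*% t(B)
  WB <- B * rule$w
  wpB <- colSums(B * (rule$w * rule$p))
  S0 <- (yw <= eta) %*% WB                  # n x k, integrated score pieces
  S0 <- sweep(S0, 2, wpB)
  S <- X[, fi[, "row"], drop = FALSE] * S0[, fi[, "col"], drop = FALSE]
  G <- crossprod(S)

  H <- qrcm_hessian(par, spec, X, yw, B, rule$p, eta = eta)
  Hinv <- tryCatch(solve(H), error = function(e) {
    stop("singular curvature matrix: consider a simpler model specification")
  })
  V <- Hinv %*% G %*% Hinv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(free_labels(spec), free_labels(spec))
  V
}

#' Global Wald test that a covariate has no effect at any quantile
#'
#' Tests the null that every free theta entry in the row of one covariate is
#' zero, using the quadratic form of those entries against their covariance
#' block; the reference distribution is chi-square with one degree of freedom
#' per tested entry.
#'
#' @param fit a [qrcm_fit] with a covariance matrix.
#' @param covariate_index row of the theta matrix to test: 1 is the
#'   intercept, 2 is the first covariate, and so on.
#' @return List with `statistic`, `df`, `p_value` and the tested row label.
#' @export
wald_test_global <- function(fit, covariate_index) {
  stopifnot(inherits(fit, "qrcm_fit"))
  if (is.null(fit$covariance)) stop("fit has no covariance matrix")
  spec <- fit$spec
  if (covariate_index < 1 || covariate_index > spec$n_coef) {
    stop("covariate_index out of range")
  }
  fi <- free_index(spec)
  rows <- which(fi[, "row"] == covariate_index)
  if (length(rows) == 0) stop("covariate has no free parameters")
  est <- theta_to_free(fit$theta$values, spec)[rows]
  Vblock <- fit$covariance[rows, rows, drop = FALSE]
  stat <- tryCatch(drop(est %*% solve(Vblock, est)), error = function(e) {
    stop("singular covariance block for covariate ", covariate_index)
  })
  df <- length(rows)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       coefficient = spec$coef_names[covariate_index])
}

#' Predicted count quantile for a covariate profile
#'
#' Applies the ceiling recovery rule \eqn{\lceil x'\beta(p\mid\hat\theta) - 1
#' \rceil} (identity transform of the working variable). Negative predictions
#' are possible under a linear specification and are returned unclamped.
#'
#' @param fit a [qrcm_fit].
#' @param x covariate row (length q+1, intercept first).
#' @param p quantile level(s) in (0,1).
#' @return Integer vector, one entry per `p`.
#' @export
predict_quantile_count <- function(fit, x, p) {
  stopifnot(inherits(fit, "qrcm_fit"))
  check_quantile_level(p)
  beta <- beta_curve(fit$theta, fit$spec, p)  # (q+1) x np or vector
  if (length(p) == 1) {
    as.integer(ceiling(sum(x * beta) - 1))
  } else {
    as.integer(ceiling(drop(x %*% beta) - 1))
  }
}

#' Probability integral transform of observed counts under a fitted model
#'
#' For each observation, finds the quantile level at which the fitted
#' quantile curve of the working response crosses \eqn{y^\circ = y + 0.5}
#' (first upward crossing over the quadrature node grid, linearly
#' interpolated), clamped to \eqn{[\epsilon, 1-\epsilon]}. Under a correctly
#' specified continuous working model these values are approximately
#' Uniform(0,1).
#'
#' @param fit a [qrcm_fit].
#' @param x covariate row or matrix of rows (intercept first); defaults to
#'   the design the model was fitted on.
#' @param y count(s); defaults to the fitted working response (already
#'   offset). When supplied, `y` is offset by +0.5 internally.
#' @param eps clamp width (default 1e-4).
#' @return Vector of PIT values in \eqn{[\epsilon, 1-\epsilon]}.
#' @export
pit <- function(fit, x = NULL, y = NULL, eps = 1e-4) {
  stopifnot(inherits(fit, "qrcm_fit"))
  if (is.null(x)) {
    X <- fit$design
    yw <- if (is.null(y)) fit$working else as.numeric(y) + 0.5
  } else {
    X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
    if (is.null(y)) stop("`y` is required when `x` is supplied")
    yw <- as.numeric(y) + 0.5
  }
  eta <- (X %*% fit$theta$values) %*% t(fit$basis_nodes)
  res <- pit_from_eta(eta, yw, fit$rule$p)
  pmin(pmax(res$p_star, eps), 1 - eps)
}

#' Distance of a sample from the Uniform(0,1) distribution
#'
#' Kolmogorov-Smirnov and Cramer-von Mises statistics of a vector of PIT
#' values against the uniform null; used by [gof_test()].
#'
#' @param u numeric vector in (0,1).
#' @param statistic `"KS"` or `"CvM"`.
#' @return Scalar statistic value.
#' @export
uniformity_statistic <- function(u, statistic = c("KS", "CvM")) {
  statistic <- match.arg(statistic)
  n <- length(u)
  us <- sort(u)
  i <- seq_len(n)
  if (statistic == "KS") {
    max(pmax(i / n - us, us - (i - 1) / n))
  } else {
    1 / (12 * n) + sum((us - (2 * i - 1) / (2 * n))^2)
  }
}

#' PIT goodness-of-fit test with Monte Carlo p-value
#'
#' Measures the distance of the empirical PIT distribution from Uniform(0,1)
#' and computes a parametric-bootstrap p-value: each replicate simulates a
#' continuous working response from the fitted model at the observed
#' covariates (draw p ~ Uniform(0,1), set \eqn{y^\circ = x'\beta(p \mid
#' \hat\theta)}), refits the model, and recomputes the statistic. The
#' p-value is the fraction of replicate statistics at least as large as the
#' observed one.
#'
#' @param fit a converged [qrcm_fit].
#' @param dataset the [qr_dataset] the model was fitted on.
#' @param statistic `"KS"` or `"CvM"`.
#' @param n_mc number of Monte Carlo replicates (at least 50; default 100).
#' @param seed integer seed for the replicates.
#' @return List with `statistic`, `value`, `p_value`, `n_mc_used` (replicates
#'   that refitted successfully) and the replicate statistics.
#' @export
gof_test <- function(fit, dataset, statistic = c("KS", "CvM"), n_mc = 100L,
                     seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(fit, "qrcm_fit"), inherits(dataset, "qr_dataset"))
  if (!fit$converged) stop("fit did not converge")
  if (n_mc < 50) stop("n_mc must be at least 50")
  obs <- uniformity_statistic(pit(fit), statistic)
  X <- fit$design
  n <- nrow(X)
  XT <- X %*% fit$theta$values               # n x k, reused per replicate

  stats_mc <- local_seed(seed, {
    vapply(seq_len(n_mc), function(r) {
      pu <- stats::runif(n)
      Bu <- basis_matrix(fit$spec, pmin(pmax(pu, 1e-9), 1 - 1e-9))
      yw_star <- rowSums(XT * Bu)
      refit <- tryCatch(
        suppressWarnings(
          fit_qrcm(dataset, fit$spec, init = fit$theta,
                   n_nodes = fit$n_nodes, working = yw_star)),
        error = function(e) NULL)
      if (is.null(refit)) return(NA_real_)
      u <- pit(refit)
      uniformity_statistic(u, statistic)
    }, numeric(1))
  })
  dropped <- sum(is.na(stats_mc))
  if (dropped > 0) {
    warning(dropped, " of ", n_mc, " Monte Carlo replicates failed to refit and were dropped")
  }
  ok <- stats_mc[!is.na(stats_mc)]
  list(statistic = statistic, value = obs,
       p_value = mean(ok >= obs), n_mc_used = length(ok),
       mc_statistics = ok)
}

#' Pointwise standard errors and confidence band of a coefficient curve
#'
#' Delta-method standard error of \eqn{\beta_c(p \mid \hat\theta) = b(p)'
#' \theta_c} from the covariance block of coefficient c's free parameters,
#' with a pointwise normal band.
#'
#' @param fit a [qrcm_fit] with covariance.
#' @param covariate_index theta row (1 = intercept).
#' @param p quantile level(s).
#' @param level confidence level for the band (default 0.95).
#' @return data.frame with `p`, `estimate`, `se`, `lower`, `upper`.
#' @export
beta_curve_band <- function(fit, covariate_index, p, level = 0.95) {
  stopifnot(inherits(fit, "qrcm_fit"))
  if (is.null(fit$covariance)) stop("fit has no covariance matrix")
  check_quantile_level(p)
  spec <- fit$spec
  fi <- free_index(spec)
  rows <- which(fi[, "row"] == covariate_index)
  if (length(rows) == 0) stop("covariate has no free parameters")
  cols <- fi[rows, "col"]
  Bp <- basis_matrix(spec, p)[, cols, drop = FALSE]
  Vblock <- fit$covariance[rows, rows, drop = FALSE]
  est <- drop(Bp %*% fit$theta$values[covariate_index, cols])
  se <- sqrt(pmax(rowSums((Bp %*% Vblock) * Bp), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(p = p, estimate = est, se = se,
             lower = est - zq * se, upper = est + zq * se)
}
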