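#' Monomial coefficients of a shifted Legendre polynomial
#'
#' The shifted Legendre polynomials \eqn{\tilde P_j(p) = P_j(2p - 1)} are
#' orthogonal on \eqn{[0,1]} and span the same space as the raw monomials
#' \eqn{1, p, \dots, p^j}, but give much better conditioned estimation. The
#' first three are \eqn{1}, \eqn{2p - 1} and \eqn{6p^2 - 6p + 1}.
#'
#' @param degree integer, 0 to 12.
#' @return Numeric vector of length `degree + 1`: monomial coefficients,
#'   constant term first.
#' @export
legendre_shifted_coeffs <- function(degree) {
  if (length(degree) != 1 || is.na(degree) || degree != round(degree) ||
      degree < 0) {
    stop("`degree` must be a single non-negative integer")
  }
  if (degree > 12) stop("`degree` must be at most 12")
  # recurrence (j+1) P~_{j+1} = (2j+1)(2p-1) P~_j - j P~_{j-1} on coefficients
  prev <- c(1)                      # degree 0
  if (degree == 0) return(prev)
  cur <- c(-1, 2)                   # degree 1: 2p - 1
  if (degree == 1) return(cur)
  for (j in 1:(degree - 1)) {
    shifted <- c(0, 2 * cur) - c(cur, 0)      # (2p - 1) * cur
    prev_pad <- c(prev, rep(0, length(shifted) - length(prev)))
    nxt <- ((2 * j + 1) * shifted - j * prev_pad) / (j + 1)
    prev <- c(cur, 0)
    cur <- nxt
  }
  cur
}

# Evaluate shifted Legendre polynomials of degrees 0..max_degree at p.
# Returns a length(p) x (max_degree+1) matrix. Uses the stable three-term
# recurrence at x = 2p - 1 rather than the monomial coefficients.
legendre_shifted_eval <- function(p, max_degree) {
  x <- 2 * p - 1
  out <- matrix(0, length(p), max_degree + 1)
  out[, 1] <- 1
  if (max_degree >= 1) out[, 2] <- x
  if (max_degree >= 2) {
    for (j in 1:(max_degree - 1)) {
      out[, j + 2] <- ((2 * j + 1) * x * out[, j + 1] - j * out[, j]) / (j + 1)
    }
  }
  out
}

#' Basis-function descriptors for quantile-coefficient models
#'
#' Constructors for the basis functions \eqn{b_j(p)} from which every
#' quantile-regression coefficient curve \eqn{\beta_c(p)} is built:
#' `basis_legendre(j)` is the shifted Legendre polynomial of degree `j`,
#' `basis_minus_log1mp()` is \eqn{-\log(1 - p)} (unbounded at the right
#' tail), `basis_log_p()` is \eqn{\log p}, and `basis_root(k)` is
#' \eqn{p^{1/k}}.
#'
#' @param degree polynomial degree (0 to 12).
#' @param power root order (integer >= 2).
#' @return A list of class `qrcm_basis` describing one basis function.
#' @export
basis_legendre <- function(degree) {
  if (degree < 0 || degree > 12 || degree != round(degree)) {
    stop("legendre degree must be an integer in 0..12")
  }
  structure(list(kind = "legendre_shifted", degree = as.integer(degree)),
            class = "qrcm_basis")
}

#' @rdname basis_legendre
#' @export
basis_minus_log1mp <- function() {
  structure(list(kind = "minus_log1mp"), class = "qrcm_basis")
}

#' @rdname basis_legendre
#' @export
basis_log_p <- function() {
  structure(list(kind = "log_p"), class = "qrcm_basis")
}

#' @rdname basis_legendre
#' @export
basis_root <- function(power) {
  if (power < 2 || power != round(power)) stop("root power must be an integer >= 2")
  structure(list(kind = "root", power = as.integer(power)), class = "qrcm_basis")
}

basis_label <- function(b) {
  switch(b$kind,
    legendre_shifted = paste0("legendre", b$degree),
    minus_log1mp = "-log(1-p)",
    log_p = "log(p)",
    root = paste0("p^(1/", b$power, ")"),
    stop("unknown basis kind: ", b$kind)
  )
}

# Evaluate a single basis function at interior quantile levels.
basis_eval_one <- function(b, p) {
  switch(b$kind,
    legendre_shifted = legendre_shifted_eval(p, b$degree)[, b$degree + 1],
    minus_log1mp = -log(1 - p),
    log_p = log(p),
    root = p^(1 / b$power),
    stop("unknown basis kind: ", b$kind)
  )
}

#' Specify a quantile-regression-coefficients model
#'
#' A model specification lists, for every regression coefficient (intercept
#' first), the basis functions of the quantile order that the coefficient
#' curve may load on. The union of all listed functions forms the shared
#' basis vector \eqn{b(p)} of length k, and a sparsity mask records which
#' \eqn{\theta_{cj}} are free; masked-out entries are fixed at zero. The
#' free-parameter count is the sum of the per-coefficient list lengths.
#'
#' @param coef_bases list of length q+1; element c is a list of
#'   [qrcm_basis][basis_legendre] descriptors for coefficient c-1.
#' @param coef_names optional labels, length q+1.
#' @return Object of class `qrcm_spec` with elements `bases` (the union,
#'   length k), `mask` ((q+1) x k logical), `coef_names`, `basis_labels`.
#' @export
model_spec <- function(coef_bases, coef_names = NULL) {
  if (!is.list(coef_bases) || length(coef_bases) < 1) {
    stop("`coef_bases` must be a non-empty list (one element per coefficient)")
  }
  for (cb in coef_bases) {
    if (!is.list(cb) || length(cb) < 1 ||
        !all(vapply(cb, inherits, TRUE, "qrcm_basis"))) {
      stop("every coefficient needs at least one qrcm_basis descriptor")
    }
  }
  labels_per_coef <- lapply(coef_bases, function(cb) vapply(cb, basis_label, ""))
  for (lab in labels_per_coef) {
    if (anyDuplicated(lab)) stop("duplicate basis function within one coefficient")
  }
  all_labels <- unique(unlist(labels_per_coef))
  union_bases <- list()
  for (cb in coef_bases) {
    for (b in cb) union_bases[[basis_label(b)]] <- b
  }
  union_bases <- union_bases[all_labels]
  k <- length(all_labels)
  q1 <- length(coef_bases)
  mask <- matrix(FALSE, q1, k, dimnames = list(NULL, all_labels))
  for (cidx in seq_len(q1)) {
    mask[cidx, labels_per_coef[[cidx]]] <- TRUE
  }
  if (is.null(coef_names)) {
    coef_names <- c("(Intercept)", if (q1 > 1) paste0("X", seq_len(q1 - 1)))
  }
  structure(
    list(bases = union_bases, mask = mask, coef_names = coef_names,
         basis_labels = all_labels, k = k, n_coef = q1),
    class = "qrcm_spec"
  )
}

#' @export
print.qrcm_spec <- function(x, ...) {
  cat("qrcm_spec:", x$n_coef, "coefficients,", x$k, "basis functions,",
      sum(x$mask), "free parameters\n")
  for (i in seq_len(x$n_coef)) {
    cat(" ", x$coef_names[i], ": ",
        paste(x$basis_labels[x$mask[i, ]], collapse = " + "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of free parameters of a model specification
#'
#' @param spec a [model_spec].
#' @return Integer: the number of unmasked entries of the theta matrix.
#' @export
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "qrcm_spec"))
  sum(spec$mask)
}

#' Evaluate the basis vector b(p)
#'
#' @param spec a [model_spec].
#' @param p quantile level(s), strictly inside (0,1).
#' @return For scalar `p` a vector of length k; otherwise a length(p) x k
#'   matrix.
#' @export
eval_basis <- function(spec, p) {
  stopifnot(inherits(spec, "qrcm_spec"))
  check_quantile_level(p)
  out <- basis_matrix(spec, p)
  if (length(p) == 1) drop(out) else out
}

# length(p) x k basis matrix, no interiority check (internal hot path)
basis_matrix <- function(spec, p) {
  k <- spec$k
  out <- matrix(0, length(p), k)
  max_deg <- -1L
  for (b in spec$bases) {
    if (b$kind == "legendre_shifted") max_deg <- max(max_deg, b$degree)
  }
  leg <- if (max_deg >= 0) legendre_shifted_eval(p, max_deg) else NULL
  for (j in seq_len(k)) {
    b <- spec$bases[[j]]
    out[, j] <- if (b$kind == "legendre_shifted") leg[, b$degree + 1] else
      basis_eval_one(b, p)
  }
  colnames(out) <- spec$basis_labels
  out
}

#' Construct a theta matrix conforming to a model specification
#'
#' @param values (q+1) x k numeric matrix; entries outside the spec's mask
#'   must be zero.
#' @param spec a [model_spec].
#' @return Object of class `theta_matrix` with elements `values` and `mask`.
#' @export
theta_matrix <- function(values, spec) {
  stopifnot(inherits(spec, "qrcm_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == dim(spec$mask))) {
    stop("theta dimensions must be (q+1) x k = ", nrow(spec$mask), " x ",
         ncol(spec$mask))
  }
  if (any(values[!spec$mask] != 0)) {
    stop("masked-out theta entries must be exactly 0")
  }
  dimnames(values) <- list(spec$coef_names, spec$basis_labels)
  structure(list(values = values, mask = spec$mask), class = "theta_matrix")
}

# free-parameter vectorisation: row-major over the mask (coefficient by
# coefficient), so Wald blocks for one covariate are contiguous.
free_index <- function(spec) {
  idx <- which(t(spec$mask))
  # positions in t(values); map back to (row, col) of values
  k <- spec$k
  col <- (idx - 1) %% k + 1
  row <- (idx - 1) %/% k + 1
  cbind(row = row, col = col)
}

theta_to_free <- function(theta_values, spec) {
  fi <- free_index(spec)
  theta_values[fi]
}

free_to_theta <- function(par, spec) {
  fi <- free_index(spec)
  values <- matrix(0, nrow(spec$mask), ncol(spec$mask))
  values[fi] <- par
  dimnames(values) <- list(spec$coef_names, spec$basis_labels)
  values
}

# labels for free parameters, aligned with free_index ordering
free_labels <- function(spec) {
  fi <- free_index(spec)
  paste0(spec$coef_names[fi[, "row"]], ":", spec$basis_labels[fi[, "col"]])
}

#' Coefficient curves beta(p | theta)
#'
#' Computes \eqn{\beta_c(p \mid \theta) = \sum_j \theta_{cj} b_j(p)} for all
#' coefficients.
#'
#' @param theta a [theta_matrix] (or plain matrix conforming to `spec`).
#' @param spec a [model_spec].
#' @param p quantile level(s) in (0,1).
#' @return For scalar `p`, a named vector of length q+1; otherwise a
#'   (q+1) x length(p) matrix.
#' @export
beta_curve <- function(theta, spec, p) {
  stopifnot(inherits(spec, "qrcm_spec"))
  values <- if (inherits(theta, "theta_matrix")) theta$values else
    theta_matrix(theta, spec)$values
  if (inherits(theta, "theta_matrix") && any(values[!spec$mask] != 0)) {
    stop("masked-out theta entries must be exactly 0")
  }
  check_quantile_level(p)
  B <- basis_matrix(spec, p)                  # np x k
  out <- values %*% t(B)                      # (q+1) x np
  rownames(out) <- spec$coef_names
  if (length(p) == 1) drop(out) else out
}

#' Serialise a model specification to JSON
#'
#' Writes the per-coefficient basis lists as plain JSON so specifications can
#' be stored alongside analysis outputs and reloaded exactly.
#'
#' @param spec a [model_spec].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "qrcm_spec"))
  per_coef <- lapply(seq_len(spec$n_coef), function(ci) {
    lapply(spec$bases[spec$mask[ci, ]], function(b) unclass(b))
  })
  obj <- list(coef_names = spec$coef_names, coef_bases = per_coef)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Read a model specification back from JSON
#'
#' @param json a JSON string or path to a JSON file written by
#'   [spec_to_json()].
#' @return A [model_spec].
#' @export
spec_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  coef_bases <- lapply(obj$coef_bases, function(cb) {
    lapply(cb, function(b) {
      switch(b$kind,
        legendre_shifted = basis_legendre(b$degree),
        minus_log1mp = basis_minus_log1mp(),
        log_p = basis_log_p(),
        root = basis_root(b$power),
        stop("unknown basis kind in JSON: ", b$kind)
      )
    })
  })
  model_spec(coef_bases, coef_names = unlist(obj$coef_names))
}
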