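# Shared oracles and fixture builders. Every oracle here is independent of
# the implementation path it checks.

# Brute-force quantile-regression oracle: the minimiser of the pinball loss
# interpolates ncol(X) observations, so enumerating all such vertices and
# keeping the lowest loss yields the exact global optimum (LP vertex
# enumeration). Only viable for small n choose k.
brute_force_qr <- function(X, t, p) {
  k <- ncol(X)
  n <- nrow(X)
  best <- Inf
  best_beta <- NULL
  combs <- utils::combn(n, k)
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    Xi <- X[idx, , drop = FALSE]
    if (abs(det(Xi)) < 1e-10) next
    b <- solve(Xi, t[idx])
    r <- t - drop(X %*% b)
    loss <- sum((p - (r <= 0)) * r)
    if (loss < best) {
      best <- loss
      best_beta <- b
    }
  }
  list(loss = best, beta = best_beta)
}

# Term-by-term pinball loss, written as a plain loop (oracle for the
# vectorised objective).
pinball_loop <- function(beta, p, t, X) {
  total <- 0
  for (i in seq_len(nrow(X))) {
    r <- t[i] - sum(X[i, ] * beta)
    omega <- as.numeric(r <= 0)
    total <- total + (p - omega) * r
  }
  total
}

# Smallest support value whose cdf reaches p (brute force over a pmf).
discrete_quantile <- function(pmf, support, p) {
  support[min(which(cumsum(pmf) >= p))]
}

# A count pmf whose deciles all sit mid-cell: every p in 0.1..0.9 lands
# exactly half-way through a probability cell, so quantile recovery has
# maximal margin against estimation noise.
midcell_pmf <- function() {
  list(pmf = c(0.05, rep(0.1, 9), 0.05), support = 0:10)
}

# Random full-rank regression instance with intercept.
random_instance <- function(n, q, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(stats::rnorm(n * q), n))
  beta <- stats::runif(q + 1, -1, 2)
  t <- drop(X %*% beta) + stats::rnorm(n)
  list(X = X, t = t)
}

# Small two-coefficient QRCM scenario with a known linear-in-p truth;
# returns the spec, true theta (shifted-Legendre coordinates), and a data
# generator. beta0(p) = 6 + 8p, beta1(p) = 1.25 + 0.5p; the wide intercept
# range spreads the counts over many support points, keeping the
# discretisation distortion of the continuous working model small.
toy_qrcm_scenario <- function() {
  spec <- model_spec(
    list(list(basis_legendre(0), basis_legendre(1)),
         list(basis_legendre(0), basis_legendre(1))),
    coef_names = c("(Intercept)", "x1"))
  theta_true <- matrix(c(10, 1.5, 4, 0.25), 2, 2)
  gen <- function(n, seed, continuous = FALSE) {
    set.seed(seed)
    x1 <- stats::rnorm(n)
    X <- cbind(1, x1)
    colnames(X) <- c("(Intercept)", "x1")
    pu <- stats::runif(n)
    B <- countqr:::basis_matrix(spec, pu)
    q_lat <- rowSums((X %*% theta_true) * B)
    y <- pmax(ceiling(q_lat - 1), 0)
    list(dataset = qr_dataset(X, y, names = colnames(X)),
         latent = q_lat, latent_p = pu)
  }
  list(spec = spec, theta_true = theta_true, gen = gen)
}
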