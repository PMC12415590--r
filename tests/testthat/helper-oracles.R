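# Independent brute-force oracles used to validate the implementation.
# These deliberately take different computational routes from the package.

# partial correlation of columns i and j of `dens` given covariate matrix C,
# via inversion of the joint covariance of [x_i, x_j, C]
oracle_pcor <- function(dens, C, i, j) {
  S <- stats::cov(cbind(dens[, i], dens[, j], C))
  P <- solve(S)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# full partial-correlation matrix by the pairwise inversion formula
oracle_pcor_matrix <- function(dens, C) {
  p <- ncol(dens)
  r <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    r[i, j] <- r[j, i] <- oracle_pcor(dens, C, i, j)
  }
  r
}

# from-scratch IDSCN Z matrix: perturb the control table with one patient
# row, recompute both partial-correlation networks pairwise, apply the
# Z formula directly
oracle_idscn_z <- function(ctl_dens, ctl_cov, pat_dens, pat_cov) {
  C0 <- as.matrix(ctl_cov)
  r0 <- oracle_pcor_matrix(ctl_dens, C0)
  r1 <- oracle_pcor_matrix(rbind(ctl_dens, pat_dens), rbind(C0, as.matrix(pat_cov)))
  n <- nrow(ctl_dens)
  z <- (r1 - r0) / ((1 - r0^2) / (n - 1))
  diag(z) <- 0
  z
}

# Benjamini-Hochberg step-up by the textbook rule
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rej <- logical(m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# BH adjusted p-values by the step-up definition (cummin from the top)
oracle_bh_adjust <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[ord] * m / (m:1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# adjusted Rand index by explicit pair counting
oracle_ari <- function(a, b) {
  n <- length(a)
  sa <- outer(a, a, "==")[upper.tri(diag(n))]
  sb <- outer(b, b, "==")[upper.tri(diag(n))]
  A <- sum(sa & sb); B <- sum(sa & !sb); C <- sum(!sa & sb); D <- sum(!sa & !sb)
  den <- (A + B) * (B + D) + (A + C) * (C + D)
  if (den == 0) return(1)
  2 * (A * D - B * C) / den
}

# classical pooled equal-variance two-sample t
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Pearson chi-square statistic and p from first principles
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Fisher's exact two-sided p for a 2x2 table by hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  m <- rowSums(tab)[1]; n <- rowSums(tab)[2]; k <- colSums(tab)[1]
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# VIFs via the diagonal of the inverted predictor correlation matrix
oracle_vif <- function(X) {
  diag(solve(stats::cor(X)))
}

# logistic regression by hand-rolled iteratively reweighted least squares
oracle_logistic_irls <- function(X, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.numeric(beta)
}

# small simulated cohort used across tests
toy_cohort <- function(seed = 1, n_controls = 30, n_patients = 12,
                       n_regions = 15, delta = 0.3) {
  spec <- if (delta == 0) {
    list(list(fraction = 1, edges = data.frame(i = 1, j = 2), delta = 0))
  } else {
    default_subtype_spec(delta, n_regions)
  }
  simulate_cohort(sim_config(n_controls = n_controls, n_patients = n_patients,
                             n_regions = n_regions, seed = seed,
                             subtype_spec = spec))
}

# atlas file writer for I/O tests
write_toy_atlas <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# group==control split without relying on package internals
cohort_controls_for_test <- function(co) {
  keep <- co$covariates$group == "control"
  list(density = co$density[keep, , drop = FALSE],
       covariates = co$covariates[keep, , drop = FALSE])
}
cohort_patients_for_test <- function(co) {
  keep <- co$covariates$group == "patient"
  list(density = co$density[keep, , drop = FALSE],
       covariates = co$covariates[keep, , drop = FALSE])
}
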