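make_rscn <- function(r, n) {
  structure(list(r = r, n = n, covariate_names = character(0)),
            class = "reference_scn")
}

test_that("residualized columns are orthogonal to the covariates", {
  set.seed(10)
  y <- matrix(rnorm(100), 20, 5)
  C <- matrix(rnorm(40), 20, 2)
  res <- residualize(y, C)
  inner <- crossprod(cbind(1, C), res)
  expect_lt(max(abs(inner)), 1e-8)
})

test_that("residualize handles degenerate designs as specified", {
  set.seed(11)
  y <- matrix(rnorm(60), 20, 3)
  # all covariates constant: residualizing reduces to mean-centering
  C0 <- matrix(1, 20, 2)
  expect_equal(residualize(y, C0), scale(y, scale = FALSE), ignore_attr = TRUE)
  # exact linear dependence of y on a covariate: residuals vanish
  age <- rnorm(20)
  y2 <- cbind(2 * age, -age + 3)
  expect_lt(max(abs(residualize(y2, cbind(age = age)))), 1e-12)
  # collinear covariates are an error naming the offender
  C2 <- cbind(a = age, b = 2 * age)
  expect_error(residualize(y, C2), "collinear")
  expect_error(residualize(y * NA, C0), "missing values")
})

test_that("reference SCN equals the brute-force partial correlation", {
  set.seed(12)
  dens <- matrix(rnorm(200), 50, 4)
  covs <- data.frame(sex = rbinom(50, 1, .5), age = rnorm(50, 45, 10),
                     education = rnorm(50, 11, 4), tiv = rnorm(50, 1450, 100))
  scn <- build_reference_scn(dens, covs)
  oracle <- oracle_pcor_matrix(dens, as.matrix(covs))
  expect_lt(max(abs(scn$r - oracle)), 1e-10)
  expect_identical(scn$n, 50L)
  expect_equal(diag(scn$r), rep(1, 4))
  expect_equal(scn$r, t(scn$r))
})

test_that("reference SCN flags degenerate inputs", {
  set.seed(13)
  dens <- matrix(rnorm(120), 30, 4)
  colnames(dens) <- paste0("R", 1:4)
  covs <- data.frame(sex = rbinom(30, 1, .5), age = rnorm(30), education = rnorm(30),
                     tiv = rnorm(30))
  dens2 <- dens
  dens2[, 2] <- 7
  expect_error(build_reference_scn(dens2, covs), "zero-variance region.*R2")
  expect_error(build_reference_scn(dens[1:5, ], covs[1:5, ]), "at least")
  expect_error(build_reference_scn(dens, covs[, 1:3]), "missing covariate")
  # two identical region columns correlate perfectly
  dens3 <- cbind(dens, R5 = dens[, 1])
  scn <- build_reference_scn(dens3, covs)
  expect_equal(scn$r[1, 5], 1)
})

test_that("a patient duplicating a control gives the duplicated-table network", {
  set.seed(14)
  dens <- matrix(rnorm(150), 30, 5)
  covs <- data.frame(sex = rbinom(30, 1, .5), age = rnorm(30, 45, 10),
                     education = rnorm(30, 11, 4), tiv = rnorm(30, 1450, 100))
  pscn <- build_perturbed_scn(dens, covs, dens[7, ], covs[7, ])
  direct <- build_reference_scn(rbind(dens, dens[7, ]), rbind(covs, covs[7, ]))
  expect_equal(pscn, direct$r)
})

test_that("the perturbation of a null patient shrinks as the control cohort grows", {
  devs <- vapply(c(20, 50, 100), function(n) {
    set.seed(n)
    dens <- matrix(rnorm(n * 5), n, 5)
    covs <- data.frame(sex = rbinom(n, 1, .5), age = rnorm(n), education = rnorm(n),
                       tiv = rnorm(n))
    rscn <- build_reference_scn(dens, covs)
    max(vapply(1:20, function(k) {
      pd <- rnorm(5)
      pc <- data.frame(sex = rbinom(1, 1, .5), age = rnorm(1), education = rnorm(1),
                       tiv = rnorm(1))
      max(abs(build_perturbed_scn(dens, covs, pd, pc) - rscn$r))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("Z matches the stated formula, including hand-computed values", {
  r <- matrix(c(1, .5, .5, 1), 2)
  rscn <- make_rscn(r, n = 5)
  pscn <- matrix(c(1, .6, .6, 1), 2)
  net <- compute_idscn(rscn, pscn)
  expect_equal(net$z[1, 2], 0.1 / ((1 - 0.25) / 4))   # = 0.5333...
  expect_equal(net$z[1, 2], 0.53333333333333333)
  # sd-denominator variant for sensitivity analysis
  net_sd <- compute_idscn(rscn, pscn, denominator = "sd")
  expect_equal(net_sd$z[1, 2], 0.1 / sqrt((1 - 0.25) / 4))
  # zero perturbation: Z = 0, p = 1
  net0 <- compute_idscn(rscn, r)
  expect_true(all(net0$z == 0))
  expect_true(all(net0$p == 1))
  # |Z| = 1.96 maps to p ~ 0.05
  rb <- make_rscn(diag(2), n = 50)
  pb <- diag(2); pb[1, 2] <- pb[2, 1] <- 1.96 / 49
  expect_equal(compute_idscn(rb, pb)$p[1, 2], 0.0499958, tolerance = 1e-5)
})

test_that("Z is monotone in |perturbation| and in the control count", {
  r <- matrix(c(1, .3, .3, 1), 2)
  zs <- vapply(c(.01, .05, .1, .2), function(d) {
    p <- r; p[1, 2] <- p[2, 1] <- r[1, 2] + d
    compute_idscn(make_rscn(r, 30), p)$z[1, 2]
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
  zn <- vapply(c(10, 30, 100), function(n) {
    p <- r; p[1, 2] <- p[2, 1] <- .4
    compute_idscn(make_rscn(r, n), p)$z[1, 2]
  }, numeric(1))
  expect_true(all(diff(zn) > 0))
})

test_that("degenerate unit correlations carry no information", {
  r <- matrix(c(1, 1, 1, 1), 2)
  p <- matrix(c(1, .8, .8, 1), 2)
  expect_warning(net <- compute_idscn(make_rscn(r, 30), p), "no information")
  expect_identical(net$z[1, 2], 0)
  expect_error(compute_idscn(make_rscn(r, 30), diag(3)), "shapes differ")
})

test_that("pipeline Z agrees with the independent brute-force oracle", {
  for (case in 1:20) {
    set.seed(300 + case)
    dens <- matrix(rnorm(150), 30, 5)
    covs <- data.frame(sex = rbinom(30, 1, .5), age = rnorm(30, 45, 10),
                       education = rnorm(30, 11, 4), tiv = rnorm(30, 1450, 100))
    pd <- rnorm(5)
    pc <- data.frame(sex = 1, age = rnorm(1, 45, 10),
                     education = rnorm(1, 11, 4), tiv = rnorm(1, 1450, 100))
    rscn <- build_reference_scn(dens, covs)
    pscn <- build_perturbed_scn(dens, covs, pd, pc)
    z <- compute_idscn(rscn, pscn)$z
    z_oracle <- oracle_idscn_z(dens, covs, pd, pc)
    expect_lt(max(abs(z - z_oracle)), 1e-10)
    expect_equal(z, t(z))
    expect_true(all(diag(z) == 0))
  }
})

test_that("FDR edge selection follows the step-up rule", {
  # construct a 4-region patient network with known p-values
  pvec <- c(0.001, 0.011, 0.02, 0.9, 1, 1)
  z <- unflatten_edges(-qnorm(pvec / 2))
  rscn <- make_rscn(diag(4), n = 50)
  pscn <- diag(4) + unflatten_edges(flatten_edges(z) * (1 - 0^2) / 49)
  diag(pscn) <- 1
  net <- compute_idscn(rscn, pscn)
  expect_equal(flatten_edges(net$p), pvec, tolerance = 1e-12)
  sel <- select_significant_edges(net, q = 0.05)
  # by hand: sorted p vs i*q/m -> largest i with p_(i) <= i*0.05/6 is i = 3
  expect_identical(sel$n_sig_edges, 3L)
  expect_identical(which(flatten_edges(sel$sig_mask) > 0), 1:3)
  expect_equal(flatten_edges(sel$sig_mask) > 0, oracle_bh_reject(pvec, 0.05))
  # all p = 1: nothing selected
  all1 <- select_significant_edges(compute_idscn(rscn, diag(4)), q = 0.05)
  expect_identical(all1$n_sig_edges, 0L)
})

test_that("heterogeneity summary reports per-patient counts with sample SD", {
  fake <- function(cnt) structure(list(n_sig_edges = cnt), class = "patient_idscn")
  s <- cohort_heterogeneity_summary(list(fake(100L), fake(300L)))
  expect_equal(s$mean, 200)
  expect_equal(s$sd, sqrt(2) * 100, tolerance = 1e-12)
  s0 <- cohort_heterogeneity_summary(list(fake(0L), fake(0L), fake(0L)))
  expect_equal(s0$mean, 0)
  expect_equal(s0$sd, 0)
  expect_error(cohort_heterogeneity_summary(list()), "no patients")
})

test_that("edge tables export in canonical flat order", {
  co <- toy_cohort(seed = 21, n_regions = 15)
  built <- build_cohort_idscns(co)
  tab <- idscn_edge_table(built$idscns[[1]])
  expect_identical(nrow(tab), nrow(edge_universe(15)))
  expect_equal(tab$z, flatten_edges(built$idscns[[1]]$z))
  expect_true(all(tab$significant == (tab$p_fdr <= 0.05)))
})

test_that("planted edges are enriched among FDR-significant edges", {
  # pooled 2x2 of (planted x significant) across patients and seeds; the
  # single-subject signal at delta = 0.3 is weak, so the enrichment is
  # modest but its odds ratio is reliably above 1 at this pooled size
  tab <- matrix(0, 2, 2)
  eu <- edge_universe(15)
  for (s in 1:10) {
    co <- simulate_cohort(sim_config(n_controls = 65, n_patients = 40,
                                     n_regions = 15, seed = 400 + s,
                                     base_correlation = diag(15)))
    built <- build_cohort_idscns(co)
    pe <- co$truth$subtype_spec[[1]]$edges
    planted <- paste(eu$i, eu$j) %in% paste(pe$i, pe$j)
    for (x in built$idscns) {
      sig <- flatten_edges(x$sig_mask) > 0
      tab <- tab + table(factor(planted, c(FALSE, TRUE)),
                         factor(sig, c(FALSE, TRUE)))
    }
  }
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_gt(or, 1)
})
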