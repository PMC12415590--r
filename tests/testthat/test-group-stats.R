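test_that("covariate-free adjusted comparison equals the classical pooled t", {
  set.seed(40)
  for (case in 1:10) {
    y <- matrix(rnorm(10), 10, 1)
    colnames(y) <- "e1"
    g <- rep(c("a", "b"), each = 5)
    res <- compare_edges_between_subtypes(y, g)
    # reported t is group-1 minus group-2
    expect_equal(res$t, oracle_pooled_t(y[g == "a", 1], y[g == "b", 1]),
                 tolerance = 1e-10)
    tt <- t.test(y[g == "a", 1], y[g == "b", 1], var.equal = TRUE)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("adjusted comparison reports direction consistently and applies BH", {
  set.seed(41)
  n <- 40
  g <- rep(c(1, 2), each = n / 2)
  covs <- data.frame(sex = rbinom(n, 1, .5), age = rnorm(n, 45, 10),
                     education = rnorm(n, 11, 4), tiv = rnorm(n, 1450, 100))
  y <- cbind(up = rnorm(n) + 2 * (g == 1),   # subtype 1 higher
             dn = rnorm(n) + 2 * (g == 2),   # subtype 2 higher
             nil = rnorm(n))
  res <- compare_edges_between_subtypes(y, g, covs)
  expect_gt(res$t[1], 0)
  expect_identical(res$direction[1], "1>2")
  expect_lt(res$t[2], 0)
  expect_identical(res$direction[2], "1<2")
  expect_equal(res$p_fdr, oracle_bh_adjust(res$p), tolerance = 1e-12)
  expect_true(all(res$p_fdr >= res$p - 1e-15))
  expect_error(compare_edges_between_subtypes(y, rep(1, n), covs), "exactly 2")
  expect_error(compare_edges_between_subtypes(y, c(1, 1, rep(2, n - 2)), covs),
               "at least 3")
})

test_that("a group indicator orthogonal to a feature yields t near 0", {
  y <- matrix(rep(c(1, -1), 10), ncol = 1)   # mean identical in both groups
  g <- rep(c(1, 2), each = 10)
  res <- compare_edges_between_subtypes(y, g)
  expect_lt(abs(res$t), 1e-10)
  expect_gt(res$p, 0.999)
})

test_that("BH implementation agrees with the brute-force step-up on random inputs", {
  set.seed(42)
  for (case in 1:1000) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(p.adjust(p, "BH") <= q, oracle_bh_reject(p, q))
    expect_equal(p.adjust(p, "BH"), oracle_bh_adjust(p), tolerance = 1e-12)
  }
})

test_that("type-I error of the edge-wise test is nominal under the null", {
  set.seed(43)
  n <- 40
  g <- sample(rep(1:2, each = n / 2))
  covs <- data.frame(sex = rbinom(n, 1, .5), age = rnorm(n), education = rnorm(n),
                     tiv = rnorm(n))
  y <- matrix(rnorm(n * 500), n, 500)
  res <- compare_edges_between_subtypes(y, g, covs)
  rate <- mean(res$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("permutation p-values behave under null and degenerate inputs", {
  set.seed(44)
  n <- 28
  g <- rep(1:2, each = n / 2)
  # feature balanced identically in both groups: observed t = 0, permutation p ~ 1
  y0 <- matrix(rep(c(1, -1), n / 2), ncol = 1)
  pr0 <- permutation_edge_test(y0, g, B = 200, seed = 1)
  expect_gt(pr0$p_perm, 0.95)
  # null features: permutation p roughly uniform
  y <- matrix(rnorm(n * 60), n, 60)
  pr <- permutation_edge_test(y, g, B = 300, seed = 2)
  ks <- suppressWarnings(ks.test(pr$p_perm, "punif"))$statistic
  expect_lt(unname(ks), 0.2)
  expect_true(all(pr$p_perm >= 1 / 301 & pr$p_perm <= 1))
  expect_warning(permutation_edge_test(y0, g, B = 50, seed = 1), "coarse")
})

test_that("permutation test is reproducible and invariant to label renaming", {
  set.seed(45)
  n <- 24
  y <- matrix(rnorm(n * 10), n, 10)
  g <- rep(c("x", "y"), each = n / 2)
  covs <- data.frame(age = rnorm(n), tiv = rnorm(n))
  a <- permutation_edge_test(y, g, covs, B = 150, seed = 7)
  b <- permutation_edge_test(y, g, covs, B = 150, seed = 7)
  expect_identical(a$p_perm, b$p_perm)
  g2 <- ifelse(g == "x", "aaa", "zzz")   # same partition, new names
  c2 <- permutation_edge_test(y, g2, covs, B = 150, seed = 7)
  expect_equal(abs(a$t_obs), abs(c2$t_obs), tolerance = 1e-12)
  expect_identical(a$p_perm, c2$p_perm)
})

test_that("demographic dispatch reproduces the printed contingency analyses", {
  # sex-by-group table: chi-square without continuity correction
  sex <- rep(c(1, 0, 1, 0), c(8, 47, 10, 55))
  grp <- rep(c("patient", "control"), c(55, 65))
  d <- data.frame(sex = sex, group = grp)
  res <- compare_demographics(d, "group", "sex", "categorical")
  expect_identical(res$test, "chi-square")
  o <- oracle_chisq(table(d$sex, d$group))
  expect_equal(res$statistic, o$statistic, tolerance = 1e-12)
  expect_equal(res$p, o$p, tolerance = 1e-12)
  expect_equal(res$p, 0.898, tolerance = 5e-4)

  # subtype-by-sex table with small expected counts: Fisher's exact test
  d2 <- data.frame(subtype = rep(c(1, 2, 1, 2), c(3, 5, 16, 31)),
                   sexg = rep(c("male", "female"), c(8, 47)))
  res2 <- compare_demographics(d2, "sexg", "subtype", "categorical")
  expect_identical(res2$test, "fisher")
  expect_gt(res2$p, 0.999)
  expect_equal(res2$p, oracle_fisher_2x2(table(d2$subtype, d2$sexg)),
               tolerance = 1e-10)
})

test_that("demographic dispatch picks the test from normality and sample size", {
  set.seed(46)
  n <- 60
  d <- data.frame(
    group = rep(c("a", "b"), each = n / 2),
    normal_var = rnorm(n, 10, 2),
    skewed_var = rexp(n)^2,
    cat_var = rbinom(n, 1, 0.5)
  )
  res <- compare_demographics(d, "group", c("normal_var", "skewed_var", "cat_var"),
                              c("continuous", "continuous", "categorical"))
  expect_identical(res$test[res$variable == "normal_var"], "t")
  expect_identical(res$test[res$variable == "skewed_var"], "mann-whitney")
  expect_identical(res$test[res$variable == "cat_var"], "chi-square")
  # identical group distributions: p = 1 for the pooled t
  d3 <- data.frame(group = rep(c("a", "b"), each = 30),
                   v = rep(rnorm(30, 5, 1), 2))
  r3 <- compare_demographics(d3, "group", "v", "continuous")
  expect_gt(r3$p, 0.999)
  expect_warning(
    compare_demographics(data.frame(group = c("a", "b"), v = c(NA, NA)),
                         "group", "v", "continuous"),
    "all-missing")
})

test_that("subgroup analysis splits, tests edges, and compares subtype proportions", {
  set.seed(47)
  n <- 40
  feat <- matrix(rnorm(n * 12), n, 12)
  labels <- rep(1:2, c(15, 25))
  clinical <- data.frame(
    sex = rbinom(n, 1, 0.5),
    migraine_duration = rlnorm(n, 2, 0.8),
    tiny = rep(c(1, 2), c(1, n - 1))
  )
  w <- capture_warnings(
    out <- subgroup_analysis(feat, labels, clinical,
                             c(sex = "binary", migraine_duration = "continuous",
                               tiny = "binary", absent = "binary")))
  expect_length(grep("skipped", w), 2)
  expect_identical(sort(names(out)), c("migraine_duration", "sex"))
  md <- out$migraine_duration
  expect_identical(sort(unique(md$split)), c("longer", "shorter"))
  expect_identical(md$n_sig_edges, sum(md$edge_tests$significant))
  expect_true(md$proportion_test$test %in% c("chi-square", "fisher"))
  expect_true(md$proportion_test$p >= 0 && md$proportion_test$p <= 1)
  # a split independent of everything rarely yields significant edges
  expect_lte(out$sex$n_sig_edges, 2L)
})
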