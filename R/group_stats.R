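#' Group-level statistics
#'
#' Covariate-adjusted edge-wise comparison between two subtypes, its
#' permutation validation, demographic/clinical group comparisons with
#' normality-driven test dispatch, and exploratory subgroup analyses.
#'
#' "Two-sample t-test controlling for covariates" is operationalized as
#' the t-statistic of the group coefficient in a least-squares model
#' `edge_Z ~ intercept + group + covariates`; with no covariates this is
#' exactly the classical pooled equal-variance two-sample t.
#'
#' @name group-stats
NULL

# t-statistics of the group coefficient for every column of Y, via
# Frisch-Waugh partialling: residualize Y and the group indicator on
# [intercept + covariates], then simple regression. Identical to the
# full-model t (same residual df).
.group_t <- function(Y, g, C) {
  n <- nrow(Y)
  X0 <- cbind(1, C)
  qr0 <- qr(X0)
  Yr <- qr.resid(qr0, Y)
  gr <- qr.resid(qr0, g)
  gg <- sum(gr^2)
  if (gg < 1e-12) stop("group indicator is collinear with the covariates")
  beta <- as.numeric(crossprod(gr, Yr)) / gg
  rss <- colSums(Yr^2) - beta^2 * gg
  df <- n - qr0$rank - 1
  if (df < 1) stop("not enough residual degrees of freedom")
  se <- sqrt(pmax(rss, 0) / df / gg)
  t <- ifelse(se > 0, beta / se, 0)
  list(t = t, beta = beta, df = df, residualized = list(Y = Yr, g = gr, qr0 = qr0))
}

#' Edge-wise covariate-adjusted comparison between two subtypes
#'
#' @param features Patients x K matrix of edge features (signed Z).
#' @param labels Two-valued subtype labels aligned with the rows.
#' @param covariates Optional data.frame/matrix of adjustment covariates
#'   (`NULL` for the unadjusted classical t-test).
#' @param q FDR level for the BH correction across the K edges.
#' @return Object of class `edge_comparison`: data.frame per edge with
#'   `edge`, `t`, `p`, `p_fdr`, `direction` (which subtype is higher,
#'   consistent with the sign of `t`), `significant`; attributes `df`,
#'   `n_per_group`, `covariates`.
#' @export
compare_edges_between_subtypes <- function(features, labels, covariates = NULL,
                                           q = 0.05) {
  features <- as.matrix(features)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("exactly 2 subtype labels required, got ", length(lv))
  if (length(labels) != nrow(features)) stop("labels do not match feature rows")
  if (min(table(labels)) < 3) stop("each subtype needs at least 3 members")
  g <- as.numeric(labels == lv[2])   # indicator of the second (higher) label
  C <- if (is.null(covariates)) matrix(nrow = length(g), ncol = 0) else
    as.matrix(as.data.frame(covariates))
  ft <- .group_t(features, g, C)
  p <- 2 * stats::pt(-abs(ft$t), df = ft$df)
  p_fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    edge = colnames(features) %||% as.character(seq_along(ft$t)),
    t = -ft$t,  # report as subtype-1-minus-subtype-2 (first label first)
    p = p, p_fdr = p_fdr,
    direction = ifelse(ft$t < 0, paste0(lv[1], ">", lv[2]),
                       paste0(lv[1], "<", lv[2])),
    significant = p_fdr <= q
  )
  attr(out, "df") <- ft$df
  attr(out, "n_per_group") <- as.integer(table(factor(labels, levels = lv)))
  attr(out, "covariates") <- if (ncol(C)) colnames(C) else character(0)
  class(out) <- c("edge_comparison", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation validation of the edge-wise subtype comparison
#'
#' Permutes the subtype labels B times (covariates fixed), recomputes the
#' covariate-adjusted |t| per edge, and reports the add-one permutation
#' p-value `p = (1 + #(|t_perm| >= |t_obs|)) / (B + 1)` with BH correction
#' across edges.
#'
#' @param features,labels,covariates As in
#'   [compare_edges_between_subtypes()].
#' @param B Number of permutations (default 10000; below 100 a warning).
#' @param seed Seed for the permutation stream.
#' @param q FDR level.
#' @return Object of class `permutation_result`: data.frame with `edge`,
#'   `t_obs`, `p_perm`, `p_perm_fdr`, `significant`; attributes `B`,
#'   `seed`.
#' @export
permutation_edge_test <- function(features, labels, covariates = NULL,
                                  B = 10000, seed = 1, q = 0.05) {
  if (B < 100) warning("B < 100 permutations gives a very coarse p-value grid")
  features <- as.matrix(features)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("exactly 2 subtype labels required")
  g <- as.numeric(labels == lv[2])
  C <- if (is.null(covariates)) matrix(nrow = length(g), ncol = 0) else
    as.matrix(as.data.frame(covariates))
  obs <- .group_t(features, g, C)
  X0qr <- obs$residualized$qr0
  Yr <- obs$residualized$Y
  n <- length(g)
  df <- obs$df
  yy <- colSums(Yr^2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  exceed <- numeric(ncol(features))
  tobs <- abs(obs$t)
  for (b in seq_len(B)) {
    gp <- g[sample.int(n)]
    gr <- qr.resid(X0qr, gp)
    gg <- sum(gr^2)
    beta <- as.numeric(crossprod(gr, Yr)) / gg
    rss <- yy - beta^2 * gg
    tperm <- abs(beta / sqrt(pmax(rss, 0) / df / gg))
    # ties at floating-point resolution count as exceedances
    exceed <- exceed + (tperm >= tobs - 1e-8 * (1 + tobs))
  }
  p_perm <- (1 + exceed) / (B + 1)
  p_fdr <- stats::p.adjust(p_perm, method = "BH")
  out <- data.frame(
    edge = colnames(features) %||% as.character(seq_along(tobs)),
    t_obs = -obs$t, p_perm = p_perm, p_perm_fdr = p_fdr,
    significant = p_fdr <= q
  )
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  class(out) <- c("permutation_result", "data.frame")
  out
}

#' Demographic/clinical comparison between two groups
#'
#' Continuous variables: Shapiro-Wilk normality in each group at alpha =
#' 0.05 decides between the pooled two-sample t-test (both groups normal)
#' and the Mann-Whitney U test. Categorical variables: Pearson chi-square
#' without continuity correction, switching to Fisher's exact test when
#' any expected cell count is below 5.
#'
#' @param data data.frame with the variables and the group column.
#' @param group Name of the two-level grouping column.
#' @param variables Character vector of variable names to compare.
#' @param kinds Character vector (`"continuous"`/`"categorical"`),
#'   recycled over `variables`.
#' @param chisq_correct Apply Yates continuity correction (default FALSE).
#' @return data.frame: `variable`, `kind`, `test`, `statistic`, `p`.
#'   All-missing variables are skipped with a warning.
#' @export
compare_demographics <- function(data, group, variables, kinds,
                                 chisq_correct = FALSE) {
  kinds <- rep_len(kinds, length(variables))
  gv <- data[[group]]
  glev <- unique(stats::na.omit(gv))
  if (length(glev) != 2) stop("grouping column must have exactly 2 levels")
  rows <- list()
  for (k in seq_along(variables)) {
    v <- variables[k]
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(gv)
    if (!any(ok)) {
      warning("variable '", v, "' is all-missing; skipped")
      next
    }
    x <- x[ok]; g <- gv[ok]
    if (kinds[k] == "continuous") {
      x1 <- x[g == glev[1]]; x2 <- x[g == glev[2]]
      normal <- function(z) {
        if (length(unique(z)) < 3 || length(z) < 3) return(FALSE)
        stats::shapiro.test(z)$p.value > 0.05
      }
      if (normal(x1) && normal(x2)) {
        tt <- stats::t.test(x1, x2, var.equal = TRUE)
        rows[[v]] <- data.frame(variable = v, kind = kinds[k], test = "t",
                                statistic = unname(tt$statistic), p = tt$p.value)
      } else {
        wt <- stats::wilcox.test(x1, x2, exact = FALSE)
        rows[[v]] <- data.frame(variable = v, kind = kinds[k],
                                test = "mann-whitney",
                                statistic = unname(wt$statistic), p = wt$p.value)
      }
    } else {
      tab <- table(x, g)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- stats::fisher.test(tab)
        rows[[v]] <- data.frame(variable = v, kind = kinds[k], test = "fisher",
                                statistic = NA_real_, p = ft$p.value)
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = chisq_correct))
        rows[[v]] <- data.frame(variable = v, kind = kinds[k], test = "chi-square",
                                statistic = unname(ct$statistic), p = ct$p.value)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exploratory subgroup analyses
#'
#' For each split variable: patients are dichotomized (binary variables
#' as-is; continuous variables by `< median` vs `>= median`), the edge
#' features are compared between the two subgroups with unadjusted
#' two-sample t-tests (BH over the K edges), and the subtype proportions
#' are compared with a chi-square test (Fisher's exact when any expected
#' cell count is below 5). Splits producing a subgroup smaller than 3 are
#' skipped with a warning.
#'
#' @param features Patients x K edge feature matrix.
#' @param labels Subtype labels aligned with the rows.
#' @param clinical data.frame of per-patient clinical variables (aligned).
#' @param splits Named character vector: names are the variables to split
#'   on, values their kind (`"binary"` or `"continuous"`).
#' @return Named list per split with `split` (the dichotomized factor),
#'   `edge_tests` (an `edge_comparison`), `n_sig_edges`, and
#'   `proportion_test` (`test`, `statistic`, `p`, `table`).
#' @export
subgroup_analysis <- function(features, labels, clinical, splits) {
  features <- as.matrix(features)
  out <- list()
  for (v in names(splits)) {
    x <- clinical[[v]]
    if (is.null(x)) {
      warning("split variable '", v, "' not found; skipped")
      next
    }
    grp <- if (splits[[v]] == "continuous") {
      ifelse(x < stats::median(x, na.rm = TRUE), "shorter", "longer")
    } else {
      as.character(x)
    }
    ok <- !is.na(grp)
    tab_n <- table(grp[ok])
    if (length(tab_n) < 2 || min(tab_n) < 3) {
      warning("split '", v, "' leaves a subgroup with < 3 patients; skipped")
      next
    }
    et <- compare_edges_between_subtypes(features[ok, , drop = FALSE], grp[ok])
    st <- table(factor(labels[ok]), grp[ok])
    expected <- outer(rowSums(st), colSums(st)) / sum(st)
    pt <- if (any(expected < 5)) {
      f <- stats::fisher.test(st)
      list(test = "fisher", statistic = NA_real_, p = f$p.value, table = st)
    } else {
      c2 <- suppressWarnings(stats::chisq.test(st, correct = FALSE))
      list(test = "chi-square", statistic = unname(c2$statistic),
           p = c2$p.value, table = st)
    }
    out[[v]] <- list(split = grp, edge_tests = et,
                     n_sig_edges = sum(et$significant),
                     proportion_test = pt)
  }
  out
}
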