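#' Imaging-clinical association screening
#'
#' Multivariate linear regression for continuous clinical outcomes and
#' multivariate logistic regression for binary ones, with the imaging
#' feature(s) of interest entered alongside sex, age, education and TIV.
#' Predictors with a variance inflation factor above 5 are excluded
#' iteratively before fitting; linear models with non-normal residuals
#' (Shapiro-Wilk at alpha = 0.05) are discarded. A model is retained for
#' interpretation only when it survives these gates and at least one
#' imaging feature has p < 0.05.
#'
#' @name association
NULL

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' j on all the others (with intercept). Constant predictors get VIF = 1.
#'
#' @param design Numeric matrix or data.frame of predictors (no intercept
#'   column).
#' @return Named numeric vector of VIFs.
#' @export
compute_vif <- function(design) {
  X <- as.matrix(as.data.frame(design))
  if (ncol(X) < 2) stop("need at least 2 predictors to compute VIFs")
  vif <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    y <- X[, j]
    if (stats::var(y) == 0) { vif[j] <- 1; next }
    others <- X[, -j, drop = FALSE]
    # summary() warns on perfect fits; perfect collinearity is expected input here
    r2 <- suppressWarnings(summary(stats::lm(y ~ others))$r.squared)
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  vif
}

#' Iterative VIF screen
#'
#' Repeatedly drops the predictor with the largest VIF above the threshold
#' (ties, including ties at Inf from perfect collinearity, drop the
#' later-listed predictor first) and recomputes, until all remaining VIFs
#' are at or below the threshold or only one predictor remains.
#'
#' @param design Predictors matrix/data.frame.
#' @param threshold VIF threshold (default 5).
#' @return List with `kept` (column names), `dropped` (in drop order) and
#'   `vif` (final VIFs of the kept predictors).
#' @export
vif_screen <- function(design, threshold = 5) {
  X <- as.data.frame(design)
  dropped <- character(0)
  repeat {
    if (ncol(X) < 2) {
      return(list(kept = colnames(X), dropped = dropped,
                  vif = stats::setNames(rep(1, ncol(X)), colnames(X))))
    }
    v <- compute_vif(X)
    if (all(v <= threshold)) return(list(kept = colnames(X), dropped = dropped, vif = v))
    worst <- max(which(v == max(v)))   # later-listed dropped first on ties
    dropped <- c(dropped, colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
}

.assoc_ci_label <- function(b, lo, hi) sprintf("%.3f [%.3f, %.3f]", b, lo, hi)

#' Multivariate linear imaging-clinical association
#'
#' @param data data.frame holding outcome, features and covariates.
#' @param outcome Name of the continuous outcome column.
#' @param features Character vector of imaging-feature column names.
#' @param covariates Covariate column names (default sex, age, education,
#'   tiv).
#' @param vif_threshold VIF exclusion threshold (default 5).
#' @return Object of class `association_model`: list with `kind`
#'   (`"linear"`), `outcome`, `features` (features surviving the VIF
#'   screen), `coefficients` (data.frame `term`, `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `p`), `vif`, `dropped`, `residual_normality_p`,
#'   `retained`, `significant_features`, `n`.
#' @export
fit_linear_association <- function(data, outcome, features,
                                   covariates = .default_covariates,
                                   vif_threshold = 5) {
  vars <- c(features, covariates)
  d <- stats::na.omit(data[, c(outcome, vars), drop = FALSE])
  if (stats::var(d[[outcome]]) == 0) stop("outcome '", outcome, "' is constant")
  if (nrow(d) <= length(vars) + 2) stop("too few observations for the design")
  scr <- vif_screen(d[, vars, drop = FALSE], threshold = vif_threshold)
  kept <- scr$kept
  X <- as.matrix(d[, kept, drop = FALSE])
  fit <- stats::lm(d[[outcome]] ~ X)
  sm <- summary(fit)
  cf <- sm$coefficients
  rownames(cf) <- sub("^X", "", rownames(cf))
  df <- fit$df.residual
  tq <- stats::qt(0.975, df)
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      ci_lo = cf[, 1] - tq * cf[, 2],
                      ci_hi = cf[, 1] + tq * cf[, 2],
                      p = cf[, 4], row.names = NULL)
  res <- stats::residuals(fit)
  swp <- if (length(unique(round(res, 12))) >= 3 && length(res) >= 3 &&
             length(res) <= 5000) {
    tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA_real_)
  } else NA_real_
  feat_kept <- intersect(features, kept)
  sig <- coefs$term %in% feat_kept & coefs$p < 0.05
  retained <- isTRUE(!is.na(swp) && swp > 0.05) && any(sig)
  structure(list(kind = "linear", outcome = outcome, features = feat_kept,
                 coefficients = coefs, vif = scr$vif, dropped = scr$dropped,
                 residual_normality_p = swp, retained = retained,
                 significant_features = coefs$term[sig], n = nrow(d)),
            class = "association_model")
}

#' Multivariate logistic imaging-clinical association
#'
#' Maximum-likelihood logistic fit. Reports Wald chi-square
#' `(coef/SE)^2`, odds ratios and Wald 95% CIs `exp(coef +/- 1.96 SE)`.
#' Non-convergence or (quasi-)complete separation flags the model as not
#' retained.
#'
#' @inheritParams fit_linear_association
#' @param outcome Name of the binary (0/1) outcome column.
#' @return An `association_model` with `kind = "logistic"` and columns
#'   `wald`, `or`, `or_lo`, `or_hi` added to `coefficients`, plus a
#'   `separation` flag.
#' @export
fit_logistic_association <- function(data, outcome, features,
                                     covariates = .default_covariates,
                                     vif_threshold = 5) {
  vars <- c(features, covariates)
  d <- stats::na.omit(data[, c(outcome, vars), drop = FALSE])
  y <- d[[outcome]]
  if (length(unique(y)) != 2) stop("outcome '", outcome, "' is not binary in the data")
  if (min(table(y)) < 5) {
    warning("fewer than 5 observations in one outcome class of '", outcome, "'")
  }
  scr <- vif_screen(d[, vars, drop = FALSE], threshold = vif_threshold)
  kept <- scr$kept
  X <- as.matrix(d[, kept, drop = FALSE])
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ X, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  rownames(cf) <- sub("^X", "", rownames(cf))
  separation <- warned || !fit$converged || any(abs(cf[, 1]) > 15) ||
    any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      wald = (cf[, 1] / cf[, 2])^2,
                      or = exp(cf[, 1]),
                      or_lo = exp(cf[, 1] - 1.96 * cf[, 2]),
                      or_hi = exp(cf[, 1] + 1.96 * cf[, 2]),
                      p = cf[, 4], row.names = NULL)
  feat_kept <- intersect(features, kept)
  sig <- coefs$term %in% feat_kept & coefs$p < 0.05
  retained <- !separation && any(sig)
  structure(list(kind = "logistic", outcome = outcome, features = feat_kept,
                 coefficients = coefs, vif = scr$vif, dropped = scr$dropped,
                 separation = separation, retained = retained,
                 significant_features = coefs$term[sig], n = nrow(d)),
            class = "association_model")
}

#' @export
print.association_model <- function(x, ...) {
  cat("<association_model> ", x$kind, " : ", x$outcome, " ~ ",
      paste(x$features, collapse = " + "), " + covariates; ",
      if (x$retained) "retained" else "not retained", "\n", sep = "")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Run the full imaging-clinical association battery
#'
#' Fits, for every clinical outcome, (a) a model with the subtype
#' indicator as the imaging feature and (b) a model entering the selected
#' differential edges jointly (when any are supplied). Continuous outcomes
#' go through linear regression, binary ones through logistic regression.
#' Only retained models are returned; every attempted model is listed in
#' the audit log with the reason it was or was not retained.
#'
#' Codings: subtype indicator 0 = subtype 1, 1 = subtype 2; sex 0 =
#' female, 1 = male.
#'
#' @param clinical data.frame of per-patient clinical variables plus the
#'   covariates (one row per patient).
#' @param labels Subtype labels (two levels) aligned with `clinical` rows.
#' @param edge_features Optional patients x E matrix of the differential
#'   edges' Z values (aligned rows); `NULL` to skip edge models.
#' @param outcomes Named character vector mapping outcome column names to
#'   `"continuous"` or `"binary"`.
#' @param covariates Covariate column names.
#' @return List with `models` (retained `association_model`s) and `audit`
#'   (data.frame: `outcome`, `feature_set`, `kind`, `retained`, `reason`).
#' @export
run_association_battery <- function(clinical, labels, edge_features = NULL,
                                    outcomes = c(headache_freq = "continuous",
                                                 headache_occurrence = "binary"),
                                    covariates = .default_covariates) {
  lv <- sort(unique(labels))
  d <- as.data.frame(clinical)
  feature_sets <- list()
  if (length(lv) == 2) {
    d$subtype <- as.numeric(labels == lv[2])
    feature_sets$subtype <- "subtype"
  }
  if (!is.null(edge_features) && ncol(edge_features) > 0) {
    ef <- as.data.frame(edge_features)
    names(ef) <- make.names(colnames(edge_features))
    d <- cbind(d, ef)
    feature_sets$edges <- names(ef)
  }
  models <- list()
  audit <- NULL
  for (oc in names(outcomes)) {
    for (fs in names(feature_sets)) {
      kind <- if (outcomes[[oc]] == "binary") "logistic" else "linear"
      m <- tryCatch({
        if (kind == "linear") {
          fit_linear_association(d, oc, feature_sets[[fs]], covariates)
        } else {
          fit_logistic_association(d, oc, feature_sets[[fs]], covariates)
        }
      }, error = function(e) e)
      if (inherits(m, "error")) {
        reason <- paste("error:", conditionMessage(m))
        retained <- FALSE
      } else if (m$retained) {
        reason <- paste("significant:",
                        paste(m$significant_features, collapse = ","))
        retained <- TRUE
        models[[paste(oc, fs, sep = ".")]] <- m
      } else {
        retained <- FALSE
        reason <- if (kind == "linear" &&
                      (is.na(m$residual_normality_p) ||
                       m$residual_normality_p <= 0.05)) {
          "non-normal residuals"
        } else if (kind == "logistic" && isTRUE(m$separation)) {
          "separation or non-convergence"
        } else "no significant imaging feature"
      }
      audit <- rbind(audit, data.frame(outcome = oc, feature_set = fs,
                                       kind = kind, retained = retained,
                                       reason = reason))
    }
  }
  list(models = models, audit = audit)
}
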