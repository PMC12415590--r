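#' Individualized differential structural covariance networks
#'
#' The core construction. A reference structural covariance network (SCN)
#' is the matrix of pairwise partial correlations of regional gray-matter
#' density across control subjects, adjusting for sex, age, education and
#' total intracranial volume (partial correlation = Pearson correlation of
#' the covariate-residualized region columns). Appending a single patient
#' row to the control table and recomputing the network gives that
#' patient's perturbed SCN. The patient's individualized differential
#' network is the edge-wise Z-score of the perturbation:
#' \deqn{Z_{ij} = \frac{pSCN_{ij} - rSCN_{ij}}{(1 - rSCN_{ij}^2)/(n - 1)}}
#' where \eqn{n} is the number of controls. Two-tailed p-values are taken
#' from the standard normal and edges selected per patient by
#' Benjamini-Hochberg FDR over the full edge universe.
#'
#' @name idscn-core
NULL

.default_covariates <- c("sex", "age", "education", "tiv")

#' Residualize a matrix on covariates
#'
#' Replaces every column of `y` by its residuals from a least-squares
#' regression on an intercept plus the covariate columns. Zero-variance
#' covariates are dropped (residualizing then reduces to mean-centering
#' when no covariate remains informative). A rank-deficient covariate
#' design is an error naming the collinear columns.
#'
#' @param y Numeric matrix (subjects x variables).
#' @param covariates Numeric matrix or data.frame (subjects x covariates).
#' @return Matrix of residuals, same shape as `y`.
#' @export
residualize <- function(y, covariates) {
  y <- as.matrix(y)
  x <- as.matrix(covariates)
  if (anyNA(y) || anyNA(x)) stop("missing values are not allowed")
  if (nrow(x) != nrow(y)) stop("row mismatch between y and covariates")
  keep <- apply(x, 2, function(v) stats::var(v) > 0)
  x <- x[, keep, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, x)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear covariates: ", paste(dropped, collapse = ", "))
  }
  qr.resid(qrX, y)
}

#' Build the reference SCN from control subjects
#'
#' @param density Controls x regions matrix of gray-matter density.
#' @param covariates data.frame/matrix with the adjustment covariates
#'   (columns `covariate_names`) for the same subjects.
#' @param covariate_names Covariates to adjust for (default sex, age,
#'   education, tiv).
#' @return Object of class `reference_scn`: list with `r` (regions x
#'   regions partial-correlation matrix, unit diagonal), `n` (number of
#'   control subjects) and `covariate_names`.
#' @export
build_reference_scn <- function(density, covariates,
                                covariate_names = .default_covariates) {
  density <- as.matrix(density)
  miss <- setdiff(covariate_names, colnames(covariates))
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  C <- as.matrix(as.data.frame(covariates)[, covariate_names, drop = FALSE])
  n <- nrow(density)
  if (n < length(covariate_names) + 3) {
    stop("need at least ", length(covariate_names) + 3, " control subjects")
  }
  sds <- apply(density, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region column(s): ",
         paste(colnames(density)[sds == 0], collapse = ", "))
  }
  res <- residualize(density, C)
  r <- stats::cor(res)
  diag(r) <- 1
  structure(list(r = r, n = n, covariate_names = covariate_names),
            class = "reference_scn")
}

#' @export
print.reference_scn <- function(x, ...) {
  cat("<reference_scn> ", nrow(x$r), " regions, n = ", x$n,
      ", adjusted for: ", paste(x$covariate_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build the perturbed SCN for one patient
#'
#' Stacks the patient's density row (and covariates) onto the control table
#' and recomputes the partial-correlation network with the identical
#' adjustment; the patient's covariates enter the (n+1)-subject regression.
#'
#' @param density,covariates Control table as in [build_reference_scn()].
#' @param patient_density Numeric vector (one row) of the patient's
#'   regional densities, same region order.
#' @param patient_covariates One-row data.frame with the covariates.
#' @param covariate_names Covariates to adjust for.
#' @return Regions x regions matrix (same shape as the reference `r`).
#' @export
build_perturbed_scn <- function(density, covariates, patient_density,
                                patient_covariates,
                                covariate_names = .default_covariates) {
  density <- as.matrix(density)
  pd <- as.numeric(patient_density)
  if (length(pd) != ncol(density)) stop("patient row has wrong number of regions")
  C <- as.data.frame(covariates)[, covariate_names, drop = FALSE]
  pc <- as.data.frame(patient_covariates)[, covariate_names, drop = FALSE]
  scn <- build_reference_scn(rbind(density, pd),
                             rbind(C, pc), covariate_names)
  scn$r
}

#' Z-score a patient's network perturbation
#'
#' Computes the patient's individualized differential network from the
#' reference and perturbed SCNs. The default denominator is the sampling
#' variance `(1 - r^2)/(n - 1)` of a correlation around `r` at sample size
#' `n`; `denominator = "sd"` selects the square-root variant for
#' sensitivity analysis. Edges where `|r| = 1` carry no perturbation
#' information; their Z is set to 0 with a warning.
#'
#' @param rscn A `reference_scn`.
#' @param pscn Perturbed SCN matrix from [build_perturbed_scn()].
#' @param patient_id Identifier carried through to outputs.
#' @param denominator `"variance"` (default) or `"sd"`.
#' @return Object of class `patient_idscn`: list with `patient_id`, `z`
#'   (symmetric, zero diagonal), `p` (two-tailed normal p-values), `n`
#'   (control count), plus `sig_mask`/`n_sig_edges` once
#'   [select_significant_edges()] has run.
#' @export
compute_idscn <- function(rscn, pscn, patient_id = "patient",
                          denominator = c("variance", "sd")) {
  stopifnot(inherits(rscn, "reference_scn"))
  denominator <- match.arg(denominator)
  r <- rscn$r
  if (!all(dim(pscn) == dim(r))) stop("pSCN and rSCN shapes differ")
  n <- rscn$n
  delta <- pscn - r
  degen <- abs(r) >= 1 - 1e-15
  diag(degen) <- FALSE
  den <- (1 - r^2) / (n - 1)
  if (denominator == "sd") den <- sqrt(den)
  z <- delta / den
  if (any(degen)) {
    warning(sum(degen) / 2, " edge(s) with |r| = 1 carry no information; Z set to 0")
    z[degen] <- 0
  }
  diag(z) <- 0
  z <- (z + t(z)) / 2   # guard against asymmetric floating-point noise
  p <- 2 * stats::pnorm(-abs(z))
  diag(p) <- 1
  structure(list(patient_id = patient_id, z = z, p = p, n = n,
                 sig_mask = NULL, n_sig_edges = NA_integer_),
            class = "patient_idscn")
}

#' @export
print.patient_idscn <- function(x, ...) {
  cat("<patient_idscn> ", x$patient_id, ": ", nrow(x$z), " regions",
      if (!is.na(x$n_sig_edges)) paste0(", ", x$n_sig_edges, " FDR-significant edges"),
      "\n", sep = "")
  invisible(x)
}

#' Select a patient's significantly altered edges by FDR
#'
#' Benjamini-Hochberg step-up over the patient's full set of unique edges
#' (each patient corrected separately).
#'
#' @param idscn A `patient_idscn`.
#' @param q FDR level (default 0.05).
#' @return The `patient_idscn` with `sig_mask` (symmetric logical matrix)
#'   and `n_sig_edges` filled in.
#' @export
select_significant_edges <- function(idscn, q = 0.05) {
  stopifnot(inherits(idscn, "patient_idscn"), q > 0, q < 1)
  pvec <- flatten_edges(idscn$p)
  padj <- stats::p.adjust(pvec, method = "BH")
  sig <- padj <= q
  idscn$sig_mask <- unflatten_edges(sig, diag = 0) > 0
  idscn$p_fdr <- unflatten_edges(padj, diag = 1)
  idscn$n_sig_edges <- sum(sig)
  idscn$q <- q
  idscn
}

#' Build IDSCNs for every patient in a cohort
#'
#' Convenience driver: builds the reference SCN from the cohort's controls,
#' then for each patient the perturbed SCN, Z matrix and FDR edge
#' selection.
#'
#' @param cohort An `idscn_cohort`.
#' @param q FDR level.
#' @param covariate_names Adjustment covariates.
#' @param denominator Passed to [compute_idscn()].
#' @return List with `rscn` and `idscns` (named list of `patient_idscn`).
#' @export
build_cohort_idscns <- function(cohort, q = 0.05,
                                covariate_names = .default_covariates,
                                denominator = "variance") {
  ctl <- cohort_controls(cohort)
  pat <- cohort_patients(cohort)
  rscn <- build_reference_scn(ctl$density, ctl$covariates, covariate_names)
  ids <- rownames(pat$density)
  idscns <- vector("list", length(ids))
  names(idscns) <- ids
  for (k in seq_along(ids)) {
    pscn <- build_perturbed_scn(ctl$density, ctl$covariates,
                                pat$density[k, ], pat$covariates[k, ],
                                covariate_names)
    net <- compute_idscn(rscn, pscn, patient_id = ids[k],
                         denominator = denominator)
    idscns[[k]] <- select_significant_edges(net, q = q)
  }
  list(rscn = rscn, idscns = idscns)
}

#' Per-patient counts of significantly altered edges
#'
#' @param idscns List of `patient_idscn` with edge selection applied.
#' @return List with `counts` (named integer vector), `mean` and `sd`
#'   (sample SD, n-1 denominator; 0 for a single patient).
#' @export
cohort_heterogeneity_summary <- function(idscns) {
  if (length(idscns) == 0) stop("no patients supplied")
  counts <- vapply(idscns, function(x) {
    if (is.na(x$n_sig_edges)) stop("run select_significant_edges() first")
    x$n_sig_edges
  }, integer(1))
  list(counts = counts, mean = mean(counts),
       sd = if (length(counts) > 1) stats::sd(counts) else 0)
}

#' Export one patient's IDSCN as a flat edge table
#'
#' @param idscn A `patient_idscn` after edge selection.
#' @param atlas Optional `region_atlas` for region names.
#' @return data.frame in canonical edge order: `region_i`, `region_j`,
#'   `z`, `p`, `p_fdr`, `significant`.
#' @export
idscn_edge_table <- function(idscn, atlas = NULL) {
  e <- edge_universe(nrow(idscn$z))
  out <- data.frame(
    region_i = if (is.null(atlas)) e$i else atlas$regions$name[e$i],
    region_j = if (is.null(atlas)) e$j else atlas$regions$name[e$j],
    z = flatten_edges(idscn$z),
    p = flatten_edges(idscn$p),
    p_fdr = if (is.null(idscn$p_fdr)) NA_real_ else flatten_edges(idscn$p_fdr),
    significant = if (is.null(idscn$sig_mask)) NA else flatten_edges(idscn$sig_mask) > 0
  )
  out
}
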