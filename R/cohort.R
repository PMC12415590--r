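#' Synthetic cohort generation
#'
#' Generates a control cohort and a patient cohort of regional gray-matter
#' density values with a known ("planted") structure, so that every stage of
#' the pipeline can be validated against ground truth. Controls are drawn
#' from a multivariate normal with a shared base correlation structure plus
#' additive linear covariate effects (sex, age, education, total
#' intracranial volume) plus regional noise. Each patient is drawn from the
#' covariance of its planted subtype: the base correlation matrix with a
#' signed perturbation added to a specified edge set, repaired to the
#' nearest positive semi-definite correlation matrix when needed. Clinical
#' variables are tied to the subtype label by a shifted-mean (continuous)
#' or shifted-log-odds (binary) model, giving the association stage a
#' recoverable signal.
#'
#' @name synthetic-cohort
NULL

#' Default planted-subtype specification
#'
#' Two subtypes with fractions 19/55 and 36/55, perturbing a shared set of
#' 40 edges (a bipartite block between regions 1..5 and 6..13) with
#' opposite-signed perturbations: subtype 1 gets `+delta` on the first 20
#' edges and `-delta` on the last 20; subtype 2 the reverse. The shared
#' edge set with opposite directions mirrors the two directional classes of
#' differential edges that this kind of analysis reports, and is the
#' configuration under which between-subtype contrasts are largest for a
#' given `|delta|`.
#'
#' @param delta Perturbation magnitude on the correlation scale.
#' @param n_regions Number of regions (needs >= 13 for the default block).
#' @return List of per-subtype specs, each with `fraction`, `edges`
#'   (data.frame `i`,`j`) and `delta` (signed, recycled over edges).
#' @export
default_subtype_spec <- function(delta = 0.3, n_regions = 116) {
  if (n_regions < 13) stop("default subtype spec needs >= 13 regions")
  edges <- expand.grid(i = 1:5, j = 6:13)
  edges <- edges[order(edges$i, edges$j), c("i", "j")]
  rownames(edges) <- NULL
  sign1 <- rep(c(1, -1), each = 20)
  list(
    list(fraction = 19 / 55, edges = edges, delta = delta * sign1),
    list(fraction = 36 / 55, edges = edges, delta = -delta * sign1)
  )
}

#' Simulation configuration
#'
#' Assembles and validates the configuration for [simulate_cohort()].
#' Defaults emulate the study design the package targets: 65 controls, 55
#' patients, 116 regions, four covariates, and two planted subtypes with
#' opposite-signed correlation perturbations of magnitude 0.3 on a shared
#' 40-edge set.
#'
#' @param n_controls,n_patients,n_regions Cohort dimensions.
#' @param seed Integer seed; every random element of the simulation flows
#'   from it.
#' @param base_correlation Either `NULL` (a random correlation matrix is
#'   generated: eigenvectors from the QR decomposition of a Gaussian
#'   matrix, eigenvalues i.i.d. Exponential(1), rescaled to unit diagonal)
#'   or a user-supplied correlation matrix.
#' @param covariate_effects Either `NULL` (per-region loadings drawn once
#'   from documented normal distributions; see Details) or a named list of
#'   numeric vectors of length `n_regions` for `sex`, `age`, `education`,
#'   `tiv`.
#' @param subtype_spec List of planted subtypes as in
#'   [default_subtype_spec()]; fractions must sum to 1. Use a single
#'   subtype with `delta = 0` for a null (exchangeable) patient cohort.
#' @param noise_sd Regional standard deviation of the density values around
#'   their mean structure (unitless density scale).
#' @param clinical_spec List controlling the subtype-linked clinical
#'   variables: `freq_base`, `freq_shift` (additive mean shift for subtype
#'   2, days/month), `freq_sd`, `occ_intercept`, `occ_slope` (log-odds
#'   shift for subtype 2).
#' @details Default covariate loadings per region: age ~ N(-0.0015, 5e-4)
#'   per year, sex ~ N(0.01, 0.01), education ~ N(8e-4, 4e-4) per year,
#'   TIV ~ N(6e-5, 3e-5) per ml — each covariate then accounts for roughly
#'   5-10\% of regional variance, a realistic share for demographic drivers
#'   of gray-matter density.
#' @return A validated list of class `idscn_sim_config`.
#' @export
sim_config <- function(n_controls = 65, n_patients = 55, n_regions = 116,
                       seed = 1,
                       base_correlation = NULL,
                       covariate_effects = NULL,
                       subtype_spec = default_subtype_spec(0.3, n_regions),
                       noise_sd = 0.05,
                       clinical_spec = list(freq_base = 3.2, freq_shift = -1.5,
                                            freq_sd = 2.0, occ_intercept = 0.5,
                                            occ_slope = 1.2)) {
  stopifnot(n_controls >= 8, n_patients >= 1, n_regions >= 2, noise_sd > 0)
  fr <- vapply(subtype_spec, function(s) s$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8) stop("subtype fractions must sum to 1")
  for (s in subtype_spec) {
    if (any(s$edges$i >= s$edges$j) || any(s$edges$j > n_regions)) {
      stop("subtype edges must satisfy i < j <= n_regions")
    }
  }
  if (!is.null(base_correlation)) {
    stopifnot(is.matrix(base_correlation),
              nrow(base_correlation) == n_regions,
              isTRUE(all.equal(base_correlation, t(base_correlation))),
              all(abs(diag(base_correlation) - 1) < 1e-12))
  }
  structure(list(n_controls = n_controls, n_patients = n_patients,
                 n_regions = n_regions, seed = as.integer(seed),
                 base_correlation = base_correlation,
                 covariate_effects = covariate_effects,
                 subtype_spec = subtype_spec, noise_sd = noise_sd,
                 clinical_spec = clinical_spec),
            class = "idscn_sim_config")
}

#' Random correlation matrix (random eigenstructure recipe)
#'
#' Eigenvectors are the Q factor of a standard Gaussian matrix; eigenvalues
#' are i.i.d. Exponential(1); the resulting covariance is rescaled to unit
#' diagonal. Uses the current RNG state.
#'
#' @param p Dimension.
#' @return p x p correlation matrix.
#' @export
random_correlation <- function(p) {
  Q <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
  lam <- stats::rexp(p)
  S <- Q %*% (lam * t(Q))
  stats::cov2cor((S + t(S)) / 2)
}

#' Apply a planted edge perturbation to a correlation matrix, with PSD repair
#'
#' Adds signed `delta` values to the specified edges of `r`. Errors if any
#' perturbed correlation leaves (-1, 1). If the perturbed matrix is not
#' positive semi-definite, negative eigenvalues are clipped to a small
#' positive floor and the matrix rescaled to unit diagonal; this shrinks the
#' planted perturbation slightly (the realised edge change is returned in
#' the attribute `realised_delta`).
#'
#' @param r Correlation matrix.
#' @param edges data.frame `i`,`j`.
#' @param delta Signed perturbation(s), recycled over edges.
#' @param floor Eigenvalue floor used in the repair.
#' @return Perturbed (repaired) correlation matrix.
#' @export
perturb_correlation <- function(r, edges, delta, floor = 1e-4) {
  delta <- rep_len(delta, nrow(edges))
  idx <- cbind(edges$i, edges$j)
  newr <- r[idx] + delta
  if (any(abs(newr) >= 1)) {
    bad <- which(abs(newr) >= 1)[1]
    stop(sprintf("infeasible perturbation: edge (%d,%d) would have correlation %.3f",
                 edges$i[bad], edges$j[bad], newr[bad]))
  }
  out <- r
  out[idx] <- newr
  out[idx[, 2:1, drop = FALSE]] <- newr
  ev <- eigen(out, symmetric = TRUE)
  if (min(ev$values) < floor) {
    vals <- pmax(ev$values, floor)
    out <- ev$vectors %*% (vals * t(ev$vectors))
    out <- stats::cov2cor((out + t(out)) / 2)
  }
  attr(out, "realised_delta") <- out[idx] - r[idx]
  out
}

#' Simulate a cohort of controls and patients with planted subtypes
#'
#' @param config A configuration from [sim_config()].
#' @return An object of class `idscn_cohort`: a list with
#'   \describe{
#'     \item{density}{subjects x regions matrix, subject IDs as rownames,
#'       region names `R001..` as colnames.}
#'     \item{covariates}{data.frame keyed by `subject_id` with `group`
#'       (`"control"`/`"patient"`), `sex` (0 female / 1 male), `age`
#'       (years), `education` (years), `tiv` (ml), and clinical columns
#'       `headache_freq` (days/month), `headache_occurrence` (0/1),
#'       `migraine_duration`, `vertigo_duration` (years), `dhi_score`
#'       (patients only; NA for controls).}
#'     \item{truth}{list: `subtype` (integer per patient, named),
#'       `subtype_spec`, `base_correlation`, `subtype_correlations`,
#'       `covariate_effects`, `config`.}
#'   }
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "idscn_sim_config"))
  set.seed(config$seed)
  p <- config$n_regions
  n_c <- config$n_controls
  n_p <- config$n_patients

  base <- config$base_correlation
  if (is.null(base)) base <- random_correlation(p)

  eff <- config$covariate_effects
  if (is.null(eff)) {
    eff <- list(sex = stats::rnorm(p, 0.01, 0.01),
                age = stats::rnorm(p, -0.0015, 5e-4),
                education = stats::rnorm(p, 8e-4, 4e-4),
                tiv = stats::rnorm(p, 6e-5, 3e-5))
  }
  stopifnot(all(c("sex", "age", "education", "tiv") %in% names(eff)))

  # per-subtype covariances (validated before any subject is drawn)
  sub_cors <- lapply(config$subtype_spec, function(s) {
    perturb_correlation(base, s$edges, s$delta)
  })

  n_tot <- n_c + n_p
  sex <- stats::rbinom(n_tot, 1, 0.15)
  age <- stats::rnorm(n_tot, 47, 12)
  education <- pmax(stats::rnorm(n_tot, 11, 4.8), 0)
  tiv <- stats::rnorm(n_tot, 1450, 120)
  group <- rep(c("control", "patient"), c(n_c, n_p))
  id <- sprintf("S%03d", seq_len(n_tot))

  # subtype assignment: deterministic counts from the fractions (largest
  # remainder), then a seeded shuffle across patients
  fr <- vapply(config$subtype_spec, function(s) s$fraction, numeric(1))
  cnt <- floor(fr * n_p)
  rem <- n_p - sum(cnt)
  if (rem > 0) {
    extra <- order(fr * n_p - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  subtype <- sample(rep.int(seq_along(fr), cnt))

  region_mean <- 0.45 + stats::rnorm(p, 0, 0.05)
  covmat <- cbind(sex = sex, age = age, education = education, tiv = tiv)
  mean_struct <- matrix(region_mean, n_tot, p, byrow = TRUE) +
    covmat %*% rbind(eff$sex, eff$age, eff$education, eff$tiv)

  noise <- matrix(NA_real_, n_tot, p)
  noise[seq_len(n_c), ] <- MASS::mvrnorm(n_c, rep(0, p), base)
  for (s in seq_along(fr)) {
    rows <- n_c + which(subtype == s)
    if (length(rows)) {
      noise[rows, ] <- MASS::mvrnorm(length(rows), rep(0, p), sub_cors[[s]])
    }
  }
  density <- mean_struct + config$noise_sd * noise
  dimnames(density) <- list(id, sprintf("R%03d", seq_len(p)))

  # clinical variables: shifted-mean / shifted-log-odds models in subtype
  cs <- config$clinical_spec
  is2 <- as.numeric(subtype == 2)
  if (length(fr) < 2) is2 <- rep(0, n_p)
  headache_freq <- rep(NA_real_, n_tot)
  headache_freq[group == "patient"] <-
    cs$freq_base + cs$freq_shift * is2 + stats::rnorm(n_p, 0, cs$freq_sd)
  headache_occ <- rep(NA_real_, n_tot)
  headache_occ[group == "patient"] <-
    stats::rbinom(n_p, 1, stats::plogis(cs$occ_intercept + cs$occ_slope * is2))
  migraine_dur <- rep(NA_real_, n_tot)
  migraine_dur[group == "patient"] <- stats::rlnorm(n_p, log(8), 0.9)
  vertigo_dur <- rep(NA_real_, n_tot)
  vertigo_dur[group == "patient"] <- stats::rlnorm(n_p, log(4.5), 1.0)
  dhi <- rep(NA_real_, n_tot)
  dhi[group == "patient"] <- stats::rnorm(n_p, 53, 16)

  covariates <- data.frame(
    subject_id = id, group = group, sex = sex, age = age,
    education = education, tiv = tiv,
    headache_freq = headache_freq, headache_occurrence = headache_occ,
    migraine_duration = migraine_dur, vertigo_duration = vertigo_dur,
    dhi_score = dhi, stringsAsFactors = FALSE
  )
  names(subtype) <- id[group == "patient"]

  structure(list(
    density = density,
    covariates = covariates,
    truth = list(subtype = subtype, subtype_spec = config$subtype_spec,
                 base_correlation = base, subtype_correlations = sub_cors,
                 covariate_effects = eff, config = config)
  ), class = "idscn_cohort")
}

#' @export
print.idscn_cohort <- function(x, ...) {
  cat("<idscn_cohort> ", sum(x$covariates$group == "control"), " controls, ",
      sum(x$covariates$group == "patient"), " patients, ",
      ncol(x$density), " regions\n", sep = "")
  invisible(x)
}

# full-precision numeric formatting so CSV round-trips are exact
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits `density.csv` (first column `subject_id`, then one column per
#' region), `covariates.csv`, and `truth.json` (subtype labels and the
#' planted edge lists). Numeric values are written with 17 significant
#' digits so [read_cohort()] round-trips exactly.
#'
#' @param cohort An `idscn_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "idscn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dens_path <- file.path(dir, "density.csv")
  dens <- cohort$density
  df <- data.frame(subject_id = rownames(dens),
                   apply(dens, 2, .fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, dens_path, row.names = FALSE, quote = FALSE)

  cov_path <- file.path(dir, "covariates.csv")
  cv <- cohort$covariates
  num <- vapply(cv, is.numeric, logical(1))
  cv[num] <- lapply(cv[num], .fmt_num)
  utils::write.csv(cv, cov_path, row.names = FALSE, quote = FALSE)

  truth_path <- file.path(dir, "truth.json")
  truth <- list(
    subtype = as.list(cohort$truth$subtype),
    subtype_spec = lapply(cohort$truth$subtype_spec, function(s) {
      list(fraction = s$fraction, delta = s$delta,
           edges = lapply(seq_len(nrow(s$edges)),
                          function(k) c(s$edges$i[k], s$edges$j[k])))
    })
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(density = dens_path, covariates = cov_path, truth = truth_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `density.csv` and `covariates.csv`
#'   (and optionally `truth.json`).
#' @return An `idscn_cohort` (with `truth` restricted to what the truth
#'   file records, or `NULL` if absent).
#' @export
read_cohort <- function(dir) {
  dens <- utils::read.csv(file.path(dir, "density.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  density <- as.matrix(dens[, -1, drop = FALSE])
  rownames(density) <- dens$subject_id
  covariates <- utils::read.csv(file.path(dir, "covariates.csv"),
                                stringsAsFactors = FALSE)
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) {
    tj <- jsonlite::read_json(tp)
    subtype <- unlist(tj$subtype)
    spec <- lapply(tj$subtype_spec, function(s) {
      em <- do.call(rbind, lapply(s$edges, unlist))
      list(fraction = s$fraction, delta = unlist(s$delta),
           edges = data.frame(i = em[, 1], j = em[, 2]))
    })
    truth <- list(subtype = subtype, subtype_spec = spec)
  }
  structure(list(density = density, covariates = covariates, truth = truth),
            class = "idscn_cohort")
}

# split helpers used throughout the pipeline
cohort_controls <- function(cohort) {
  keep <- cohort$covariates$group == "control"
  list(density = cohort$density[keep, , drop = FALSE],
       covariates = cohort$covariates[keep, , drop = FALSE])
}

cohort_patients <- function(cohort) {
  keep <- cohort$covariates$group == "patient"
  list(density = cohort$density[keep, , drop = FALSE],
       covariates = cohort$covariates[keep, , drop = FALSE])
}
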