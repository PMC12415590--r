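#' Full-pipeline orchestration
#'
#' [run_full_pipeline()] drives the analysis end to end from input files
#' (or an in-memory cohort) to a run directory of delimited-text and JSON
#' artifacts: reference network, per-patient differential networks, edge
#' ranking, subtyping, stability, inter-subtype comparisons (parametric
#' and permutation), subgroup analyses, the association battery, and a
#' manifest with a content hash of every file. All randomness flows from
#' the single configured seed through named per-stage substreams, so
#' re-running a config reproduces identical outputs.
#'
#' @name pipeline
NULL

#' Derive a per-stage seed from the run seed
#'
#' Deterministic substreams: the stage name is hashed onto 0..9999 and
#' combined with the run seed modulo 2^31 - 1.
#' @param seed Run seed (integer).
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% (2^31 - 1))
}

#' Pipeline run configuration
#'
#' @param atlas_path,density_path,covariates_path Input files (`NULL` when
#'   a cohort object is passed to [run_full_pipeline()] directly).
#' @param out_dir Output directory.
#' @param q FDR level for per-patient edge selection and group tests.
#' @param top_K Feature-edge count for subtyping.
#' @param K_list Feature counts for the stability analysis.
#' @param k_grid Candidate cluster numbers.
#' @param n_repeats k-means restarts per k.
#' @param B Permutation iterations for the validation test.
#' @param seed Run seed.
#' @param denominator Z denominator variant (`"variance"` or `"sd"`).
#' @param feature_value Feature mode for clustering (`"z"`, `"abs_z"`,
#'   `"sig"`).
#' @return List of class `idscn_run_config`.
#' @export
run_config <- function(atlas_path = NULL, density_path = NULL,
                       covariates_path = NULL, out_dir = "idscn_run",
                       q = 0.05, top_K = 80, K_list = c(60, 70, 80, 90),
                       k_grid = 2:20, n_repeats = 100, B = 10000, seed = 1,
                       denominator = "variance", feature_value = "z") {
  stopifnot(q > 0, q < 1, top_K > 0, all(K_list > 0), all(k_grid >= 2),
            n_repeats > 0, B > 0)
  structure(as.list(environment()), class = "idscn_run_config")
}

.write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' @param config An `idscn_run_config`.
#' @param cohort Optional `idscn_cohort`; when `NULL` the cohort is read
#'   from the configured density/covariates paths.
#' @param atlas Optional `region_atlas`; when `NULL` and `atlas_path` is
#'   set, loaded from file; otherwise region indices are used as names.
#' @return Invisibly, a list with the in-memory stage results
#'   (`rscn`, `idscns`, `ranking`, `subtypes`, `stability`, `comparison`,
#'   `permutation`, `subgroups`, `associations`, `manifest`); artifacts
#'   under `config$out_dir`.
#' @export
run_full_pipeline <- function(config, cohort = NULL, atlas = NULL) {
  stopifnot(inherits(config, "idscn_run_config"))
  t0 <- Sys.time()
  if (is.null(cohort)) {
    if (is.null(config$density_path) || is.null(config$covariates_path)) {
      stop("stage load: no cohort given and no density/covariates paths configured")
    }
    cohort <- read_cohort(dirname(config$density_path))
  }
  need <- c("subject_id", "group", .default_covariates)
  miss <- setdiff(need, names(cohort$covariates))
  if (length(miss)) stop("stage load: missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(config$atlas_path) && is.null(atlas)) {
    atlas <- load_atlas(config$atlas_path)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("idscn", "subtypes", "comparisons", "associations")) {
    dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  }
  files <- character(0)

  # reference + per-patient networks
  built <- build_cohort_idscns(cohort, q = config$q,
                               denominator = config$denominator)
  rscn <- built$rscn
  idscns <- built$idscns
  files <- c(files, .write_table(
    data.frame(edge_universe(nrow(rscn$r)), r = flatten_edges(rscn$r)),
    file.path(config$out_dir, "idscn", "reference_scn.csv")))
  het <- cohort_heterogeneity_summary(idscns)
  files <- c(files, .write_table(
    data.frame(patient_id = names(het$counts), n_sig_edges = het$counts),
    file.path(config$out_dir, "idscn", "heterogeneity.csv")))

  # ranking, subtyping, stability
  ranking <- rank_edges(idscns)
  files <- c(files, .write_table(as.data.frame(ranking),
    file.path(config$out_dir, "subtypes", "edge_ranking.csv")))
  features <- build_feature_matrix(idscns, ranking, config$top_K,
                                   value = config$feature_value)
  subtypes <- cluster_patients(features, k_grid = config$k_grid,
                               n_repeats = config$n_repeats,
                               seed = stage_seed(config$seed, "cluster"))
  files <- c(files, .write_table(
    data.frame(patient_id = names(subtypes$labels), subtype = subtypes$labels),
    file.path(config$out_dir, "subtypes", "labels.csv")))
  files <- c(files, .write_table(subtypes$silhouette_by_k,
    file.path(config$out_dir, "subtypes", "silhouette_by_k.csv")))
  stability <- stability_analysis(idscns, K_list = config$K_list,
                                  k_grid = config$k_grid,
                                  n_repeats = config$n_repeats,
                                  seed = stage_seed(config$seed, "stability"),
                                  value = config$feature_value)
  files <- c(files, .write_table(stability$pairs,
    file.path(config$out_dir, "subtypes", "stability_ari.csv")))

  # inter-subtype comparisons
  pat <- cohort_patients(cohort)
  covs <- pat$covariates[, .default_covariates, drop = FALSE]
  comparison <- permutation <- NULL
  if (subtypes$chosen_k == 2 && min(table(subtypes$labels)) >= 3) {
    comparison <- compare_edges_between_subtypes(features, subtypes$labels,
                                                 covs, q = config$q)
    files <- c(files, .write_table(as.data.frame(comparison),
      file.path(config$out_dir, "comparisons", "subtype_edge_tests.csv")))
    permutation <- permutation_edge_test(features, subtypes$labels, covs,
                                         B = config$B,
                                         seed = stage_seed(config$seed, "perm"),
                                         q = config$q)
    files <- c(files, .write_table(as.data.frame(permutation),
      file.path(config$out_dir, "comparisons", "subtype_edge_perm.csv")))
  }

  # subgroup analyses
  subgroups <- NULL
  if (subtypes$chosen_k == 2) {
    splits <- c(sex = "binary")
    for (v in c("migraine_duration", "vertigo_duration")) {
      if (v %in% names(pat$covariates)) splits[v] <- "continuous"
    }
    if ("headache_occurrence" %in% names(pat$covariates)) {
      splits["headache_occurrence"] <- "binary"
    }
    subgroups <- withCallingHandlers(
      subgroup_analysis(features, subtypes$labels, pat$covariates, splits),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(subgroups)) {
      sg <- do.call(rbind, lapply(names(subgroups), function(v) {
        s <- subgroups[[v]]
        data.frame(split = v, n_sig_edges = s$n_sig_edges,
                   proportion_test = s$proportion_test$test,
                   proportion_p = s$proportion_test$p)
      }))
      files <- c(files, .write_table(sg,
        file.path(config$out_dir, "comparisons", "subgroups.csv")))
    }
  }

  # association battery
  associations <- NULL
  if (subtypes$chosen_k == 2 && !is.null(comparison)) {
    sig_edges <- which(comparison$significant)
    ef <- if (length(sig_edges)) features[, sig_edges, drop = FALSE] else NULL
    outcomes <- c()
    if ("headache_freq" %in% names(pat$covariates)) {
      outcomes["headache_freq"] <- "continuous"
    }
    if ("headache_occurrence" %in% names(pat$covariates)) {
      outcomes["headache_occurrence"] <- "binary"
    }
    if (length(outcomes)) {
      associations <- run_association_battery(pat$covariates, subtypes$labels,
                                              ef, outcomes = outcomes)
      files <- c(files, .write_table(associations$audit,
        file.path(config$out_dir, "associations", "audit.csv")))
      for (nm in names(associations$models)) {
        files <- c(files, .write_table(associations$models[[nm]]$coefficients,
          file.path(config$out_dir, "associations", paste0(nm, ".csv"))))
      }
    }
  }

  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    seed = config$seed,
    n_controls = rscn$n,
    n_patients = length(idscns),
    n_regions = nrow(rscn$r),
    chosen_k = subtypes$chosen_k,
    r_version = as.character(getRversion()),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = sub(paste0("^", config$out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(rscn = rscn, idscns = idscns, ranking = ranking,
                 features = features, subtypes = subtypes,
                 stability = stability, comparison = comparison,
                 permutation = permutation, subgroups = subgroups,
                 associations = associations, manifest = manifest))
}
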