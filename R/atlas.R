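#' Region atlases and the edge index space
#'
#' An atlas is an ordered list of brain regions (1-based indices, short
#' names, and a major-area label per region). It fixes the edge universe of
#' every network in the pipeline: the \eqn{n(n-1)/2} unordered region pairs,
#' always enumerated in row-major upper-triangle order
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). All flat edge vectors and
#' all square matrices produced by the package share this order, so outputs
#' are byte-comparable across runs.
#'
#' @name atlas
NULL

#' Load a region atlas from a delimited text file
#'
#' The file must be comma-delimited UTF-8 with a header `index,name,area`;
#' lines starting with `#` are ignored. Indices must be contiguous from 1
#' and names unique. The packaged 116-region atlas with a conventional
#' seven-area grouping is available via [aal116_atlas_path()].
#'
#' @param path Path to the atlas file.
#' @return An object of class `region_atlas`: a list with `regions`
#'   (data.frame `index`, `name`, `area`), `n_regions`, and `areas`
#'   (the distinct area labels in order of first appearance).
#' @examples
#' atlas <- load_atlas(aal116_atlas_path())
#' atlas$n_regions   # 116
#' @export
load_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("index", "name", "area")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("atlas file is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("atlas file is empty")
  df <- df[, required]
  if (anyNA(df)) stop("atlas file contains missing values")
  idx <- as.integer(df$index)
  dup <- idx[duplicated(idx)]
  if (length(dup)) {
    stop("duplicate region index in atlas file: ", paste(unique(dup), collapse = ", "))
  }
  if (!identical(sort(idx), seq_len(nrow(df)))) {
    stop("non-contiguous region indices: expected 1..", nrow(df),
         ", got ", paste(utils::head(sort(idx), 5), collapse = ","), " ...")
  }
  dupn <- df$name[duplicated(df$name)]
  if (length(dupn)) {
    stop("duplicate region name in atlas file: ", paste(unique(dupn), collapse = ", "))
  }
  df <- df[order(idx), ]
  df$index <- sort(idx)
  rownames(df) <- NULL
  structure(
    list(regions = df, n_regions = nrow(df), areas = unique(df$area)),
    class = "region_atlas"
  )
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("<region_atlas> ", x$n_regions, " regions, ",
      n_edges(x$n_regions), " edges, ",
      length(x$areas), " areas (", paste(x$areas, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Path to the packaged 116-region atlas
#'
#' A 116-region AAL-style parcellation (90 cerebral regions plus 26
#' cerebellar regions) with a conventional grouping into seven major areas:
#' frontal, temporal, parietal, occipital, limbic, subcortical, cerebellum.
#' The grouping is a documented convention for summarising edge
#' distributions, not a reproduction of any particular published mapping.
#'
#' @return Path to the installed atlas CSV.
#' @export
aal116_atlas_path <- function() {
  system.file("extdata", "aal116_atlas.csv", package = "idscn", mustWork = TRUE)
}

#' Number of unique edges among n regions
#' @param n_regions Number of regions.
#' @return `n_regions * (n_regions - 1) / 2`.
#' @export
n_edges <- function(n_regions) n_regions * (n_regions - 1L) / 2L

#' Enumerate the edge universe of an atlas
#'
#' Deterministic row-major upper-triangle order: (1,2), (1,3), ..., (1,n),
#' (2,3), ..., (n-1,n). Every flat edge vector in the package follows this
#' order.
#'
#' @param atlas A `region_atlas`, or a single integer number of regions.
#' @return data.frame with integer columns `i`, `j` (`i < j`), one row per
#'   edge, `n(n-1)/2` rows.
#' @export
edge_universe <- function(atlas) {
  n <- if (inherits(atlas, "region_atlas")) atlas$n_regions else as.integer(atlas)
  if (is.na(n) || n < 2L) stop("need at least 2 regions")
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  data.frame(i = i, j = j)
}

#' Human-readable labels for edges
#' @param edges data.frame with columns `i`, `j`.
#' @param atlas A `region_atlas`.
#' @param sep Separator between the two region names.
#' @return Character vector like `"CAU.R-HES.R"`.
#' @export
edge_labels <- function(edges, atlas, sep = "-") {
  stopifnot(inherits(atlas, "region_atlas"))
  paste(atlas$regions$name[edges$i], atlas$regions$name[edges$j], sep = sep)
}

# Flat <-> square helpers. `edges` defaults to the full universe; all of
# these respect the canonical row-major upper-triangle order.

#' Extract the flat upper-triangle vector of a symmetric matrix
#' @param m Square matrix.
#' @return Numeric vector in canonical edge order, length `n(n-1)/2`.
#' @export
flatten_edges <- function(m) {
  e <- edge_universe(nrow(m))
  m[cbind(e$i, e$j)]
}

#' Rebuild a symmetric matrix from a flat edge vector
#' @param v Flat vector in canonical edge order.
#' @param diag Value for the diagonal (default 0).
#' @return Symmetric matrix.
#' @export
unflatten_edges <- function(v, diag = 0) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (n != round(n)) stop("length of v is not a triangular number")
  n <- as.integer(n)
  e <- edge_universe(n)
  m <- matrix(diag, n, n)
  m[cbind(e$i, e$j)] <- v
  m[cbind(e$j, e$i)] <- v
  m
}

#' Tabulate edges by major-area pair
#'
#' Counts how many of the given edges fall within each unordered pair of
#' major areas. Within-area counts sit on the diagonal; the table is
#' symmetric and its upper triangle plus diagonal sums to the number of
#' input edges.
#'
#' @param edges data.frame with columns `i`, `j` (region indices).
#' @param atlas A `region_atlas`.
#' @return Symmetric integer matrix, one row/column per area.
#' @export
area_distribution <- function(edges, atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  areas <- atlas$areas
  m <- matrix(0L, length(areas), length(areas), dimnames = list(areas, areas))
  if (nrow(edges) == 0L) return(m)
  bad <- !(edges$i %in% atlas$regions$index) | !(edges$j %in% atlas$regions$index)
  if (any(bad)) {
    stop("edge references unknown region index (row ",
         paste(which(bad), collapse = ","), ")")
  }
  ai <- atlas$regions$area[edges$i]
  aj <- atlas$regions$area[edges$j]
  lo <- pmin(ai, aj)
  hi <- pmax(ai, aj)
  tab <- table(factor(lo, levels = areas), factor(hi, levels = areas))
  for (a in seq_along(areas)) for (b in seq_along(areas)) {
    if (a <= b) {
      cnt <- tab[a, b] + if (a < b) tab[b, a] else 0L
      m[a, b] <- m[b, a] <- as.integer(cnt)
    }
  }
  m
}
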