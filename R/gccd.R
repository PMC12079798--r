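#' Select the shared epsilon grid from sample barcodes
#'
#' The grid must start below the smallest cycle birth and end above the
#' largest cycle death seen in typical barcodes.  Classical (full-cloud)
#' Vietoris-Rips barcodes of the sample clouds are computed, the minimal
#' birth is floored and the maximal death ceiled to whole angstroms, both
#' ends are extended by `4 * sigma_max` (four standard deviations of the
#' widest smoothing Gaussian), and the lower end is clamped at no less than
#' one grid spacing so the grid stays positive.
#'
#' @param sample_clouds non-empty list of [alpha_carbon_cloud()] objects.
#' @param sigma_max largest smoothing parameter that will be used (angstroms).
#' @param spacing grid spacing (angstroms).
#' @param dim homology dimension inspected (default 1).
#' @param sample_cutoff top of the sampling filtration (angstroms); large by
#'   default so typical deaths are observed rather than capped.
#' @return an [epsilon_grid()], with attributes `min_birth` and `max_death`
#'   recording the observed extremes.
#' @export
select_epsilon_grid <- function(sample_clouds, sigma_max, spacing = 0.1,
                                dim = 1L, sample_cutoff = 1e3) {
  if (length(sample_clouds) == 0L) stop("sample_clouds must be non-empty")
  births <- numeric()
  deaths <- numeric()
  for (cloud in sample_clouds) {
    de <- as.matrix(stats::dist(cloud_xyz(cloud)))
    bc <- rips_barcode(de, dims = dim, cutoff = sample_cutoff)[[as.character(dim)]]
    births <- c(births, bc$bars$birth)
    deaths <- c(deaths, bc$bars$death)
  }
  if (length(births) == 0L) {
    stop("grid selection failed: every sample barcode is empty")
  }
  lo <- floor(min(births)) - 4 * sigma_max
  hi <- ceiling(max(deaths)) + 4 * sigma_max
  lo <- max(lo, spacing)
  grid <- epsilon_grid(lo, hi, spacing)
  attr(grid, "min_birth") <- min(births)
  attr(grid, "max_death") <- max(deaths)
  grid
}

#' Gaussian CROCKER matrix of a conformation
#'
#' For each residue distance rho from 1 to the scheme's inter-chain value, a
#' Vietoris-Rips filtration is built from the masked dissimilarity matrix (see
#' [build_dissimilarity()]), its dimension-`dim` barcode computed with deaths
#' capped at `cutoff`, and the barcode vectorized into a Gaussian Betti vector
#' on the shared grid.  The columns, in increasing rho, form the Gaussian
#' CROCKER matrix: rows index spatial scale, columns residue distance.
#' Smoothing acts only along the spatial axis; residue distances are discrete
#' and each column comes from its own filtration.
#'
#' @param cloud an [alpha_carbon_cloud()].
#' @param grid an [epsilon_grid()].
#' @param sigma Gaussian smoothing parameter (angstroms).
#' @param dim homology dimension (default 1).
#' @param scheme a [residue_scheme()]; default derived from the cloud.
#' @param M sentinel dissimilarity; default [choose_M()] above the cutoff.
#' @param cutoff death cap; default `max(grid) + 0.001`.
#' @param weight optional weight function passed to
#'   [gaussian_betti_vector()].
#' @param column_mode `"independent"` rebuilds the dissimilarity matrix for
#'   every rho; `"incremental"` unmasks newly admissible pairs of the
#'   previous matrix.  Results are identical; both paths are kept as a
#'   regression cross-check.
#' @return a `gaussian_crocker` object: numeric matrix
#'   `length(grid) x inter_chain_value` with attributes `grid`, `rhos`,
#'   `sigma`, `dimension`, `cutoff`, `M`, `scheme`.
#' @export
gaussian_crocker <- function(cloud, grid, sigma, dim = 1L,
                             scheme = scheme_for_cloud(cloud),
                             M = choose_M(cutoff), cutoff = max(grid) + 0.001,
                             weight = NULL,
                             column_mode = c("independent", "incremental")) {
  column_mode <- match.arg(column_mode)
  if (cutoff < max(grid)) stop("cutoff must reach the top of the grid")
  if (M <= cutoff) stop("M must exceed the persistence cutoff")
  rhos <- seq_len(scheme$inter_chain_value)
  values <- matrix(0, nrow = length(grid), ncol = length(rhos))
  key <- as.character(dim)
  if (column_mode == "independent") {
    for (j in seq_along(rhos)) {
      D <- build_dissimilarity(cloud, rhos[j], M, scheme)
      bc <- rips_barcode(D, dims = dim, cutoff = cutoff)[[key]]
      values[, j] <- gaussian_betti_vector(bc, grid, sigma, weight)
    }
  } else {
    de <- as.matrix(stats::dist(cloud_xyz(cloud)))
    rd <- residue_distance_matrix(cloud, scheme)
    D <- ifelse(rd <= 1L, de, M)
    diag(D) <- 0
    for (j in seq_along(rhos)) {
      if (j > 1L) {
        newly <- rd == rhos[j]
        D[newly] <- de[newly]
      }
      Dj <- structure(D, rho = rhos[j], M = M)
      bc <- rips_barcode(Dj, dims = dim, cutoff = cutoff)[[key]]
      values[, j] <- gaussian_betti_vector(bc, grid, sigma, weight)
    }
  }
  structure(values, grid = grid, rhos = rhos, sigma = sigma,
            dimension = as.integer(dim), cutoff = cutoff, M = M,
            scheme = scheme, class = "gaussian_crocker")
}

#' Gaussian CROCKER column differences (GCCD) matrix
#'
#' Successive column differences of a Gaussian CROCKER matrix: the first
#' column is kept, and column j (j > 1) becomes column j minus column j - 1.
#' The GCCD matrix records the change in Gaussian Betti numbers as
#' progressively more sequence-distant connections are allowed, localising
#' each class of cycles at the residue distance where it emerges; entries may
#' be negative.  Row-wise cumulative sums invert the construction exactly,
#' and the sum of all columns equals the final (classical Rips) column.
#'
#' @param crocker a `gaussian_crocker` object.
#' @return a `gccd_matrix` object with the same attributes.
#' @export
gccd_from_crocker <- function(crocker) {
  stopifnot(inherits(crocker, "gaussian_crocker"))
  values <- unclass(crocker)
  if (ncol(values) > 1L) {
    values[, -1L] <- values[, -1L, drop = FALSE] -
      values[, -ncol(values), drop = FALSE]
  }
  attributes(values) <- attributes(crocker)
  class(values) <- "gccd_matrix"
  values
}

#' Reconstruct the Gaussian CROCKER matrix from a GCCD matrix
#'
#' Exact inverse of [gccd_from_crocker()] (row-wise cumulative sums).
#'
#' @param gccd a `gccd_matrix`.
#' @return the `gaussian_crocker` matrix.
#' @export
crocker_from_gccd <- function(gccd) {
  stopifnot(inherits(gccd, "gccd_matrix"))
  values <- unclass(gccd)
  values <- t(apply(values, 1L, cumsum))
  attributes(values) <- attributes(gccd)
  class(values) <- "gaussian_crocker"
  values
}

#' Compute a GCCD matrix directly from a conformation
#'
#' Convenience wrapper: [gaussian_crocker()] followed by
#' [gccd_from_crocker()].
#'
#' @inheritParams gaussian_crocker
#' @param ... passed on to [gaussian_crocker()].
#' @return a `gccd_matrix`.
#' @export
gccd_matrix <- function(cloud, grid, sigma, ...) {
  gccd_from_crocker(gaussian_crocker(cloud, grid, sigma, ...))
}

#' @export
print.gaussian_crocker <- function(x, ...) {
  cat(sprintf(
    "gaussian_crocker: %d epsilon rows x %d residue-distance columns, sigma %g, dim %d\n",
    nrow(x), ncol(x), attr(x, "sigma"), attr(x, "dimension")))
  invisible(x)
}

#' @export
print.gccd_matrix <- function(x, ...) {
  cat(sprintf(
    "gccd_matrix: %d epsilon rows x %d residue-distance columns, sigma %g, dim %d\n",
    nrow(x), ncol(x), attr(x, "sigma"), attr(x, "dimension")))
  invisible(x)
}

#' Serialize CROCKER / GCCD matrices
#'
#' `write_crocker_csv()` writes a plain-text layout: a header row with the
#' rho values (first cell blank), then one row per epsilon value whose first
#' cell is the grid value, all rounded to ten decimal places.
#' `read_crocker_csv()` restores the matrix.  `write_crocker_rds()` keeps the
#' full object with its metadata (sigma, dimension, cap, scheme) in a compact
#' binary container.
#'
#' @param m a `gaussian_crocker` or `gccd_matrix`.
#' @param path output file.
#' @return `path` invisibly (writers); the matrix (reader).
#' @export
write_crocker_csv <- function(m, path) {
  grid <- attr(m, "grid")
  rhos <- attr(m, "rhos")
  tab <- cbind(round(as.numeric(grid), 10), round(unclass(m), 10))
  header <- paste(c("epsilon", paste0("rho_", rhos)), collapse = ",")
  writeLines(header, path)
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname write_crocker_csv
#' @export
read_crocker_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  grid_values <- tab[[1]]
  values <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(values) <- NULL
  spacing <- if (length(grid_values) > 1) diff(grid_values)[1] else 1
  structure(values,
            grid = epsilon_grid(min(grid_values), max(grid_values), spacing),
            rhos = seq_len(ncol(values)))
}

#' @rdname write_crocker_csv
#' @export
write_crocker_rds <- function(m, path) {
  saveRDS(m, path)
  invisible(path)
}
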