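#' Regular grids of spatial-scale values
#'
#' All vectorized summaries share one regular grid of epsilon values
#' (angstroms).  The grid must be strictly increasing, regularly spaced and
#' non-negative.
#'
#' @param from,to,by grid range and spacing in angstroms.
#' @return an `epsilon_grid`: the numeric vector of grid values with a
#'   `spacing` attribute.
#' @export
epsilon_grid <- function(from, to, by) {
  stopifnot(by > 0, to > from, from >= 0)
  values <- seq(from, to, by = by)
  structure(values, spacing = by, class = "epsilon_grid")
}

#' @export
print.epsilon_grid <- function(x, ...) {
  cat(sprintf("epsilon_grid: %d values from %g to %g by %g angstroms\n",
              length(x), min(x), max(x), attr(x, "spacing")))
  invisible(x)
}

#' Betti number at a spatial scale
#'
#' The dimension-k Betti number at scale epsilon is the number of bars
#' `[b, d)` with `b <= epsilon < d` — equivalently, the number of persistence
#' diagram points with `x <= epsilon` and `y > epsilon`.
#'
#' @param bc a [barcode()].
#' @param epsilon numeric vector of scales.
#' @return integer vector of Betti numbers, one per scale.
#' @export
betti_number <- function(bc, epsilon) {
  vapply(epsilon, function(e) {
    sum(bc$bars$birth <= e & e < bc$bars$death)
  }, integer(1))
}

#' Gaussian Betti number
#'
#' Smooth surrogate for the Betti number: an isotropic bivariate Gaussian with
#' scale `sigma` is centred at each persistence-diagram point `(b, d)`, and
#' instead of counting points in the region `{x <= epsilon, y > epsilon}` the
#' sum of Gaussian masses over that region is computed.  The region is a
#' product of half-planes, so each bar's contribution factors as
#' `Phi((epsilon - b) / sigma) * (1 - Phi((epsilon - d) / sigma))`, a value in
#' `[0, 1]` for unit weight.  An optional weight `w(b, d) >= 0` per bar lets
#' the curve prioritise classes by birth, death or lifetime; the unweighted
#' curve is the special case `w = 1`.
#'
#' @param bc a [barcode()].
#' @param epsilon numeric vector of scales.
#' @param sigma Gaussian scale parameter (angstroms, > 0).
#' @param weight `NULL` for unit weights, or a vectorized function
#'   `function(birth, death)` returning non-negative weights.
#' @return numeric vector of Gaussian Betti numbers.
#' @export
gaussian_betti_number <- function(bc, epsilon, sigma, weight = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (n_bars(bc) == 0) return(numeric(length(epsilon)))
  b <- bc$bars$birth
  d <- bc$bars$death
  w <- if (is.null(weight)) rep(1, length(b)) else weight(b, d)
  if (any(w < 0)) stop("weights must be non-negative")
  pb <- stats::pnorm(outer(epsilon, b, "-") / sigma)
  pd <- stats::pnorm(outer(epsilon, d, "-") / sigma, lower.tail = FALSE)
  as.vector((pb * pd) %*% w)
}

#' Gaussian Betti vector on a grid
#'
#' @inheritParams gaussian_betti_number
#' @param grid an [epsilon_grid()].
#' @return a `gaussian_betti_vector`: numeric vector over the grid with
#'   attributes `grid`, `sigma`, `dimension` and `n_bars`.
#' @export
gaussian_betti_vector <- function(bc, grid, sigma, weight = NULL) {
  values <- gaussian_betti_number(bc, as.numeric(grid), sigma, weight)
  structure(values, grid = grid, sigma = sigma, dimension = bc$dimension,
            n_bars = n_bars(bc), class = "gaussian_betti_vector")
}

#' Normalized multi-dimension Gaussian Betti vector
#'
#' Baseline spatial-only summary: Gaussian Betti vectors for dimensions 0, 1
#' and 2, each divided by the number of points in its persistence diagram so
#' the dimensions share a scale, concatenated in dimension order.  An empty
#' diagram contributes a zero block (0/0 is defined as 0).
#'
#' @param barcodes named list with elements `"0"`, `"1"`, `"2"` of
#'   [barcode()] objects (possibly empty).
#' @param grid an [epsilon_grid()].
#' @param sigma Gaussian scale parameter.
#' @return numeric vector of length `3 * length(grid)`.
#' @export
normalized_multidim_vector <- function(barcodes, grid, sigma) {
  blocks <- lapply(c("0", "1", "2"), function(k) {
    bc <- barcodes[[k]]
    if (is.null(bc)) stop("barcode for dimension ", k, " is missing")
    nb <- n_bars(bc)
    if (nb == 0) return(numeric(length(grid)))
    gaussian_betti_number(bc, as.numeric(grid), sigma) / nb
  })
  unlist(blocks, use.names = FALSE)
}

#' Write a vector summary as CSV
#'
#' One header row carries the grid values; values are rounded to ten decimal
#' places on save.
#'
#' @param v numeric vector (e.g. a Gaussian Betti vector).
#' @param grid the [epsilon_grid()] the values live on.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vector_csv <- function(v, grid, path) {
  stopifnot(length(v) %% length(grid) == 0)
  tab <- rbind(as.numeric(grid), matrix(round(v, 10), ncol = length(grid),
                                        byrow = TRUE))
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
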