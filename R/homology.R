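#' Barcode objects
#'
#' A barcode is the multiset of `[birth, death)` intervals of one homology
#' dimension of one Vietoris-Rips filtration.  Classes still alive at the top
#' of the filtration are capped: their death is set to the cap value.
#' Zero-length intervals `[b, b)` are empty and never stored.
#'
#' @param dimension homology dimension (k = 0 components, 1 loops/tunnels,
#'   2 voids).
#' @param birth,death numeric vectors of interval endpoints (angstroms),
#'   `0 <= birth < death <= cap`.
#' @param cap value substituted for infinite deaths.
#' @return an object of class `barcode` with fields `dimension`, `bars`
#'   (data frame `birth`, `death`) and `cap`.
#' @export
barcode <- function(dimension, birth = numeric(), death = numeric(),
                    cap = Inf) {
  stopifnot(length(birth) == length(death))
  if (any(birth < 0) || any(death <= birth) || any(death > cap)) {
    stop("bars must satisfy 0 <= birth < death <= cap")
  }
  bars <- data.frame(birth = as.numeric(birth), death = as.numeric(death))
  bars <- bars[order(bars$birth, bars$death), , drop = FALSE]
  rownames(bars) <- NULL
  structure(list(dimension = as.integer(dimension), bars = bars,
                 cap = cap),
            class = "barcode")
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf("dimension %d barcode: %d bar(s), cap %g\n", x$dimension,
              nrow(x$bars), x$cap))
  if (nrow(x$bars) > 0) {
    print(utils::head(x$bars, 10))
    if (nrow(x$bars) > 10) cat("...\n")
  }
  invisible(x)
}

#' @rdname barcode
#' @param x a `barcode`.
#' @export
n_bars <- function(x) nrow(x$bars)

#' Vietoris-Rips persistence barcodes from a dissimilarity matrix
#'
#' Computes persistent homology of the Vietoris-Rips filtration of `D` over
#' the two-element field, up to the spatial scale `cutoff`.  Any class alive
#' at the cutoff is assigned death = `cutoff`.  Dimension 0 follows the usual
#' convention: one bar per connected component, all born at 0, the everlasting
#' component capped like any other.  Sentinel entries of a masked
#' dissimilarity matrix (see [build_dissimilarity()]) must exceed the cutoff,
#' so masked connections never enter the complex.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param dims homology dimensions to compute (subset of 0:2).
#' @param cutoff top of the filtration (angstroms).
#' @return named list mapping dimension (as character) to [barcode()].
#' @export
rips_barcode <- function(D, dims = 1L, cutoff) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0)) {
    stop("D must be symmetric with zero diagonal")
  }
  M <- attr(D, "M")
  if (!is.null(M) && M <= cutoff) {
    stop("cutoff must be below the sentinel M, else forbidden connections ",
         "would enter the complex")
  }
  dims <- sort(unique(as.integer(dims)))
  if (any(dims < 0) || any(dims > 2)) stop("supported dimensions are 0, 1, 2")
  pairs <- .rips_pairs_cpp(D, max(dims), cutoff)
  out <- list()
  for (k in dims) {
    sel <- pairs$dimension == k
    out[[as.character(k)]] <- barcode(k, pairs$birth[sel], pairs$death[sel],
                                      cap = cutoff)
  }
  out
}

#' Brute-force persistence barcode (test oracle)
#'
#' Independent reference computation of Vietoris-Rips persistence by explicit
#' enumeration of every simplex up to dimension `dim + 1` and dense boundary
#' matrix reduction over the two-element field (classic left-to-right column
#' reduction).  The same death-capping rule as [rips_barcode()] applies.
#' Combinatorial enumeration restricts inputs to at most 15 points.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param dim single homology dimension (0, 1 or 2).
#' @param cutoff top of the filtration.
#' @return a [barcode()].
#' @export
brute_force_barcode <- function(D, dim, cutoff) {
  D <- unclass(D)
  n <- nrow(D)
  if (n > 15L) stop("brute-force oracle is limited to 15 points")
  stopifnot(dim %in% 0:2)
  topdim <- dim + 1L

  # enumerate simplices with diameter <= cutoff, as vertex index vectors
  simplices <- list()
  diams <- numeric()
  sdims <- integer()
  for (k in 0:topdim) {
    combos <- utils::combn(n, k + 1)
    for (ci in seq_len(ncol(combos))) {
      v <- combos[, ci]
      dm <- if (k == 0) 0 else max(D[v, v])
      if (dm <= cutoff) {
        simplices[[length(simplices) + 1L]] <- v
        diams <- c(diams, dm)
        sdims <- c(sdims, k)
      }
    }
  }
  keys <- vapply(simplices, paste, "", collapse = ",")
  ord <- order(diams, sdims, keys)
  simplices <- simplices[ord]
  diams <- diams[ord]
  sdims <- sdims[ord]
  m <- length(simplices)
  index_of <- stats::setNames(seq_len(m), vapply(simplices, paste, "",
                                                 collapse = ","))

  # dense GF(2) boundary matrix
  B <- matrix(FALSE, m, m)
  for (j in seq_len(m)) {
    if (sdims[j] == 0) next
    v <- simplices[[j]]
    for (drop in seq_along(v)) {
      face <- paste(v[-drop], collapse = ",")
      B[index_of[[face]], j] <- TRUE
    }
  }

  low <- function(col) if (any(col)) max(which(col)) else 0L
  lows <- integer(m)                      # lows[j] = pivot row of column j
  for (j in seq_len(m)) {
    repeat {
      lj <- low(B[, j])
      if (lj == 0L) break
      prev <- which(lows[seq_len(j - 1L)] == lj)
      if (length(prev) == 0L) break
      B[, j] <- xor(B[, j], B[, prev[1L]])
    }
    lows[j] <- low(B[, j])
  }

  birth <- numeric()
  death <- numeric()
  for (j in seq_len(m)) {
    i <- lows[j]
    if (i > 0L && sdims[i] == dim) {       # pair (i, j): bar of dimension dim
      if (diams[j] > diams[i]) {
        birth <- c(birth, diams[i])
        death <- c(death, diams[j])
      }
    }
  }
  # unpaired creators of dimension dim: capped
  positive <- which(lows == 0L & sdims == dim)
  unpaired <- positive[!(positive %in% lows)]
  for (i in unpaired) {
    if (cutoff > diams[i]) {
      birth <- c(birth, diams[i])
      death <- c(death, cutoff)
    }
  }
  barcode(dim, birth, death, cap = cutoff)
}

#' Serialize barcodes to CSV
#'
#' Writes rows of (dimension, birth, death); [read_barcodes()] restores the
#' named list form.
#'
#' @param barcodes named list of [barcode()] objects (as from
#'   [rips_barcode()]).
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_barcodes <- function(barcodes, path) {
  rows <- do.call(rbind, lapply(barcodes, function(bc) {
    if (n_bars(bc) == 0) return(NULL)
    cbind(dimension = bc$dimension, bc$bars)
  }))
  if (is.null(rows)) {
    rows <- data.frame(dimension = integer(), birth = numeric(),
                       death = numeric())
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_barcodes
#' @param dims dimensions to restore (empty barcodes included).
#' @param cap cap value recorded on the restored barcodes.
#' @export
read_barcodes <- function(path, dims = 0:2, cap = Inf) {
  tab <- utils::read.csv(path)
  out <- list()
  for (k in dims) {
    sel <- tab$dimension == k
    out[[as.character(k)]] <- barcode(k, tab$birth[sel], tab$death[sel],
                                      cap = cap)
  }
  out
}
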