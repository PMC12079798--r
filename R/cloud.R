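#' Alpha-carbon point clouds
#'
#' An `alpha_carbon_cloud` is the sole structural input to the topological
#' pipeline: one conformation's alpha-carbon coordinates (angstroms) together
#' with a chain identifier and an author residue number per atom.  Records are
#' ordered by chain (order of first appearance) and then by residue number,
#' strictly increasing within each chain.
#'
#' @param records data frame with columns `chain` (character), `residue`
#'   (non-negative integer, author numbering), `x`, `y`, `z` (finite, in
#'   angstroms).
#' @param residue_range optional inclusive `c(first, last)` integer vector;
#'   when set, every record must lie inside it.
#' @return An object of class `alpha_carbon_cloud`: the validated, ordered
#'   record data frame with attributes `n_chains` and `residue_range`.
#' @examples
#' cloud <- alpha_carbon_cloud(data.frame(
#'   chain = "A", residue = 1:4,
#'   x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0))
#' n_points(cloud)
#' @export
alpha_carbon_cloud <- function(records, residue_range = NULL) {
  required <- c("chain", "residue", "x", "y", "z")
  if (!is.data.frame(records) || !all(required %in% names(records))) {
    stop("`records` must be a data frame with columns chain, residue, x, y, z")
  }
  records <- as.data.frame(records)[required]
  records$chain <- as.character(records$chain)
  if (nrow(records) == 0L) {
    stop("empty selection: no alpha-carbon records")
  }
  xyz <- as.matrix(records[c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  res <- records$residue
  if (any(is.na(res)) || any(res < 0) || any(res != round(res))) {
    stop("residue numbers must be non-negative integers")
  }
  records$residue <- as.integer(res)
  if (!is.null(residue_range)) {
    residue_range <- as.integer(residue_range)
    stopifnot(length(residue_range) == 2L, residue_range[1] <= residue_range[2])
    if (any(records$residue < residue_range[1] |
              records$residue > residue_range[2])) {
      stop("records outside the declared residue_range")
    }
  }
  chain_levels <- unique(records$chain)
  ord <- order(match(records$chain, chain_levels), records$residue)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  dup <- duplicated(records[c("chain", "residue")])
  if (any(dup)) {
    stop("duplicate (chain, residue) pair: ",
         paste0(records$chain[dup][1], "/", records$residue[dup][1]))
  }
  structure(records,
            n_chains = length(chain_levels),
            residue_range = residue_range,
            class = c("alpha_carbon_cloud", "data.frame"))
}

#' @export
print.alpha_carbon_cloud <- function(x, ...) {
  rng <- attr(x, "residue_range")
  cat(sprintf("alpha_carbon_cloud: %d atoms, %d chain(s)%s\n",
              nrow(x), attr(x, "n_chains"),
              if (is.null(rng)) "" else
                sprintf(", residues %d-%d", rng[1], rng[2])))
  invisible(x)
}

#' @rdname alpha_carbon_cloud
#' @param cloud an `alpha_carbon_cloud`.
#' @export
n_points <- function(cloud) nrow(cloud)

#' @rdname alpha_carbon_cloud
#' @export
n_chains <- function(cloud) attr(cloud, "n_chains")

#' Coordinates of a cloud as a numeric matrix
#' @param cloud an `alpha_carbon_cloud`.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
cloud_xyz <- function(cloud) {
  as.matrix(as.data.frame(cloud)[c("x", "y", "z")])
}

#' Restrict a cloud to a residue range and/or set of chains
#'
#' Selection is idempotent: re-applying the same range is a no-op.
#'
#' @param cloud an `alpha_carbon_cloud`.
#' @param residue_range inclusive `c(first, last)` or `NULL` to keep all.
#' @param chain_ids chains to keep, or `NULL` for all.
#' @return the restricted `alpha_carbon_cloud`.
#' @export
restrict_cloud <- function(cloud, residue_range = NULL, chain_ids = NULL) {
  df <- as.data.frame(cloud)
  if (!is.null(chain_ids)) df <- df[df$chain %in% chain_ids, , drop = FALSE]
  if (!is.null(residue_range)) {
    df <- df[df$residue >= residue_range[1] & df$residue <= residue_range[2], ,
             drop = FALSE]
  }
  if (nrow(df) == 0L) stop("empty selection after restriction")
  alpha_carbon_cloud(df, residue_range = residue_range)
}

#' Trajectory frame sets
#'
#' A `trajectory_frames` object holds an ordered list of conformations of one
#' molecular-dynamics trajectory, all sharing an identical (chain, residue)
#' roster, together with a class label and a trajectory identifier.
#'
#' @param frames list of [alpha_carbon_cloud()] objects with identical rosters.
#' @param label one of `"glycosylated"`, `"aglycosylated"`, `"unlabeled"`.
#' @param trajectory_id integer identifier.
#' @param frame_indices strictly increasing integer vector, one per frame.
#' @return an object of class `trajectory_frames`.
#' @export
trajectory_frames <- function(frames, label = "unlabeled", trajectory_id = 0L,
                              frame_indices = seq_along(frames) - 1L) {
  label <- match.arg(label, c("glycosylated", "aglycosylated", "unlabeled"))
  stopifnot(length(frames) >= 1L, length(frame_indices) == length(frames))
  frame_indices <- as.integer(frame_indices)
  if (any(diff(frame_indices) <= 0)) {
    stop("frame_indices must be strictly increasing")
  }
  roster <- function(cl) paste(cl$chain, cl$residue, sep = "/")
  ref <- roster(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(roster(frames[[i]]), ref)) {
      stop(sprintf("frame %d has an inconsistent (chain, residue) roster",
                   frame_indices[i]))
    }
  }
  structure(list(frames = frames, label = label,
                 trajectory_id = as.integer(trajectory_id),
                 frame_indices = frame_indices),
            class = "trajectory_frames")
}

#' @export
print.trajectory_frames <- function(x, ...) {
  cat(sprintf("trajectory_frames: id %d, %s, %d frame(s) of %d atoms\n",
              x$trajectory_id, x$label, length(x$frames),
              nrow(x$frames[[1]])))
  invisible(x)
}
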