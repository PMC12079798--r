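#' Synthetic alpha-carbon fixtures with planted topology
#'
#' Generators for multi-chain point clouds whose topological features are
#' analytically known, so every downstream stage (filtrations, barcodes,
#' Gaussian CROCKER and GCCD matrices, classification) can be exercised
#' without real structure data.  Fixtures are topological test objects, not
#' physically realistic chains.
#'
#' `make_chain_loop()` places `n_points` alpha carbons (one chain) on a circle
#' of the given radius, optionally perturbed by isotropic Gaussian noise.  The
#' residue numbering controls the residue distance at which the planted loop
#' closes:
#'
#' * `gap = 1`: residues are numbered consecutively in circle order, so the
#'   loop requires its wrap-around connection and closes only at residue
#'   distance `n_points - 1`.
#' * even `gap = 2 s` (requires even `n_points` and `gap <= n_points - 2`):
#'   residues follow a stride-`s` zigzag (numbers `1, 1 + s, ...` laid out
#'   odd-positions-up, even-positions-down), so for every residue distance
#'   below `gap` the admissible connection graph is a path or empty — hence
#'   carries no loops at all — and the planted loop closes exactly at residue
#'   distance `gap`, born at the polygon edge length `2 r sin(pi / n)`.
#'
#' @param n_points number of alpha carbons (>= 4).
#' @param radius circle radius (angstroms).
#' @param gap planted adjacency gap: the largest residue distance between
#'   sequence-adjacent vertices on the loop (1, or an even value).
#' @param noise_sd isotropic Gaussian noise on coordinates (angstroms).
#' @param seed integer seed; generation is seed-deterministic.
#' @return an [alpha_carbon_cloud()] with one chain.
#' @export
make_chain_loop <- function(n_points, radius, gap = 1L, noise_sd = 0,
                            seed = 1L) {
  n <- as.integer(n_points)
  gap <- as.integer(gap)
  if (n < 4L) stop("n_points must be >= 4")
  if (radius <= 0) stop("radius must be > 0")
  if (gap < 1L || gap > n) stop("gap must lie in 1..n_points")
  if (gap > 1L) {
    if (gap %% 2L != 0L || n %% 2L != 0L || gap > n - 2L) {
      stop("planted gaps above 1 require even gap <= n_points - 2 and even ",
           "n_points")
    }
  }
  theta <- 2 * pi * (seq_len(n) - 1) / n
  xyz <- cbind(radius * cos(theta), radius * sin(theta), 0)
  if (gap == 1L) {
    res <- seq_len(n)
  } else {
    s <- gap %/% 2L
    zig <- c(seq(1L, n, by = 2L), rev(seq(2L, n, by = 2L)))
    res <- 1L + (zig - 1L) * s
  }
  xyz <- .add_noise(xyz, noise_sd, seed)
  alpha_carbon_cloud(data.frame(chain = "A", residue = res,
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                stringsAsFactors = FALSE))
}

#' Two-chain ring fixture
#'
#' Two chains, each occupying one arc of a common circle with consecutive
#' residue numbering along the arc.  Within-chain connection graphs are
#' chordal arcs at every residue distance, so no within-chain column of a
#' dimension-1 GCCD matrix receives mass; the large ring closes only when
#' inter-chain connections are allowed, i.e. in the final column.  This
#' emulates a quaternary-structure tunnel spanning a protein dimer.
#'
#' @param n_per_chain alpha carbons per chain (>= 2).
#' @param radius circle radius (angstroms).
#' @inheritParams make_chain_loop
#' @return an [alpha_carbon_cloud()] with chains `"A"` and `"B"`.
#' @export
make_two_chain_ring <- function(n_per_chain, radius, noise_sd = 0,
                                seed = 1L) {
  n <- as.integer(n_per_chain)
  if (n < 2L) stop("n_per_chain must be >= 2")
  if (radius <= 0) stop("radius must be > 0")
  m <- 2L * n
  theta <- 2 * pi * (seq_len(m) - 1) / m
  xyz <- cbind(radius * cos(theta), radius * sin(theta), 0)
  xyz <- .add_noise(xyz, noise_sd, seed)
  alpha_carbon_cloud(data.frame(
    chain = rep(c("A", "B"), each = n),
    residue = rep(seq_len(n), 2L),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

#' Labeled synthetic trajectory pair
#'
#' Stand-in for a glycosylated / aglycosylated trajectory pair: both classes
#' are chain-loop fixtures, but their planted loop radii differ by
#' `class_effect`, and frames within a trajectory differ by i.i.d. isotropic
#' positional noise.  With `class_effect` large relative to `noise_sd` the
#' classes are separable end-to-end; with `class_effect = 0` they are
#' indistinguishable and classification sits at chance.
#'
#' @param n_frames frames per trajectory (>= 1).
#' @param class_effect difference between class loop radii (angstroms).
#' @param noise_sd per-frame positional noise (angstroms).
#' @param seed integer seed.
#' @param n_points alpha carbons per frame.
#' @param radius base loop radius of the glycosylated class.
#' @param gap planted adjacency gap passed to [make_chain_loop()].
#' @param trajectory_id id recorded on both returned trajectories.
#' @return list with elements `glycosylated` and `aglycosylated`, each a
#'   [trajectory_frames()] object.
#' @export
make_labeled_frames <- function(n_frames, class_effect, noise_sd = 0.05,
                                seed = 1L, n_points = 12L, radius = 1.5,
                                gap = 2L, trajectory_id = 0L) {
  stopifnot(n_frames >= 1)
  make_set <- function(r, label, subseed) {
    frames <- lapply(seq_len(n_frames), function(i) {
      make_chain_loop(n_points, r, gap = gap, noise_sd = noise_sd,
                      seed = subseed + i)
    })
    trajectory_frames(frames, label = label, trajectory_id = trajectory_id,
                      frame_indices = seq_len(n_frames) - 1L)
  }
  base <- (as.integer(seed) %% 100000L) * 10000L  # keep derived seeds < 2^31
  list(
    glycosylated = make_set(radius, "glycosylated", base),
    aglycosylated = make_set(radius + class_effect, "aglycosylated",
                             base + 5000L))
}

# deterministic isotropic Gaussian perturbation; leaves the caller's RNG
# stream untouched
.add_noise <- function(xyz, noise_sd, seed) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0) return(xyz)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd), ncol = 3)
}
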