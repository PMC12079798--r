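#' Residue-distance scheme
#'
#' Residue distance within a chain is the absolute difference of author
#' residue numbers.  Between chains it takes a single bookkeeping value
#' `inter_chain_value = max_within + 1`, one more than the largest
#' within-chain distance, so that the final filtration of the family (at rho =
#' `inter_chain_value`) allows every connection and reduces to the classical
#' Vietoris-Rips filtration on spatial distances alone.  For an Fc dimer with
#' 206 residues per chain, `max_within` is 205 and the inter-chain value 206.
#'
#' @param max_within largest within-chain residue distance (integer >= 1).
#' @return a `residue_scheme` list with fields `max_within` and
#'   `inter_chain_value`.
#' @export
residue_scheme <- function(max_within) {
  max_within <- as.integer(max_within)
  if (is.na(max_within) || max_within < 1L) {
    stop("max_within must be an integer >= 1")
  }
  structure(list(max_within = max_within,
                 inter_chain_value = max_within + 1L),
            class = "residue_scheme")
}

#' Residue-distance scheme implied by a cloud
#'
#' `max_within` is the largest residue-number span of any chain, computed from
#' author numbers (numbering gaps count).
#'
#' @param cloud an [alpha_carbon_cloud()].
#' @return a [residue_scheme()].
#' @export
scheme_for_cloud <- function(cloud) {
  span <- tapply(cloud$residue, cloud$chain,
                 function(r) max(r) - min(r))
  residue_scheme(max(span))
}

#' Residue distance between two records
#'
#' @param a,b single-row record data frames (or lists) with `chain` and
#'   `residue` fields, from the same cloud.
#' @param scheme a [residue_scheme()].
#' @return integer: `|r_a - r_b|` for same-chain records, otherwise the
#'   scheme's inter-chain value.
#' @export
residue_distance <- function(a, b, scheme) {
  if (identical(as.character(a$chain), as.character(b$chain))) {
    abs(as.integer(a$residue) - as.integer(b$residue))
  } else {
    scheme$inter_chain_value
  }
}

# full matrix of residue distances for a cloud
residue_distance_matrix <- function(cloud, scheme) {
  rd <- abs(outer(cloud$residue, cloud$residue, "-"))
  same <- outer(cloud$chain, cloud$chain, "==")
  rd[!same] <- scheme$inter_chain_value
  rd
}

#' Choose the sentinel value M for forbidden connections
#'
#' Pairs whose residue distance exceeds rho are assigned the dissimilarity
#' `M`, a value strictly larger than the largest spatial scale at which
#' persistent homology is computed, so those connections are effectively
#' forbidden.  Any such value is equivalent; a fixed default pad keeps runs
#' reproducible.
#'
#' @param epsilon_max largest spatial scale of the persistence computation
#'   (angstroms).
#' @param pad positive padding added beyond `epsilon_max`; default 10.
#' @return `epsilon_max + pad`.
#' @export
choose_M <- function(epsilon_max, pad = 10) {
  stopifnot(epsilon_max > 0)
  if (!is.numeric(pad) || pad <= 0) stop("pad must be > 0")
  epsilon_max + pad
}

#' Build the dissimilarity matrix at a fixed residue distance
#'
#' Entry (i, j) is the Euclidean distance between alpha carbons i and j when
#' their residue distance is at most `rho`, and the sentinel `M` otherwise.
#' As rho grows, entries only decrease (from `M` to the Euclidean value), so
#' each filtration is nested inside the next; at rho equal to the scheme's
#' inter-chain value the matrix is exactly the Euclidean distance matrix.
#'
#' @param cloud an [alpha_carbon_cloud()].
#' @param rho residue distance, `1 <= rho <= scheme$inter_chain_value`.
#' @param M sentinel dissimilarity for forbidden pairs (angstroms); see
#'   [choose_M()].
#' @param scheme a [residue_scheme()]; default derived from the cloud.
#' @return a symmetric matrix with zero diagonal, with attributes `rho` and
#'   `M`.
#' @export
build_dissimilarity <- function(cloud, rho, M, scheme = scheme_for_cloud(cloud)) {
  rho <- as.integer(rho)
  if (is.na(rho) || rho < 1L || rho > scheme$inter_chain_value) {
    stop("rho must lie in 1..", scheme$inter_chain_value)
  }
  if (!is.numeric(M) || M <= 0) stop("M must be a positive sentinel value")
  de <- as.matrix(stats::dist(cloud_xyz(cloud)))
  rd <- residue_distance_matrix(cloud, scheme)
  d <- ifelse(rd <= rho, de, M)
  diag(d) <- 0
  dimnames(d) <- NULL
  structure(d, rho = rho, M = M)
}
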