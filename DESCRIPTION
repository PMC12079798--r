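Package: gccd
Title: Gaussian CROCKER Column Differences for Spatial and Sequential Protein Topology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topological summaries of multi-chain biomolecular structures that
    track Vietoris-Rips persistent homology jointly over a continuous spatial
    distance parameter (angstroms) and a discrete residue distance parameter.
    Builds Gaussian CROCKER matrices (grids of Gaussian-smoothed Betti numbers)
    and their column-difference (GCCD) form, which localises loops and tunnels
    by the residue distance at which they emerge.  Includes alpha-carbon
    readers for PDB/mmCIF structures and trajectory tables, a persistent
    homology engine with an independent brute-force oracle, Gaussian Betti
    vectorizations, synthetic fixtures with planted topological features, and
    the downstream k-nearest-neighbour classification protocol with
    trajectory-level train/validation/test splits, multidimensional scaling
    and principal component embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
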