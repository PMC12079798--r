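# gccd

Topological summaries of multi-chain biomolecular structures that track
loops and tunnels jointly over **spatial scale** and **sequence distance**,
for structural bioinformaticians analysing conformations from molecular
dynamics trajectories or deposited structures.

## The method

A conformation is reduced to its alpha-carbon point cloud, each atom carrying
a chain identifier and an author residue number.  Two dissimilarities are
defined between atoms: the Euclidean distance (Å) and the *residue distance*
ρ — the absolute difference of residue numbers within a chain, and a single
bookkeeping value (largest within-chain distance + 1) between chains.

For each ρ, pairs with residue distance above ρ are masked with a large
sentinel *M*, and the masked matrix generates a Vietoris–Rips filtration;
its dimension-k persistence barcode {[b, d)} is smoothed into a **Gaussian
Betti vector** on a shared ε grid, each bar contributing

    Φ((ε − b)/σ) · (1 − Φ((ε − d)/σ))

(the mass of an isotropic Gaussian of scale σ centred at (b, d) over the
region {x ≤ ε, y > ε} counted by the Betti number β_k(ε)).  Stacking the
vectors for ρ = 1, 2, … as columns gives the **Gaussian CROCKER matrix**;
differencing successive columns gives the **Gaussian CROCKER column
differences (GCCD) matrix**, which localises each class of cycles at the
residue distance where it first appears: within-chain loops of small
sequence span show up in early columns, immunoglobulin-fold-like loops in
middle columns, and quaternary tunnels that need both chains in the final
column.  Flattened GCCD matrices feed a k-nearest-neighbour classifier with
trajectory-level train/validation/test splits, plus MDS and PCA embeddings.

The Vietoris–Rips persistence engine (GF(2) boundary-matrix reduction) is
built in, with an independent brute-force oracle used throughout the tests.

## Worked example

Two chains forming a ring that exists only because the chains assemble:

```r
library(gccd)

ring <- make_two_chain_ring(n_per_chain = 8, radius = 1.5,
                            noise_sd = 0.05, seed = 1)
ring
#> alpha_carbon_cloud: 16 atoms, 2 chain(s)

grid <- epsilon_grid(0.2, 4, 0.1)
G <- gccd_matrix(ring, grid, sigma = 0.25)
G
#> gccd_matrix: 39 epsilon rows x 8 residue-distance columns, sigma 0.25, dim 1

round(colSums(abs(unclass(G))), 2)
#> [1]  0.00  0.00  0.00  0.00  0.00  0.00  0.00 18.29
```

Every within-chain column is zero — no loop can be built from one chain —
and the ring's entire signal sits in the final, inter-chain column (here
18.29 summed |Gaussian Betti| units over the grid).  A single-chain fixture
with a planted adjacency gap behaves the same way along the sequence axis:
`make_chain_loop(12, 1.5, gap = 4)` puts zero mass in GCCD columns 1–3 and
its loop mass in column 4.

Real structures flow through the same functions:

```r
cloud <- read_structure("structure.pdb", assembly = 1,
                        residue_range = c(241, 446))
grid  <- select_epsilon_grid(list(cloud), sigma_max = 0.5)   # data-driven range
G     <- gccd_matrix(cloud, grid, sigma = 0.25)
write_crocker_csv(G, "gccd.csv")
```

and labeled trajectory sets run end to end with
`summarize_frames()` → `evaluate_splits()` (16 train/test splits, nested
9-fold hyperparameter search over σ and odd k).  A thin command-line
wrapper with `fixtures`, `grid`, `gccd`, `classify` and `embed` subcommands
is installed at `inst/cli/gccd.R`.

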