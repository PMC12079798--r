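---
title: "Spatial and sequential topology with Gaussian CROCKER column differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial and sequential topology with Gaussian CROCKER column differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gccd)
```

## The problem

Proteins with several amino-acid chains have structure at many spatial
scales: small loops closed by a handful of sequence-adjacent residues,
immunoglobulin-fold loops closed between sequence-distant segments of one
chain, and quaternary tunnels that only exist because two or more chains
assemble.  Persistent homology of the alpha-carbon point cloud detects all of
these as dimension-1 classes, but a classical Vietoris–Rips filtration sees
only spatial distance and cannot say *which part of the sequence* a loop
needs.  This package summarises a conformation jointly over two parameters:

* a continuous spatial scale $\varepsilon$ (angstroms), the usual
  Vietoris–Rips parameter, and
* a discrete residue distance $\rho$: within a chain, the absolute
  difference of author residue numbers; between chains, a single bookkeeping
  value one larger than the largest within-chain distance.

For each $\rho$ we build a masked dissimilarity matrix: entry $(i, j)$ is the
Euclidean distance between alpha carbons $i$ and $j$ if their residue
distance is at most $\rho$, and a large sentinel $M$ otherwise.  Each matrix
generates one Vietoris–Rips filtration; as $\rho$ grows the filtrations are
nested, and at the inter-chain value the classical filtration is recovered.

## From barcodes to GCCD matrices

Each filtration's dimension-1 persistence barcode is a multiset of intervals
$[b, d)$.  The Betti number at scale $\varepsilon$ counts bars with
$b \le \varepsilon < d$; sampling it on a grid gives a Betti vector, which is
discontinuous in the underlying data and therefore unstable.  We smooth by
replacing each count with Gaussian mass: centring an isotropic bivariate
Gaussian of scale $\sigma$ at each diagram point $(b, d)$ and integrating
over the counted region $\{x \le \varepsilon,\ y > \varepsilon\}$.  Because
that region is a product of half-planes, each bar contributes the exact
closed form

$$\Phi\!\left(\frac{\varepsilon - b}{\sigma}\right)\,
  \left(1 - \Phi\!\left(\frac{\varepsilon - d}{\sigma}\right)\right),$$

which the test suite verifies against numerical double integration.  The
Gaussians are deliberately not truncated or renormalised near the diagonal
or zero: the smoothed curve is plainly the integral of the sum of Gaussians.
An optional non-negative weight $w(b, d)$ per bar (for example the lifetime
$d - b$) rescales contributions; the default is $w \equiv 1$.

Stacking the Gaussian Betti vectors for $\rho = 1, 2, \ldots$ as columns
yields the **Gaussian CROCKER matrix** (rows: $\varepsilon$ grid, columns:
residue distance).  Smoothing acts only along the spatial axis; residue
distances are integers and each column comes from its own filtration — no
persistence is computed across $\rho$.  Differencing successive columns
(keeping the first) produces the **GCCD matrix**, which records where along
the sequence-distance axis each class of cycles first appears: a loop that
needs connections of residue distance $g$ contributes nothing to columns
below $g$ and appears in column $g$.  Row-wise cumulative sums invert the
differencing exactly, and the sum of all GCCD columns is the classical-Rips
Gaussian Betti vector — both identities are enforced in the tests at
$10^{-10}$.

## Tunable parameters

* **$\varepsilon$ grid** — selected from data by `select_epsilon_grid()`:
  classical dimension-1 barcodes of a sample of conformations are computed,
  the minimal birth is floored and the maximal death ceiled to whole
  angstroms, and both ends are extended by $4\sigma_{\max}$ so the widest
  smoothing Gaussian fits inside the grid.  The lower end is clamped at one
  spacing so the grid stays positive.  The default spacing is 0.1 Å, which
  resolves every bar length we generate while keeping matrices small; the
  row count is a documented choice, not part of the method.
* **Death cap** — persistence is computed up to `max(grid) + 0.001` Å; any
  class still alive receives that death.  The 0.001 Å guard avoids numerical
  edge effects at the top of the grid.
* **Sentinel $M$** — `choose_M()` returns the cap plus a 10 Å pad.  Any
  value strictly above the cap is equivalent (the masked pairs never enter
  the complex); a fixed default keeps runs bit-reproducible.
* **$\sigma$** (smoothing, Å) — treated as a hyperparameter.  The default
  search grid is $\{0.125, 0.25, 0.5\}$; its maximum is tied to the grid
  buffer rule above.  Smaller $\sigma$ tracks the raw Betti vector more
  closely (the tests check that total variation decreases monotonically in
  $\sigma$ and that the $\sigma \to 0$ limit recovers the Betti vector away
  from bar endpoints).
* **$k$** (neighbour count) — odd values only, so binary majority votes
  cannot tie.

## Homology engine and its oracle

No persistent-homology backend is assumed: the package carries its own
engine (`rips_barcode()`, in C++) — simplex enumeration up to one dimension
above the requested homology dimension, filtration order by diameter then
dimension then lexicographic vertices, and standard boundary-matrix
reduction over the two-element field with sparse columns and a
pivot-to-column map.  Coefficients in GF(2) are the universal choice for
Vietoris–Rips cycle arithmetic.  Zero-length bars are empty intervals and
are discarded.  Dimension 0 keeps one bar per component, all born at 0, the
everlasting component capped like any other.

A second, fully independent implementation (`brute_force_barcode()`, pure R,
dense GF(2) matrix, classic left-to-right reduction, at most 15 points)
serves as the oracle: the suite checks bar-for-bar agreement on hundreds of
random clouds in dimensions 0–2, plus analytic cases (a unit square gives
one loop $[1, \sqrt 2)$; a unit-edge regular hexagon gives one loop born at
1; a path's filtration can never contain a loop).

## The classification protocol

Each frame of a labeled trajectory becomes a flattened summary vector
(row-major over $\varepsilon$ then $\rho$): the dimension-1 GCCD matrix, or
one of two spatial-only baselines — the classical dimension-1 Gaussian Betti
vector, and the concatenation of dimension-0/1/2 Gaussian Betti vectors,
each divided by its own diagram size so dimensions share a scale (an empty
diagram contributes a zero block; 0/0 is defined as 0, the only continuous
choice).  Barcodes are computed once per frame and re-vectorized per
$\sigma$, since the barcode does not depend on $\sigma$.

Prediction is k-nearest neighbours on Euclidean distances between summaries,
with splits at the *trajectory* level: with four trajectories per class,
each of the 16 test splits holds out one (glycosylated, aglycosylated) pair,
and hyperparameters $(\sigma, k)$ are chosen by the mean accuracy over the
nine leave-one-pair-out validation splits of the remaining 3 + 3
trajectories.  Test frames therefore never influence hyperparameter
selection.  Grid-search ties break toward the smallest $\sigma$, then the
smallest $k$ (least smoothing, fewest neighbours); k-NN distance ties break
by the stable (trajectory, frame) order.  Both rules exist purely for
determinism.  Embeddings for visual inspection use classical metric MDS on
the precomputed distance matrix and PCA with explained-variance ratios.

## What the synthetic generators emulate

`make_chain_loop()` plants a single-chain loop whose closing residue
distance is controlled exactly.  With consecutive numbering (`gap = 1`) the
loop needs its wrap-around connection and closes at residue distance
$n - 1$.  For an even `gap` $= 2s$, residue numbers follow a stride-$s$
zigzag around the circle, so every admissible connection graph below the gap
is a path or empty — provably loop-free — and the loop closes exactly at the
gap, born at the polygon edge length.  Odd gaps above 1 admit no such
arrangement (a cyclic arrangement of distinct integers always has two
adjacent steps summing over each turn), so the constructor rejects them.
`make_two_chain_ring()` splits a circle between two consecutively numbered
chains, confining the ring to the inter-chain column.
`make_labeled_frames()` builds trajectory pairs whose planted loop radii
differ by a class effect, with i.i.d. isotropic Gaussian positional noise
per frame — noise is a perturbation model, not molecular dynamics.

What these fixtures do *not* reproduce: realistic bond geometry, secondary
structure, the hundreds of short noisy bars of a real protein diagram, or
frame-to-frame autocorrelation of a simulated trajectory.  Passing tests
demonstrate the correctness of the machinery and the localisation behaviour
of the GCCD construction, not classification performance on real
conformations.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic
fixtures: clouds of 4–16 points, 12-frame trajectories, grids of 50–300
rows.  These sizes keep the whole suite at around half a minute while still
exercising every code path end to end; real multi-hundred-residue
conformations run through the same functions, at minutes per frame on one
core (columns are computed independently per $\rho$, so the construction
parallelises naturally, though the shipped implementation is serial).  All
randomness — fixture noise, frame sampling, random test clouds — flows from
explicit integer seeds, and repeated runs are bit-identical; matrices are
rounded to ten decimal places only on save.

## Known limitations

* Homology dimensions above 2 are not supported (the enumeration stops at
  tetrahedra).
* The brute-force oracle is limited to 15 points by design.
* Assembly expansion reads PDB `REMARK 350` transforms only; mmCIF input is
  parsed as the asymmetric unit.
* Insertion codes are not handled; the analysed residue ranges are assumed
  free of them.
* Sequence alignment between different proteins is out of scope: residue
  distances are comparable across data sets only when the sequences match.
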