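---
title: "Persistent-Laplacian interface features for binding affinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent-Laplacian interface features for binding affinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaff)
```

## The model

A protein–protein complex is reduced to its binding interface: given a
partner assignment (chains of partner A vs partner B), every heavy atom of
one partner within a cutoff `r` of the other partner is retained. On the
retained atoms we use a *modified distance*

\[
D_{\mathrm{mod}}(a_i, a_j) =
\begin{cases}
\infty & a_i, a_j \text{ in the same partner}\\
\lVert r_i - r_j \rVert & \text{otherwise,}
\end{cases}
\]

so that any simplicial construction on it can only see intermolecular
contacts. The Vietoris–Rips filtration of \(D_{\mathrm{mod}}\) has a
bipartite 1-skeleton at every scale; triangles never form, so
0-dimensional classes record cross-partner contact scales (their deaths are
merge distances) and 1-dimensional classes are even cycles that never die
(their signal lives in birth scales and counts).

Two descriptor families are computed per ordered element pair
\((e_A, e_B)\) over the element list (C, N, O, S by default):

* **Barcode counts.** Persistence intervals from boundary-matrix reduction
  over \(\mathbb{Z}_2\); bars shorter than a lifespan cutoff are discarded
  as noise, finite deaths are histogrammed over distance bins, infinite
  bars counted separately.
* **Persistent-Laplacian spectra.** For a nested pair of sublevel
  complexes \(K \subseteq L\), the \(p\)-persistent Laplacian is
  \(\Delta_p^{K,L} = \partial_{p+1}^{L,K}(\partial_{p+1}^{L,K})^{*} +
  (\partial_p^{K})^{*}\partial_p^{K}\), where the up-part acts through the
  subspace of \((p+1)\)-chains of \(L\) whose boundary stays in \(K\). Its
  kernel dimension (harmonic spectrum) equals the persistent Betti number
  — a property the test suite verifies on hundreds of random filtrations —
  while the positive eigenvalues carry geometry that plain persistence
  discards. At each bin threshold \(t\) we form the operator at the
  diagonal pair \((t, t)\) (for \(p = 0\) this is the graph Laplacian of
  the cross-contact graph at \(t\)) and summarise its eigenvalues with
  eight statistics: sum, min over significant eigenvalues, max, mean,
  population sd and variance, sum of squares, and the count of significant
  eigenvalues.

The feature vector is completed by a 74-slot physicochemical block per
partner (surface areas, interaction energies, charges, contact counts), a
pooled per-residue sequence-embedding block (3 segments × 1280 = 3840 by
default), and a layout manifest that makes ablation masks (auxiliary-only,
topology-only, embedding-only) exact sub-vectors. Binding free energy in
kcal/mol is regressed on the vector with either a six-layer, 400-unit ReLU
MLP or a gradient-boosted tree baseline, evaluated under grouped
cross-validation in which every mutant record travels with its parent
complex.

## The persistent Laplacian in practice

Homology is computed over \(\mathbb{Z}_2\) (the natural choice for
persistence pairing), but a Laplacian needs an inner product, so boundary
matrices are additionally produced over the reals with orientations induced
by the ascending global vertex order. The up-part of the persistent
operator is computed as the generalized Schur complement of the up-Laplacian
of \(L\) over the \(p\)-simplices outside \(K\) (Moore–Penrose inverse via
`MASS::ginv`); an explicit orthonormal-null-space construction of the
constrained chain subspace is implemented as an independent route and the
two agree to \(10^{-9}\) in the tests. Eigenvalues within
`zero_tol = 1e-8 * max(1, lambda_max)` of zero count as harmonic;
"significant" means above that tolerance. The "min" statistic is taken over
significant eigenvalues because the raw minimum is almost always a trivial
zero; the raw variant stays available via `min_over_positive = FALSE`.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| interface cutoff `cutoff_r` | 10 | Å | covers first and second contact shells of an interface; also used as the nonbinding-chain contact threshold so one notion of contact exists |
| element list | C, N, O, S | — | standard element-specific topology practice for proteins |
| Rips cap `max_filtration` | 12 | Å | beyond typical noncovalent interaction range; bounds complex size |
| Rips `max_dim` | 2 | — | yields H0/H1; bipartite complexes never need more |
| spectral/death bins | 2–12 in 1 Å steps | Å | progressively tighter thresholds across the contact range |
| Laplacian dimensions `p_list` | 0 | — | dimension-0 carries the cluster/merge signal; `p = 1` available at extra cost |
| lifespan cutoff | 0.1 | Å | discards near-diagonal noise bars |
| probe radius | 1.4 | Å | water probe for accessible surface area |
| sphere samples `n_points` | 960 (240 in block assembly) | — | golden-angle lattice; deterministic, ~1% accuracy |
| Coulomb constant | 332.0637 | kcal·Å/(mol·e²) | unit-consistent electrostatics |
| NW scoring | BLOSUM62, open 10, extend 0.5 | — | common default; identity uses the full alignment length as denominator |
| conversion temperature | 298.15 | K | standard state for \(\Delta G = RT\ln K_d\); Ki treated as Kd-equivalent |

Hydrogens are excluded from the topological features by default (crystal
structures usually lack them); they participate in energies only when
present. Alpha filtrations (half-edge-length filtration values over a
Delaunay triangulation, built by an exhaustive empty-circumsphere test that
is adequate for small interface patches) are provided for intra-partner
geometric features; the headline cross-interaction features always use
Rips on \(D_{\mathrm{mod}}\).

## Regression heads

The MLP follows the six-hidden-layer, 400-unit ReLU architecture with
dropout 0.1, Adam at initial learning rate \(10^{-3}\), minibatch 64, and
early stopping (patience 20) on an internal 10% validation split — grouped
by parent structure whenever group labels are available, so the stopping
signal measures cross-group generalisation. The trainer cosine-anneals the
step size over the epoch budget (60 by default), applies decoupled weight
decay \(10^{-4}\), and keeps an exponential moving average of the weights
(decay 0.999) that is used for validation and prediction; a
snapshot-ensemble mode (cyclic restarts, averaged members) is available via
`snapshots`. Features and labels are standardised with training-fold
statistics only. The GBDT baseline (xgboost) uses 500 trees, depth 6,
learning rate 0.05, subsample 0.8. Cross-validation reports pooled
out-of-fold metrics (the headline convention) alongside per-fold values.

ΔΔG mutation records convert to absolute ΔG only when the parent's ΔG is
known (\(\Delta G_{\mathrm{mut}} = \Delta G_{\mathrm{wt}} +
\Delta\Delta G\), positive ΔΔG meaning weaker binding); replicate
measurements are averaged on the ΔG scale; range-valued affinities keep the
stated boundary estimate by default, with every curation action logged
under a reason code.

## What the synthetic data emulate — and what they do not

`generate_fixture_complex()` builds toy dimers whose interface topology is
known in closed form: a two-atom contact, a 2×2 bipartite lattice (known H0
merge scales and cycle births at the face diagonals), a six-atom
alternating ring (one 1-cycle closing at the hexagon side, three more at
the diameter), and an idealised two-helix dimer for interface-size
bookkeeping. Barcodes asserted from these manifests are derived from the
construction geometry, not recomputed by the package, so they are genuine
oracles; coordinates are written in PDB format (3-decimal precision, hence
the \(10^{-3}\) Å tolerances in the tests).

`generate_synthetic_dataset()` draws grouped feature vectors around
per-group centres (centre sd 0.8, within-group sd 0.6 — records of one
parent resemble each other as mutant complexes do) and labels
\(y = f(x) + \varepsilon\), \(\varepsilon \sim N(0, 0.5^2)\) kcal/mol, for
a documented sparse map with linear, interaction, sinusoidal and quadratic
terms on a scale centred at −9 kcal/mol. It emulates the *statistical*
shape of an affinity regression task — grouped records, a smooth nonlinear
signal of a few informative features among decoys, measurement noise — and
deliberately not the content of real data: there are no real structures,
no actual language-model embeddings, and the map is far simpler than
binding physics. Passing recovery tests therefore demonstrates that the
pipeline, splits and heads are wired correctly and have capacity, not that
the features predict real affinities. Because held-out *groups* occupy
feature regions never seen in training, grouped cross-validation on these
data includes a genuine covariate-shift component; the pooled correlations
it yields are conservative relative to record-level shuffling.

## Numerical choices

* Filtrations are sorted by (value, dimension, insertion); zero-length
  bars are dropped; ties in filtration values break by dimension then
  insertion order.
* The `Inf` sentinel is the platform's `+Inf` and is never binned or
  compared into filtration values.
* `max_dim > 3` Rips construction is refused without an explicit override.
* Degenerate inputs: empty atom subsets give all-zero feature cells
  (logged), coplanar 3-D point sets fall back to a planar triangulation
  with a warning, an empty interface is returned as an empty region after
  a warning rather than an error.
* The Shrake–Rupley lattice is deterministic given `n_points`; areas are
  rotation-invariant only to sampling resolution (~1–2%), while all
  distance-based features are invariant to \(10^{-6}\).
* Alignment traceback ties resolve diagonal > up > left; gap cost is
  `open + L*extend`, matching `Biostrings::pairwiseAlignment`, which the
  tests use as an independent score oracle.
* All stochastic routines (splits, generators, training) take explicit
  seeds and restore the caller's RNG state.

## Problem sizes used by the tests and the acceptance script

Random-filtration identities run on clouds of ≤ 10 points (dimensions ≤ 2,
about a hundred filtrations); the recovery experiment uses n = 2000
records, 40 features, 5-fold grouped CV with the default heads; surface
areas use 240–960 lattice points. These sizes were chosen so the whole
suite exercises every contract at full fidelity while remaining quick on a
single CPU.

## Known limitations

* No mmCIF reader, no missing-residue repair, no protonation, no mutant
  side-chain modelling: structures are taken as given.
* The Poisson–Boltzmann slots default to a Debye-screened Coulomb
  surrogate (dielectric 80, κ for 150 mM ionic strength) that preserves
  the slot's physical meaning; externally computed PB energies can be
  supplied and take precedence.
* The bundled charge template is a coarse residue-level assignment; PQR
  input (e.g. PDB2PQR) is the recommended override for serious use.
* No protein-language-model inference is bundled; the embedding block
  accepts any per-residue embedder (a deterministic stub and a file-backed
  reader are provided).
* The exhaustive Delaunay construction behind alpha filtrations scales as
  \(O(n^5)\) and is meant for small patches only.
* The 74-slot auxiliary schema is a versioned reconstruction; it is
  configurable and its exact composition should be revisited if a
  reference specification becomes available.
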