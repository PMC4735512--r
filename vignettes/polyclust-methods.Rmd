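---
title: "polyclust: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polyclust: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polyclust studies how self-association of Polycomb group (PcG) proteins —
specifically the head-to-tail polymerization of the Polyhomeotic (Ph)
sterile alpha motif — shapes nuclear protein clusters and long-range
chromatin contacts. It combines three analysis stages with seeded
synthetic-data generators so that every stage can be exercised against a
known ground truth: a lattice Monte-Carlo simulator of the
strings-and-binders chromatin model, cluster statistics for single-molecule
localization (STORM) data, and 4C-seq contact-profile quantification.
This vignette records the models, the tunable parameters, and the design
decisions taken where the problem left the design open.

## The chromatin polymer model

The chromatin fibre is a self-avoiding polymer of `n_nodes` (default 400)
beads on a simple cubic lattice. Conformations evolve by the pivot
algorithm: a random node and one of the 47 non-identity signed-permutation
lattice symmetries rotate one chain arm; proposals that collide are
replaced by a single-site fallback move that displaces one bead by one
lattice unit while keeping squared bond lengths in {1, 2}. The chain is
initialized as a straight rod followed by a burn-in of `10 * n_nodes`
accepted pivot moves, which guarantees a valid self-avoiding start without
rejection sampling over random walks. Moves that would break binder-binder
bridge bonds (the two bonded nodes ending farther apart than
`neighbor_radius`, default `sqrt(3)` — the touching 3×3×3 neighbourhood)
pass a Metropolis test at probability `exp(-E_bond * n_broken)`. Energies
are expressed in units of thermal energy, so no explicit temperature
appears; `E_bond` defaults to 1 kT per bond. Because a cluster of *n*
molecules can hold up to *n* bonds with a partner cluster (one interaction
surface per molecule), the energy barrier against separating two large
bonded clusters scales with the smaller cluster's size.

### Binders: spreading, bridging, stability

`N_endog` endogenous Ph molecules and `N_exog` exogenous molecules
(wild-type Ph or the polymerization-dead Ph-ML, depending on the model
variant) form a well-mixed reservoir; there is no explicit diffusion.
Three rules govern their kinetics:

* **Association is molecule-centric mass action with cooperative
  avidity.** Each free molecule binds somewhere on the polymer in a given
  sweep with hazard `min(1, k_a * sum_v W_v)` and chooses its node with
  probability proportional to `W_v = A_v * (1 + occ_v)`, where `A_v` is
  the node's affinity (an i.i.d. uniform(0, 1) constant fixed at
  initialization) and `occ_v` its occupancy. `k_a` is therefore a per-step,
  per-free-molecule rate. The `1 + occ` factor implements the observation
  that every bound molecule presents an additional surface that recruits
  further molecules; it is what makes spreading cooperative and lets
  strong-affinity nodes win the competition for a limited pool. Node
  weights are frozen at the start of each sweep (a tau-leap
  approximation); occupancy caps and the capping gate are checked live,
  and a blocked draw leaves the molecule free.
* **Dissociation is stabilized by polymerization.** A resident molecule
  unbinds with probability `k_d / occ_v`. Without this stabilization the
  free pool pins every node at marginal criticality and deep clusters
  cannot form at any parameter setting we explored; with it, occupancy
  condenses onto high-affinity nodes, which is the regime in which
  limited versus unlimited spreading become distinguishable mechanisms.
* **Bridging consumes interaction surfaces.** After binding, molecules
  with a free surface at distinct nodes within `neighbor_radius` form a
  bond with probability `k_join`; existing bonds break with probability
  `k_break`. Each molecule carries one surface by default, so a molecule
  holds at most one bridge, and two clusters can be joined by at most
  `min(n1, n2)` bonds. Node saturation does not block bridging.

In limited-spreading variants a node accepts at most `N_max = 15`
molecules, the value used throughout for the spreading cap. A cluster is a
maximal set of bound molecules connected by co-occupancy of a node or by
bridge bonds.

### Mutant mechanisms

Ph-ML carries a mutated mid-loop polymerization interface, which is
precisely the surface that distant-molecule polymerization (bridging)
requires; Ph-ML therefore contributes no bridging surface in either mutant
variant. The two competing mechanisms differ in what else the mutation
does:

* `weak_binding_ML`: Ph-ML binds and spreads like wild type but leaves
  clusters ten-fold faster (`k_d_exog = 10 * k_d_endog`).
* `capping_ML`: Ph-ML has wild-type kinetics, but each Ph-ML that joins an
  existing cluster removes one interaction surface from a uniformly chosen
  uncapped resident Ph. Association of either species to a cluster whose
  Ph are all capped is blocked, so the association rate reaches zero when
  Ph-ML equals Ph in a cluster. A cap resets only when the capped molecule
  itself returns to solution.

### Default kinetics

The kinetic defaults (`k_a = 0.002`, `k_d = 0.01`, `k_join = 0.005`,
`k_break = 0.2`, `E_bond = 1`) were calibrated once so that the baseline
simulation sits in the biologically sensible regime — tens of clusters, a
molecule-weighted median cluster size between nucleation (2) and the
spreading cap (15), and rare but observable bridging — and so that the
four variants separate qualitatively. The qualitative conclusions are
insensitive to moderate changes in these values; what matters is the
ordering of the regimes (cooperative association strong enough for
condensation, dissociation slow enough for cluster persistence, bridging
sparse enough that clusters do not percolate into one aggregate).

### Observables

Snapshots are taken every `snapshot_every` steps (default 50) after a 50%
burn-in. Reported per iteration:

* cluster counts with (`n_clusters`) and without (`n_clusters_multi`)
  single molecules;
* the molecule-weighted median cluster diameter over clusters of two or
  more molecules, with `diameter = diameter_scale * n^(1/3)` (molecule
  content scales with the cube of diameter). Excluding single molecules
  and weighting clusters by their content mirror the conventions used for
  the imaging data, where single-bin clusters sit below the resolution
  limit and size distributions are localization-weighted;
* three bridging readouts: the node-pair contact matrix and its scalar
  mean over ever-occupied node pairs (`contact_frequency()`), the
  per-snapshot contact frequency among *cluster sites* (nodes holding at
  least two molecules; undefined and dropped when fewer than two such
  sites exist), and the raw number of bridged node pairs per snapshot
  (`bridged_pairs`), which is the most stable of the three and the one
  used for contact-gain comparisons.

### The two mechanism studies

`mechanism_study()` packages the two concentration-response experiments.
Both use 200 nodes and 20 iterations — half the full polymer at a size
where a complete study runs in a few minutes on one core; the qualitative
signatures are unchanged at 400 nodes.

* **ML study** (4000 steps, `N_endog = 30`, Ph-ML grid 0, 10, 30, 90,
  270): the weak-binding variant's weighted median diameter rises and then
  stays at the spreading cap, while the capping variant rises at
  sub-stoichiometric Ph-ML (the gate closes exactly at 1:1, so the rise
  window lies below that ratio — hence the grid point at Ph-ML:Ph = 1:3)
  and then falls sharply as clusters are capped young. Capping also
  abolishes cluster-site contacts, far more strongly than weak binding.
* **WT study** (8000 steps — condensation coarsens slowly — `N_endog =
  100`, extra-Ph grid 0, 30, 60, 150, 400): with the cap retained
  (`wt_limited`), extra Ph multiplies cluster sites and long-range
  bridged contacts while sizes change modestly; with the cap removed
  (`wt_unlimited`), mass condenses into a few large clusters whose
  contact gain stays far below the limited model's at matched
  concentration.

Each signature is judged by one-sided Wilcoxon rank tests over iterations
at the 0.05 level. One operationalization deserves note: for the
unlimited-spreading model the claim "grows clusters without the contact
gain" is tested as a contrast against the limited model at the top
concentration rather than as a within-variant null result, because with
one to three cluster sites the per-pair contact frequency of the condensed
regime is too ill-determined for a stable within-variant test.

## STORM cluster analysis

Localizations are binned on a square grid and clusters called as
8-connected components of non-empty bins, including isolated single bins.
The bin size adapts to each cell's localization count,
`15 nm * sqrt(n_avg / n_cell)` clamped to [10, 30] nm, so denser cells get
finer bins; colocalization always uses fixed 15-nm bins on a grid shared
by both channels. Binning is half-open with the origin at the minimum
coordinate; a point exactly on a boundary belongs to the higher-index bin.

Cluster diameter is the equivalent-square edge `bin_size * sqrt(n_bins)`;
a single bin therefore has diameter `bin_size`. The equivalent-circle
alternative differs by the constant `2/sqrt(pi)` (about 1.13), and since
the estimator convention behind published absolute medians is not
recoverable, absolute nanometre medians are not targeted — recovery is
assessed against planted truth instead, where the square-edge estimator is
within a few percent once clusters are dense enough to fill their
footprint. Size distributions weight each cluster by its localization
content; the weighted median is the smallest diameter at which the
cumulative localization weight reaches one half. Colocalization excludes
single-bin clusters (below the 30 nm resolution limit), calls two
clusters colocalized when they share at least one bin, and reports per
channel the fraction of multi-bin-cluster localizations sitting in
colocalized clusters. Robustness to localization density is checked by a
random 50% split of events; the two halves' weighted diameter
distributions are compared with a two-sample Kolmogorov-Smirnov distance,
with 0.15 as the "very similar" threshold. Halving every cell halves the
cohort average too, so the adaptive rule returns the same bin size for
halves as for full data.

## 4C-seq contact quantification

Restriction-fragment count tracks (0-based, half-open coordinates
internally; printed 1-based coordinates are converted on ingest) are
normalized per sample to a common total of 1e6 reads inside the reference
region around the Bithorax complex (chr3R:12367359-12885749, dm3). The
scale constant is arbitrary — all downstream statistics are ratios.
Fragments within 5 kb of the viewpoint are masked by the any-overlap rule,
replicates are averaged per condition, and the contact-change track is
`test/control - 1`, with zero-control fragments flagged undefined rather
than infinite. A 3-fragment running mean (truncated at track ends) is
available for display tracks but is deliberately *not* applied before
inference: the running mean induces serial correlation between
neighbouring fragments that would invalidate the near/far comparison's
error model.

Near and far regions split the BX-C (12480479-12821577) at a fixed
boundary — 12681222 (the iab-3/iab-4 boundary) for the Abd-B and Fab-6
viewpoints, 12598911 (the bxd transcript start) for Ubx — with "near" the
side containing the viewpoint. Pooled near and far contact-change values
are compared with a two-tailed Welch t-test; each group is first checked
with an Anderson-Darling normality test and, on violation (p < 0.05), an
exact Wilcoxon rank-sum test is substituted (exact only when both groups
have at most 50 values; beyond that the normal approximation is
indistinguishable and the exact null distribution is not computable).
Identical constant groups short-circuit to p = 1.

Changed-contact windows tile the BX-C in disjoint 200-bp windows; a window
is "decreased" when the replicate-averaged test/control ratio of its
overlapping fragments falls below 0.5 and "increased" above 1.5 (the
symmetric reading of the >50% rule). Window midpoints are measured to the
centre of the nearest peak — all peaks are candidates regardless of height
— and changed versus unchanged distances compared by t-test. Significant
contacts (consumed as merged windows from an external caller, whose FDR
parameters are carried in configuration for provenance only) are converted
to restriction-fragment counts by the any-overlap rule, partitioned into
the BX-C neighbourhood (within 2 Mb of the BX-C border) versus distal
(beyond 2 Mb, same chromosome), and intersected with peak sets for overlap
fractions.

## Synthetic data

The localization generator plants clusters in a circular nuclear section
(7 µm, a typical cultured-cell nucleus) with log-uniform diameters spanning
30-700 nm and 200 clusters per cell, matching the observed order of
hundreds of clusters spanning that size range. Molecules per cluster scale
with diameter cubed (3 molecules at 30 nm); each molecule emits a
geometric number of localizations (mean 4, the simplest memoryless
blinking model), jittered with 10 nm Gaussian noise (the imaging
precision); background localizations are uniform at 2 per µm². Planted
clusters are placed by largest-first dart throwing with a minimum
edge-to-edge gap of 100 nm — more than twice the 3-sigma jitter spill plus
two bins — because planted objects must remain resolvable as distinct
clusters for the planted truth to be well defined. The generator does not
emulate drift, chromatic offsets, repeated-blinking overcounting
structure, or spatial clustering of the background, so recovery results
speak to the binning/component-calling logic, not to microscope
calibration. The two-channel generator emits a chosen fraction of clusters
in both channels (independent blinking from the same molecule positions)
and alternates the remainder between channels.

The 4C generator tiles the reference region with geometric-length
fragments (mean 256 bp, a 4-cutter's expected spacing), places 10
non-overlapping 500-bp peaks in the BX-C, and draws negative binomial
counts (size 10) around a power-law contact decay from the viewpoint
(exponent 1, scale 2 kb) with 3-fold enrichment at peak fragments and
5e5 expected reads per sample. The test condition multiplies far-region
intensity by the planted depletion factor (0.5) and, optionally,
peak-overlapping fragments by a peak-depletion factor (off by default, so
the two planted effects can be studied separately). Because samples are
then rescaled to equal in-region totals, a planted far depletion of 0.5
appears as a far-region mean ratio slightly above -0.5 (the normalization
redistributes the removed reads); the recovered value stays within 0.1 of
the planted effect under the default geometry. Under a null generator
(both factors 1) the near/far p-value is uniform across seeds.

## Numerical notes and limitations

* All randomness flows through R's RNG (also inside the compiled core), so
  a seed fully determines every output; simulation iteration `i` uses
  `seed + i`.
* The binding sweep freezes node weights per step and caps the per-step
  hazard at 1; both are discretization choices visible only at extreme
  rates, and the occupancy chain they induce is reproduced exactly by the
  transition-matrix oracle used in the tests.
* Tie-breaks: the capping victim is uniform among uncapped resident Ph;
  the first free molecule of a species binds (molecules are
  exchangeable); candidate bridge pairs are scanned in node order with
  live surface checks.
* Cluster-site contact frequency is undefined (and dropped) in snapshots
  with fewer than two multi-molecule sites; the condensed regime of
  unlimited spreading approaches that limit, which is why contact-gain
  comparisons use the bridged-pair count.
* The simulator is a lattice model with a single binder type per study; it
  does not model nucleosomes, epigenetic states, the SCM protein, or
  rate fitting to experimental data.
* 2D analysis throughout for STORM (the imaged optical section is
  effectively a slab); localization counts are relative, never absolute
  molecule counts.
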