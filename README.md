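# polyclust

Polycomb group (PcG) proteins silence developmental genes and assemble
into nuclear clusters. The clustering is driven by head-to-tail
polymerization of the sterile alpha motif (SAM) of Polyhomeotic (Ph), and
it couples two scales: local *spreading* of molecules along chromatin and
*bridging* between distant chromatin sites, which creates long-range
contacts. polyclust is an R package for researchers studying that
coupling. It provides, as one tested pipeline:

* a lattice Monte-Carlo simulator of the **strings-and-binders** chromatin
  model — a self-avoiding polymer of nodes with uniform(0,1) affinities
  `A_v`, plus diffusing binders that associate by mass action with
  cooperative avidity (`P(bind at v) ∝ A_v (1 + occ_v)`), dissociate with
  polymer-stabilized kinetics (`k_d / occ_v`), spread up to `N_max = 15`
  copies per node, and bridge nodes within `√3` lattice units with
  per-bond energy `E_bond` (kT) under Metropolis dynamics. Four variants
  implement the competing mutant mechanisms: weak-binding Ph-ML,
  oligomer-capping Ph-ML (each Ph-ML joining a cluster removes one
  interaction surface from a resident Ph; association stops at 1:1), and
  limited versus unlimited spreading of extra wild-type Ph;
* **STORM cluster analysis**: adaptive binning
  (`15 nm × √(n_avg/n_cell)`, clamped to 10–30 nm), 8-connected
  component cluster calling, localization-weighted size distributions,
  and two-channel colocalization with single-bin clusters excluded;
* **4C-seq quantification**: normalization over the BX-C reference region,
  3-fragment running-mean smoothing, viewpoint masking, `test/control − 1`
  contact-change tracks, near/far contact statistics with
  Anderson–Darling-guarded t/Wilcoxon tests, >50%-changed 200-bp windows,
  nearest-peak distances, and long-range contact partitioning
  (≤2 Mb neighbourhood vs distal);
* **seeded synthetic-data generators** with planted ground truth for every
  stage (localization tables with planted clusters, two-channel data with
  a planted shared fraction, restriction-fragment maps, 4C tracks with
  planted far-region depletion), plus a YAML-config runner and CLI.

## Worked example

Generate a synthetic nucleus, run the cluster pipeline, and compare with
the planted truth; then quantify a planted far-contact depletion in
synthetic 4C tracks:

```r
library(polyclust)

g <- gen_localizations(loc_gen_params(seed = 1))   # ~2.9 M localizations
b <- adaptive_bin_size(nrow(g$table), nrow(g$table))
cs <- call_clusters(rasterize(g$table, b))
nrow(cs$clusters)                                  # 255 clusters called
count_clusters_above(cs, 30)                       # 200 above 30 nm
weighted_size_distribution(cs)$weighted_median     # 501.5 nm
g$weighted_median_diameter                         # planted: 515.8 nm

g4 <- gen_4c_tracks(fourc_gen_params(seed = 1))    # planted 0.5 far depletion
rt <- fourc_ratio_track(g4$track, "PhML", "S2", g4$scheme)
near_far_summary(rt, g4$scheme)$means
#>  viewpoint region       mean n_fragments
#>        vp1   near  0.1447487         503
#>        vp1    far -0.4408603         793
```

The 200 recovered super-resolution clusters match the 200 planted ones,
the localization-weighted median diameter is recovered within 3%, and the
far-region contact-change mean sits at −0.44: the planted 50% depletion
minus the small positive shift that equal-total normalization imposes on
the remaining signal (the near side rises to +0.14 for the same reason).

The simulation studies that discriminate the mutant mechanisms run with:

```r
ml <- mechanism_study("ML", seed = 1)   # weak-binding vs capping Ph-ML
wt <- mechanism_study("WT", seed = 1)   # limited vs unlimited spreading
plot_concentration_sweep(ml, "weighted_median_diameter")
```

In the capping model the weighted median cluster diameter rises at
sub-stoichiometric Ph-ML and then falls sharply, and cluster-site contacts
collapse; in the weak-binding model sizes rise to the spreading cap and
plateau. Limited spreading of extra wild-type Ph multiplies cluster sites
and bridged contacts; unlimited spreading condenses mass into a few large
clusters without the contact gain.

## Command line

```sh
Rscript inst/cli/polyclust.R synth   --config cfg.yaml --out out/
Rscript inst/cli/polyclust.R storm   --config cfg.yaml --out out/
Rscript inst/cli/polyclust.R fourc   --config cfg.yaml --out out/
Rscript inst/cli/polyclust.R simulate --config cfg.yaml --out out/
```

Configs are YAML with `subcommand`, `seed` and a per-module `params`
block; unknown keys are rejected. Every run writes tidy CSV outputs, a
resolved-config copy and a log with the seed and package version, and
reruns with the same seed reproduce outputs byte-identically.

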