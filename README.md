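# cgagg

Trajectory analysis for coarse-grained (MARTINI-style) simulations of
lipid-anchored membrane proteins that aggregate in a planar bilayer —
built around the observables used to characterize Ras nanoclustering in
model membranes, with a synthetic trajectory generator so every stage is
testable against known ground truth.

## What it computes

Given frames (GRO files or in-memory objects) and a per-bead topology
table, the package provides:

* **Cluster detection** — two proteins are in contact when any two of
  their backbone beads lie within a cutoff (default 0.75 nm,
  minimum-image distance); clusters are connected components of the
  contact graph. Output: per-frame cluster counts, size multisets,
  labels, and an aggregation time (first time the count holds at a
  target for a dwell of frames).
* **Residue contact-probability maps** — counts `C_ij` of contacts
  between residue *i* in one molecule and residue *j* in another,
  accumulated per frame and molecule pair, normalized to

  `P_ij = C_ij / (F · C(M,2) · N_r²)`

  with `F` frames, `M` proteins and `N_r` residues per protein, so
  `0 ≤ P_ij ≤ 1/N_r²`. High-contact pairs are extracted with a strict
  threshold (default `10⁻⁸`-scale), and the ratio
  `R = (ΣC_ij/F)_a / (ΣC_ij/F)_b` compares total per-frame contacts
  between two ensembles.
* **Lateral diffusion** — center-of-mass tracks are unwrapped through
  periodic boundaries, the time-origin-averaged mean-square displacement
  `MSD(t) = ⟨|r(τ₀+t) − r(τ₀)|²⟩` is fit by least squares, and
  `D = slope/(2d)` with `d = 2`, reported in 10⁻⁸ cm²/s with a
  block-averaged (over molecules) standard error.
* **Coarse-grained SASA and interface burial** — Shrake–Rupley areas
  with a 0.56 nm probe (≈4× the atomistic water probe, matching
  four-heavy-atom beads) on a deterministic Fibonacci point lattice;
  per-residue window averages, ΔSASA = late − early, and buried-residue
  extraction at a burial-magnitude threshold (default 0.75 nm²).
* **Lipid domain statistics** — per-species lipid bead contacts with
  protein residues, the liquid-ordered : liquid-disordered
  (DPPC : DLiPC) contact ratio with block-averaged error, and a
  per-leaflet DPPC–DLiPC mixing ratio that tracks domain de-mixing.
* **Synthetic data** — a sticky Brownian generator (rigid protein blobs,
  per-cluster `D ∝ size^−α`, irreversible merging, ground-truth sidecar),
  a striped ternary DPPC/DLiPC/CHOL field with tunable de-mixing
  progress, and analytic SASA fixtures.

All analysis results are tibbles (or carry `tidy()`/`glance()` methods),
so they compose with dplyr/ggplot2; `autoplot()` methods cover the
common figures. `run_pipeline()` chains all stages from one config and
writes TSV artifacts plus a schema-validated, byte-deterministic JSON
report; `inst/scripts/cgagg.R` is a command-line shim over the same
functions.

## Worked example

Simulate 16 membrane-anchored 186-residue proteins aggregating in a
22 × 23 nm periodic plane (monomer D = 10.5 × 10⁻⁸ cm²/s, 150 steps of
4 ns), then run the three core analyses:

```r
library(cgagg)

cfg <- sticky_sim_config(n_proteins = 16, n_residues = 186,
                         box_xy = c(22, 23), d_free = 10.5,
                         dt = 4, n_steps = 150, seed = 42)
sim <- simulate_sticky_brownian(cfg)

cs <- cluster_timeseries(sim$trajectory, sim$topology, cutoff = 0.75)
cs[c(1, 75, 151), 1:3]
#>   time_ns n_clusters largest_size
#> 1       0         16            1
#> 2     296         12            2
#> 3     600         10            3

est <- fit_diffusion(msd_profile(unwrap_trajectory(sim$trajectory,
                                                   sim$topology),
                                 max_lag = 200),
                     fit_window = c(20, 120))
est
#> <diffusion_estimate> D = 7.198 x 1e-8 cm^2/s (block stderr 1.1), fit lags 20-120 ns

pm <- contact_probability(accumulate_residue_contacts(sim$trajectory,
                                                      sim$topology))
pm
#> <contact_map> N_r = 186, M = 16, F = 151, max P = 6.19e-07
```

The cluster count decays from 16 to 10 as dimers and trimers form; the
ensemble diffusion coefficient (7.2 ± 1.1) sits below the 10.5 monomer
input because merged clusters move as slower rigid units; and the
contact map concentrates probability on blob-periphery residues, capped
by the normalization bound `1/N_r² ≈ 2.9 × 10⁻⁵`.

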