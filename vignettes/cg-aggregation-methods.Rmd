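---
title: "Methods: cluster, contact, diffusion and surface-area analysis of coarse-grained membrane-protein aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained aggregation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgagg)
```

cgagg quantifies how lipid-anchored proteins (the motivating system is
full-length H-Ras, a 186-residue GTPase whose farnesylated/palmitoylated
C-terminal anchor ties it to the inner bilayer leaflet) assemble into
nanoclusters in coarse-grained molecular-dynamics trajectories. This
vignette is the package's own account of the models and numerical
choices behind each stage, what the synthetic generator does and does
not emulate, and the limits of what passing tests demonstrate.

## Geometry and conventions

Coordinates are in nm, times in ns, and boxes are orthorhombic only:
periodic distances use the minimum-image convention (each displacement
component wrapped into `(-L/2, +L/2]`), so inputs may arrive wrapped.
Triclinic boxes are rejected rather than silently approximated — the
target systems are rectangular. Residues are numbered 1-based to match
structural-biology convention (e.g. switch I at residues 30–40 of the
G-domain); bead indices are 0-based internally. Diffusion coefficients
are reported in 10⁻⁸ cm²/s; internally the package works in nm²/ns with
the conversion 1 × 10⁻⁸ cm²/s = 10⁻³ nm²/ns, which is itself under
test.

Topology (molecule id, molecule type, residue index, bead role, bead
radius) is supplied as an explicit table rather than inferred from GRO
atom names, because coarse-grained naming schemes are ambiguous about
bead roles. The GRO reader tolerates the 5-character residue/atom id
fields wrapping at 100000 by reconstructing residue serials from
change-detection, so systems of several hundred thousand beads parse
without corruption. Frame spacing is treated as data-defined (the
toolkit checks that it is constant) rather than assumed.

## Cluster detection

Two proteins are *in contact* when any two of their backbone beads lie
within a cutoff, default 0.75 nm — the standard coarse-grained
backbone–backbone contact criterion — and clusters are the connected
components of the contact graph. Design points:

* The criterion applies to backbone beads only (one per residue in the
  coarse-grained mapping), even where including side-chain beads would
  detect more contacts; this keeps the criterion well-defined across
  mappings.
* A pair exactly at the cutoff counts as in contact (closed interval,
  the natural reading of "within").
* Monomers count as size-1 clusters in `n_clusters`; since the size
  multiset is returned per frame, the "aggregates only" convention is
  recoverable by dropping size-1 entries.
* Labels are canonicalized to the smallest member id and are *not*
  tracked across frames; the target observables need only per-frame
  counts.
* "Aggregation complete" is operationalized as the count reaching a
  target (default 1) and holding for a dwell of consecutive frames
  (default 5), because reported aggregation times in this field are
  approximate and a noisy series can touch the target transiently.
  `NA` means "not reached".

The neighbor search uses a periodic cell list (compiled), falling back
to an exact all-pairs scan for small systems; both paths are checked
against a brute-force oracle.

## Residue contact-probability maps

For every frame and unordered pair of protein molecules, residue pair
`(i, j)` registers a contact when the backbone bead of residue `i` in
one molecule and that of `j` in the other are within the cutoff. The
count is binary per (frame, molecule pair, unordered residue pair):
with one backbone bead per residue the two bead orientations of the
same residue pair are a single physical event. Counts are stored
symmetrically. The probability map is

$$P_{ij} = \frac{C_{ij}}{F \cdot \binom{M}{2} \cdot N_r^2}$$

— contacts per frame, per molecule pair, per equally-likely residue
pairing — so `P` is symmetric and bounded by `1/N_r²` (≈ 2.9 × 10⁻⁵ at
`N_r = 186`). This normalization is a reconstruction from the prose
definition of the normalization term (the probability that a random
residue in one molecule contacts a random residue in a different
molecule); it is consistent with the 10⁻⁹–10⁻⁸ scale on which
high-contact thresholds in this literature are set, but readers should
treat it as this package's documented convention rather than a claim
about any particular prior implementation. High-contact extraction is a
strict `>` filter sorted by descending `P` with lexicographic
tie-breaks.

The ensemble-comparison ratio divides total per-frame contacts,
`R = (ΣC/F)_a / (ΣC/F)_b`, making windows of unequal length comparable;
it satisfies `R(a,a) = 1` and `R(a,b)·R(b,a) = 1` exactly.

## Lateral diffusion

Molecule tracks are lateral (xy) centers of mass. Within a frame the
center of mass is computed relative to the molecule's first bead via
minimum-image offsets (correct for molecules straddling the boundary);
across frames, minimum-image inter-frame displacements are accumulated
to unwrap periodic jumps. This assumes every molecule moves less than
half a box edge between saved frames — trajectories saved too sparsely
cannot be unwrapped unambiguously, and the generator emits wrapped
frames precisely so this logic is exercised. Center of mass (rather
than a reference bead) is the adopted convention and is documented as
such.

The estimator is the Einstein relation: time-origin-averaged
`MSD(t) = ⟨|r(τ₀+t) − r(τ₀)|²⟩` over all molecules and valid origins,
an ordinary least-squares fit of MSD against lag over a fit window, and
`D = slope/(2d)`, `d = 2`. The default window, lags in 10–50% of the
maximum lag, avoids the short-lag regime (poorly resolved at coarse
frame spacing) and the long-lag tail (few origins, high variance); on
very short profiles where that window holds fewer than 3 lag points the
fit falls back to all lags. Published fit windows in this area are
chosen per-curve, so the window is always user-settable.

Uncertainty comes from block averaging over *molecules* (default 5
blocks): aggregated proteins are strongly correlated in time, so
time-blocking would underestimate the error; molecule-blocking is
honest as long as molecules are approximately independent, which holds
before aggregation and degrades after — the reported error should be
read as a lower bound late in an aggregating trajectory.
Diffusion in different aggregation regimes is selected by time window
(for example 40–160 ns for monomers, later multi-µs windows during and
after aggregation), not by per-molecule state classification.

At the scale the package targets for verification — 500 independent
walkers, 30 frames at 4 ns, fit over 8–48 ns lags — the estimator
recovers known inputs across the 0.2–11.2 × 10⁻⁸ cm²/s range with
median relative error below 5% (worst case below 15% over 20 seeds);
those problem sizes are the package's verification design, chosen to
make sampling error a controlled, testable quantity.

## Coarse-grained SASA and ΔSASA

Per-bead accessible areas use Shrake–Rupley: `n` quasi-uniform points
on each bead's expanded sphere (radius `r_bead + probe`); a point is
accessible if outside every occluder's expanded sphere; area is the
accessible fraction of `4π(r+probe)²`. Numerical choices:

* The probe is 0.56 nm by default — the coarse-grained convention of
  roughly four times the 0.14 nm atomistic water probe, matching beads
  that map four heavy atoms.
* Bead radii are explicit topology inputs (default 0.26 nm, half the
  standard coarse-grained bead interaction diameter); no radius is
  hard-coded in the computation, and because the radii any given study
  used are generally unstated, no verification target depends on
  absolute areas.
* Sphere points come from a deterministic Fibonacci spiral — no RNG, so
  results are bit-reproducible at fixed `n`; 960 points put isolated-
  sphere errors well under 0.5% and two-sphere errors under 2%, and
  refinement 240 → 960 → 3840 converges monotonically.
* Lipid beads occlude (a membrane-facing residue is genuinely buried);
  solvent/ion stand-ins (`OTHER`) do not. Both lists are configurable,
  and whether any given published analysis included lipid occlusion is
  usually unstated — these are this package's documented choices.
* Periodic images occlude via minimum image.

ΔSASA between analysis windows is `late − early` per residue (window
averages on frames sampled at a declared spacing, summed over beads
within a residue so residue totals conserve bead totals, then averaged
over protein copies). Under this sign convention interface burial is
*negative*; because figure-level conventions in the literature
sometimes quote the threshold on the positive magnitude, the package
reports both the signed delta and the burial magnitude
`max(−Δ, 0)` and applies the default 0.75 nm² threshold to the
magnitude. Profiles computed with different probes refuse to subtract.

## Lipid-domain statistics

Protein–lipid contacts count lipid beads (any role) within the cutoff
of any bead of a chosen protein residue range, each lipid bead counted
once globally even if it touches several proteins. The domain
preference ratio is `count_DPPC / count_DLiPC` averaged over a window,
with a block-averaged standard error over contiguous time blocks; a
ratio near 1 indicates boundary localization. When no DLiPC contact
occurs at all the ratio is undefined and reported as `NA` with the
counts retained (a degenerate input, not an error).

De-mixing is tracked per leaflet as the fraction of DPPC contact slots
occupied by DLiPC, `hetero / (hetero + 2·homo_DPPC)`; in a randomly
mixed field its expectation is `n_DLiPC / (n_DPPC + n_DLiPC − 1)`, and
it declines toward a boundary-only floor as stripes form. Leaflets are
assigned by z relative to the median lipid z — adequate for the flat
synthetic bilayers here, and replaceable by an explicit leaflet column
for undulating membranes. The same 0.75 nm cutoff serves protein–lipid
and lipid–lipid contacts by default (one shared, configurable
criterion).

## The synthetic generator: what it emulates, and what it does not

`simulate_sticky_brownian()` stands in for the undeposited
coarse-grained trajectories the analyses were designed around. Its
defaults are the study conditions of the reference bilayer systems: 32
proteins of 186 residues in a 44 × 46 nm periodic plane, monomer
D = 10.5 × 10⁻⁸ cm²/s, 4 ns frames, 0.75 nm sticking scale. Protein
centers take 2D Gaussian steps; each cluster moves rigidly with
`D = d_free · size^(−α)`, α = 1 by default (Stokes-like, loosely
calibrated to the ~10-fold slowdown observed during aggregation);
clusters merge irreversibly when any two member centers come within the
bind radius, reflecting the observation that large aggregates, once
formed, are very stable in this force-field regime. Each protein is a
rigid disc of backbone beads (sunflower spiral, ≈1 nm radius, random
per-protein orientation) riding on its center at the lower-leaflet
plane — internal fluctuations are deliberately absent, as the reference
simulations themselves restrain internal structure. Frames are emitted
wrapped with ground truth kept unwrapped, so the unwrapping code path
is genuinely tested. One root seed drives every stream.

Two honesty notes. First, merging is center-based while detection is
bead-based, so detected cluster labels equal ground-truth labels
exactly only for single-bead proteins (where the two criteria
coincide); multi-bead blobs can touch transiently without merging,
which is physically reasonable but means blob runs are checked for
consistency (monotone true counts, contact statistics) rather than
label equality. Second, the aggregation kinetics are a qualitative
stand-in — no quantitative rate law is claimed, and nothing downstream
depends on matching any particular decay curve. More broadly, passing
tests on generator output demonstrates correctness of the *analysis
machinery* under known ground truth; it does not validate force-field
realism, lipid–protein coupling, membrane undulations, or any other
physics the generator does not contain.

`generate_domain_field()` emulates the end state of lipid de-mixing
into liquid-ordered (DPPC/cholesterol) and liquid-disordered (DLiPC)
stripes: default composition 3480 : 2304 : 1536 (5:3:2), one bead per
lipid, two flat leaflets, with `demix_progress` interpolating per-bead
domain assignment between fully mixed and fully striped. It is a static
spatial model — no lipid dynamics, no protein–lipid coupling.

## Pipeline reproducibility

`run_pipeline()` executes clusters → contacts → diffusion → SASA →
domains from one config (R list or YAML), logs stage parameters and
timing to stderr, and writes TSV artifacts plus a JSON report validated
against the schema shipped in `inst/schema/`. The report contains no
timestamps, so identical inputs and seed give byte-identical reports —
the determinism contract is itself a test. A failing stage aborts with
the stage named and leaves a `MANIFEST` marking the run incomplete.
The bundled `tiny` fixture profile (8 proteins, 2000 lipid beads, 200
frames in a quarter-area box to keep protein density comparable) runs
the full pipeline in well under five minutes on one CPU; `paper_scale`
reproduces the full 32-protein, 7320-lipid composition for
scale checks.

## Known limitations

* Orthorhombic boxes and flat bilayers only; no undulation-aware
  leaflet assignment.
* The generator's kinetics are qualitative; cluster-shape metrics
  (linearity of aggregates) are out of scope.
* Contact-map normalization is a documented reconstruction (see above).
* Block errors over molecules lose independence late in aggregation.
* GRO and TSV are the only on-disk formats; binary trajectory formats
  would enter through an adapter, not the core readers.
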