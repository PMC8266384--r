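---
title: "Methods: particle arrays, hinge geometry, conservation surfaces and tight-binding fits"
author: "retarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: particle arrays, hinge geometry, conservation surfaces and tight-binding fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retarrays)
```

# Scope

`retarrays` packages the bespoke computations that arise when characterising
higher-order assembly of the RET receptor tyrosine kinase with its
GDNF-family ligand/co-receptor complexes: (i) detection and statistical
characterisation of linear particle arrays in cryo-EM 2D-classification
metadata, (ii) a coordinate-level simulator that provides ground truth for
that analysis, (iii) rigid-body hinge and distance measurements on atomic
models, (iv) a residue-class conservation score mapped onto structure
surfaces, and (v) dissociation-constant estimation in the tight-binding
(receptor-depletion) regime.  Upstream image processing — motion correction,
CTF estimation, classification, reconstruction, model building — is out of
scope; the package starts from the text outputs those tools produce (STAR
files, coordinate files, alignments, titration tables).

# Linear-array statistics from 2D-classification metadata

## Model and procedure

During 2D classification every picked particle acquires an in-plane rotation
angle $\psi$ (the rotation aligning it to its class average) and a centroid
$(x, y)$ in pixels.  If ligand-bound receptor complexes associate end-to-end
on the grid, neighbouring particles share both a characteristic centroid
spacing and nearly equal $\psi$.  The analysis therefore:

1. enumerates every unordered within-micrograph pair with centroid
   separation at most `cutoff_px` pixels (default 170 px; at the default
   1.26 Å/px this is the 214.2 Å neighbourhood),
2. folds each $\psi$ into $[0, 360^\circ/n)$ for a $C_n$-symmetric particle
   (default $n = 2$, so $[0, 180^\circ)$) and takes the absolute difference
   $\Delta\psi = |\psi_a^{folded} - \psi_b^{folded}|$,
3. bins pairs on a (distance, $\Delta\psi$) grid with half-open bins of
   2 Å × 2.6°, anchored at zero, normalised by the maximum count, and
4. reports the dominant peak: the 4-connected component of bins with
   normalised frequency ≥ `peak_threshold` (default 0.5) containing the
   global maximum, with means and SDs computed over the raw member pairs,
   not over bin centres.

A genuine array population appears as a sharp peak (e.g. near 181 Å and
4.5°), while unassociated background pairs spread diffusely with pair
density growing linearly in distance.

## Numerical and convention choices

* **Pair counting.** Each unordered pair is counted once (`id_a < id_b`).
  Doubling every count reproduces per-particle neighbour counting, so the
  choice does not affect peak positions, only absolute counts.
* **Angle handling.** $\psi$ values are first made non-negative
  (mod 360) and kept at full precision; `round_psi = TRUE` reproduces
  workflows that round $\psi$ to whole degrees before differencing.  The
  folded absolute difference can exceed $180^\circ/n$ only through the
  fold-boundary wrap (a pair at, say, 1° and 179° under C2); the
  `circular_dpsi` option folds those onto the shorter arc.  The default
  keeps the plain absolute difference, which is what a literal
  implementation of the published procedure computes; boundary wraps
  affect a fraction of order $\Delta\psi_0 / (180^\circ/n)$ of array pairs
  and land far from the peak, so they dilute rather than bias it.
* **Binning.** Bins are half-open $[lo, hi)$ so a value exactly on an edge
  belongs to the upper bin; the grid spans $[0, \text{cutoff}]$ in distance
  and $[0, 360/n)$ in $\Delta\psi$.
* **Peak definition and tie-break.** "Bins above half the maximum" admits
  several readings; we use the 4-connected component containing the global
  maximum, which is reproducible and closest to thresholding a surface
  plot.  On equal maxima the first in distance-major scan order wins.
* **Geometry is strictly 2D.** Distances are computed in pixel space and
  converted once via the pixel size; particles are assumed to lie at the
  same Z height.
* **Search structure.** Neighbour search uses a cell list with
  cutoff-sized cells; the test suite proves exact equality with the
  all-against-all enumeration on hundreds of random tables.

## STAR I/O

The package reads both the flat dialect (a single `data_` block with one
`loop_`) and the optics-group dialect (pixel size taken from the optics
block when present).  Column labels default to the canonical RELION names
and can be remapped; unknown columns ride along unchanged, and a write/read
round trip preserves all numeric fields to 1e-6 (6-decimal fixed-point
output).

# The synthetic micrograph generator

The generator emulates the *coordinate-level* signature of linear arrays —
it produces no images.  Each array gets a uniform random anchor and
direction; member $k+1$ lies a $N(\text{spacing}, \text{spacing\_sd})$ step
beyond member $k$; $\psi_0$ is uniform and successive members add a
random-signed $N(\Delta\psi_0, \Delta\psi_{sd})$ increment (the analysis
sees only $|\Delta\psi|$, so the sign is unobservable).  Background
particles are uniform with uniform $\psi$, rejection-sampled against a
minimum-separation constraint.

Defaults encode the regime of the study the analysis was designed for:
14 micrographs of a 4096-px field at 1.26 Å/px; arrays at 181 ± 3 Å spacing
and 4.5° ± 2.3° $\psi$ offset, lengths 2–4 with weights (0.5, 0.3, 0.2)
favouring short runs; 25 arrays plus 200 background particles per
micrograph, i.e. ≈ 268 particles per micrograph with roughly the
observed split between array members and background picks; and a 60-px
minimum separation, below which picks of a ~320–340 px box would overlap.
These are *conditions*, not tuning knobs: they were fixed from the
published data regime before any recovery experiment and are not adjusted
to test outcomes.

What the simulator deliberately omits: orientation-dependent $\psi$ error
from finite angular sampling in classification, curved or branched arrays,
micrograph-edge effects on picking, and density variation between
micrographs.  Passing the recovery tests therefore shows the *pipeline*
recovers planted geometry through binning and peak extraction at realistic
densities — it does not validate 2D classification itself.

Recovery is assessed by `evaluate_recovery()`: the peak means must land
within one histogram bin (2 Å, 2.6°) of the planted values — the
resolution limit the binning imposes.  Across 20 seeds at the default
conditions the pipeline recovers both quantities in ≥ 95% of runs; a
background-only control is flagged as non-recovery.

# Rigid-body hinge and distance measurements

Atomic models are reduced to one C-alpha per residue (highest-occupancy
altloc, ties broken alphabetically); PDB and mmCIF inputs yield identical
models.  Superposition pairs residues by number within the selected ranges
(unpaired residues are dropped with a message) and solves the orthogonal
Procrustes problem by the SVD construction with determinant correction, so
the rotation is always proper.

The hinge measurement superposes chain B onto chain A over a *reference*
domain, then measures the residual rotation of the *moving* domain (a
second superposition of the aligned moving domain) via
$\theta = \arccos((\mathrm{tr}\,R - 1)/2)$, together with the largest
moving-domain C-alpha displacement.  For the unliganded receptor
ectodomain the natural choice is reference CLD(1-2) and moving CLD(3-4),
which isolates flexing about the calcium-binding CLD(2-3) interface.
Domain boundaries are not printed as exact ranges in structural papers;
the defaults used in the acceptance checks — CLD(1-2) = 22–247,
CLD(3-4) = 248–498 — follow the modelled span (22–498), the calcium
ligands marking the CLD2/CLD3 junction and the rigid CLD3–CLD4 linker at
383–385, and both ranges are ordinary arguments, because a hinge angle of
this kind is boundary-sensitive at the level of a degree or so.  We report
the full residual-rotation angle rather than a screw-axis decomposition.

`ca_distance()` and `measure_report()` cover named C-alpha separations
(e.g. the membrane-proximal CRD C-terminal spacing within a receptor
dimer); failed lookups in a batch report are per-row, not fatal.

# Conservation surfaces

Residues are grouped into physicochemical classes — aromatic (F, W, Y),
aliphatic (A, I, L, V), alcohol (S, T), positive (R, K), negative (D, E),
side-chain amide (N, Q), with C, G, H and M each counted individually.
Proline is absent from that published grouping; we give it its own
singleton class, consistent with the "counted individually" treatment of
the other unlisted residues.  The per-position score is the fraction of
comparator sequences whose residue falls in the reference residue's class
— the only reading of a 0–1 "similarity" that produces a continuous scale
from class identity alone.  Gaps and unknowns (`X`) stay in the
denominator and never match; the reference is excluded from its own
denominator.  Columns where the reference itself has a gap are skipped,
and output positions follow the ungapped reference numbering so they map
directly onto structure residue numbers (plus a user offset).  A
divergent domain can be excluded with a position mask rather than a
hard-coded rule.

Scores are written into the B-factor field as $100 \times s$ (preserving
two decimals in the fixed-width PDB field) with $-1.00$ as the sentinel
for unscored residues, ready for surface colouring (red 1 → yellow 0.5 →
white 0) in molecular-graphics software.  Alignments are consumed, not
computed: aligned FASTA is read via seqinr and Clustal via a small
dedicated parser (name + chunk lines, conservation rows ignored).

# Tight-binding K_D estimation

When the labelled-receptor concentration $R$ is comparable to $K_D$,
free-ligand depletion makes the hyperbolic isotherm invalid and the exact
1:1 solution must be used:

$$ f(L) = \frac{(R + L + K_D) - \sqrt{(R + L + K_D)^2 - 4RL}}{2R}, $$

evaluated in the rationalised form $2L / (R + L + K_D + \sqrt{\cdot})$,
which is stable when the subtraction cancels (small $L$).  `fit_kd()`
performs bounded Levenberg–Marquardt least squares with $K_D$ the single
free parameter on fractional-binding data, started at the concentration of
half-maximal signal and bounded in $[10^{-3}, 10^6]$ nM; the standard
error is the linearised (Wald) SE at the optimum, and non-convergence is
reported as a flag with diagnostics, never as a silent value.

Raw signals are normalised min–max to fractional binding.  Normalisation
is applied automatically only when the signal is clearly not already
fractional (outside $[-0.5, 1.5]$): re-normalising near-fractional noisy
data pins the two extreme observations to exactly 0 and 1 and biases the
fit.  For raw instrument signals the 3-parameter variant
(`free_amplitude = TRUE`, fitting amplitude and baseline) is the
recommended alternative to min–max normalisation for the same reason.
The receptor concentration to use is the labelled *protein* concentration
(83.7 nM in the motivating assay), not the fluorophore concentration.

Simulated titrations use a two-fold (1:1) serial dilution, 16 points from
5000 nM by default, matching standard thermophoresis practice.  On
noiseless curves the fitter recovers planted constants to below 1e-6
relative error; with 5% additive noise the median of 100 replicates stays
within 10% and the ±2 SE interval covers the truth at ≥ 90% over 200
replicates.

# Problem sizes and determinism

The test and acceptance workloads are sized for a single CPU: recovery
runs use 14 micrographs × ~268 particles (≈ 2 700–2 800 pairs) per seed
over 20 seeds; oracle-equivalence checks use 50 random tables of up to 200
particles; Monte-Carlo fitter checks use 100–200 replicates of 16-point
curves.  Every stochastic step flows from a single user-supplied seed, and
fixed-seed runs are byte-identical, including the command-line outputs.

# Known limitations

* The array analysis trusts upstream picking and classification; it cannot
  distinguish a genuine end-to-end contact from a picking artefact with
  the same spacing statistics.
* Real-data pair counts depend on micrograph selection and picking
  thresholds, which are not modelled; the simulator matches densities and
  geometry, not the full picking pipeline.
* Hinge angles depend on the chosen domain boundaries (order 1°); treat
  reported angles together with the ranges used.
* Residue pairing in superposition is by residue number, not sequence
  alignment, so cross-species comparisons need pre-matched numbering.
* The conservation score weights every comparator equally; it is a class
  identity fraction, not an evolutionary rate model.
* The K_D fitter assumes a 1:1 binding stoichiometry and independent
  errors; per-capillary raw-trace processing is upstream of the package.
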