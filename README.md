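# retarrays

Analysis toolkit for structural studies of the RET receptor tyrosine kinase
and its GDNF-family ligand (GFL) / GFRα co-receptor complexes.  Ternary
RET^ECD^–GFL–GFRα complexes can associate end-to-end on cryo-EM grids into
linear arrays of 2–4 particles; this package provides the statistics to
detect and characterise such arrays from 2D-classification metadata, plus
the companion measurements such studies need: rigid-body hinge geometry on
atomic models, residue-class conservation surfaces, and dissociation
constants in the tight-binding regime.

It is written for structural biologists and cryo-EM practitioners who have
RELION-style STAR files, PDB/mmCIF models, multiple sequence alignments and
titration tables, and want reproducible, scriptable versions of these
analyses.

## What it computes

**Array statistics.**  For every unordered within-micrograph particle pair
with centroid separation ≤ 170 px (214.2 Å at 1.26 Å/px by default), the
pair distance and the folded in-plane angle difference
Δψ = |ψ_a − ψ_b| (ψ folded into [0°, 180°) for a C2-symmetric particle)
are binned on a 2 Å × 2.6° grid.  The dominant peak — the 4-connected
component of bins at ≥ 0.5 of the maximum normalised frequency containing
the global maximum — is summarised by the mean ± SD distance and Δψ of its
member pairs.  A synthetic coordinate simulator with planted arrays and
known ground truth makes the whole pipeline testable without micrographs.

**Hinge geometry.**  After superposing chain B onto chain A over a
reference domain (SVD/Kabsch, determinant-corrected), the residual
rotation of a moving domain gives the hinge angle
θ = arccos((tr R − 1)/2), with the largest moving-domain Cα displacement
alongside; named Cα–Cα distances complete the measurement set.

**Conservation surfaces.**  Alignment columns are scored 0–1 as the
fraction of homologs whose residue shares the reference residue's
physicochemical class (aromatic F/W/Y; aliphatic A/I/L/V; alcohol S/T;
positive R/K; negative D/E; amide N/Q; C, G, H, M individually), and the
scores are written into B-factors (×100) for surface colouring.

**Tight-binding K_D.**  When the labelled receptor concentration R is
comparable to K_D, the bound fraction follows the receptor-depletion
quadratic

    f(L) = ((R + L + Kd) − sqrt((R + L + Kd)² − 4·R·L)) / (2·R)

and `fit_kd()` estimates K_D by bounded Levenberg–Marquardt least squares,
returning a classed fit with `print`/`summary`/`coef`/`predict`/`plot`
methods.

## Worked example

```r
library(retarrays)

# simulate 14 micrographs (~270 particles each) with planted arrays at
# 181 +/- 3 A spacing and 4.5 +/- 2.3 deg psi offset, then analyse them
sim   <- simulate_micrographs(array_model(), sim_config(seed = 1))
cfg   <- array_config()          # 170 px, 1.26 A/px, C2, 2 A x 2.6 deg, 0.5
pairs <- find_pairs(sim$table, cfg)
peak  <- extract_peak(bin_pairs(pairs, cfg), pairs, cfg)
peak
#> Array peak: distance 180.7 +/- 2.0 A, delta-psi 4.5 +/- 1.5 deg (342 pairs, 8 bins)
evaluate_recovery(sim$truth, peak, array_model())
#> Recovery: distance off by 0.26 A (within bin), delta-psi off by 0.04 deg (within bin) -> recovered

# tight-binding fit on a noisy simulated titration (R = 83.7 nM)
set.seed(42)
fit_kd(simulate_binding_curve(90, receptor_conc_nM = 83.7, noise_sd = 0.05))
#> Tight-binding fit: Kd = 73.7 +/- 11 nM (R = 83.7 nM, n = 16, SSE = 0.0414)
```

The peak means land within one histogram bin (2 Å, 2.6°) of the planted
spacing and angle offset — the resolution limit the binning imposes — and
the noisy K_D estimate sits within two standard errors of the planted
90 nM.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/retarrays.R simulate --seed 1 --outdir sim_out
Rscript inst/scripts/retarrays.R peaks --star sim_out/particles.star --outdir peaks_out
```

Every subcommand writes a `manifest.json` (package version, parameters,
seed, input checksums) so runs can be reproduced exactly.

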