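---
title: "Preparing predicted structures as molecular-replacement search models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing predicted structures as molecular-replacement search models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrprep)
```

## The problem

Molecular replacement (MR) solves the crystallographic phase problem by
placing a structurally similar model in the unit cell of the unknown protein
and borrowing its phases. When no experimental homolog exists, a *predicted*
structure can serve as the search model — but predictions from
coarse-grained simulated annealing come as ensembles of imperfect models, and
handing them to an MR program naively wastes most of their signal. The parts
of the model that fluctuate strongly across the trajectory are exactly the
parts most likely to be wrong, and they actively harm the rotation/translation
search; conversely, per-atom B factors that reflect the real positional
uncertainty help the likelihood-based placement.

`mrprep` implements the model-preparation and evaluation steps of that
pipeline for the three-sites-per-residue representation (Cα always, Cβ except
for glycine, backbone O). It deliberately stops at the boundaries of the MR
programs themselves: it prepares, scores, clusters and triages, but does not
run the force field, the phasing search or the density rebuilding.

## From trajectory to trimmed search model

**R.m.s.f.** For each residue the root-mean-square fluctuation is the RMS
deviation of its Cα position in each frame from its mean position, measured
over the trailing portion of the trajectory (`windowFraction`, default 0.25)
because an annealing run only equilibrates near the end. Frames are first
rigid-body superposed (Kabsch over all Cα) onto the window mean, iterated
twice so the mean and the fits are self-consistent; without this, global
drift or tumbling of the whole molecule would masquerade as per-residue
flexibility. The raw, unsuperposed alternative is exposed via
`superpose = FALSE` and is the right choice when frames are already in a
common frame — all the analytic noise-recovery checks in the test suite use
it, since the synthetic generator adds noise in a fixed frame.

**B factors.** The isotropic temperature factor follows from the mean-square
displacement as \(B_k = \frac{8\pi^2}{3}\,\mathrm{rmsf}_k^2\), so 1 Å of
fluctuation corresponds to ≈ 26.32 Å². The relation is per residue: every
atom of residue *k* receives \(B_k\), since the fluctuation is measured on
the Cα trace. `assignBfactors()` offers this scheme alongside the flat
20 Å² baseline; the two differ only in the B column, never in coordinates.

**Trimming.** Residues with r.m.s.f. *strictly greater than* the cutoff
(default 1.5 Å, which delineates the most flexible coil regions) are removed
whole — all three sites — rather than down-weighted. A residue exactly at the
cutoff is kept; the strictness is deliberate, documented and tested, and it
makes trimming idempotent. Surviving residues keep their original numbering
so the trimmed model still aligns residue-for-residue with the full one.
`stratifyTrimmed()` reports what the cut removed by secondary-structure class
(helix/strand/coil plus "unstructured" for residues unresolved in the
reference).

## Similarity metrics

All metrics operate on Cα coordinates, the natural choice for coarse-grained
models and the convention for GDT.

* **Kabsch superposition** (`kabschSuperpose`) returns the proper rotation
  and translation minimising the r.m.s.d. under a fixed correspondence, via
  SVD with the determinant correction, never a reflection.
* **Qw** (`qw`) compares internal pairwise distances:
  \(Q_w = \langle \exp[-(r_{ij}-r'_{ij})^2 / 2\sigma_{ij}^2] \rangle\) over
  pairs with \(|i-j| \ge 3\), with \(\sigma_{ij} = (1+|i-j|)^{0.15}\) Å. The
  normalisation \(2/((N-2)(N-3))\) is exactly the reciprocal of the number of
  qualifying pairs, so the score is a mean of Gaussians and lies in (0, 1].
  Being distance-based it needs no superposition and is exactly invariant
  under rigid motion.
* **Q over template-aligned regions** (`qTemplate`) is the same functional
  form restricted to residue pairs both present in an alignment, with one
  extra filter: pairs whose *template* distance is below 2 Å are excluded
  from both the sum and the normalisation (a step function treats such pairs
  as unphysical). With a full identity alignment and all template distances
  ≥ 2 Å it reduces to `qw` exactly — the test suite asserts this consistency.
* **GDT-TS** (`gdtTS`) averages, over thresholds 1/2/4/8 Å, the fraction of
  Cα within threshold after one all-residue Kabsch superposition. This is a
  simplification relative to CASP's LGA, which searches maximal subsets; the
  single-superposition variant is deterministic and cheap, and the difference
  only matters for models with large correctly-predicted *and* large wrong
  segments.
* **Contact maps** (`contactMap`) use a 9.5 Å Cα–Cα cutoff and a minimum
  sequence separation of 3; `contactOverlap` turns two maps into
  precision/recall/Jaccard, the quantitative version of the familiar
  red/blue contact-map overlay.

The minimum sequence separation (default 3 for the Q metrics and contact
maps) excludes pairs whose distances are fixed by chain connectivity and
would otherwise inflate every score; it is exposed as a parameter everywhere
it applies.

## Judging ensemble convergence

`mutualQMatrix()` scores every pair of frames with Qw;
`clusterModels()` runs average-linkage agglomerative clustering on the
dissimilarity \(d = 1 - Q\) and cuts the tree at \(d = 1 - q_{\text{thr}}\)
(default \(q_{\text{thr}} = 0.75\), midway between the ≈ 0.9 mutual
similarity of well-converged runs and the ≈ 0.5 typical of scattered ones).
Average linkage plus `stats::hclust`'s deterministic merge order makes the
result reproducible; labels are renumbered by first appearance so permuting
the input only permutes the labels.

`classifyPattern()` encodes the qualitative read-out of a clustergram:

* **single_dominant** — the largest cluster holds at least half the frames
  (the fraction is tunable). The sampling converged; such targets are
  usually tractable and more trials are worth running.
* **multi_cluster** — no dominant cluster, but at least two clusters of ≥ 2
  frames whose mean between-cluster Q stays above 0.5. Several related folds
  were sampled; one of the minor clusters may be the native basin.
* **dispersed** — everything else: singleton scatter, or clusters so
  mutually dissimilar (between-cluster Q ≤ 0.5) that the target itself is
  probably too hard for the protocol.

The between-cluster similarity floor is a design choice worth spelling out:
cluster *sizes* alone cannot separate the "several related folds" regime
from the "mutually dissimilar folds" one — ten tight pairs could be either —
so the classifier additionally requires multi-cluster layouts to be
inter-similar (mean between-cluster Q > 0.5, the level reported for failed
targets) and otherwise calls the ensemble dispersed.

## Trial triage

Success of an MR trial is decided by one number: the cross-validation
R factor after rebuilding, \(R_{\text{free}} < 0.45\) strictly. The
translation-function Z-score never decides success, because confidently
wrong placements with TFZ ≥ 8 do occur; such trials fail with the advisory
"high TFZ without confirmed rebuild". Map correlation thresholds (< 0.1
likely failed, > 0.25 likely correct) are likewise advisory only. The triage
input is a plain TSV table (`trial_id, tfz, llg, r_free, map_cc`) rather
than program logs, whose dialects vary across versions; a documented schema
keeps the verdicts deterministic and testable.

## The synthetic-fixture generator

Every test input is generated in code. `makeIdealHelix()` places Cα on the
textbook α-helix (1.5 Å rise, 100° twist, 2.3 Å radius — ≈ 3.8 Å consecutive
spacing and i,i+4 contacts inside 9.5 Å); `makeExtendedStrand()` is a
zig-zag extended chain at the same spacing, a genuinely different fold at
equal length. `perturbEnsemble()` adds independent per-frame isotropic
Gaussian noise of s.d. σ\_k per axis to all atoms of residue k, optionally
composed with a random global rigid motion per frame. Under this model the
expected Cα r.m.s.f. is \(\sqrt{3}\sigma_k\), which is what makes parameter
recovery an exact, analytic check. `makeTwoFoldEnsemble()` plants half the
frames on each fold, giving the mutual-Q matrix a two-block structure with a
controlled band gap.

What the generator does *not* emulate: real annealing frames are
time-correlated and their fluctuations anisotropic and coupled along the
chain; real ensembles contain partially folded frames rather than Gaussian
clouds around two ideal geometries. Passing tests therefore demonstrate that
the estimators, the trimming rule, the metrics and the clustering recover
*planted* structure correctly — they do not certify phasing success on real
crystallographic data, which additionally depends on the MR search itself.

## Numerical choices and problem sizes

* Superposition uses two fixed passes against the window mean; the fits
  change negligibly after the second pass for any ensemble the noise model
  produces.
* Q-matrix symmetry is enforced to 1e-8 on input and the matrix is
  symmetrised before clustering; the stored matrix is exact to 1e-12.
* Degenerate inputs: trimming that empties a model warns and returns a
  zero-residue model with a complete report; an empty predicted contact map
  makes precision NA with a warning; Qw requires ≥ 4 residues (its
  normalisation degenerates below that), superposition ≥ 3 points.
* The suite sizes its simulations for sharp yet fast checks: 2000 frames for
  the 5 % r.m.s.f.-recovery band (the relative error of an RMS over *m*
  frames scales as \(1/\sqrt{2m}\) ≈ 1.6 %), 20-residue/20-frame ensembles
  for clustering, 20 seeds for the stochastic properties.

## Limitations

The package prepares and evaluates; it does not phase. GDT-TS is the
single-superposition variant. One chain per model: oligomeric search
ensembles must be split and prepared per chain. Insertion codes and
alternate conformers beyond 'A' are rejected rather than interpreted. B
factors above 999.99 Å² cannot be written to the fixed-width PDB field and
are an error — trim such residues instead.
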