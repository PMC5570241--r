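---
title: "Model quality assessment in modqa6: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model quality assessment in modqa6: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Given a candidate 3D model of a protein and its target sequence — but not the
native structure — estimate how accurate the model is, residue by residue and
globally. `modqa6` implements a hybrid strategy: three *pure-single* scores
computed from the model plus sequence-based predictions, and three
*quasi-single* scores computed by comparing the model against a reference
ensemble of models built independently for the same target. The method never
compares a model against other user-submitted models, so a single model can
be scored alone and results for one model never depend on what else was
submitted.

# Component scores

All six component tracks are per-residue similarities in [0, 1], aligned to
target positions `1..L`; a residue absent from the model is absent from every
track.

**CDA.** Model contacts are residue pairs at sequence separation ≥ 5 whose
CB–CB distance (CA for glycine) is ≤ 8 Å. For residue `i`,
`CDA(i) = (Σ p)/c` over the `c` model contacts of `i` covered by the
predicted contact map; `c = 0` leaves the score undefined. The contact atom
(CB) and the separation floor are package policy: contact predictors
conventionally emit medium/long-range CB contacts, and short-range pairs are
trivially in contact in any fold. Both are configurable
(`model_contacts(threshold, min_separation)`).

**SSA.** The model's own 3-state secondary structure is assigned from
coordinates by the Kabsch–Sander hydrogen-bond model (below), and
`SSA(i)` is the predicted probability of that state. A model claiming a
helix where the predictor is confident in coil scores low, regardless of
which is right — the assumption (shared with all consensus-of-predictions
methods) is that the predictor is usually right.

**ProQ2 channel.** A pass-through for an external per-residue local score;
the package does not re-implement any third-party scorer. When absent, the
channel runs at the neutral constant 0.5 and the ranking combination drops
its global from the mean (flagged "degraded").

**MF5s.** The model is superposed on every reference with the iterative
TM-score search; per-residue Cα distances are averaged across references
(uniform weights by default — no reference ranking is assumed) and converted
by `S_r = 1/(1 + (d̄/3.9)²)`. The 3.9 Å constant makes `d = 3.9 Å`
correspond to similarity 0.5.

**MFcQs.** The superposition-free local Q-score
`q(i) = mean_j exp(−(d_ij^a − d_ij^b)²)` over shared partners `j ≠ i`,
averaged across references. The Gaussian width is 1 Å (Levitt–Gerstein
lineage) and configurable; all partners are included by default, with a
`min_separation` flag, since the lineage does not fix a separation rule.

**DBA.** `DBA = 1 − |S_r − (1 − P_d)|` with `S_r` the MF5s mean-track value
(a deliberate choice — the per-reference values are noisier and the mean is
what the error estimate itself uses) and `P_d` the predicted disorder
probability.

# Secondary structure assignment

Hydrogen bonds use the Kabsch–Sander electrostatic model: the amide H sits
1 Å from N opposite the preceding carbonyl;
`E = 0.084·332·(1/d_ON + 1/d_CH − 1/d_OH − 1/d_CN)` kcal/mol and a bond
exists below −0.5 kcal/mol. Two consecutive `i→i+4` turns make residues
`i+1..i+4` helical (H); ladders of ≥ 2 consecutive parallel or antiparallel
bridges make strands (E); everything else — including 3₁₀/π helices, isolated
bridges, turns and bends — reduces to C, which is exactly the standard
8-to-3 reduction in which only H and E are preserved. Proline never donates;
chain breaks (non-consecutive target numbering) and residues missing backbone
atoms are treated as boundaries and default to C. Because no reference DSSP
binary is available in the build environment, the assignment was checked
during development against an independent coordinate-based annotator
(P-SEA, via biotite) on the generated ideal fixtures, and the resulting
strings are frozen in the test suite.

# Superposition and TM-score

`kabsch()` is the SVD formulation with determinant correction (proper
rotations only). `tm_superpose()` runs the standard iterative-extension
search: seed fragments of length `n, n/2, n/4` (min 4) at up to 10 evenly
spaced starts, each refined by keeping residue pairs within a `d0`-derived
cutoff and re-superposing until the kept set repeats (≤ 20 iterations),
returning the frame maximizing
`TM = (1/L_norm)·Σ 1/(1+(d_i/d0)²)`, `d0 = 1.24(L_norm−15)^⅓ − 1.8` floored
at 0.5 Å. `L_norm` is always the full target length, for consistency with the
global score convention (below). The capped seed count is a speed/coverage
trade-off adequate for the protein sizes the fixtures use; the cutoff-relax
rule (grow by 0.5 Å until ≥ 3 pairs) handles degenerate seeds.

# The combiner network

A fixed 30–15–1 multilayer perceptron with logistic activations reads, for
each covered residue, a sliding window of size 5 over the six component
tracks (method-major feature order). Window cells that fall off the chain,
off the model, or on an undefined score are imputed with 0.5, the
sigmoid-neutral midpoint. The output is the consensus per-residue
similarity; errors in Å are recovered by `d = 3.9·√(1/s − 1)`, with the
similarity floored at 0.01 so the largest reportable local error is
`3.9·√99 ≈ 38.8` Å rather than infinity (configurable).

Training is plain mini-batch backpropagation with momentum on squared error:
defaults `lr = 0.05`, `momentum = 0.9`, `epochs = 500`, `batch = 32`,
uniform(−0.5, 0.5) initialization, all seeded so weights are
bit-reproducible. The loss, activations and schedule are declared package
policy — the method's architecture is fixed, its original training recipe is
not public. Training targets are *observed* similarities: each fixture decoy
is superposed on its native and the observed per-residue distances pass
through the same `S_r` transform.

The shipped `inst/extdata/combiner_weights.txt` was trained on the synthetic
fixture benchmark (workspace seed 42, ensemble 20, 8-rung ladder, 5000
sampled residue examples, training seed 42):

```r
ws  <- make_workspace("ws", seed = 42, per_rung = 17, ensemble_size = 20)
tr  <- build_training_set(ws)
set.seed(42); keep <- sample.int(nrow(tr$features), 5000)
net <- train_combiner(tr$features[keep, ], tr$targets[keep], seed = 42)
write_weights(net, "combiner_weights.txt")
```

It exists so that scoring runs are reproducible out of the box; it is
explicitly *not* a reproduction of any production server's weights, which
were trained on real blind-prediction data this package does not ship.

# Global scores, variants and the P-value

Every global score is `Σ (per-residue similarity) / L` with the *full* target
length as divisor: unmodelled residues count zero, so partial models are
penalized proportionally to their coverage. This follows from defining the
global as the mean over the target, not over the model. The quasi-single
clustering-style scores are `MFclust_s` (mean TM against the references),
`MFclustQ_s` (mean over references of the model's global Q, again normalized
by `L` — the ancestral global Q normalization is not restated anywhere
authoritative, so the divisor rule is applied uniformly and is configurable
in spirit via the local API), and their midpoint `MFclust2_s`.

The two combinations are exact arithmetic means:
`cor = (MFclustQ_s + DBA + ModFOLD6)/3` and
`rank = (MFclustQ_s + ProQ2 + CDA + DBA + SSA + ModFOLD6)/6`. When a member
is unavailable the mean of the available members is used with a warning and
a `degraded` attribute — never a silent substitution of another variant.

The P-value estimates `P[observed TM < 0.2 | predicted score]` — the chance
the model is no better than a random fold match. Its functional form is not
published, so the package fits a declared substitute: isotonic regression of
the indicator `TM < 0.2` on the predicted score, constrained nonincreasing,
clamped to `[1e-6, 1]`, fitted per variant on the synthetic decoy benchmark
and shipped beside the weights. With no calibration file the P-value is
omitted, never fabricated.

# The fixture generator

`make_native()` builds ideal-geometry backbones (NeRF chain extension with
Engh–Huber-style bonds/angles; helix φ/ψ = −57/−47, strand −119/+113) from a
segment grammar. Coil linkers take turn-prone base dihedrals with ±8°
seeded jitter — a deliberate compromise: fully random coil dihedrals produce
extended chains with *no* tertiary contacts, which would silence the CDA
channel; the fixed turn motif keeps folds compact so contacts exist at any
seed, while letters and jitter still vary. Decoys apply one rigid Gaussian
offset per residue (per-residue noise preserves local bonding better than
per-atom noise) over a default ladder of 0–6 Å across 8 rungs, with optional
segment shifts. Reference ensembles are *mid-ladder* decoys (1–2.5 Å noise),
not copies of the native: quasi-single scoring is thereby tested in its
realistic imperfect-reference regime. Prediction files blend ground truth
computed from the native with noise by a `fidelity` parameter (default
0.85 — roughly the secondary-structure accuracy of modern predictors).
Default ensemble size is 20 for test speed; the production-scale setting of
the method this models is 130, and the parameter is exposed.

What a green test on these fixtures establishes: formula correctness,
geometric soundness, end-to-end determinism, and that the combiner genuinely
fuses its inputs (it beats every single component out of sample on the
fixture benchmark). What it does not establish: performance on real CASP- or
CAMEO-style model populations, whose error modes (register shifts, domain
swaps, template bias, side-chain packing) the Gaussian/segment-shift decoys
do not emulate.

# Numerical and degenerate-input policy

- Similarity floor 0.01 before distance inversion; B-factor errors ≥ 1000 Å
  clamp to 999.99 with a warning (field width).
- Residue mapping trusts PDB numbering when ≥ 90% of numbered positions
  match the target letters; otherwise an exhaustive ungapped offset scan is
  used and an exact tie between offsets is an error naming both — never a
  guess. `X` matches any letter; common modified residues map to their
  parent; altloc resolves to highest occupancy, then first seen.
- Missing CB with backbone present: a virtual CB from ideal tetrahedral
  geometry; CA-only residues fall back to CA in CB-based scores.
- CA-only stretches assign C; `tm_superpose` needs ≥ 5 shared positions;
  Kabsch needs ≥ 3 points; local Q-scores with no eligible partner are
  absent, not zero.
- Contact predictions below the 8 Å rule keep all provided pairs — no
  probability threshold is applied before CDA averaging.

# Limitations

Single chain only (first chain, first MODEL); no mmCIF; no true multi-model
clustering mode; decoys are not physically realistic (no side chains beyond
CB, no minimization); the shipped weights and calibration are fixture-trained
and should be retrained on real data for production use.
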