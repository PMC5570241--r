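# modqa6

Estimation of protein model accuracy (EMA/QA) for single 3D models, without
the native structure. `modqa6` is aimed at structural bioinformaticians who
need per-residue error estimates (in Ångströms) and calibrated global quality
scores for candidate protein models — for picking the best model out of a
set, for annotating which regions of a model to trust, or for building
controlled QA benchmarks offline.

## Method

Each model is scored one at a time (quasi-single mode: a model is never
compared against other submitted models, only against a reference ensemble
built for the same target). Six per-residue component scores are computed,
all mapped to similarities in [0, 1]:

- **CDA** (contact distance agreement, pure-single): residues `i`, `j` are in
  contact when their CB–CB distance (CA for Gly) is ≤ 8 Å at sequence
  separation ≥ 5; `CDA(i) = (Σp)/c`, the mean predicted contact probability
  over the `c` realized contacts of `i` that have a prediction.
- **SSA** (secondary structure agreement, pure-single): `SSA(i) = p_CHE`, the
  predicted probability (PSIPRED-style pC/pH/pE) of the 3-state class residue
  `i` adopts in the model, assigned from coordinates by Kabsch–Sander
  hydrogen bonding with the standard 8→3 reduction (H, E kept; all else C).
- **ProQ2 channel** (pure-single): a pass-through for an external local score
  in [0, 1]; optional, imputed at 0.5 when absent.
- **MF5s** (quasi-single): the model is TM-score-superposed on every
  reference model; mean per-residue distances `d̄` convert to similarities by
  `S_r = 1 / (1 + (d̄ / 3.9)²)`.
- **MFcQs** (quasi-single): mean superposition-free local Q-score
  `mean_j exp(−(d_ij^model − d_ij^ref)²)` over the reference ensemble.
- **DBA** (disorder agreement, quasi-single): `DBA = 1 − |S_r − (1 − P_d)|`,
  penalizing confidently-placed residues that are predicted disordered.

A 30–15–1 logistic MLP reads a size-5 sliding window of the six tracks
(30 inputs) and emits the consensus per-residue similarity, converted to an
error in Å by inverting the `S_r` transform (`d = 3.9·√(1/s − 1)`). Global
scores are sums of per-residue similarities divided by the full target length
`L`, giving ten globals (the six components, three ModFOLDclust-style
quasi-single scores, and the consensus `ModFOLD6`), plus two optimized
combinations:

- `ModFOLD6_cor = (MFclustQ_s + DBA + ModFOLD6) / 3` (best linear agreement
  with observed quality),
- `ModFOLD6_rank = (MFclustQ_s + ProQ2 + CDA + DBA + SSA + ModFOLD6) / 6`
  (best top-model ranking),

and a P-value — the calibrated probability that the model's similarity to
the native is no better than random (observed TM-score < 0.2).

## Worked example

Generate a synthetic workspace (a compact helix/sheet fold, an 8-rung decoy
ladder, 20 imperfect reference models, and matching prediction files), then
score every decoy:

```r
library(modqa6)

ws  <- make_workspace(file.path(tempdir(), "demo_ws"), seed = 42,
                      per_rung = 2, ensemble_size = 20)
res <- run_qa(list(
  sequence = ws$fasta, models = ws$model_dir, refs = ws$ref_dir,
  ss2  = ws$prediction_paths[["ss2"]],
  diso = ws$prediction_paths[["diso"]],
  rr   = ws$prediction_paths[["rr"]],
  proq2 = ws$proq2_dir, variant = "ModFOLD6_rank",
  out = file.path(tempdir(), "demo_out")))

head(res$summary[, c("model", "ModFOLD6", "ModFOLD6_cor",
                     "ModFOLD6_rank", "p_value")], 5)
#>         model ModFOLD6 ModFOLD6_cor ModFOLD6_rank p_value
#> 1 decoy_r0_01    0.951        0.629         0.717   1e-06
#> 2 decoy_r0_02    0.950        0.629         0.716   1e-06
#> 3 decoy_r1_01    0.936        0.619         0.699   1e-06
#> 4 decoy_r1_02    0.935        0.621         0.681   1e-06
#> 5 decoy_r2_02    0.892        0.596         0.674   1e-06
```

The summary is sorted by the chosen variant, descending: the two rung-0
decoys (exact copies of the native) rank first, and scores fall off with the
perturbation scale. Per model you also get the per-residue picture:

```r
res$results[["decoy_r3_01"]]
#> <qa_result> decoy_r3_01 (target synthetic_target)
#>   globals: CDA=0.524 SSA=0.508 ProQ2=0.691 DBA=0.617 MF5s=0.569 MFcQs=0.239
#>            MFclust_s=0.306 MFclustQ_s=0.239 MFclust2_s=0.273 ModFOLD6=0.752
#>   variants: ModFOLD6=0.752 ModFOLD6_cor=0.536 ModFOLD6_rank=0.555  P=1e-06

round(res$results[["decoy_r3_01"]]$per_residue_error[1:10], 2)
#>    1    2    3    4    5    6    7    8    9   10
#> 1.35 1.93 2.72 4.15 2.76 2.02 3.03 1.44 2.47 2.71
```

These errors are the predicted distance (Å) of each residue from its native
position; a P-value of 1e-6 (the clamp floor) says the model is confidently
not random. The output directory holds, per model, the input PDB with errors
written into the B-factor column, a CASP QA (QMODE 2) record, a per-residue
TSV, and a `summary.tsv` over all models.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/modqa6.R fixtures make --grammar H15-C5-E8-C3-E8 --seed 42 --out ws/
Rscript inst/cli/modqa6.R score --seq ws/synthetic_target.fasta \
    --models ws/models --refs ws/refs --ss2 ws/synthetic_target.ss2 \
    --diso ws/synthetic_target.diso --rr ws/synthetic_target.rr \
    --proq2 ws/proq2 --variant all --out out/
```

## Acceptance script

`scripts/acceptance.R` regenerates a seeded synthetic workspace, scores its
full decoy ladder end to end with the shipped combiner weights and
calibration, and writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Shipped data

`inst/extdata/combiner_weights.txt` holds the combiner trained on the
synthetic fixture benchmark (seed 42; ~5000 residue examples), and
`inst/extdata/calibration.txt` the matching P-value curves — both plain text
and regenerable (see the methods vignette). They are fixture-trained
artifacts for reproducible scoring, not a reproduction of any server's
production weights.
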