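# pocketflex

Many therapeutic targets exist in two forms with identical sequence but
different mechanical context — the canonical example being RANKL, the
osteoclastogenesis cytokine, which circulates as a soluble trimer (sRANKL)
and also sits tethered to the membrane of immune cells (mRANKL).  A
small molecule that binds only the soluble form would inhibit bone
resorption without the immunosuppression caused by blocking the membrane
form.  Because the two forms differ only in how freely they breathe,
the selective binding site must be found in their *conformational
flexibility*, not in their sequence or crystal structure.

`pocketflex` implements that analysis as a reusable R pipeline for
structural bioinformaticians:

- **Ensemble I/O** — read/write conformational ensembles as multi-model
  PDB, with strict per-model validation and species residue-numbering
  maps (rat = mouse + 2 = human + 1 for RANKL constructs).
- **Flexibility metrics** — per-frame residue-pair distance series
  *d(f)*; the exceedance probability
  *P(d − d_ref > t)* (one-sided, opening direction; presets *t* = 1.8 Å
  and 2.0 Å); the SDRP statistic — the sum of the distances of four
  monitored residue pairs per frame — histogrammed in 2 Å bins anchored
  at multiples of the width, with the modal bin supplying representative
  docking conformers; pocket length/width sizing; and a two-ensemble
  comparison verdict.
- **Screening cascade** — the two-step triage funnel over
  engine-agnostic docking-score tables: a differential-binder rule
  (score < −6 against the soluble form *and not* against the tethered
  form), a secondary threshold (score < −3.5), and induced-fit
  re-ranking as a rank-top stage, with a full per-compound audit trail.
- **Assay statistics** — osteoclast inhibition ratio, growth inhibition
  ratio, KD = kd/ka, selectivity index KD(reference)/KD(primary), organ
  coefficients, and a deterministic four-parameter logistic IC50 fitter
  (`fit_logistic4()`, a classed model object with `coef`/`predict`/
  `plot` methods).
- **Synthetic data** — a seeded Ornstein–Uhlenbeck generator that plants
  breathing ensembles with known per-frame distances, score tables with
  known selective binders, and 4PL dose–response curves, so every stage
  of the pipeline can be tested against ground truth.

## Worked example

```r
library(pocketflex)

par <- breathing_params(tether_factor = 0.4, d0_shift = 1.5,
                        n_frames = 5000, seed = 1)
free <- simulate_breathing_ensemble(par, "free")
teth <- simulate_breathing_ensemble(par, "tethered")
compare_ensembles(free$ensemble, teth$ensemble, free$pairs, threshold = 1.8)
#> Flexibility comparison (threshold 1.8 A):
#>   pair exceedance_A exceedance_B  delta more_flexible
#>  pair1       0.0756            0 0.0756             A
#>  pair2       0.0614            0 0.0614             A
#>  pair3       0.0686            0 0.0686             A
#>  pair4       0.0634            0 0.0634             A
#> modal SDRP bin: A [76, 78) A, B [70, 72) A
#> pocket at representatives: A 20.33 x 17.55 A, B 17.89 x 16.91 A
#> overall more flexible: A
```

Every monitored pair opens beyond 1.8 Å about 5% of the time in the
free ensemble and essentially never in the tethered one, the free form's
SDRP concentrates in the 76–78 Å bin versus 70–72 Å when tethered, and
the pocket measured at the representative conformers is larger in the
free form — the site is flexible, inducible, and selective.

Downstream, a synthetic screen with 20 planted selective binders among
500 compounds is recovered exactly by the default cascade:

```r
screen <- simulate_score_tables(planted_screen(500, 20, seed = 1))
res <- run_cascade(screen$table, default_cascade_config(k_final = 20))
res
#> Screening cascade: 500 compounds in
#>   stage 1 differential(moe: sRANKL<-6, not mRANKL)      -> 20 survivors
#>   stage 2 threshold(glide: sRANKL<-3.5)                 -> 20 survivors
#>   stage 3 rank_top(ifd: sRANKL, k=20)                   -> 20 survivors
#> final survivors: 20

selectivity_index(kd_primary = 5.78, kd_reference = 124)$si_rounded
#> [1] 21
```

The whole analysis can also be driven from one YAML config via
`run_pipeline()` (see `?pipeline_config`) or the thin shell wrapper at
`inst/scripts/pipeline.R`, which writes a deterministic JSON report plus
TSV sidecars.

## Documentation

The methods vignette (`vignettes/flexibility-screening.Rmd`) describes
the statistics, the generator's model and its deliberate simplifications,
parameter defaults, and numerical conventions.
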