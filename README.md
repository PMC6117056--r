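# lunghetero

Quantitative imaging of **regional emphysema heterogeneity** in chronic
obstructive pulmonary disease (COPD), for researchers working with chest
CT densitometry and oxygen-enhanced MRI (OEMRI).

Emphysema severity is routinely summarized by a single whole-lung number,
but *where* the destruction sits along the cranial-caudal axis carries
independent information about gas transfer and arterial oxygenation. This
package implements both modalities' whole-lung indices and their
heterogeneity counterparts, plus the cohort statistics that relate them
to pulmonary function:

- **CT arm** — tracheal-air HU calibration (additive shift to
  -1000 HU), low attenuation volume below the strict `< -960` HU cut-off,
  isovolumetric cranial-caudal partitioning into 12 equal-volume parts
  with the apex/base partitions excluded, per-partition LAV%, whole-lung
  **LAV%**, and **SD-LAV** — the SD of the 10 kept per-partition values.
- **MRI arm** — per-pixel relative enhancement ratio between the
  steady-state tails of the room-air and 100%-oxygen phases,
  `RER = 100·|SI_enh − SI_base| / |SI_base|`, pooled over three coronal
  sections into **MRER** (pixel-weighted mean) and **SD-RER** (sample SD
  of 10 equal-count cranial-caudal partition means).
- **Statistics arm** — Shapiro-Wilk-gated t / Mann-Whitney group
  comparison, gated Pearson/Spearman correlation, and bidirectional
  stepwise regression with standardized betas and cumulative R².
- **Synthetic data** — CT phantoms with a controllable emphysema
  fraction and cranial-caudal gradient, oxygen wash-in MRI phantoms, and
  linked clinical covariates with known ground truth, so the entire
  chain is testable without patient data.

## Worked example

Generate a caudal-dominant emphysema phantom (30% target fraction),
measure it, and relate imaging indices to lung function on a synthetic
cohort:

```r
library(lunghetero)

## CT densitometry on a phantom with a caudal-dominant gradient
ph  <- generateCTPhantom(ctPhantomConfig(lavFractionTarget = 0.30,
                                         gradientStrength = 0.45, seed = 2))
res <- ctDensitometry(ph$volume)
res
#> LavResult (threshold -960 HU, shift 0.3731 HU)
#>   whole-lung LAV%: 30.1
#>   SD-LAV over 10 partitions: 5.1
round(perPartition(res), 2)
#>  [1] 21.33 25.17 26.57 25.87 30.07 31.12 32.87 32.52 36.01 37.41
```

The whole-lung LAV% recovers the 30% ground truth; the per-partition
values rise from the cranial (21%) to the caudal (37%) end — that spread
is what SD-LAV measures.

```r
## OEMRI on the same subject: emphysema suppresses oxygen enhancement
mr <- generateOEMRIPhantom(oemriPhantomConfig(enhancementAmplitudeMean = 0.126,
                                              enhancementGradient = 0.3,
                                              seed = 2), truth = ph$truth)
rerAnalysis(mr$series)
#> RerResult over 3 section(s)
#>   MRER: 9.36 %  SD-RER: 1.311 %
#>   excluded low-baseline pixels: 0

## cohort layer: group comparison and stepwise attribution
coh <- generateCohort(cohortConfig(seed = 1))
compareGroups(coh$table, "mrer")
#> GroupComparison: mrer
#>   COPD     n=40  median 11.7 (10.2, 14)  mean 12.3 +/- 3.4
#>   control  n=9  median 19.8 (18.2, 21.8)  mean 20.7 +/- 4.4
#>   test: t (Welch)  statistic -5.424  p = 0.0002659

copd <- coh$table[coh$table$group == "COPD", ]
stepwiseRegression(copd, "pao2", c("age", "bmi", "lav_pct", "sd_lav"))
#> RegressionReport: pao2 ~ stepwise(age, bmi, lav_pct, sd_lav), n = 40
#>   sd_lav     beta = -0.571  p = 0.0001192
#>   cumulative R-squared = 0.326
```

The COPD group's oxygen enhancement is markedly lower than the controls'
(12.3% vs 20.7%), and stepwise selection attributes arterial oxygenation
(PaO₂) to the *heterogeneity* index SD-LAV rather than to overall
severity — the structure planted by the generator's covariate links.

An end-to-end run (generate → ct-quant → oemri-quant → stats, with all
per-subject files and a JSON report) is one call:

```r
runPipeline(runConfig(seed = 42, cohort = list(nCOPD = 8, nControl = 3)),
            "out/")
```

or, from a shell, via the thin CLI wrapper:

```sh
Rscript inst/scripts/lunghetero.R all --out out/ --seed 42
```

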