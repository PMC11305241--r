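# thiastat

Functional vitamin B1 (thiamine) and B2 (riboflavin) status assessment for
animal cohorts, from raw erythrocyte enzyme kinetics to per-animal
subclinical-deficiency calls and endophenotype clusters.

## The problem

Thiamine diphosphate (TDP) is the active cofactor of erythrocyte
transketolase (TKT). In marginal thiamine deficiency, part of the TKT pool
circulates as apoenzyme, so adding TDP *in vitro* stimulates activity — the
classic "TDP effect". `thiastat` implements the full analysis chain used in
functional B-vitamin epidemiology:

1. **Specific activities** from kinetic spectrophotometry:
   `U/mg = (ΔA₃₄₀/min) / 6.22 × dilution / [protein]`, with technical
   replicates aggregated (mean + CV QC) before anything else.
2. **Activation indices**: PAR = a₀.₃/a₀, FAR = a₃/a₀.₃, SAR = FAR/PAR,
   SAD = FAR − PAR, and a latency (percent-stimulation) index; glutathione
   reductase (GR) serves as the riboflavin-dependent control.
3. **Age-decay models**: activities decline with age under pseudo-first-order
   kinetics, `A(t) = A₀·e^(−kt)`, fitted log-linearly; half-life `t½ = ln2/k`.
   Markers are age-normalized as observed/predicted from the cohort
   regression.
4. **Distribution selection**: each marker is fitted by maximum likelihood
   to a catalog of eight families (Normal, LogNormal, Exponential, Gamma,
   Weibull, sinh-arcsinh/SHASH, 2- and 3-component normal mixtures) and
   ranked by AICc.
5. **One-sided tolerance cutoffs** (content P = 0.90, confidence γ = 0.95):
   exact noncentral-t parametric limits when the AICc winner is Normal,
   distribution-free order-statistic limits otherwise.
6. **Deficiency classification** into B1 subtypes — *low-TDP* (abnormal
   age-normalized STKT/TKT+TDP, PAR or latency) vs *high-TDP* (abnormal
   FAR, SAR or SAD, indicating low-TDP-affinity enzyme forms) — and B2
   (abnormal age-normalized GR).
7. **Endophenotype clustering**: Ward minimum-variance agglomeration on
   robust-standardized {age, BCS, PAR, FAR, sex}, cluster count chosen by
   Sarle's cubic clustering criterion.

A seeded synthetic-cohort generator reproduces the statistical structure of
a 60-cat colony study (3-component age mixture on 1–17 y, SHASH-discretized
body condition scores, 44:16 F:M, activity half-lives 8.7/10.7/43.3 y,
planted 8+7+1 deficiency endophenotypes), so the entire pipeline is testable
with no external data.

## Worked example

```r
library(thiastat)

cfg <- pipeline_config(synthetic = cohort_config(seed = 7, mode = "activities"),
                       seed = 7, out = tempfile())
res <- run_pipeline(cfg)

res$age_fits$decay_stkt
#> Pseudo-first-order decay: k=0.07429 /y, half-life=9.33 y (n=60, R2=0.334, P=1.33e-06)

res$summary$n_deficient
#> [1] 6
res$summary$status_counts
#> $not_deficient [1] 54; $B1_deficient [1] 5; $B2_deficient [1] 1

res$clusters$chosen_k
#> [1] 3
```

The decay fit recovers the configured STKT half-life (8.7 y) within its
sampling band. Far fewer animals are *called* deficient (6) than are planted
(16): a one-sided 90 %-content cutoff can, by construction, flag only the
most extreme ~10 % of a cohort per marker — and a nonparametric
order-statistic cutoff at n = 60 at most one animal per marker. The
`truth_evaluation()` confusion summary quantifies exactly this (high
specificity, deliberately bounded sensitivity); see the methods vignette.

## Command line

```sh
Rscript inst/cli/thiastat.R run --synthetic --seed 7 --out out/
Rscript inst/cli/thiastat.R simulate --seed 7 --n 60 --out out/
Rscript inst/cli/thiastat.R run --input cohort.csv --content 0.9 --confidence 0.95 --out out/
```

## Input schema (v1)

`cat_id, sex {F,M}, age_years, bcs (1–9)`, then either raw kinetics
(`tkt_rate_{0|03|3}_rep{1..3}, gr_rate_rep{1..3}, protein_mg_ml, dilution`)
or precomputed activities
(`stkt_u_mg, tkt_tdp03_u_mg, tkt_tdp3_u_mg, gr_u_mg`). Empty cells are
missing values.
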