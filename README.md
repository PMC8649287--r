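# bpvar — usual blood-pressure variability and cardiovascular risk

Visit-to-visit variability of systolic blood pressure (SBP) — how much a
patient's clinic readings fluctuate from visit to visit — predicts
cardiovascular events and death, but a per-patient SD computed from 4–9
readings is mostly noise, and using it as a Cox covariate attenuates the
association toward the null (regression dilution bias). `bpvar` implements,
for biostatisticians and epidemiologists, the full corrected workflow:

* a **heteroscedastic Bayesian hierarchical model** for short SBP series,
  `y_ij = α_i + β_i t_ij + ε_ij`, `ε_ij ~ N(0, σ_i²)`,
  `(α_i, β_i) ~ BVN(μ, Σ)`, `log σ_i ~ N(θ, ω²)`, fitted by a vectorised
  Gibbs/Metropolis sampler with split-R̂/ESS diagnostics. The posterior
  means of `α_i` ("usual SBP") and `σ_i` ("usual SBP variability") are the
  regression-dilution-corrected exposures;
* **counting-process Cox models** on attained-age-split follow-up (Lexis
  expansion), with per-5 mm Hg hazard ratios, geometric-mean decade HRs,
  **floating absolute risks** (reference-free CIs by non-negative least
  squares on pairwise contrast variances), and 3-knot restricted cubic
  spline dose–response checks;
* **Rosner's regression-dilution ratio** from two non-overlapping reading
  windows as the classical sensitivity route;
* incidence tables with **exact (Garwood) Poisson intervals**;
* **chained-equation multiple imputation** with Rubin's-rule pooling;
* a calibrated **synthetic cohort generator** with known ground truth
  (ages 45–84, quarterly readings over 2 years with mean 4.5 kept, usual
  SBP 137.1 ± 10.7 mm Hg, within-subject SD 12.7 ± 2.3 mm Hg, true HR 1.30
  per 5 mm Hg of σ_i, ~9.7-year median follow-up, realistic covariate
  missingness), so every estimator can be tested for parameter recovery.

The repository is organised as an analysis: the package under `R/` holds
all computation; the numbered scripts under `analysis/` are thin drivers
that run the study end to end and write tables under `results/`; the
methods vignette (`vignettes/usual-bp-variability.Rmd`) documents the
model, priors, sampler and design choices.

## Worked example

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_variability.R
Rscript analysis/03_impute.R
Rscript analysis/04_survival.R
Rscript analysis/05_incidence.R
```

`01` generates 2,000 subjects and prints the cohort's vitals:

```
readings per subject: mean 4.52 (range 4-8)
median follow-up (reverse KM): 9.70 years
events: 656 (32.8%)
true usual SBP: 137.1 (SD 10.6); true SBP variability: 12.7 (SD 2.4)
```

`02` fits the hierarchical model (two chains; all split-R̂ ≤ 1.03) and
shows the shrinkage at work — the naive per-subject SDs spread 5.9 mm Hg
around the truth, the posterior means 0.96:

```
theta = 2.529  omega = 0.179  (pop. median sigma 12.54 mm Hg)
usual SBP: 136.8 (SD 9.3); usual variability: 12.74 (SD 0.96)
naive SD spread 5.92 shrunk to 0.96
```

`04` fits the Cox models on the five imputed tables and pools them. With a
generating HR of 1.30 per 5 mm Hg, the naive exposure is attenuated almost
to the null while the shrinkage-corrected exposure covers the truth:

```
per-5 HR, usual SD: 1.648 (1.121-2.424)
per-5 HR, naive SD: 1.066 (1.001-1.135)  <- attenuated
dilution slope 0.105 (lambda 9.50); corrected per-5 HR 0.713
```

(The Rosner-corrected value is unstable at this cohort size — the
two-reading windows have reliability ~0.06, so λ is large and noisy; the
vignette quantifies this.) The floated-risk group table from the same run
is monotone in variability, each group carrying its own CI:

```
             group log_hr   hr floated_var    lo   hi
1          10-11.9  0.000 1.00     0.00799 0.839 1.19
2 var_group12-13.9  0.174 1.19     0.00220 1.086 1.31
3 var_group14-15.9  0.372 1.45     0.01348 1.155 1.82
4    var_group>=16  0.637 1.89     0.14485 0.897 3.99
pairwise-variance reproduction residual: 0.1%
spline nonlinearity z = 0.39 (log-linear if |z| < 2)
```

`05` writes the incidence table (events, person-years, rate per 1000
person-years, exact Poisson CI) by outcome and variability group.

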