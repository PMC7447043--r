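---
title: "Methods: ALT-based NAFLD phenotyping, fibrosis scoring and genetic association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ALT-based NAFLD phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nafldphen)
```

# The phenotype model

NAFLD has no scalable gold-standard diagnosis: biopsy is invasive, imaging
is insensitive or unavailable at biobank scale. The phenotype implemented
here is deliberately minimal — chronic ALT elevation with other liver
disease excluded — because those two ingredients exist in every EHR.

A participant is a **case** under the primary `alt_threshold` definition
when two ALT measurements both strictly exceed the sex-specific threshold
(40 U/L men, 30 U/L women) and are separated by at least `minGapDays` and
at most `windowDays`, anywhere before enrollment. A **control** has at
least one pre-enrollment ALT and never exceeds the control ceiling
(30/20 U/L). Everyone between — a maximum ALT in the intermediate band, or
isolated spikes without a qualifying pair — is **indeterminate** and
excluded from the analytic set, preserving specificity at both ends.
Participants with any ICD code for alcohol-related, viral,
hereditary/metabolic or cholestatic liver disease or liver metastases are
**excluded** outright.

Assumptions worth making explicit:

- *Time axis.* Integer days relative to enrollment (day 0); "prior to
  enrollment" means day ≤ 0, so labs drawn on the enrollment day count.
  "Six months" is fixed at 183 days and "two years" at 730 days; calendar
  arithmetic would make classification depend on enrollment date, which we
  avoid for determinism.
- *Chronicity is a pair, not a trajectory.* Two elevated values with the
  right spacing are taken as evidence of persistent elevation. Nothing is
  modeled about the shape of the ALT series between them.
- *Control status is max-based.* Since the intermediate band is carved out
  of both ends, a control is equivalently "maximum pre-enrollment ALT at or
  below the ceiling", and at least one measurement is required — absence of
  evidence is indeterminate ("no ALT"), never a control.
- *Participants with a qualifying pair that fail a metabolic-mode
  requirement* are indeterminate rather than controls: their ALT history
  disqualifies them as controls no matter what their metabolic profile
  says.

# Metabolic risk factors

All baseline flags use the most recent pre-enrollment observation per
analyte. Code matching is case-insensitive prefix matching on dot-stripped
codes ("272.x" is the prefix `272`), so ICD-9 and ICD-10 lists are plain
editable vectors (`defaultCodePatterns()`, `defaultExclusionPatterns()`).
The shipped lists are pragmatic defaults, not an institutional standard,
and are meant to be replaced with local ones.

Decisions where the rules left room:

- The fasting surrogate for triglycerides is a draw before 9 AM; a TG
  record without a time stamp never satisfies it (conservative — an
  unstamped draw cannot be shown to be fasting).
- "At least two prescriptions" for diabetes medications means records on
  two *distinct days*; a duplicate order on one day is one prescription
  event.
- The type-1-diabetes pattern (insulin without oral agents, onset age
  < 40, BMI < 25, or a ketoacidosis code) negates only the
  *diagnosis-code* route to T2D; an HbA1c ≥ 6.5%, glucose ≥ 200 mg/dL or
  two medication days stand on their own. Onset age is estimated as age at
  enrollment plus (earliest qualifying code or lab day)/365.25.
- Hypertension is derived and used as a Model-3 covariate and can be named
  by a definition (`alt2htn`), but is *not* counted in `any_metabolic`:
  the metabolic case requirement is the literal list obesity,
  dyslipidemia, T2D, prediabetes.
- The AUDIT-C covariate is the raw most-recent score (0–12); the misuse
  flag uses the standard VA screening cutoffs (≥ 4 men, ≥ 3 women).

# Fibrosis scores

`fib4()` and `nfs()` are exact formula evaluations; both error on
non-positive ALT (and platelets for FIB-4) and are otherwise defined for
any finite inputs — range checking is the caller's concern, and the tests
exploit that by probing non-physiological corners (an intercept-only NFS).
The NFS dysglycemia term is diabetes *or prediabetes*, as the phenotype
uses it. Two boundary conventions coexist in the source material for the
NFS advanced-fibrosis flag (`> 0.676` vs `≥ 0.676`); the flag defaults to
`≥` — the convention under which case counts are reported — and
`nfsStrict = TRUE` switches to the strict inequality. FIB-4 uses a strict
`> 2.670` and the platelet surrogate a strict `< 150` (10⁹/L; counts in
cells/µL are divided by 10⁹ at the reader).

# Association and meta-analysis

Dosages enter additively (continuous in [0, 2], imputation-ready although
the generator emits integers). Binary outcomes use maximum-likelihood
logistic regression, continuous outcomes least squares; p-values are Wald,
matching standard GWAS convention, and are never truncated. The three
nested models are: (1) age, sex, 10 genetic PCs; (2) + AUDIT-C; (3) +
diabetes-or-prediabetes, hypertension, dyslipidemia, obesity.

Strata are combined by fixed-effects inverse-variance weighting
(w = 1/se²), with Cochran's Q at k−1 degrees of freedom for heterogeneity;
Q is undefined (NA) below two strata. Degenerate fits — constant dosage,
single-class outcomes, non-convergence or separation (detected by absurd
coefficient/SE magnitudes) — are flagged `estimable = FALSE` and dropped
from the combination rather than erroring, so one monomorphic stratum
cannot sink a panel. Plain ML logistic is used throughout; no Firth or
other small-sample correction (rare-variant strata should be interpreted
accordingly).

# The synthetic cohort generator

The generator is first-class, tested code: its defaults *are* the study
conditions the package is evaluated under, and they are not tuning knobs.

- Ancestry mix 72.8 / 20.2 / 7.0% (EU / AA / LA), age 64.5 ± 13.1 years,
  8.4% female — large veteran-biobank marginals.
- Genotypes: Binomial(2, EAF) per variant under Hardy-Weinberg
  equilibrium, no LD. The 16-variant panel carries European EAFs; the same
  frequencies stand in for all ancestries unless `eaf_<ancestry>` columns
  are supplied, because ancestry-specific frequencies were not published
  for this panel.
- Case status: logistic in the planted per-allele log-odds (PNPLA3
  rs738409 at log 1.31 is the largest), with the intercept solved by
  `uniroot` so the realized-cohort mean probability equals the target
  prevalence of 0.31. Covariate effects on status default to zero — pure
  genotype planting keeps recovery tests interpretable.
- Overlays: 22% of participants receive an exclusionary code (composition
  ~73% alcohol-related, 11% viral, 16% other) and 23.3% of the remainder
  an intermediate-band ALT maximum, mirroring the attrition a real cohort
  shows between eligibility and analysis.
- Metabolic truth is drawn conditional on case status at published
  case/control rates, then *encoded* in the data through the same rules
  the classifier reads: an HbA1c in [5.7, 6.49] for prediabetes, two
  dyslipidemia codes with a low HDL, two diabetes-medication days, a BMI
  ≥ 30, and so on. Statins are prescribed independently at 30% so that a
  statin alone never implies dyslipidemia — deliberately exercising that
  rule's negative branch.
- AUDIT-C ~ Binomial(12, 0.22), chosen so roughly a third of a
  predominantly male cohort exceeds the misuse cutoff.
- Every stage draws from a sub-seed derived deterministically from the
  master seed, so stages are individually reproducible and a cohort is
  bit-identical under the same configuration.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: ALT trajectories are i.i.d. noise around
a status-dependent level, not physiology; codes have no ontology beyond
the configured prefixes; there is no missingness mechanism beyond absent
analytes, no linkage disequilibrium, no dosage uncertainty, and no
correlation between metabolic factors besides their dependence on case
status. The round-trip guarantee (planted labels recovered exactly when
the exclusion and indeterminate overlays are off) validates the *rule
engine*, not the clinical validity of the rules.

# Numerical choices and degenerate inputs

- Intercept calibration: `uniroot` on [−30, 30] with tolerance 1e−10.
- Percentages are rounded half-up at the printed precision (`floor(x·10^d
  + 0.5)/10^d`), matching how published tables round.
- Cohen's κ is unweighted, accepts any k×k table, and is defined as 1 when
  both raters agree perfectly on a single category (p₀ = pₑ = 1); for
  valid tables pₑ = 1 forces p₀ = 1, so the undefined case cannot arise.
- PPV is undefined (error) at TP+FP = 0; empty ALT series classify as
  indeterminate "no ALT"; an empty call table yields an all-zero
  accounting.
- Missing analytes yield `FALSE` risk-factor flags and `NA` fibrosis
  scores, never errors; missing sex is an error because every threshold is
  sex-specific.

# Problem sizes used in the checks

The test suite and acceptance script size their simulations as: 1,000
random inputs for formula-equivalence, 1,000 random mini-participants for
the brute-force classifier comparison, 1,000 null replicates at n = 2,000
for type-I error, 50 replicates at n = 50,000 for CI coverage of the
planted OR 1.31, and a 30,000-participant end-to-end cohort. These are
large enough for the binomial tolerances used (e.g. 3 SE bands) while
keeping a full run in the tens of seconds to low minutes.

# Known limitations

The phenotype requires elevated ALT, so NAFLD with normal enzymes —
including burned-out cirrhosis — is invisible to it; the published
validation supports PPV only (nothing about sensitivity or NPV is claimed
or computable here); the exact institutional code lists behind the original
T2D and sensitivity definitions are not public, so the shipped defaults
are approximations meant to be edited; and the chart-review statistics of
the source study cannot be recomputed without its records — the package
replaces them with simulated-adjudication properties whose expected values
are known by construction.
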