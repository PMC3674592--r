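---
title: "Testing the transferability of a weighted genetic risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the transferability of a weighted genetic risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(grstransfer)
library(dplyr)
```

## The problem

Most susceptibility variants for common autoimmune diseases — rheumatoid
arthritis (RA) is the motivating case — were discovered and validated in
cohorts of European ancestry. Whether the aggregate risk they convey carries
over to other populations is a separate empirical question: allele
frequencies drift between populations, linkage disequilibrium with the
unobserved causal variants differs, and the causal architecture itself may
differ. When the non-European cohort is small (tens of cases), per-SNP
association tests are hopeless; what can be tested is the *aggregate* signal.

`grstransfer` implements that aggregate test. A weighted genetic risk score
(GRS) summarizes a panel of susceptibility markers into one variable per
individual:

$$\mathrm{GRS}_j \;=\; \sum_{i=1}^{m} w_i \, g_{ij},$$

where $g_{ij} \in \{0, 1, 2\}$ counts the risk alleles individual $j$
carries at SNP $i$ and $w_i = \ln \mathrm{OR}_i$ is the per-allele log odds
ratio from a large discovery meta-analysis in the reference population
(taking replication-stage estimates avoids winner's-curse inflation). The
score's association with disease is fitted by logistic regression,
summarized as the odds ratio per unit of GRS.

The transferability question is then: *is the score's effect in the small
target cohort compatible with what the reference population would show at
the same sample size?* A small cohort alone could produce a null OR by
chance. The package answers with an empirical null distribution: draw many
random subsamples from the large reference cohort, each with exactly the
target's case and control counts, re-estimate the OR in each, and locate
the target cohort's OR in that distribution.

## Pipeline stages

1. **Genotype input** (`read_genotypes()`): PLINK text `.ped`/`.map` or a
   simple wide TSV of allele-pair calls. Reading canonicalizes each SNP's
   counted allele to the alphabetically first observed allele, so parsing
   is deterministic under row reordering. `orient_to_risk_allele()` then
   recodes counts onto the weight panel's risk alleles (`g' = 2 - g` where
   the counted allele is the non-risk allele). Palindromic (A/T, C/G)
   markers are matched by allele label only; no strand inference is
   attempted, so strand-ambiguous data must be resolved upstream.

2. **Quality control** (`apply_qc()`): three filters in a fixed order —
   samples with missingness above 10%, then SNPs with call rate below 90%
   among retained samples, then SNPs violating Hardy–Weinberg equilibrium
   (HWE) at exact-test $p < 10^{-3}$. Sample-first ordering (the common
   PLINK practice) makes call rates depend only on retained samples. All
   boundaries are strict, and every exclusion is reported with the metric
   that caused it.

3. **HWE exact test** (`hwe_exact_test()`): the conditional (Levene)
   distribution of the heterozygote count given the allele counts, summing
   the probabilities of all configurations no more probable than the
   observed one. A relative tolerance of `1e-12` guards the inclusion
   comparison against floating-point ties; monomorphic markers have a
   single attainable configuration and thus $p = 1$, so they are never
   excluded by this filter. By default the test runs on controls only —
   a genuine disease association distorts genotype proportions in cases,
   and testing them would discard true signals — with an all-samples
   option.

4. **Population comparison** (`allele_frequencies()`,
   `align_minor_frequencies()`, `maf_correlation()`,
   `maf_difference_bins()`): the minor allele of every SNP is fixed in the
   *reference* cohort (frequency $\le 0.5$ there, with the counted allele
   designated at an exact tie) and carried across populations, so an
   aligned "MAF" may legitimately exceed 50% elsewhere. Correlation is
   Pearson's $r$ with the p-value of the regression-slope $t$ test; the
   difference bins use a strict lower boundary (a difference of exactly
   0.10 falls in the middle bin). Cohorts known only through published
   frequency vectors (`published_frequencies()`) can enter these
   comparisons but not pooling or scoring, since they carry no
   individual-level genotypes.

5. **Pooling** (`pool_cohorts()`): control cohorts from the same broad
   population may be pooled when their control MAFs are tightly correlated;
   the pipeline requires a configurable pairwise correlation (default
   0.9) before pooling and otherwise analyses cohorts separately with a
   recorded warning. Pooling restricts to the SNP intersection and
   disambiguates colliding sample ids by cohort prefix.

6. **Scoring and association** (`compute_grs()`, `fit_association()`):
   missing genotypes are imputed as twice the risk-allele frequency of the
   sample's own group — cases and controls of the analysis population,
   separately — computed from the samples with called genotypes. The score
   is used unstandardized (the raw weighted count); a per-SD rescaling
   exists as an option but is never the default, so odds ratios are per
   unit of summed log-OR-weighted allele count. Inference is Wald
   throughout: $\mathrm{OR} = e^{\hat\beta}$,
   $\mathrm{CI}_{95} = e^{\hat\beta \pm 1.96\,\mathrm{SE}}$, with the SE
   from the observed information. Complete separation and non-convergence
   raise errors with diagnostics instead of returning unstable estimates.

7. **Transferability** (`null_or_distribution()`, `empirical_p()`,
   `effect_size_ratio()`): $B$ subsamples (default 1000) are drawn from
   the reference without replacement, stratified by phenotype, at exactly
   the target's case/control counts. Imputation frequencies are recomputed
   *within each subsample*, keeping every draw self-contained — the same
   rule a self-contained small cohort would face. The empirical p-value is
   one-sided lower-tail with the add-one correction,
   $p = (\#\{b: \mathrm{OR}_b \le \mathrm{OR}_\mathrm{target}\} + 1)/(B+1)$,
   so the smallest attainable value is $1/(B+1)$ and a target OR below
   every null OR is reported as $p < 1/B$. The direction is deliberate:
   the scientific claim is that the target effect falls *below* the
   reference distribution; a two-sided option doubles the smaller tail.
   The between-cohort effect-size ratio
   $\mathrm{OR}_\mathrm{ref}/\mathrm{OR}_\mathrm{target}$ gets a combined
   standard-error interval by recovering each log-OR's SE from its printed
   95% CI, $(\ln U - \ln L)/(2 \times 1.96)$.

### Numerical and design choices

* **Subsample reproducibility.** One master seed spawns a deterministic
  substream per draw, so growing $B$ extends the null without reshuffling
  earlier draws, and reruns are bit-identical.
* **Degenerate subsample fits** (separation in a small draw) are redrawn
  with full accounting rather than imputed, so the null always holds
  exactly $B$ usable odds ratios; a failure rate above 20% of $B$ aborts.
* **The resampling loop** runs on a dosage-matrix fast path that is
  asserted (in the test suite) to reproduce the public
  `compute_grs() |> fit_association()` composition to within $10^{-10}$.
* **Tie-breaks**: minor-allele designation at a reference frequency of
  exactly 0.5 takes the counted allele; heterozygote cells serialize with
  the alphabetically first allele first.

## What the simulator emulates — and what it does not

`simulation_config()` / `simulate_study()` generate two-population
case-control studies with exactly the structure the analysis assumes:
Hardy–Weinberg genotypes at specified risk-allele frequencies, a logistic
disease model additive in allele counts, case-control ascertainment by
rejection sampling (exact for desk-scale cohorts), MCAR genotype dropout,
whole-SNP genotyping failures, and Balding–Nichols divergence of the target
population's frequencies (Beta-distributed around the ancestral frequency
with variance $F p (1-p)$, truncated to $(0.001, 0.999)$).

The shipped scenarios define the study conditions used throughout the
tests:

* `"uk-like"` — reference and target from one population; 28 markers with
  per-allele ORs spread over 1.1–1.4 (the typical effect range of
  confirmed non-HLA autoimmune loci), reference ascertained at 500 cases /
  430 controls — a deliberate ~10× down-scaling of a large consortium
  cohort that keeps test runtimes in seconds while leaving the reference
  an order of magnitude larger than the target — and a target of 43 cases
  / 163 controls, the size of the motivating African dataset.
* `"africa-null"` — same reference; target frequencies diverged at
  $F = 0.2$ (chosen so the cross-population MAF correlation visibly
  degrades, mimicking the observed lack of UK–Africa correlation) with
  four markers forced below 2% frequency (several Caucasian RA loci are
  barely polymorphic in West/Central Africa), and all-null generative
  weights in the target.
* A 2% MCAR dropout rate reflects routine chip/MassArray genotyping loss;
  the baseline disease log-odds of $-4$ keeps the disease uncommon while
  keeping rejection sampling cheap.

The simulator deliberately omits linkage disequilibrium between panel SNPs
(the panel is built from independent markers), covariates (age, sex),
population stratification within a cohort, genotyping error that is not
missingness (so HWE violations arise only by sampling), and any
non-additive or interaction effects. Passing tests therefore certify the
statistical machinery under the model's own assumptions; they cannot
certify robustness to LD, confounding, or differential genotyping artifacts
in real data.

## Problem sizes used in the checks

The test suite exercises: exact-HWE equivalence against a brute-force
enumeration oracle for *every* genotype configuration with up to 50
individuals; parameter recovery on 200 simulated cohorts of 2,000 cases /
2,000 controls (95% CI coverage of the generative per-unit-GRS effect);
calibration of the empirical p on 200 repetitions of a 43/163 target drawn
from the reference's own generative model against $B = 200$ subsample
nulls; and MAF concordance across 200 pairs of 120-individual samples.
The acceptance script runs the full pipeline on the `"africa-null"`
scenario with the default $B = 1000$.

## Worked example

```{r example, eval = FALSE}
study <- simulate_study(scenario_config("africa-null", seed = 1))
panel <- study$panel

ref <- apply_qc(study$reference)$genotypes
tgt <- apply_qc(study$target)$genotypes
common <- intersect(unique(ref$snp_id), unique(tgt$snp_id))
panel <- dplyr::filter(panel, snp_id %in% common)

ref_fit <- fit_association(compute_grs(dplyr::filter(ref, snp_id %in% common), panel))
tgt_fit <- fit_association(compute_grs(dplyr::filter(tgt, snp_id %in% common), panel))

null <- null_or_distribution(ref, panel, n_case = 43, n_control = 163,
                             B = 1000, seed = 1)
empirical_p(null, tgt_fit$or_value)
autoplot(null, or_target = tgt_fit$or_value)
```

The same flow, driven by a YAML file describing real genotype files, is
available as `run_pipeline("study.yaml")` or from the shell via the
`grstransfer` script (`inst/scripts/`): `grstransfer run --config
study.yaml --out results/`.

## Known limitations

* Strand-ambiguous markers are matched by allele label only; data on
  opposite strands must be harmonized before import.
* The weight file shipped under `inst/extdata/` carries the real marker
  list of a 28+1-SNP RA panel but **synthetic** allele assignments and
  odds ratios (flagged by its `_synthetic` filename); it is a structural
  stand-in for a published weight table, not a scientific resource.
* The empirical null conditions on the one observed reference cohort; with
  a reference only a few times larger than the target, subsample ORs are
  correlated and the null is narrower than a fresh-cohort null would be.
* No covariate adjustment and no per-SNP association testing are provided,
  by design.
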