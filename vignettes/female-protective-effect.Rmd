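---
title: "Modelling the female protective effect in family data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the female protective effect in family data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpefam)
```

Autism spectrum disorder (ASD) is diagnosed three to four times more often in
males than in females. The female protective effect (FPE) hypothesis explains
this with a liability threshold model: a latent, normally distributed
liability underlies diagnosis, and females require a higher liability than
males before meeting diagnostic criteria. The hypothesis makes concrete,
testable predictions about *families*: relatives of female cases should carry
more inherited risk than relatives of male cases; mothers of affected
children should tolerate — and therefore carry — more polygenic risk than
fathers; and affected children should over-inherit polygenic risk relative to
the average of their parents, most strongly when no high-impact de novo
variant helps push them over the threshold.

`fpefam` implements the three analysis arms used to test these predictions —
registry-style sibling recurrence, polygenic-score group contrasts, and the
polygenic transmission disequilibrium test (pTDT) — together with a
liability-threshold family simulator that generates the cohorts those arms
need. Everything runs end to end on simulated data, so every stage of the
pipeline is testable without access-restricted registry or biobank data.

## The generative model

Each individual carries, for each phenotype (ASD and intellectual
disability, ID), a liability

$$ L = g + e \;(+\, \delta\,\mathbb{1}[\text{de novo carrier}]), $$

where $g$ is the common polygenic component, $e$ an independent residual,
and $\delta$ the liability shift contributed by a high-impact de novo
variant. Founder liability is standard normal: $g \sim N(0, h^2)$ and
$e \sim N(0, 1 - h^2)$. A child's polygenic component is the mid-parent
value plus Mendelian segregation noise,

$$ g_{\text{child}} = \tfrac{1}{2}(g_{\text{mother}} + g_{\text{father}})
   + N(0, h^2/2), $$

which keeps the population variance of $g$ at $h^2$ across generations and
gives the parent–offspring regression its expected slope of $1/2$ per
parent. De novo variants arise only in offspring (they are new mutations,
never transmitted) and are excluded from the founder variance
normalisation; carriers' liabilities exceed the standard-normal envelope by
construction. An individual is diagnosed when $L$ exceeds the sex-specific
threshold $T_s = \Phi^{-1}(1 - K_s)$ implied by the prevalence $K_s$. The
ASD and ID liabilities share their de novo shocks (rare-variant influences
overlap heavily across the two diagnoses) while their polygenic components
are correlated only through `rg_asd_id`, which defaults to zero because the
estimated ASD–ID genetic correlation does not differ significantly from
zero.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `h2_common` | 0.85 | The single polygenic component stands in for *all* additive inherited liability, so the anchor is twin-study heritability of ASD (~0.8–0.9), not SNP heritability. |
| ASD prevalence | 2% male, 0.55% female | A ~3.6:1 male:female ratio in the middle of the reported 3–4:1 range. |
| ID prevalence | 1.5% male, 1.0% female | Male cumulative incidence ~1.5% by age 18 in registry data; a ~1.5:1 sex ratio. |
| `dnv_rate` | 0.01 | With `dnv_effect` below, implies ~13% of male and ~21% of female simulated cases carry a high-impact de novo variant, bracketing reported carrier fractions (11–17%). |
| `dnv_effect` | 1.5 liability SD | Same calibration as above. |
| `rg_asd_id` | 0 | Estimated ASD–ID genetic correlation not significantly different from zero. |
| `score_r2` | 0.05 | The observed score `pgs_obs` is a weak proxy of the polygenic component, emulating current ASD polygenic scores, which explain only a few percent of liability variance. |
| birth years | 1981–2005 | The registry follow-up window. |

Two scale choices deserve emphasis because they *are* the study conditions:

* **Registry size.** `simulate_registry()` defaults to 200,000
  two-plus-child families (family sizes 2–4 with weights 0.55/0.33/0.12).
  The emulated registry analysis drew on a case-*enriched* case–cohort
  sample, so its raw family count would under-power a population-
  representative simulation. The default is instead sized so the *analysis
  cells* match the emulated study: about 1,700 siblings of female ASDnoID
  index cases and about 7,000 siblings of male ASDnoID index cases.
* **Trio cohort.** `simulate_trio_cohort()` defaults to 4,800 ascertained
  families of two parents and two children, matching the combined size of
  the emulated family collections, with one proband per family and a
  designated (oldest) unaffected sibling where one exists.

### Parental screening

Family ASD collections exclude not only parents with an ASD diagnosis but
also, in the stricter designs, parents with a substantial concentration of
ASD-like traits. `simulate_trio_cohort()` models this with a sub-diagnostic
screen: a parent passes when their ASD liability is at least
`parent_screen_margin` (default 0.75) liability SD below their sex-specific
diagnostic threshold. At default thresholds this screens out roughly 10% of
fathers and 4% of mothers, consistent with reported broader-autism-phenotype
rates in parents of affected children. The asymmetry of the screen — the
female threshold is higher, so mothers can pass while carrying more
liability — is precisely the mechanism that produces the mother–father
polygenic gap among ascertained families.

### True scores versus observed scores

The simulator emits the polygenic component directly on the liability scale
(`pgs_asd`; no genotypes are simulated) *and* a noisy proxy `pgs_obs` with
squared correlation `score_r2 = 0.05` to the true component. Architecture
analyses — the pTDT stratum gradient, the mother–father contrast — default
to the error-free component: these are statements about the generative
model, and the noisy proxy merely attenuates them (by roughly
$\sqrt{h^2 / (h^2 + v_{\text{noise}})}$ on the standardized scale) without
changing their direction. The proxy exists to emulate what real, weak
polygenic scores would show: with it, simulated pTDT deviations shrink from
~2.5 mid-parent SD to the ~0.1–0.4 SD magnitudes familiar from real
cohorts, and the sanity check that an autosomally constructed score shows no
male–female difference in an unascertained population is run on it.

## The analysis arms

### Sibling recurrence

For each index-case cell (sex × diagnosis group among ASDnoID, ASDandID,
IDnoASD), `run_recurrence_analysis()`:

1. selects one index case per family, uniformly among eligible children
   (families with none are dropped);
2. selects one sibling per index case, uniformly and *independently of
   diagnosis*, within the 1981–2005 birth-year window;
3. matches each sibling to `ratio = 2` controls of identical sex and birth
   year, sampled without replacement after removing all siblings of index
   cases from the pool (index cases themselves remain — the control cohort
   is population-representative and may contain diagnosed individuals);
4. fits the logistic regression `status ~ sib_of_case` per outcome; the OR
   is the exponentiated coefficient with a 95% Wald interval.

Female-versus-male comparisons use a Wald test on the log-OR difference and
are *gated*: a comparison is only reported when both ORs are individually
significant, mirroring the analysis rule of the emulated study
(`sex_or_comparisons()`).

Numerical choices: age matching means exact birth-year equality (the
simplest faithful reading of "age- and sex-matched"); controls are unique
within an analysis; a zero cell in the 2×2 table is reported through the
Haldane–Anscombe correction (+0.5 everywhere) with an explicit `degenerate`
flag, never silently; the logistic fit uses iteratively reweighted least
squares (`stats::glm`) with a deviance tolerance of 1e-10 and at most 25
iterations, and with no covariates it reproduces the closed-form
cross-product ratio to well below 1e-6 relative error.

**A known property of the design.** Under complete ascertainment — a family
enters when at least one child is affected, and one affected child is
consumed as the index — the *null* sibling rate is not the population
prevalence $p$ but $p/(2 - p)$ in two-child families (the classic
proband-method truncation). The procedure is therefore *conservative* under
the null: with no familial aggregation at all, its odds ratios sit below 1,
and the package's tests document this rather than pretending the null OR is
1. The female-versus-male comparison is essentially unaffected, because both
cells share the truncation. The Wald machinery itself is calibrated, which
the tests verify on an exchangeable null (randomly split unascertained
individuals), where rejections occur at the nominal 5% rate.

### Polygenic-score contrasts

`score_samples()` implements plain linear scoring (weight × dosage summed
over the variants shared with the weight table); `standardize_scores()`
expresses scores in reference-population SD units (sample SD, $n-1$; the
reference is also centred, which changes interpretability but not any group
difference). `compare_prs_groups()` is OLS of score on a 0/1 indicator plus
principal-component covariates; `proband_sex_comparison()` adds an ID-status
covariate to the male-versus-female proband contrast because comorbid ID is
both more frequent in female cases and associated with lower polygenic
load. PCs are consumed as input columns; computing them is upstream of this
package.

### pTDT

The pTDT deviation for a trio is the child's score minus the mid-parent
mean, scaled by the SD of the mid-parent distribution over all families in
the analysis (computed before stratification; a fixed constant can be
supplied to mirror a published scaling). `ptdt_test()` is the one-sample
two-sided t test of zero mean deviation; under random sampling of trios the
Mendelian expectation makes this an exact null, which the package verifies
by simulation at scale (the rejection rate at $\alpha = 0.05$ over 5,000
unascertained replicates stays within Monte-Carlo error of 5%). Ascertaining
an affected child with unaffected parents breaks the null upward; requiring
an unaffected sibling breaks it slightly downward for that sibling.
`ptdt_compare()` contrasts two strata with Welch's two-sample t test
(pooled-variance available via `var_equal = TRUE`); Welch is the default
because stratum variances genuinely differ under ascertainment.

The liability-space prediction for the stratified pTDT is a gradient of
polygenic over-inheritance (lowest to highest): male cases with a
high-impact de novo variant, then male cases without / female cases with,
then female cases without — each de novo shock and each lowering of the
threshold reduces the polygenic risk a case must have inherited.
`run_ptdt()` reports the four case strata and the unaffected-sibling strata;
male unaffected siblings under-inherit on average (they stayed unaffected
against the lower male threshold), another FPE signature.

### De novo classification

`is_high_impact()` applies the three published classes exactly as printed:
protein-truncating variants in constrained genes (pLI strictly greater than
0.9), copy-number variants hitting at least one constrained gene, and
missense variants with MPC of at least 2; inherited variants never qualify.
Annotation (pLI, MPC, constrained-gene overlap) is consumed as input —
thresholds, not annotation pipelines, are the implementable content.

## What the simulator does and does not emulate

The simulator reproduces: sex-differential thresholds and their familial
consequences, Mendelian transmission of a polygenic score, de novo shocks
shared across ASD and ID, ascertainment of family cohorts with screened
parents, and registry-style index/sibling/control selection. It does not
simulate genotypes, linkage disequilibrium or allele frequencies (the
polygenic component lives directly on the liability scale); assortative
mating; shared environment; diagnostic-bias mechanisms (masking, evaluator
bias, later female diagnosis); or secular trends in diagnosis rates. Passing
tests therefore demonstrate that the *analysis pipeline* recovers the
signatures a liability-threshold FPE generates — not that real data are free
of the confounds the simulator omits.

## Problem sizes

The test suite and the acceptance script run the registry arm at its default
200,000 families (about 1.1 million individuals) for 20 replicate cohorts,
the trio arm at 4,800 families per replicate, the pTDT null calibration at
5,000 replicates of 100 trios, and the oracle comparison on 1,000 random
2×2 tables — sizes chosen so each Monte-Carlo band (3 binomial SEs) is tight
enough to be informative while a full run completes on a single CPU in a few
minutes.

## A short worked example

```{r example, eval = FALSE}
library(fpefam)

scenario <- run_fpe_scenario(
  n_registry_families = 60000,
  n_trio_families = 1200,
  seed = 7
)
scenario$summary
autoplot(scenario, "recurrence")
autoplot(scenario, "ptdt")
```

The summary reports the female- and male-index recurrence ORs, the
mother–father polygenic gap with its p value, the pooled proband pTDT
deviation, the male unaffected-sibling deviation, and whether the
four-stratum gradient held — the five FPE diagnostics in one row.
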