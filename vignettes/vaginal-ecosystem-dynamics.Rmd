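---
title: "Methods: longitudinal analysis of the vaginal ecosystem across childbirth"
author: "vagcycle"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`vagcycle` implements a longitudinal analysis of vaginal 16S amplicon surveys
spanning pregnancy, delivery, and one postpartum year, together with a
synthetic cohort generator whose every stochastic ingredient has a closed-form
ground truth. The package is organised as an analysis workflow: the numbered
drivers under `analysis/` narrate one pass over a simulated cohort, while all
computation lives in package functions that the test suite validates against
independent oracles.

# Community states

Each sample is an ASV count vector. After removing low-yield libraries
(< 40,000 reads, the boundary being inclusive on the keep side), frequencies
are computed per sample and two features drive state designation:

* the Shannon diversity index $H = -\sum_i f_i \ln f_i$ (natural log), with
  the *effective number of ASVs* $e^H$ (the Hill number of order 1); and
* the top ASV (most abundant; ties broken deterministically by the
  lexicographically smallest ASV id) and its frequency.

A sample is labelled **diverse** when $H > 2$ *or* the top-ASV frequency is
below 0.5; otherwise it takes the taxonomic label of its top ASV. The source
description of this rule is permissive ("might be labelled"); we adopt the
hard disjunction and expose both thresholds as arguments, so the
SDI-only variant used in some displays is `diverse_topfreq = 0`. Status flags
record majority (> 1/2), super-majority (> 2/3; the exact cutoff is never
stated in the source analyses, so we fix the natural 2/3 and expose it), and
dominance (> 0.7, strict).

Species-level labels for *Lactobacillus* ASVs come from semi-global alignment
against type-strain 16S references: the query must align end to end, end-gaps
in the (full-length) reference are free, scoring +1/-1/-2
(match/mismatch/gap), ambiguity codes count as mismatches, and identity is
matching columns over query-spanning columns with acceptance at $\ge 0.98$.
Note that 5 substitutions in a 235-nt amplicon give 230/235 = 0.9787 under
this definition, i.e. just below threshold; external search tools that report
"98%" for such hits use a different identity definition. Ties yield
multi-species assignments, which a curation map shortens to the dominant
vaginal species (*L. crispatus*, *L. gasseri*, *L. jensenii* groups);
uncurated sets are joined with "/".

# Temporal dynamics

Diversity day-trends are linear mixed-effects fits (`nlme`), `diversity ~
day` with random intercept and slope per pregnancy, estimated by **maximum
likelihood** (not REML) so fixed effects remain comparable across nested
configurations; the fixed slope is tested two-sided with $df =
n_\text{pregnancies} - 2$ (containment). Pregnancies with one timepoint are
dropped with a warning. A numerical note: exactly noise-free linear data make
this model singular (the optimiser cannot separate residual and random-effect
variance at zero) and the fit errors informatively; at noise SD $10^{-6}$ the
slope is recovered to $10^{-4}$ with SE below $10^{-5}$.

Turnover uses all within-pregnancy sample pairs collected 24.5-63 days apart
(the day equivalent of 3.5-9 weeks, inclusive), scored by Bray-Curtis
dissimilarity on fourth-root transformed counts (the transform moderates the
influence of extremely dominant ASVs). Pairs bin to the start month,
$\lfloor \text{earlier day} / 30.44 \rfloor$ with a 365.25/12-day month, except
that delivery-spanning pairs (one day < 0, one $\ge$ 0) are placed at month 0;
per-(pregnancy, month) means are formed before pooling, following the
"binned ... and averaged" reading. Canberra distances are scaled by the
number of non-double-zero coordinates so both metrics live in [0, 1].

# Time to dominance

For a focal taxon (member-ASV frequencies summed before thresholding), a
pregnancy is **at risk** if it is not dominated (> 0.7) at its first
postpartum sample and has at least one follow-up sample. The event is the
first postpartum day with frequency above 0.7; otherwise the case is censored
at its last sampled day. Kaplan-Meier curves use Greenwood variance with a
95% CI on the log-survival scale (the survival ecosystem's default; "plain"
and "log-log" are exposed), clamped to [0, 1]. Cox models maximise the
counting-process partial likelihood with the Efron tie correction. The
90-day landmark analysis drops cases whose endpoint falls at or before day
90, restarts the clock there, and defines exposure by onset at or before the
landmark; time-dependent covariates enter as (start, stop] interval pairs
splitting at onset. Multiple pregnancies of one participant enter as
separate cases.

Two caveats that the synthetic cohort makes visible:

* **Visit-schedule estimand.** With monthly visits, transitions before the
  first visit are screened out by the at-risk rule and later transitions are
  detected only at the next visit. For a constant hazard $\lambda$, first
  visit $v_1$ and last visit $v_L$, the quantity the pipeline estimates is
  $(F(v_L) - F(v_1)) / (1 - F(v_1))$ with $F(t) = 1 - e^{-\lambda t}$, not
  the continuous-time incidence $F(365)$. `truth_summary()` reports both
  (`observable_incidence` vs `taxon_incidence_1yr`), and the test suite shows
  the KM point estimate and CI are calibrated for the former: at 200
  pregnancies, CI coverage of the visit-schedule estimand is ~95%, while
  coverage of the continuous-time value is necessarily below nominal because
  the two quantities differ by ~0.035 at a one-year incidence of 0.5.
* **Univariate models under correlated exposures.** In the default cohort,
  contraception triples all recovery hazards from its onset. A univariate
  time-dependent model for a *null* covariate whose onsets fall later in
  follow-up (e.g. menses resumption) can show spurious association through
  this omitted variable, and the 90-day landmark contraception estimate is
  attenuated because late initiators sit in the unexposed group and early
  events are excluded. Both are properties of the estimators the analysis
  deliberately mirrors, not of the code.

# Parity inference

State outcomes are modelled one-versus-rest per focal state with binary
logistic regression; the covariance is the cluster-aggregated sandwich
estimator with the **gestation** as the cluster (participant-level clustering
is exposed as an option since participants may contribute several
gestations). Unequal sampling effort is addressed by drawing six gestational
samples per gestation without replacement (gestations with fewer contribute
all samples, since dropping them would bias toward well-sampled gestations),
fitting each draw, and averaging odds ratios, CI endpoints, and p values over
100 iterations under a mandatory seed; the averaged CI is descriptive, not a
combined-inference interval. Degenerate iterations are recorded as failed
and excluded from the means, and unstable states are flagged rather than
suppressed. Birth-to-conception intervals bin at $\le 18$ vs > 18 months
(18 itself is "short"), cross-tabulated against *L. crispatus* predominance
(average gestational frequency > 0.5) among parous gestations only, tested
with a two-sided Fisher's exact test.

# Cytokine integration

Concentrations below an analyte's lower detection limit are set to half its
minimum detectable concentration; values above the upper limit are set to
that limit; flags are kept. PCA operates on log10 concentrations,
column-centered and unit-scaled (analytes span orders of magnitude). The
phase effect is tested by PERMANOVA on Canberra distances of the log10
concentrations (consistent with the PCA input; Canberra requires
non-negative data, so concentrations must sit at or above 1 pg/mL after
censoring — true for the default limits), with
$p = (1 + \#\{F^\pi \ge F\})/(n_\text{perm}+1)$ and seeds mandatory for every
permutation stream (999 permutations by default).

The repeated-measures correlation $r_{rm}$ comes from the
analysis-of-covariance decomposition (subject intercepts plus a common
slope): magnitude $\sqrt{SS_x/(SS_x+SS_e)}$, sign from the slope, F test on
$(1, n_{obs} - n_{subjects} - 1)$ df. It equals the Pearson correlation of
subject-mean-centered variables, which the tests verify to $10^{-10}$.
Networks compute $r_{rm}$ for every variable pair — taxa agglomerated to
genus except *Lactobacillus* at species level, plus the SDI, plus log10
cytokines — adjust with Benjamini-Hochberg across **all pairs jointly** (the
source is silent on the family; stratified adjustment is a config
alternative), and keep positive correlations with $r_{rm} > 0.35$ and
adjusted $p < 0.001$; isolated nodes are dropped.

Constrained correspondence analysis chi-square-standardises the community
matrix, projects it by row-weighted least squares onto the constraint space
(log10 cytokines), and decomposes by singular values; the constrained
fraction is constrained over total inertia and its significance is an
ANOVA-like permutation test of the joint constraint effect. The quadrant
query used to flag persistently nonoptimal samples is provided as a generic
threshold filter, not hard-coded.

# The synthetic cohort

The generator emulates the study design: weekly gestational sampling from
about day -210 to day -7, monthly postpartum visits on a 30-day grid over
365 days of follow-up, library sizes $N(156041, 42865^2)$ with 2% low-yield
samples, and a 40-ASV panel in which *L. crispatus* is carried by two ASVs
so species-level aggregation is exercised. Six states are modelled; each
pregnancy draws a gestational state from parity-dependent probabilities
(nulliparous *L. crispatus* probability 0.4; a parous odds ratio of 0.2,
applied to *L. crispatus* and renormalised over the remaining states, which
makes the configured OR exact and the other states' ORs available in closed
form; parous pregnancies with birth-to-conception intervals > 18 months get
a 2-fold odds recovery by default). Samples are Dirichlet-multinomial around
state centroids (precision 150). Dominated centroids put 0.85 on the focal
species over a small companion flora (centroid effective ASV number ~2);
the diverse centroid is an anaerobe bloom with traces of *Lactobacillus*
(effective ~15), so the delivery shift reproduces the observed
2 → ~13 change in median effective ASVs. At delivery the state switches to
diverse with probability 0.8; recovery is a competing-risks race of
exponential per-taxon hazards (defaults tuned so the covariate-free
any-*Lactobacillus* one-year incidence is ~0.49), modulated
proportionally by behavioural covariates (contraception HR 3, lactation end
HR 2, menses HR 1) from their onset days. Cytokines are log-normal with
log10 mean linear in the sample's realised Shannon index (slope 0.3 for the
10 delivery-responsive analytes, 0 for the rest; residual SD 0.3) and
detection limits 2 and 10,000 pg/mL.

What the generator does **not** emulate: visit-day jitter and dropout,
overdispersion beyond the Dirichlet-multinomial, sequencing batch effects,
taxon-specific cytokine signatures (coupling is through diversity only),
reversals of dominance after a transition, and menses/contraception
physiology beyond hazard multipliers. Passing recovery tests therefore show
estimator correctness under the assumed data-generating process, not
robustness to real-data artefacts.

# Problem sizes and tolerances

The validation suite uses: 1,000 random compositions for the diversity
oracle ($10^{-12}$); hand product-limit fixtures and 200 replicate
200-pregnancy cohorts for KM recovery and CI calibration; 50 replicates of
500 cases for time-dependent Cox recovery of HR 2 (15%); 25 replicate
100-gestation cohorts for the parity OR of 0.2 (25%); 500 null simulations
with 999 permutations for PERMANOVA type-I error ([0.03, 0.07] at
$\alpha = 0.05$); 1,000 datasets for the $r_{rm}$ equivalence ($10^{-10}$);
a 4x3 toy matrix against a direct eigendecomposition for CCA ($10^{-10}$);
and a 60-pregnancy cohort for the delivery-turnover ordering. Seeds are
fixed throughout; permutation and subsampling functions refuse to run
without one.
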