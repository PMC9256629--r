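---
title: "Methods: trio de novo mutation analysis with dnmtrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio de novo mutation analysis with dnmtrio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmtrio)
```

`dnmtrio` implements a complete two-cohort trio study of germline de novo
mutations (DNMs): the filter cascade that turns per-trio genotype calls
into accepted DNMs, a multi-caller structural-variant consensus, clustered
mutation detection, mutational-signature attribution, and the comparison
statistics. This vignette is the package's account of the methods: the
models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open.

## The DNM filter cascade

A candidate DNM is a variant where the child carries an allele that cannot
have been transmitted — the canonical configuration is child `0/1` with
both parents `0/0`. `is_mendelian_violation()` implements the general
transmission rule (the child's two alleles cannot be formed by drawing one
allele from each parent); it is checked in the tests against exhaustive
enumeration of all 27 biallelic trio genotype combinations. Missing
genotypes fail closed: a variant whose de novo status cannot be verified is
never called de novo.

The cascade applies, in order:

1. *Annotation retention* (`annotation_mode`, default `"off"`): optional
   population-frequency (< 1%), deleteriousness-vote (≥ 2 of 4 tools) and
   exon/splice-region retention. The genome-wide endpoint counts are
   incompatible with an exon-only restriction, so this stage defaults to
   off and is interpreted, when enabled, as either a disjunction (`"any"`)
   or a conjunction (`"all"`) — a deliberate configuration point because
   the intended combination is ambiguous for genome-wide calling, and a
   functional sub-analysis would want the conjunctive form.
2. *Mendelian-violation requirement*, with an optional `rescue_cohort_mv`
   flag that readmits variants carrying an upstream cohort-mode violation
   annotation: joint genotyping is not re-implemented, so this evidence is
   consumed as an input flag.
3. *Parental evidence*: each parent ≤ 1 read supporting the alternate
   allele (`max_parent_alt_reads`), parental depth ≥ 7 (`min_parent_dp`),
   child alternate reads ≥ 3 (`min_child_alt_reads`), and exclusion of
   repeat/segmental-duplication-flagged sites. Repeat masking is consumed
   as a per-variant flag; the package ships no repeat tracks.
4. *Genotype quality*: child GQ ≥ 99 and parents ≥ 50. "GQ 99" is read as
   ≥ 99 because standard callers cap GQ at 99, where equality and ≥
   coincide.

The per-stage retained counts (SNVs and indels separately) are reported as
a `filter_summary` tibble; monotone non-increase along the cascade is a
tested invariant, as is equivalence with an order-free single-pass
conjunction of all rules.

Indels are restricted to allele-length differences of 1–49 bp (structural
variants take over at 100 bp and are handled by their own pipeline);
multiallelic records are decomposed into one candidate per alternate
allele, with other alternate alleles mapped to reference — the treatment of
multiallelic sites is a package choice, made because decomposition keeps
every candidate allele visible to the cascade.

## Multi-caller SV consensus

Six callers' call sets are merged per family with the both-breakpoint
criterion: at merge range $d$, two calls of the same type on the same
chromosome belong together iff $|s_1-s_2|\le d$ and $|e_1-e_2|\le d$,
closed under single linkage (the behaviour of SURVIVOR-style overlap
merging). The representative interval is the per-coordinate median of the
members; support counts distinct callers, never calls. Merging is
permutation-invariant and clusters at a smaller range refine clusters at a
larger one (both property-tested against a transitive-closure oracle).

Filters, in order:

* **Strand and caller support**: ≥ 1 read on each strand, then deletions
  need 6 callers (or ≥ 4 if ≤ 300 bp) and duplications ≥ 5 (or ≥ 4 if
  ≤ 1500 bp). No support rule is stated for insertions and inversions in
  the underlying design (a handful existed pre-filter and none survived),
  so they are held to the duplication rule — the less stringent of the
  two, a conservative reading flagged here as a design choice. An
  alternative `strict_support` mode requires a flat ≥ 5 callers.
* **Multi-range consistency**: an event reported at the canonical 50 bp
  range is kept only if a same-type consensus with ≥ 50% reciprocal
  overlap exists at ≥ 2 of the seven ranges (1000, 500, 250, 150, 50, 25,
  10 bp; the canonical range counts as one). The 50% reciprocal-overlap
  criterion for cross-range matching and the choice of 50 bp as the
  reporting range are package decisions: the cross-pedigree rule is
  defined at 50 bp, which makes it the natural canonical range.
* **Cross-pedigree filter**: an event is discarded (from every matching
  family) if another family carries a same-type event with both
  breakpoints within 50 bp and length within 10% — recurrent "de novo"
  calls across unrelated families are overwhelmingly shared artifacts or
  leaked inherited variants. The length ratio is directionless:
  $|l_1-l_2|/\max(l_1,l_2)$.

## Clustered mutations

A cluster is a maximal run of same-chromosome DNMs in one offspring where
every consecutive pair is strictly less than the window (10 or 100 bp)
apart. Clusters are events, not pairs: a triplet counts once. The strict
inequality and the maximal-run construction are package choices (only the
window label is externally fixed); the construction is tested against an
O(n²) pairwise-linkage oracle, and every <10 bp cluster is provably
contained in a <100 bp cluster.

## Mutational signatures

SNVs are classified into the 96 pyrimidine-centred trinucleotide channels
(substitution class × 5′ base × 3′ base, purine-centred mutations
reverse-complemented), giving a catalogue $c \in \mathbb{Z}_{\ge0}^{96}$.
Exposures are fitted by non-negative least squares,
$\min_{e \ge 0} \lVert M e - c \rVert_2$, with the Lawson–Hanson
active-set algorithm — deterministic, unregularised; the reference matrix
$M$ is an input (a COSMIC-format TSV is accepted unchanged; tests use a
synthetic 96×5 matrix so no download is needed).

Each mutation is then assigned to exactly one signature: for channel $k$,
the signature maximising $e_s M_{ks}$ — the mixture-posterior-proportional
score — with ties broken to the lowest signature index and all-zero scores
going to an `"unassigned"` bucket. The assignment rule is a package
decision (the external pipeline's internal rule is undocumented); it is the
natural "one and only one signature" realisation of the fitted mixture.
Fitting is per cohort with per-mutation assignment by default; per-family
fitting is available by calling `fit_exposures()` on per-family
catalogues.

Cohort comparison is per signature: the 2×2 table (this signature vs all
others) × (cohort A vs B) by uncorrected chi-square, with an automatic
Fisher-exact fallback when any expected cell is below 5, Holm-adjusted over
the tested family. Per-family testing (Kruskal–Wallis or the Williams
binomial on per-offspring proportions) is restricted to signatures carried
by at least 10 offspring in each cohort — below that, per-family
distributions are too sparse to compare. For comparison against external
cohorts of different size, `downscale_catalogue()` rescales counts with
largest-remainder rounding so totals match exactly; remainder ties break by
index, making the operation deterministic.

## Statistics layer

* **Spectrum homogeneity**: Pearson chi-square without continuity
  correction (df = 1). The uncorrected form is used because it reproduces
  the classical homogeneity statistics for large count tables; the Yates
  correction would change them materially.
* **Holm adjustment** everywhere a family of endpoints or signatures is
  tested (step-down Bonferroni, verified against the definitional oracle).
* **Kruskal–Wallis** with tie correction for per-offspring endpoint
  comparisons; **Kolmogorov–Smirnov** (two-sided, asymptotic p) for indel
  and SV size spectra.
* **Negative-binomial regression** (NB2: variance $\mu + \mu^2/\theta$,
  log link, dispersion by maximum likelihood) of count endpoints on the
  exposure variable, unadjusted and confounder-adjusted, with Poisson and
  normal fits of the same design reported for AIC comparison — on
  overdispersed counts the NB model wins the AIC comparison, and in the
  zero-dispersion limit NB and Poisson agree (tested). Confounder pairs
  with $|r| > 0.7$ are pruned to the one ranked higher in a user-supplied
  plausibility ordering; the choice is recorded in the result rather than
  inferred. Wald 95% intervals are reported.
* **Williams overdispersed binomial** for signature proportions: logistic
  regression of per-offspring successes out of totals on cohort, with a
  heterogeneity factor $\phi$ inflating the binomial variance of offspring
  $i$ to $m_i p q\,(1+\phi(m_i-1))$. $\phi$ is estimated by iteratively
  equating the leverage-corrected weighted Pearson statistic to its
  expectation and reweighting by $1/(1+\phi(m_i-1))$; with no
  overdispersion the fit reduces to plain logistic regression ($\phi = 0$,
  tested), and under beta-binomial data the reported scale factor exceeds
  1 (tested).
* **Rates**: mean per-offspring counts with seeded percentile-bootstrap
  95% intervals (2000 replicates by default; the percentile method is the
  package's choice of CI construction).
* **Power**: `power_simulation()` draws Poisson per-offspring counts for
  two cohorts (baseline mean 62, the observed genome-wide rate scale
  ≈ 3719 SNVs / 60 offspring) and tests each replicate with
  Kruskal–Wallis. The machinery behind the original design's power claim
  is not documented, so the package states its own: with 30 offspring per
  cohort and a 1.5-fold rate increase, simulated power at α = 5% is
  essentially 100%, comfortably above the claimed 80%.

All stochastic routines take explicit seeds and restore the caller's RNG
state; identical seeds give bit-identical results.

## The synthetic-study generator

`simulate_study()` emits a complete input bundle with known ground truth.
Its defaults are the study conditions the package targets, fixed once:

| parameter | default | meaning |
|---|---|---|
| `n_families_per_cohort` | 30 | trios per cohort |
| `dnm_rate_mean` | 62 | mean DNMs/offspring at the reference paternal age (30 y) |
| `paternal_age_slope` | 0.02 /y | log-linear age effect (≈ 1.2 extra DNMs/y at the mean — the field's rule of thumb) |
| `cohort_fold` | 1.0 | rate ratio exposed/control (the null finding) |
| `indel_fraction` | 0.1 | ≈ 389 indels / 4108 DNMs |
| `paternal_fraction` | 0.8 | the canonical ~80:20 paternal:maternal origin ratio |
| `cluster_fraction` | 0.02 | small clustered fraction, as observed genome-wide |
| `parent_contamination_prob` | 0.05 | a stray single parental alt read (below threshold) |
| `sv_caller_sensitivity` | 0.95 | per caller |
| `breakpoint_jitter_sd` | 10 bp | truncated-normal breakpoint error (clamped at ±2σ: callers localise breakpoints from bounded local read evidence, so unbounded Gaussian tails are unrealistic) |
| `fp_sv_rate` | 5 | caller-private false positives per caller per family |

Counts are Poisson with log-mean linear in paternal age and cohort
(matching the NB analysis model with zero dispersion; `dispersion > 0`
switches to NB2 to exercise the AIC comparison). SNV positions are drawn
without replacement from genome positions whose actual trinucleotide
context matches the sampled channel, so generator channels and
genome-derived classification agree exactly (tested). Decoys each violate
exactly one named filter rule; inherited background variants are
Mendelian-consistent with filter-passing metrics, so only the violation
requirement removes them — on such input the cascade has recall 1 and
false-discovery 0 (tested).

What the generator does **not** emulate: read-level errors beyond the
parental-contamination knob, mapping artifacts, repeat-context error
enrichment, caller-correlated SV false positives, real chromosome lengths
or GC structure, and transmission phasing (parental origin is planted, not
inferred — read-backed phasing is out of scope). Passing tests therefore
demonstrate correctness of the pipeline's logic and statistics under a
clean error model, not robustness to every artifact of real sequencing
data.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty variant streams give
all-zero summaries; zero catalogues give zero exposures with a warning;
degenerate 2×2 margins are errors; Kruskal–Wallis on constant data returns
H = 0, p = 1. NNLS is deterministic (active set, tolerance ~1e-8);
downscaling and assignment tie-breaks are by index.

The shipped test suite runs the statistical simulations at sizes chosen to
give tight checks at interactive runtimes: cascade and merge oracles at
1000 random variants / 5 seeds; mixture recovery at n = 2000 over 20
replicates (mean absolute error < 0.05); NB null calibration at 500
replicates of n = 200; full-pipeline null calibration at 5 replicate
studies of 4+4 families with count-level calibration delegated to
`power_simulation()` at 400 replicates; power at 1000 replicates.

## Known limitations

The package consumes caller output; it does not align reads or call
variants, and function-effect prediction is consumed as annotation fields.
The cohort-mode genotyping rescue is a flag, not a re-implementation of
joint genotyping. Insertion/inversion consensus support rules are an
extrapolation (above). The Williams estimator uses the classic moment
iteration, not full beta-binomial likelihood; for heavily unbalanced
totals the two can differ. Bootstrap CIs are percentile-method and can
undercover for very small cohorts.
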