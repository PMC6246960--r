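---
title: "Methods: ctDNA detection, quantification and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ctDNA detection, quantification and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnaconcord)
```

# Scope

`ctdnaconcord` analyses matched tumor–plasma samples: somatic mutations
identified in a solid tumor are queried in the cell-free DNA (cfDNA) of
the patient's plasma, per-sample concordance is tabulated, circulating
tumor DNA (ctDNA) is quantified in copies per mL plasma, and baseline
ctDNA is used to stratify survival. All callers operate in
check-known-variants mode — they test a supplied locus, they do not
discover variants — and all internal coordinates are 0-based half-open;
1-based conventions appear only at the VCF/SAM boundary.

# Plasma variant detection

Sequencing low-frequency variants in plasma is error-limited, so all four
procedures suppress error with molecular family structure or an explicit
error model.

**Read families.** Reads sharing alignment start and end positions are
assumed to descend from one cfDNA molecule (an *endogenous* or
*positional* UMI); with tagged chemistry the family key additionally
includes the UMI sequence, so an identical tag at different coordinates
is two molecules. A family's consensus allele is its strict majority
(> half the reads); a tied family carries no evidence and is dropped from
consensus collapsing — majority semantics are implied by the > 95%
consistency rule below.

**Detection gates.** All gates are collected in `caller_thresholds()`:

| procedure | gates (defaults) |
|---|---|
| positional consensus | ≥ 2 families, each ≥ 5 reads, consistency strictly > 95% |
| tagged-UMI + CKV | consensus %SR ≥ 0.4 (SNV) / ≥ 0.2 (multi-base indel) |
| UMI family support | ≥ 2 alt-consensus families of ≥ 3 reads |
| amplicon binomial | depth ≥ 10, alt reads ≥ 2, %SR ≥ 0.3 (SNV) / 0.2 (indel), confidence ≥ 50 |

Count and %SR gates are inclusive (≥); the consistency gate is strict
(>), so a 20-read family with 19 variant reads — exactly 95% — does not
qualify. Each consistency check is evaluated family by family before
qualifying families are counted; the alternative reading (consistency
pooled over the two best families) is not implemented.

**The amplicon confidence score** is a reconstruction: the upstream
caller's score is proprietary. We use the Phred-scaled exact binomial
upper tail, $-10\log_{10} P(X \ge k)$ with $X \sim \mathrm{Binom}(n,
p_0)$ and a configurable null per-read error rate $p_0$ (default 0.1%),
so the published "confidence ≥ 50" corresponds to a tail probability of
$10^{-5}$. Gates are evaluated in the order depth → variant reads → %SR
→ confidence, and the first failure is reported as the machine-readable
`reason`; the %SR gate precedes confidence so that a fraction-based
failure is attributed to the fraction, not to the error model.

Two points the published rules leave open, and our choices:

* *Single-base indels.* The %SR thresholds distinguish SNVs from "indels
  spanning multiple bases" only. We apply the indel threshold (0.2%) to
  1-bp indels as well; `single_base_indel_as_snv = TRUE` switches them to
  the SNV threshold.
* *Family-support internals.* Only the stated family gate (two families
  of ≥ 3) is implemented for the UMI family-support path; the upstream
  caller's internal probabilistic model is out of scope.

# ddPCR quantification

A droplet digital PCR reaction partitions the template into $N$ droplets.
With a fraction $p$ of positive droplets, the Poisson correction gives
$\lambda = -\ln(1-p)$ molecules per droplet, hence $\lambda N$ molecules
in the reaction and $\lambda / v$ copies/µL for droplet volume $v$
(default 0.85 nL, the common large-instrument convention; it is
configurable because it cancels from every allele-fraction ratio and only
scales absolute concentrations). MAF is computed from the mutant and
wild-type estimates, and scaling to copies/mL plasma divides by the
fraction of the elution loaded and the plasma volume extracted. A fully
positive channel is saturation and raises an error rather than returning
a truncated estimate.

Yield-based conversion uses a haploid genome mass of 3.3 pg (≈ 303
genome equivalents per ng):

$$\mathrm{copies/mL} = \frac{\mathrm{yield}_{ng/mL} \times 1000}{3.3}
  \times \frac{\mathrm{MAF}\%}{100},$$

the constant under which a 22 ng/mL median yield at the 0.03% detection
threshold equals 2 copies/mL. The 0.03% threshold is inclusive (≥). Each
sample's ctDNA level is represented by its highest-MAF mutation, with
ties broken by lexicographic assay/locus label so results are
deterministic.

# Concordance

A sample with at least one followable tumor mutation is *concordant* when
at least one of those mutations is detected in plasma by the applicable
procedure's gates. The stricter all-mutations rule is exposed as
`require_all_variants` but is not the default: tracked mutations are
selected per sample, and any detected tumor-derived fragment demonstrates
tumor DNA in circulation. Summaries are stratified by stage (early
≤ IIA / advanced ≥ IIB; unknown stage excluded from the stage block),
tissue and platform, with samples assayed on both platforms counted in
each platform row. Percentages are rounded half-up to two decimals, the
convention of printed contingency tables (base R's half-to-even would
differ on exact ties). Plasma results at loci absent from the tumor list
raise a warning and are ignored.

# Survival analysis

The survival estimators are implemented in the package — the cut-point
scan needs the standardized two-group log-rank statistic internally — and
are cross-checked against the `survival` package in the test suite.

* **Kaplan–Meier**: product-limit $S(t) = \prod_{t_i \le t} (1 -
  d_i/n_i)$; the median is the earliest time with $S \le 0.5$
  (left-continuous convention when $S$ sits exactly at 0.5), undefined if
  never reached.
* **Log-rank**: observed-minus-expected over pooled event times with the
  hypergeometric covariance; $k$-group chi-square on $k-1$ df, and the
  signed standardized statistic $z = U_1/\sqrt{V_{11}}$ for two groups.
  A numerically singular covariance falls back to a Moore–Penrose
  inverse; zero-variance event times contribute zero.
* **Maximally selected cut point**: candidates are midpoints of adjacent
  sorted unique biomarker values leaving at least `min_group_fraction`
  (default 10%) of records on each side; the returned cut point maximizes
  $|z|$. No small-sample correction of the selected maximum is applied —
  the statistic is reported as a selection criterion, not a test — and a
  maximum that is numerically zero (e.g. identical survival in all
  subjects) flags the result unreliable. Only detected samples enter the
  search; undetected samples are assigned 0 copies/mL for display but
  never influence the cut point. Because the statistic uses ranks of the
  biomarker only, it is invariant under monotone transformations of the
  ctDNA scale. A sample exactly at the cut point is *low* (≤ rule).
* **Cox proportional hazards**: Breslow tie handling (the simplest
  standard choice), Newton iteration with step-halving to gradient norm
  < 1e-8, Wald 95% CIs on the log-HR scale, reference group `high`. A
  group with no events produces a monotone partial likelihood; the fit is
  flagged rather than silently reported.

The three-group report (high / low / not detected) contains per-group
curves and medians, the global and all pairwise log-rank p-values —
published analyses vary in which they quote, so both are emitted — the
median-survival differences against the high group, and the hazard-ratio
table.

# Synthetic data

Two generators make the pipeline testable without patient data.

**Cohort generator** (`simulate_cohort()`). Defaults encode the study
conditions the analysis assumes: a 180-patient pan-cancer mix dominated
by lung (93/180), breast (42/180) and colorectal (22/180); stages
36 early / 133 advanced / 11 unknown; 59.18% of tumors with one
followable mutation and 35.71% with 2–3 (drawn over support 1–4);
mostly SNVs (85%); cfDNA yields log-uniform within 7.13–405 ng/mL
plasma, with the early-stage range (7.13–80) kept below the advanced
range (15–405) because yield increases with stage — the published
summaries give only the pooled range, so the per-stage bounds are our
choice under that constraint; plasma detectability drawn per stage with
probability 0.32 (early) / 0.82 (advanced), the observed concordance
rates; and plasma MAF for detectable samples log-uniform over
0.28–94.7%. The observed MAF range spans two orders of magnitude and its
distribution is unreported, so log-uniform is a stand-in, not a claim.
Undetectable samples have all mutations at MAF 0 exactly.

**Read simulator** (`simulate_read_families()`). Each molecule becomes
one family (positional coordinates drawn uniquely unless a collision rate
is configured — collisions are the known failure mode of endogenous UMIs
and default to 0), family sizes from a configurable distribution
(default: shifted geometric, mean 6 — a fixture choice, no published
family-size distribution exists), and per-read error at a configurable
rate. One third of errors produce an untracked "other" base and two
thirds the opposite tracked allele, the three-wrong-bases argument with
the tracked allele as one of them; at MAF 0 the non-reference read
fraction therefore estimates the error rate and the "other" fraction one
third of it. No base-level sequence, quality scores or fragment-length
realism is attempted.

**Survival simulator** (`simulate_survival()`). Exponential event times
per group with administrative censoring at the study horizon — 27 months
converted at the calendar-average 30.44 days/month ≈ 822 days — and an
optional uniform accrual window (default 0). Default hazards place the
high group at a ~208-day median with the low and not-detected groups at
hazard ratios 0.2331 and 0.1875 against it, reproducing the prognostic
ordering the analysis expects; the Nelson–Aalen cumulative hazard of
simulated data is verified linear with the configured slope.

What passing tests on these generators shows is *internal* consistency:
the callers detect what the simulator spiked in, the estimators recover
the parameters the simulator used. It does not show performance on real
cfDNA, which has non-uniform fragment ends, context-dependent error,
PCR chimeras and contamination that the generators deliberately omit.

# Pipeline and reproducibility

`run_pipeline()` chains simulate → assay (ddPCR droplets and/or tagged-UMI
NGS per the platform mix, defaults 74:39:25 ddPCR:NGS:both out of 138) →
concordance → quantification → survival. The generating prognostic groups
are assigned from a configurable true cut point (default 210.53
copies/mL) *before* survival is drawn; the analysis then re-estimates the
cut point from the simulated data, so cut-point recovery is an honest
round trip. A single master seed is fanned out to every stage through
fixed documented offsets (`cohort` +100000, `droplets` +200000, `reads`
+300000, `survival` +400000, plus per-sample indices), so identical
configurations reproduce identical outputs and any stage can be re-run
from its written inputs; the output manifest records the seed and the
MD5 of the written configuration.

# Numerical choices and problem sizes

* Proportion maps must sum to 1 within 1e-9; violations name the
  offending map.
* Newton convergence at gradient norm < 1e-8; likelihood ascent enforced
  by step-halving.
* Degenerate inputs fail loudly: empty family lists give
  `reason = "no_families"`, zero consensus depth `"no_depth"`, saturated
  droplet channels and all-identical biomarker values raise errors.
* Test problem sizes were chosen so the whole suite runs in well under a
  minute: marginal-recovery checks at n = 10 000, error-symmetry at
  50 000 reads, caller sensitivity at 10 000 molecules, cut-point
  recovery over 100 replicates of n = 100, Cox CI coverage over 200
  replicates of n = 400, log-rank type-I error over 500 replicates of
  n = 300, and Poisson consistency over 500 replicates of 2 000 molecules
  in 10 000 droplets.

# Known limitations

* The amplicon confidence score and the family-support path are
  reconstructions of partially documented callers; their numeric scores
  are not comparable to the originals beyond the stated gates.
* The generators draw mutation loci as abstract coordinates; no sequence
  context, clonal structure or FFPE artifact model.
* No multivariable Cox, competing risks, time-varying covariates or
  progression endpoints.
* Absolute per-sample copy numbers from droplet data depend on the
  fraction of the elution loaded per reaction, which real studies rarely
  record per sample; MAF-based quantities are unaffected.
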