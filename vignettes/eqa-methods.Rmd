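---
title: "Methods: consensus assignment, error scoring and simulation in immunoEQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus assignment, error scoring and simulation in immunoEQA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoEQA)
```

## The problem

External quality assessment (EQA, also called external proficiency testing)
programmes in histocompatibility and immunogenetics circulate blinded samples
to participating laboratories, collect their reported results — HLA/KIR/HPA
genotypes, anti-HLA antibody specificity panels, crossmatch calls, chimerism
percentages — and score each result against an *assigned value*: the value
the provider treats as true. immunoEQA implements the full evaluation chain
of such a programme: nomenclature-aware comparison of typing results,
assigned-value determination (organizer reference, participant consensus, or
robust statistics), classification of errors into a taxonomy, aggregation of
success rates by scheme, year and analytical family, and a seeded synthetic
report generator so every stage can be exercised without confidential
laboratory data.

Thirteen schemes are modelled, grouped into five analytical families
(serology; molecular typing; antibodies; crossmatch; chimerism) — see
`scheme_registry()`. Chimerism (percent recipient cells after stem-cell
transplantation) is the only quantitative scheme; everything else is scored
qualitatively.

## Assigned values

**Organizer reference.** For DNA-based typing the organizer's own typing
results are considered correct, so whenever a reference table is supplied,
`typing_assigned_value()` and `assign_values()` use it regardless of what
participants reported.

**Typing consensus.** Without a reference, participant genotypes are grouped
into concordance-equivalence classes — two genotypes fall in one class when
either is a refinement of the other at their shared resolution
(`genotypes_equivalent()`). If the modal class reaches the typing threshold
(default 75%, the only consensus fraction the field documents; the package
applies the same default to typing and qualitative calls, configurable via
`consensus_params()`), its highest-resolution member becomes the consensus;
otherwise the parameter is not evaluable. A minimum of `min_n = 3`
contributing values is required for quantitative and typing consensus — the
field states no explicit floor, so this is a configurable package choice,
not a rule taken from any standard.

**Antibody consensus (75%/95% rules).** Per specificity, with positive
fraction `p` and omission fraction `q = 1 - p`:

* `p >= 0.75` — POSITIVE consensus;
* `q >= 0.95` — NEGATIVE consensus;
* `0.75 <= q < 0.95` — *non-assessable negative*: too many omissions to call
  positive, too few to call negative; never penalized;
* otherwise — NO consensus.

All threshold comparisons are inclusive ("at least 75%"), and the four
statuses partition the unit interval, which the test suite sweeps at step
0.001. Laboratories reporting a specificity as inconclusive should be removed
from that specificity's denominator before calling `antibody_consensus()`.

**Robust location/scale for chimerism.** Quantitative consensus uses the
classical iterative winsorized estimator (ISO 13528 Annex C, "Algorithm A"):

* initialize `x* = median(x)`, `s* = 1.483 * median(|x - x*|)`;
* iterate: clip the data to `x* ± 1.5 s*`, then `x* <- mean(clipped)`,
  `s* <- 1.134 * sd(clipped)`;
* stop when both updates move less than `tol * max(s*, tol)`
  (default `tol = 1e-6`) or after `max_iter = 100` iterations.

The constants 1.483 and 1.134 are the usual consistency factors for the MAD
and the winsorized standard deviation under normality. Two numerical choices
matter in practice. First, a **degenerate scale** (`s* = 0`, common when most
laboratories report the same rounded percentage) stops the iteration
immediately — the estimator is undefined on zero spread — and downstream
scoring falls back to an absolute window. Second, the relative convergence
criterion is floored at `tol` itself so the loop terminates on all finite
inputs. When no value is ever clipped the estimator equals the arithmetic
mean and `1.134 * sd` exactly, a property the tests assert; one arbitrarily
large outlier moves `x*` only by a bounded amount.

## Scoring and the error taxonomy

Every result receives exactly one status — CORRECT, ERROR or NOT_EVALUABLE —
and an ERROR carries exactly one category, so categories partition the
errors. For typing, `evaluate_typing()` applies a fixed decision order
(nomenclature > null allele > concordance > homozygosity > mismatch), which
makes the classification deterministic and independent of the order in which
ambiguity alternatives were written:

1. **NOMENCLATURE** — the payload does not parse, or reports the wrong locus.
2. **NULL_ALLELE** — some reported call still encompasses a null
   (non-expressed, suffix N) allele that the laboratory did not explicitly
   exclude, while the assigned genotype is fully expressed. Ambiguities
   containing a null allele must be resolved allele-by-allele; a generic
   "every null allele excluded" annotation is deliberately not representable
   in the report format.
3. **CORRECT** — the genotype is concordant with the assigned one *at the
   reported resolution*: reduced resolution is never penalized, so `A*24:02`
   matches an assigned `A*24:02:01:01`. An expressed-vs-null suffix conflict
   is discordant even when all numeric fields agree, because expression must
   be evidenced on the cells. A report at *higher* resolution than the
   assigned value is discordant under the prefix rule.
4. **HOMOZYGOSITY** — a single distinct reported allele (one call, or the
   same allele written twice) against a heterozygous assigned genotype, when
   the reported allele is concordant with one assigned copy. Reporting one
   allele and doubling it are treated identically; the `reported_doubled`
   flag is recorded but not scored, since the underlying claim is the same.
5. **ALLELE_MISMATCH** — any other (random) mismatch.

Antibody panels score per specificity (false-positive / false-negative
identification), with non-assessable and no-consensus specificities excluded
from scoring; screening calls score as SCREENING on mismatch. Chimerism uses
`|value - x*| / s* <= z_limit` (default 2) or, with a degenerate scale, an
absolute window of `abs_tol` percentage points (default 5). Neither knob is
prescribed by the programme description, so both are configuration values.
Disease-association schemes score the genotype and, separately, the reported
risk label against a genotype-to-risk map (`risk_map()`); the bundled
`cd_risk_map()` is a literature-informed editable default, because risk
interpretation depends on local guidelines. Whole-blood crossmatches are
scored against the whole-blood consensus only — never against the OR of the
T- and B-lymphocyte results, a documented source of over-interpretation
errors.

**Pass rule.** `scheme_pass()` defaults to "at most one errored sample per
scheme-year". EQA standards require a pass criterion but do not quantify one
publicly, so the rule is fully configurable (`max_error_samples`). The
pass-all statistic (`labs_passing_all()`) counts a laboratory in the
denominator if it has at least one scheme outcome that year.

**Aggregation.** Success rate is error-free results over valid results;
not-evaluable items never enter numerator or denominator. Scheme means are
unweighted over years; family means are unweighted over scheme means (not
pooled over result counts — pooling would be dominated by the antibody
schemes' enormous result volumes). All percentages are rounded half-up to
one decimal *at presentation only*; internal arithmetic is unrounded, and
family means are computed over unrounded scheme means (with the bundled
tables, both orders reproduce the same family figures). Recomputing the
bundled 12-year table means reproduces the published per-scheme means for 12
of 13 schemes; the B57 row recomputes to 99.3 against a printed 99.4,
consistent with the published mean having been taken over unrounded yearly
inputs, so B57 is excluded from the regression fixture.

## The synthetic-data generator

`simulation_config()` defines a miniature programme — by default 20
laboratories, 16 samples per scheme-year, 3 years — sized so that a full
pipeline run takes seconds while still giving stable rate estimates across
replicate seeds; the bundled 12-year participation table
(`reference_participation()`) can be used to configure full-scale rosters
instead. Defaults are chosen to emulate the published summary structure:

* per-scheme error rates default to `1 - mean success rate / 100` from the
  bundled tables (e.g. 0.052 for chimerism, 0.010-0.011 for high-resolution
  typing);
* per-scheme category mixes default to the published error-category
  proportions: 60.1% null-allele errors in high-resolution typing, 40.1%
  allele-variant mismatches in KIR, 62.2% quantification errors in
  chimerism. The published antibody proportions (89.7% identification,
  1.4-1.9% screening, 5.4% two-antigen-bead interpretation) do not sum to
  100, so the default mix normalises them to
  FN 0.4485 / FP 0.4485 / screening 0.019 / interpretation 0.084;
* method-tag mixes default to the published modal methods and late-period
  shares (NGS for high-resolution typing, SSO for low-resolution, Luminex
  single-antigen for anti-HLA antibodies, STR for chimerism).

Error injection is *realized concretely*, never just labelled: a null
alternative is appended unexcluded, a genotype copy is dropped, a pool allele
is substituted, a quantification is shifted 15-25 points beyond the
acceptance window (away from the [0, 100] boundary), a specificity is
toggled, a wrong risk label is reported. Each (scheme, year, laboratory)
triple draws from its own substream derived from the master seed, so adding
a scheme or year never perturbs another's draws and the same seed yields
byte-identical output files.

Three generator choices keep the injected signal identifiable, and they are
deliberate idealizations:

* **truth genotypes are heterozygous pairs of distinct expressed alleles**
  (EQA providers favour informative samples), so a dropped copy always
  scores HOMOZYGOSITY and an added null always scores NULL_ALLELE;
* **null alleles have zero truth frequency** in the default pool: they exist
  for injection, not as plausible truths;
* **honest reports carry no noise by default** (`chimerism_noise_sd = 0`):
  laboratories report the rounded truth unless an error is injected, so the
  expected recovered success rate equals `100 * (1 - error rate)` exactly
  and the per-result error indicator is Bernoulli by construction.

Within one sample the per-slot error probabilities are scaled in proportion
to the category-mix mass carried by each result slot (for chimerism:
quantification at `2 r * 0.622`, the qualitative detection call at
`2 r * 0.378`), so that the *average* per-result error probability equals
the configured scheme rate while the expected category shares equal the
configured mix.

What the generator does **not** emulate: real HLA haplotype or linkage
structure (the allele pool is a small fictitious set), assay-specific failure
physics (probe dropout, fluorescence), reporting-noise distributions of real
chimerism assays, inconclusive results, or year-to-year drift in the category
mixes (the published proportions are pooled over 12 years, so the generator
holds them constant per scheme). Passing recovery tests therefore shows that
the scoring and aggregation chain is self-consistent and unbiased under the
stated error model — not that real laboratories behave like the model.

## Problem sizes used in the checks

The test suite and the acceptance script use: the full bundled 12-year
tables for the worked examples; 1,000 random datasets (n between 3 and 50,
half with up to 20% planted outliers) for the robust-estimator oracle
comparison at 1e-9; a 0.001-step sweep for the consensus partition; all
report-times-truth genotype combinations from a 4-allele pool (including one
null allele) for the decision-tree oracle — 650 reports built from ambiguous
calls against 10 unambiguous truths; and 200 replicate seeds of the
20-laboratory, 16-sample chimerism and high-resolution-typing configurations
for rate and category-mix recovery (128,000 and 64,000 scored results
respectively).

## Interfaces

The package is a library in the style of the analysis packages of this
field: the exported functions, the CSV/JSON readers and writers
(`write_reports()`, `write_truth()`, `write_panel()`,
`read_simulation_config()`) and `run_eqa_simulation()` are the intended
surface, with `scripts/acceptance.R` as the reproducible end-to-end driver;
no shell command-line tool is shipped.

## Known limitations

* Serology is modelled as one-field antigen calls without broad/split
  equivalence tables; supply scheme-specific tables through the risk-map
  mechanism if needed.
* No allele-catalogue validation (IPD-IMGT/HLA) or G/P-group expansion:
  alleles are validated syntactically, not against a release.
* The consensus-class construction is greedy first-match; concordance at
  shared resolution is not transitive, so pathological mixtures of
  resolutions could split a class. With reference-mode typing (the normal
  case for DNA-based schemes) this never arises.
* `evaluate_chimerism()` scores against the consensus of the submitted
  values; if a large coordinated fraction of laboratories shared the same
  bias, the consensus itself would shift — a known property of
  consensus-based proficiency testing, not a defect of the estimator.
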