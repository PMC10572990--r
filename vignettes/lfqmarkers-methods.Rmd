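---
title: "Models and design choices in lfqmarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in lfqmarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqmarkers)
```

# The inference chain

`lfqmarkers` turns a long-format table of peptide intensities from a
label-free LC-MS experiment into (i) pairwise differential-expression
calls, (ii) exclusive-marker sets for each exposure group, and (iii)
pathway and interactome summaries of those markers. This vignette
documents the statistical model at each stage, the tunable parameters,
the choices made where several reasonable definitions exist, and what
the synthetic-data generator does and does not emulate.

The experimental unit structure is fixed by the design the package
targets: four exposure groups (CT, PCP, NIC, PCPNIC) by two sexes,
four biological replicate pools per group/sex, three technical
replicate injections per pool. Sexes are always analyzed separately.

# Quantification

**Identification filter.** A protein enters quantification only if it
has at least 2 distinct peptides and was observed, through any
peptide, in at least 2 distinct runs (`filter_identifications()`,
parameters `min_peptides`, `min_runs`). The run-presence rule is
applied *per protein*, not per peptide: the alternative (each peptide
individually required in two runs) is stricter and would interact with
the intensity-dependent missingness model in ways the presence filter
downstream already handles. This is a genuine ambiguity in common
practice; the per-protein reading is the package's documented choice.

**Hi3 abundance.** For each (protein, run) cell the abundance is the
arithmetic mean of the `min(3, available)` highest peptide intensities
in that run. Cells with one or two observed peptides use the mean of
what is available rather than being discarded — the identification
filter already guarantees two peptides globally, and keeping partial
cells maximizes the information available to the 3-of-4 presence
filter. Cells with no observation are absent rows, never zeros, and no
imputation is performed anywhere.

**Technical aggregation.** Run-level abundances are averaged across
the technical replicates of a pool before any statistics
(`aggregate_technical()`). The biological pool (n = 4 per condition)
is therefore the unit of inference. Treating all 12 injections per
condition as independent replicates would triple the apparent sample
size and understate the variance of the pool means
(pseudo-replication); averaging first is the conservative choice. A
pool counts as present if the protein appeared in at least one of its
three injections.

# Differential expression

For one sex and one ordered pair (focal, reference) of groups,
`protein_stats()` computes per protein, over pool-level abundances:

* presence counts per condition;
* condition means and coefficients of variation, CV = sample SD /
  mean;
* fold change FC = max(μ_f, μ_r) / min(μ_f, μ_r) on raw (untransformed)
  abundances;
* a two-level one-way ANOVA on the pool values (equivalent to the
  pooled-variance t-test, F = t²), via `stats::oneway.test(var.equal =
  TRUE)`;
* direction "up" iff the focal mean exceeds the reference mean.

`pairwise_compare()` then applies the cascade in a fixed order —
presence, CV, fold change, ANOVA — recording the first filter that
eliminated each protein:

| filter   | rule                            | default     |
|----------|---------------------------------|-------------|
| presence | ≥ `presence_min` of `presence_of` pools in **both** conditions | 3 of 4 |
| CV       | CV ≤ `cv_max` in **both** conditions | 0.30   |
| FC       | FC **strictly** > `fc_min`      | 1.5         |
| ANOVA    | p **strictly** < `alpha`        | 0.05        |

Choices worth spelling out:

* **CV scope.** The CV is computed over the four pool values within
  each condition, and the rule must hold in both conditions — the most
  conservative symmetric reading among the plausible ones (single
  condition, pooled, run-level).
* **Raw scale.** Both FC and ANOVA operate on raw Hi3 abundances by
  default, mirroring the screening convention of the acquisition
  software this pipeline is modeled on; `log_transform = TRUE`
  switches both to natural-log scale for users who prefer
  variance-stabilized inference.
* **No multiplicity correction for calls.** The cascade uses the
  per-comparison p < 0.05 as stated; a Benjamini–Hochberg `q_value`
  column is always reported for transparency but never used for
  calls. The CV and FC filters act as additional (non-inferential)
  guards, and marker calls additionally require concordance across
  three comparisons, which sharply reduces the practical
  false-positive burden (the planted-truth tests call zero false
  markers at 100 proteins).
* **Degenerate variance.** When every pool value is identical in both
  conditions the ANOVA mean square within is 0; the package defines
  F = 0, p = 1 when the means are equal and p = 0 when they differ,
  so zero-noise synthetic data cannot divide by zero.
* **Too few observations.** A protein with fewer than two pool values
  in a condition has its statistics flagged undefined
  (`stats_defined = FALSE`, ANOVA skipped) rather than raising an
  error; the presence filter excludes it from DE calls anyway.

# Marker set algebra

All six unordered group pairs are compared once; the reference role
goes to CT first, then NIC, then PCP, so the combined group is always
focal. Two marker definitions are exposed because the verbal
definition "commonly deregulated in all comparisons involving the
group" and the operational construction used for the combined group
(exclusive Venn regions intersected) do not coincide:

* `plain_intersection`: DE in all three comparisons involving the
  group.
* `exclusivity_refined` (default for the combined group): for each
  comparison, take the group's *exclusive* region among the
  comparisons sharing the same reference (e.g. only in PCPNIC vs CT,
  not in PCP vs CT or NIC vs CT), then intersect across the group's
  comparisons.

The refined set is always a subset of the plain one (tested as an
invariant). Membership ignores direction everywhere; directions are
attached per comparison from the group's own perspective
("Up"/"Down") with a `consistent` flag, since direction agreement is
an empirical observation, not a membership rule.

The sex-exclusivity summary uses, as denominator, the union of
proteins DE in at least one comparison of at least one sex, and counts
those DE in exactly one sex. The denominator choice is not forced by
any formal definition; the union-of-all-comparisons reading is the
package's documented one.

# Enrichment and interactome

`pathway_frequency()` ranks pathways by the raw count of query
proteins they annotate — matching the bar-chart summaries it
reproduces — not by an overrepresentation statistic, which would
require a background universe the offline annotation does not fix.
Ties at the k-th rank are broken lexicographically by pathway id so
output is deterministic; `k` defaults to 6.

`build_marker_graph()` keeps edges with confidence ≥ 0.4 (inclusive,
the "medium confidence" convention; scores above 1 are auto-detected
as the 0–1000 dialect and divided by 1000), induces the subgraph on
the marker set, and reports markers left with degree 0 in an
`unmapped` sidecar rather than dropping them silently. Subnetworks are
the maximal same-function node sets within each connected component; a
subnetwork is *isolated* when its component holds no other function.
Centrality ranking is by unweighted betweenness, then degree, then
name. The packaged fixture edge lists (`*_synthetic.tsv`) are
synthetic reconstructions consistent with the described connectivity
of the two published marker maps — adequate for testing graph
operations, but not measured interaction data.

# The synthetic-data generator

`generate_dataset()` draws, in order: peptide counts per protein
(shifted Poisson with floor `min_peptides_per_protein = 2`, mean
3594/337 ≈ 10.7), log-normal base abundances (`meanlog = log(1e6)`,
`sdlog = 1.2`), per-peptide ionization factors (log-normal,
`sdlog = 0.8`), pool-level biological noise, planted fold changes,
and per-observation technical noise:

> intensity(peptide, run) = base × bio(pool) × fold(group, sex) ×
> ionization(peptide) × tech(run)

Noise terms are log-normal with unit mean parameterized by CV
(`bio_cv = 0.15`, `tech_cv = 0.10` by default — typical mid-range
values for label-free intensities at the pool and injection level;
the emulated study reports no variance estimates, so these defaults
are chosen for realism and testability, not fidelity to that
dataset). Dropout is Bernoulli with logistic probability decreasing
in log intensity (`plogis(slope × (midpoint − log I))`); the default
`dropout_midpoint = -Inf` disables it, and tests exercising
missingness set a finite midpoint (11 on the natural-log intensity
scale gives a few percent missingness at the default abundance
level). With zero CVs and no dropout the chain is exactly
deterministic, and the Hi3 estimate equals base × fold × mean of the
top-3 ionization factors — an identity the tests assert.

The ground-truth object carries the planted effects, the peptide map
with ionization factors, and *expected* DE and marker sets obtained by
applying the same set algebra to the planted fold ratios (a protein is
expected-DE in a comparison iff its planted ratio exceeds 1.5 in
either direction). Because the expected sets come from the planted
parameters and the pipeline's sets from simulated data, agreement is a
genuine end-to-end parameter-recovery check, not a tautology.

What the generator does **not** emulate: correlated peptide
missingness within a protein, retention-time or m/z structure,
between-run normalization drift, interference/co-isolation,
identification FDR, or heavy-tailed contamination. Passing tests
therefore demonstrate correctness of the inference chain under the
stated stochastic model, not robustness to every artifact of real
LC-MS data.

# Problem sizes and determinism

The test suite and the acceptance script run at deliberately modest
sizes chosen to exercise every code path with comfortable margins:
parameter-recovery simulations use 100 proteins with 10 planted
fold-4 effects at 5 % CVs; the null calibration uses 5000 proteins
simulated directly at the pool level (the unit of inference), whose
p < 0.05 rate must fall in the binomial 99 % interval around 0.05;
oracle-equivalence checks use 200+ quantification cells, 1000 ANOVA
draws, Venn families up to 6 sets and graphs up to 12 nodes, each
against an independent brute-force implementation. All randomness is
seeded; identical configurations and seeds give byte-identical
outputs, including the pipeline manifest.

# Known limitations

* The cascade's raw-scale ANOVA is anticonservative under strong
  mean–variance coupling; use `log_transform = TRUE` when that is a
  concern.
* With four pools per condition the CV filter is itself noisy; a
  protein can oscillate across the 30 % boundary between seeds at
  moderate `bio_cv`.
* The exclusivity-refined marker definition depends on the full
  comparison lattice; it errors, by design, when an arrow is missing
  rather than degrading to the plain intersection.
* Pathway ranking by raw count favors large pathways; it reproduces
  the summary it models and is not an enrichment test.
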