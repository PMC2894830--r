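---
title: "Methods: duplicability of self-interacting genes in a protein interaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplicability of self-interacting genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupliPIN)
```

## The question and the data model

A protein that binds an identical copy of itself (a homomer) appears in a
protein interaction network (PIN) as a self-loop on its gene. One model of
interactome evolution holds that new complexes arise preferentially through
duplication of such self-interacting genes: the duplicate pair inherits the
interaction and can diverge into a heteromer. If that is so, self-interacting
genes should be *more duplicable* — retained in duplicate more often — than
genes without self-interaction, and the mode of duplication (whole-genome
duplication, WGD, versus small-scale duplication, SSD) should matter, since
dosage-balance constraints act differently under the two.

dupliPIN implements this analysis as a reusable pipeline over six
tab-separated inputs: a PPI edge list with self-loops, an all-against-all
peptide similarity hit table, a human–mouse ortholog map, an ohnolog
(WGD-derived gene) id list, a GO annotation table with a GO-slim mapping,
and a per-duplicate-pair Ks table. The central container is the S4
`InteractionNetwork`: canonical unordered gene-id pairs, with `(g, g)`
encoding a self-interaction, and the gene universe defined as the
interaction-bearing genes.

## Degree convention

Degree is the number of *distinct interaction partners*. Whether a
self-interaction makes a gene its own partner is a genuine convention
choice; dupliPIN counts it as **+1** (the gene is one of its own partners),
applied consistently everywhere. All degree-based outputs can be rerun
under the alternative (+0) reading via `geneDegree(countSelf = FALSE)`.
The degree-distribution slope (`degreeDistribution()`) is a plain
least-squares fit of log count on log degree over non-zero cells — a
descriptive power-law check only, never used downstream.

## Duplicability classification

`classifySimilarity()` applies the three-way similarity rule per gene,
using only its top non-self hit (minimal E-value, ties broken by maximal
bit score, then lexicographic subject id — deterministic and
order-independent):

* **excluded** — no hit at all, not even a self-hit (typically
  low-complexity masking or very short peptides); reason `unalignable`;
* **singleton** — no non-self hit with E-value < 0.1;
* **duplicate** — top non-self hit with E-value ≤ 1e-20 *and* at least 50%
  of **both** peptides aligned (`alignment_length / length` per sequence,
  single top hit, HSPs not merged);
* **ambiguous** — everything in between.

A hit that clears the E-value bar but fails the coverage test yields
*ambiguous*, not *singleton*: the gene has strong similarity evidence, so a
singleton call would be wrong. When a hit table carries several peptides
per gene, the longest peptide represents the gene. Raising the duplicate
E-value threshold can only grow the duplicate set (a tested monotonicity
property). Ambiguous and excluded genes never enter association tables.

`classifyOrthology()` gives the comparative, sister-lineage definition:
singleton = one-to-one ortholog in mouse; duplicate = one-to-many (two or
more mouse co-orthologs, i.e. mouse-lineage duplication); anything else
(no record, `other`/mixed relations) is excluded. Because duplicability is
measured in the mouse lineage, it cannot be confounded by interaction
changes that follow a human duplication.

`assignMechanism()` merges an ohnolog id list over the similarity calls:
listed genes are WGD — with source `reclassified` when the similarity
verdict was not *duplicate*, since synteny-based evidence overrides the
sequence-similarity call — and unlisted similarity-duplicates are SSD. The
report breaks reclassified counts down by prior verdict rather than
assuming which class they came from.

## Association statistics

`chiSquareTest()` computes the 2×2 Pearson statistic with the Yates
continuity correction on by default,

$$\chi^2 = \sum_{\text{cells}} \frac{\big(\max(|O - E| - 0.5,\, 0)\big)^2}{E},$$

with `df = 1` and the upper-tail chi-square p-value. The correction term is
floored at zero so near-proportional tables give exactly 0. The uncorrected
statistic is always reported alongside. From the published human-PIN
contingency counts this reproduces χ² = 45.02 (p = 1.96e-11) for the
singleton/duplicate partition and χ² = 3.96 (p = 0.047) for the mouse
one2one/one2many partition at printed precision.

Percentages in report tables are integer percents rounded
half-away-from-zero. One published cell (433/2595 printed as 16%) is not
reproducible under any standard rounding — 433/2595 is 16.7%, which this
package reports as 17% — an apparent truncation in the source table that we
document rather than silently match. Odds ratios are the cross-product
ratio with a log-normal 95% interval; zero cells trigger the flagged
Haldane–Anscombe correction (0.5 per cell).

## Degree-stratified analysis

`equalFrequencyBins()` sorts items and cuts them into near-equal
contiguous bins, remainder to the earliest bins, with the rule that tied
values never straddle a boundary (the boundary moves forward past the run,
and the remaining items are re-split). Realized bin sizes are part of the
output. The bins are display-only: the test of whether WGD membership
rises with connectivity is a per-gene logistic regression
(`fitDegreeLogistic()`, maximum likelihood via IRLS) of the binary outcome
on raw degree, with Wald tests. Complete separation is flagged
(`converged = FALSE`) rather than fatal. For the Ks analysis
(`ksBinMeans()`), each duplicate pair's Ks is attached to both member
genes; gene-level records are cut into equal-frequency Ks bins and the
mean degree per bin is reported. A gene in several pairs contributes one
record per pair. Ks-stratified tables are descriptive; no specific
age-adjustment procedure is claimed.

## Simulation-based enrichment

`runEnrichment()` compares the observed count of focal genes per GO-slim
term against (i) a simulated null — uniform draws of `|focal|` genes from
the background, all terms counted jointly per draw, giving the expected
mean, SD and Z score (default 10,000 draws, mandatory seed; SD = 0 flags Z
as unavailable) — and (ii) the exact hypergeometric null.

The *reported* p-value is two-sided by tail doubling,
$p = \min(1,\, 2\min(P(X \ge k),\, P(X \le k)))$. This is a deliberate
design choice: the report calls both over- and under-representation from
the same table, and a one-sided tail taken in the direction of the
observed deviation would have a null type-I rate near $2\alpha$ at
threshold $\alpha$ (the upper and lower tails are disjoint events). The
doubled p controls the rate at $\alpha$, which the test suite verifies
empirically on null universes. The directional one-sided tail remains
available as `hypergeomTailP()`. Bonferroni adjustment uses m = the number
of terms tested *within the same namespace* (biological process and
molecular function adjusted separately, matching the split report tables);
m is printed so the joint convention can be audited. Direction is `over`
iff observed exceeds the simulated mean.

## The synthetic-data generator

`generateBundle()` emits all six inputs plus per-gene ground truth,
mutually consistent and byte-reproducible under one master seed (named
sub-streams per file, so adding an output never perturbs existing ones).
Defaults are fixed at the conditions of the human dataset the pipeline
models: 8881 genes; preferential-attachment degree model with 2 edges per
gene (~4 mean degree, power-law tail); 21% baseline self-interaction; 62%
duplicates, 7.4% ambiguous, ~1.15% unalignable; half of duplicates WGD; a
planted self-interaction↔duplicability odds ratio of 1.5; ~12% of the
ohnolog list drawn from non-duplicates (synteny-only evidence); a 2.3%
one2many ortholog rate with a 1.4× multiplier for self-interacting genes;
lognormal Ks with median 2.0 (WGD, ancient two-round vertebrate
duplications) versus 0.6 (SSD, mixed ages), log-SD 0.4; and GO-slim-style
annotations at field-realistic base rates with kinase activity and cell
death planted at 2× and 1.8× among self-interacting genes.

Two constructions keep planted effects clean. Self-loops are assigned
*after* graph growth with
$\operatorname{logit} p = \operatorname{logit}(\text{base}) + c\,k +
\log(\text{OR})\cdot 1[\text{duplicate}]$, so the odds ratio is exact by
construction conditional on degree (`degree_self_coupling` defaults to
0.02; set it to 0 to isolate the OR). The degree–WGD coupling is planted
through vertex assignment: among duplicates, WGD-labeled genes occupy
high-degree vertices ranked by a latent score $c\,k + \varepsilon$ with
standard-logistic noise, so P(WGD | k) follows a logistic curve with slope
≈ `degree_wgd_coupling` (default 0.08) while gene labels and duplicate
pairings stay intact.

Planted similarity hits respect the classifier thresholds with margin
(duplicate E-values log-uniform on [1e-120, 1e-25], ambiguous strictly
inside (1e-20, 0.1), singleton decoys at E ≥ 0.5), so classification
recovers planted labels exactly — by design, a round-trip test of the
classifier logic, not a claim about real BLAST output, where borderline
E-values, multi-HSP alignments and asymmetric hits blur the boundaries.
Likewise the generator does not emulate interaction false positives/
negatives, study bias in PPI detection, or the GO annotation DAG; passing
tests demonstrate correct statistical machinery and recoverable planted
effects, not field performance on any particular database release.

## Numerical choices and problem sizes

Seeds are mandatory wherever randomness enters; results are reproducible
and input-order invariant (enrichment sorts its gene sets internally).
Test problem sizes were chosen as the smallest that make the statistical
checks sharp: the classifier round trip runs at 10,000 genes; odds-ratio
coverage uses 100 replicates at 5,000 genes; logistic-slope recovery uses
5,000 genes; enrichment type-I control uses 200 null universes of 2,000
genes with focal sets of 1,000 (large annotation counts keep the discrete
hypergeometric null near-continuous, so the nominal rate is meaningful);
the hypergeometric tail is checked against exhaustive subset enumeration
for every universe size up to 15.

## Limitations

* The pipeline consumes precomputed similarity hits, ortholog maps,
  ohnolog lists and Ks values; it does not run searches, infer orthology
  or estimate Ks, so its conclusions inherit the quality of those inputs.
* The chi-square test assumes independent genes; paralogous gene families
  violate independence mildly, and no family-level correction is applied.
* Bonferroni control is per namespace; with many namespaces a joint
  correction would be stricter.
* Published WGD/SSD-versus-singleton statistics depend on the exact
  post-merge singleton set of the original compilation, which is not
  recoverable from printed totals; the pipeline reports its own computed
  values for these comparisons rather than treating the printed ones as
  reproduction targets.
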