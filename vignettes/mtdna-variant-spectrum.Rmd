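---
title: "Methods: mtDNA variant-spectrum analysis for case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA variant-spectrum analysis for case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Human mitochondrial DNA (mtDNA) is a 16,569-bp circular genome, maternally
inherited, with an extreme mutational bias toward transitions
(purine&harr;purine A&harr;G, pyrimidine&harr;pyrimidine C&harr;T) over
transversions. In a case-control resequencing study, each subject's mtDNA is
deep-sequenced, variants are called against the revised Cambridge Reference
Sequence (rCRS, NC_012920.1), and the question is whether cases carry an
unusual spectrum — more novel variants, more transversions, more
disease-associated polymorphisms, more heteroplasmies — than matched
controls. `mitospectra` implements that whole analysis: variant
representation and classification, novelty and disease-association lookup
against a flat-file catalog, allele-fraction thresholding with orthogonal
confirmation, cross-platform concordance error statistics,
macrohaplogroup assignment, and the proportion/contingency statistics
layer, together with a cohort simulator that provides ground truth for
every stage.

## Variant representation and classification

Variants are rows of a tibble: 1-based rCRS `position`, `ref`, `alt`
alleles, a `class`, and an optional `allele_fraction`. An insertion has an
empty `ref` and is anchored to the base *after which* the sequence is
inserted; a deletion has an empty `alt`. Multi-base substitutions are
decomposed into adjacent single-base substitutions before classification,
because the transition/transversion taxonomy is per base: of the 12 ordered
base pairs, 4 are transitions and 8 transversions, which is why a 2:1
transversion:transition ratio is expected from random sequencing error
while real mtDNA variation runs near 28:1 the other way.

Indels inside repeated tracts are ambiguous in placement: inserting a C
anywhere in the 303–309 poly-C run yields the same molecule. Catalog
lookup must therefore be placement-invariant, so `normalize_variants()`
shifts every indel to the 3'-most placement (the HGVS convention), wrapping
across the circular origin. The placement rule is a convention choice —
how the original analyses keyed homopolymer indels when matching catalogs
is not documented — but any placement-invariant canonicalization gives the
same novelty answers, and the tests verify canonicalization by brute-force
sequence equality over all placements. Position 3107, the historical
placeholder `N` of the rCRS, is excluded from the substitution space and
from all screened-base denominators: no true base exists there.

## Thresholds and confirmation

Three thresholds govern calling, all surfaced as arguments with the study's
values as defaults:

* **reporting threshold** (default 0.05): calls below 5% allele fraction
  are never reported;
* **heteroplasmy filter** (default 0.25): mixed calls below 25% are
  excluded as likely false positives; fractions in [0.25, homoplasmic
  cutoff) are *heteroplasmic*;
* **homoplasmic cutoff** (default 0.95): observed heteroplasmies in this
  design ranged 25–60%, and no upper boundary between heteroplasmy and
  fixation is dictated by the data, so 0.95 was chosen to tolerate
  sequencing noise at fixed alleles. It is configurable and nothing
  downstream depends on its exact value.

Confirmation is a disjunction: a primary call survives iff its normalized
key appears in at least one confirming list (software reanalysis, a
sequencing rerun, or an orthogonal platform), keeping the primary allele
fraction. Duplicate keys within one raw list collapse to the maximum
fraction so results are order-independent.

## Concordance statistics

Comparing a test call set against an orthogonal truth set over a screened
region (the bases the orthogonal method actually covered after quality
trimming) yields per-class counts S (truth only: false negatives), B
(both), I (test only: false positives), stratified into transitions,
transversions, and insertions+deletions. The false-negative variant rate
is S/(S+B), the false-positive variant rate I/(I+B); a zero denominator is
reported as undefined, not 0. Overall accuracy is
(screened bases − S − I) / screened bases, i.e. every screened base
without a discordant call counts as concordant — this matches the
">99.9%" framing used for such comparisons. Matching is key-exact and
fraction-blind: two platforms confirming the same heteroplasmy at
different fractions still agree.

## Haplogroup assignment

The bundled haplogroup table is a curated two-to-three-level fixture tree
over the eight macrohaplogroups relevant to an African-American cohort
(L0, L1, L2, L3, M, J, H, U), with H — the rCRS's own lineage — as the
root with an empty defining set. Assignment scores each node by the
cumulative match fraction along its root-to-node path
(matched defining variants / path defining-set size); the fraction, rather
than the raw matched count, avoids biasing toward deep nodes with long
paths. Nodes with no matched defining variant are not candidates, so a
variant-free genome falls back to the root haplogroup H. Ties break to the
deepest node, then lexicographically. Private variants never change any
node's score. Back-mutations are not modelled — a missing defining variant
simply lowers the score — which is adequate at fixture scale but is a
known limitation against full phylogenies; the production-scale
alternative (maximum-likelihood placement against the full PhyloTree) is
out of scope, and per-sample agreement with assignments made by other
tools is therefore not asserted anywhere.

## Statistics layer

* **Fisher's exact test, two-tailed**, uses the "sum of all tables with
  probability at most the observed" rule with relative tolerance 1e-7 for
  ties — the convention of `stats::fisher.test()` and of the common online
  calculators. The implementation is checked against an independent
  hypergeometric enumeration oracle over all margins &le; 30.
* **Modified-Wald (adjusted Wald) intervals** use the
  add-2-successes/add-2-failures center (x+2)/(n+4) with normal-quantile
  half-width and clipping to [0, 1]; this variant (not the +z&sup2;/2 form)
  reproduces all five published intervals from their (x, n) inputs.
  A clipped negative lower bound with a positive point estimate renders as
  "<0.01%", matching the published tables.
* **t tests from summary statistics** use the Welch form with
  Welch–Satterthwaite degrees of freedom; with equal group sizes it
  coincides numerically with the pooled form, and it is the safer choice
  where group variances differ several-fold (as they do for intra-ocular
  pressure).
* Printed percentages round half away from zero, since banker's rounding
  would disagree with the published tables at .5 boundaries.

## The synthetic cohort generator

There is no bundled real data: the rCRS sequence itself is not
redistributed here. `rcrs_synthetic()` builds a deterministic synthetic
stand-in that preserves what the analysis actually consumes: the 16,569-bp
coordinate frame, the placeholder N at 3107, the 303–309 poly-C tract plus
several planted homopolymer tracts, and the correct reference allele at
every position named in the bundled catalog. Everything derived from it is
labelled `synthetic`.

`simulate_cohort()` emulates the study conditions with these defaults,
each traceable to an observed quantity:

| parameter | default | rationale |
|---|---|---|
| cohort | 22 cases + 22 controls | study design |
| macrohaplogroup weights | L0 2/44, L1 9/44, L2 12/44, L3 15/44, M 1/44, J 2/44, H 1/44, U 2/44 | observed composition (86% African) |
| defining-set sizes | 10–46 along root-to-node paths | African lineages diverge far from the rCRS |
| private variants / sample | Poisson(10) | total burden &approx; 49/sample, &approx;2,166 instances |
| ts:tv bias | 28:1 | between the observed 27:1 (cases) and 30:1 (controls) |
| novel rate / instance | 0.002 | 4 novel / 2,166 instances |
| heteroplasmy rate / sample | 6/44, fraction U(0.25, 0.60) | six observed heteroplasmies in that range |
| disease-variant carriage | printed per-group counts / 22 | reproduces 84 and 87 instances in expectation |
| common indels | 4 tract polymorphisms, freq 0.05–0.55 | indel burden concentrated at homopolymers |

The per-instance novel rate and the per-sample rates are converted to
per-private-draw probabilities using the expected burden computed from the
tree and weights, so realized per-instance rates match the configured ones
in expectation. Transversions among defining variants are allocated to
tree edges deterministically, weighted by each edge's inclusion
probability, so the cohort-level ts:tv ratio converges to ~28:1 as the
simulated cohort grows rather than to whatever a random draw happened to
place on heavily shared edges. Group labels are independent of haplogroup
and of everything else: the generator is a null model, reflecting the
study's central negative finding.

`simulate_platform_errors()` overlays the sequencing-error model: each
sample's screened region is the D-loop portion of the amplicon plus one
random 300-bp coding window (~1,330 bp/sample, ~58,000 bases cohort-wide),
false negatives hit indels with probability 0.75 (transitions 0.002,
transversions 0), and false positives are injected per retained variant
with odds fp/(1−fp) so that I/(I+B) estimates the configured rate
(transitions 1%, transversions 11.8%). Errors are injected only inside the
screened region, where the concordance comparison can see them, and every
injection is written to a ledger that the tests reconcile exactly against
`compare_callsets()` output.

**What the generator does not emulate.** Samples are i.i.d. given the
haplogroup layer — there is no coalescent within haplogroups, so variant
sharing between samples of the same lineage is all-or-nothing at the
defining sets. One visible consequence is that the singleton share of the
rarity histogram (~40–50%) sits below the ~71% observed in real data,
where subclade structure makes sharing more graded. Read-level error,
strand bias, depth variation, nuclear pseudogene contamination and
recombination (absent in mtDNA) are all unmodelled. Passing tests
therefore demonstrate correctness of the *analysis* over call sets with
realistic summary structure, not robustness to raw-read artifacts.

## Numerical and design choices

* Coordinates are 1-based inclusive on a circular genome; indel
  normalization wraps across the origin, with a guard against the
  degenerate whole-genome tract.
* The genome length is 16,569 bp throughout; an internally inconsistent
  smaller figure that circulates in some summaries is contradicted by the
  coordinate range 16,497–16,569 and treated as a typo.
* Novelty is keyed on (position, ref, alt), not position alone, and is
  fraction-blind: heteroplasmic and homoplasmic observations of one allele
  share a catalog key.
* Degenerate Fisher tables (a zero margin) return p = 1; undefined error
  rates are flagged rather than coerced; `tstv_ratio()` with zero
  transversions is flagged infinite rather than capped.
* Stochastic generator checks in the test suite pin a seed and assert that
  injected error counts lie inside the central 99.8% interval of their
  exact binomial law — tight enough to catch any mis-implemented rate,
  wide enough not to fail on ordinary sampling fluctuation. Distributional
  cohort checks run at 44 samples (the study size) and convergence checks
  at 500 samples, sizes chosen so the whole suite stays fast while the
  binomial bands remain informative.
* Fisher units for case/control contrasts are carriers (subjects), the
  convention used for every published contrast here; for indel-instance
  comparisons the original unit is ambiguous, so no published p-value for
  that comparison is asserted.

## Known limitations

Amino-acid consequence annotation is carried as catalog metadata, not
computed from codons (the synthetic reference has no real reading frames),
so synonymous/nonsynonymous contrasts on *simulated* cohorts are not
meaningful — the published nonsynonymous comparisons are computed from
their printed carrier counts instead. The haplogroup fixture tree is
deliberately small; users with a full phylogeny can supply their own TSV.
Pathogenicity prediction, conservation lookups and ancestral-reference
(RSRS) re-rooting are out of scope.
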