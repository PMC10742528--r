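---
title: "Trio variant prioritisation: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio variant prioritisation: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippotrio)
```

## The problem

A sequenced rare-disease trio yields millions of variants; a reporting
laboratory can assess only a handful. Clinical services in the UK solve this
by restricting analysis to preselected gene panels, at the cost of missing
pathogenic variants outside the panel. The alternative implemented here is
panel-agnostic: keep any variant whose annotations mark it as having high
pathogenic potential, regardless of gene, and rely on allele frequency,
in-silico scores, ClinVar and call quality to keep the burden low. This
package implements both strategies over the same cohort representation so
that their efficiency — diagnoses and reportable findings *per variant
assessed* — can be compared like for like.

## Cohort representation

A cohort is a pair of tables: `variants` (one row per site and alternate
allele, keyed `chrom:pos:ref:alt`, 1-based VCF coordinates) and `calls` (one
row per variant and sample with genotype class, allele depths and genotype
quality), plus the pedigree. Multi-allelic records are decomposed before any
filtering: per-allele INFO values are split positionally, allele depths are
re-indexed to (ref, alt), and genotypes are re-expressed relative to the one
alt allele under consideration. An annotation absent from a record stays
`NA`; no filter ever sees a silently imputed zero.

Gene symbols are matched exactly (after whitespace stripping, case
sensitive). Alias resolution is deliberately out of scope: it would make
results depend on an external alias table and a resolution policy, and the
deterministic behaviour is easier to audit.

## Inheritance models

`classify_single()` is a pure function of one trio context:

* **de novo** — proband het (or hemizygous on chrX in a male), both parents
  present and hom-ref, and all three genotype qualities strictly above
  `min_gq`. With `min_gq = 0` the quality requirement disappears; this mode
  exists because the panel-based workflow's gene-agnostic de novo search is
  explicitly not filtered on quality, while the panel-agnostic cascade uses
  `min_gq = 40`.
* **dominant inherited** — proband het and no *unaffected* sequenced parent
  carries the allele. A carrier parent who is affected or of unknown status
  does not block the call, and an absent parent cannot confirm or refute
  transmission, so the variant is retained (this is what inflates the
  candidate count in a family sequenced without one parent).
* **hom recessive** — proband hom-alt, every present parent het.
* **X-linked recessive** — chrX, male proband hemizygous (or called hom-alt,
  the common encoding for male X genotypes), mother het, father not a
  carrier.
* Mitochondrial and chrY variants are never classified: neither strategy
  under comparison analyses them.

A parent whose genotype at a site is missing (`./.`) is treated as absent at
that site for the same reason an unsequenced parent is: transmission cannot
be confirmed through an uncalled genotype.

**Compound heterozygotes.** Pairs are formed per gene among proband-het
variants. With both parents sequenced, a pair is kept only when one variant
is carried by the mother alone and the other by the father alone — provable
trans configuration. With an absent parent, origin becomes unknowable for
variants not seen in the sequenced parent; such pairs are kept but flagged
`phase_unknown`, because dropping them would silently discard exactly the
candidates that matter in incomplete trios, while keeping them unflagged
would overstate certainty. A pair is rejected if the two alleles are
provably on the same parental haplotype, if either allele is unattributable
de novo, if both parents carry both (no phase information at all), or if any
unaffected family member carries both alleles (they would be an unaffected
compound het). Read-backed phasing is out of scope.

## The filter cascade

Thresholds live in `hippo_config()`; the defaults are the values of the
strategy being modelled, and every comparison is strict (`>` / `<`):

| parameter | default | unit | role |
|---|---|---|---|
| `af_dominant` | 0.001 | fraction | max population AF, dominant arm |
| `af_recessive` | 0.05 | fraction | max population AF, recessive arm |
| `cohort_af_max` | 0.01 | fraction | within-cohort AF cap (both arms) |
| `coding_window_bp` | 20 | bp | window around coding exons |
| `spliceai_min` | 0.2 | delta score | splicing variants only |
| `cadd_min` | 15 | PHRED | all variants |
| `allele_balance_min` | 0.2 | fraction | het calls only |
| `gq_min` | 40 | PHRED-like | proband (and de novo confirmation) |
| `missing_score_policy` | retain | — | absent CADD/SpliceAI/AD |

Decisions the cascade embodies, where the design was genuinely open:

* **Missing scores fail open** (`retain`): a pathogenicity *filter* should
  not discard a variant because an annotation pipeline produced no score for
  it (indels routinely lack CADD in some annotation setups). The `drop`
  policy is available for users who want the conservative behaviour; the
  policy is also the documented treatment for absent allele depths and an
  absent cohort AF.
* **The ClinVar override has a bounded scope**: a P/LP classification
  rescues a variant blocked by a carrier unaffected parent (pathogenic
  variants are retained even if inherited, e.g. reduced-penetrance dominant
  disease) and rescues failing CADD/SpliceAI rules, but never the
  allele-frequency caps. An unbounded override would let recurrent benign
  P-submissions of common variants flood the output, defeating the purpose
  of a burden-reducing filter.
* **FILTER status is ignored** by the panel-agnostic cascade (it quality
  controls *all* variants through GQ and allele balance instead), while the
  panel-based emulation requires PASS — mirroring the two workflows'
  differing QC rows.
* **"Splicing variant"** for the SpliceAI rule means every consequence term
  is a splice-site, splice-region or intronic term; the rule is skipped for
  variants that qualify through a coding consequence.
* **Synonymous variants**: a variant synonymous on *every* transcript fails
  the variant-type rule, except when its SpliceAI score exceeds the
  threshold, in which case it is retained with the rule marked `overridden`
  in the trace. The panel-based emulation instead drops synonymous variants
  unconditionally (its workflow states that synonymous variants affecting
  splicing are ignored).
* **Cohort AF** is read from the `COHORT_AF` INFO field; when the field is
  entirely absent the package computes the founder allele frequency from the
  cohort's own genotypes. In an eight-family cohort a single founder
  heterozygote already exceeds the 0.01 cap, so small cohorts should supply
  the field from their joint-called background (the modelled study drew it
  from >15,000 joint-called samples).
* **Candidates are per proband**: a variant shared by two affected siblings
  yields two candidate rows, matching how reported-variant counts are
  tallied per proband in the modelled study.

Every emitted candidate carries a `rule_trace` listing all nine rules with
outcome `pass`, `fail`, `overridden` or `skipped`; a candidate exists only
if no rule failed. Output order is deterministic (family, proband,
chromosome 1–22/X/Y/MT, position, ref, alt).

`restrict_to_gencc()` keeps candidates whose gene has a *definitive* or
*strong* gene–disease validity record; weaker assertions (moderate, limited,
disputed, refuted) do not qualify.

## Reportability review

`apply_exclusion_criteria()` models the post-filter curation step as six
rules over curator-supplied evidence flags (second hit found, phenotype
match, tissue expression, pathway plausibility, LoF curation, IGV artefact).
Evidence is an *input* — the package never queries expression atlases or
literature — and an unknown flag never fires a rule, so the engine defaults
open. The one carve-out mirrors the curation policy being modelled: a
phenotype mismatch does not exclude a variant classified P/LP in ClinVar.
Whether a heterozygous hit sits in a recessive-disease gene is likewise
encoded by the curator through the `second_hit_found` flag (setting it to
`false` asserts both facts); the gene-validity table used for the known/novel
gene distinction carries no inheritance mode, so the package cannot and does
not infer it.

## Panel-based tiering

Tier precedence is first-match: Tier 1 (pLoF or confirmed de novo in a green
panel gene) over Tier 2 (other coding ± 8 bp non-synonymous in a green
gene) over gene-agnostic de novo over gene-agnostic Exomiser
(rank ≤ 3 *and* score ≥ 0.95; a variant without Exomiser annotations never
enters this branch). The workflow being emulated presents the panel tiers
before the gene-agnostic branch and never states a precedence for variants
qualifying twice, so the more specific label wins here. The gene-agnostic de
novo branch applies no genotype-quality or FILTER requirement but does keep
the dominant-arm AF cap (it sits downstream of the inheritance/AF prefilter
funnel); the Exomiser branch consumes its annotations as-is with no AF cap.
The recessive AF cap (0.01) applies to both the homozygous and compound-het
arms, since the emulated workflow lists a single recessive threshold.

## Comparison statistics

Rates are `100 * n / n_assessed`. The report's reportable-rate numerator for
the gene-validity-restricted strategy is the reportable count of the
*unrestricted* cascade: the curation step is applied to all candidates
independent of gene-validity status, and its yield is related to the smaller
restricted assessment burden. This reproduces the published 12/15 = 80%
figure and is the one place a per-family `reportable <= assessed` inequality
can be violated by construction (the inequality holds for the unrestricted
and panel-based strategies).

The **Wilcoxon signed-rank** engine offers exact enumeration over all `2^n`
sign assignments (average ranks under ties, so it remains exact with tied
differences) and a tie-corrected normal approximation with continuity
correction; `auto` chooses exact for tie-free data up to n = 20. The
published assessment-burden p-values (0.022 restricted, 0.35 all-genes)
arise under the normal approximation, which is what any mainstream
statistics package produces for these tied data. The **Fisher** engine sums
hypergeometric probabilities not exceeding the observed table's. The
report's 2×2 tables pair diagnoses with *assessed totals* per strategy —
(3, 15 | 2, 63) giving p = 0.066 for the restricted comparison and
(3, 41 | 2, 63) giving p = 0.39 for all genes — which is the construction
that reproduces the published values; both engines equal brute-force
enumeration oracles in the test suite. Diagnostic status itself is always a
truth label supplied by the user: clinical causality is not computable from
annotations, so the package computes rates, never diagnoses.

The phenotype-term comparison (HPO terms recorded per proband by researcher
vs clinician) is carried as counts only; no semantic similarity is
attempted.

## Synthetic cohorts

`generate_cohort()` emulates the modelled study design: eight families,
seven full trios plus one family sequenced as father and two affected
monozygotic twins without maternal DNA. Defaults plant the study's finding
pattern — de novo variants in most families, compound heterozygotes in
three, one pathogenic variant inherited from an unaffected carrier parent —
all constructed to satisfy every cascade predicate. Background variants
(150 per family by default; tests use 20–125 to keep the suite fast) draw
population AF from a 70/30 mixture of a broad Beta(2, 5) and a rare-tail
Beta(0.5, 60), CADD from a truncated Normal(8, 5), a quarter synonymous
consequences, and genotypes that are predominantly inherited from a single
unaffected parent — so the background is overwhelmingly filterable (well
under the documented 5% ceiling; typically < 0.5%).

The truth manifest records, per variant, the by-construction value of every
predicate and the derived `satisfies_hippo`. Two honesty notes: a plant
asked to violate the cascade draws *one* predicate to break, and when the
broken predicate is rescued by another (a pathogenic inherited plant whose
CADD break is overridden by its own ClinVar status) the manifest records the
true outcome, not the intention; and the manifest evaluates single-variant
arms, so an accidental background compound-het pair can legitimately pass
the cascade without being manifest-satisfying — the recovery tests therefore
treat the manifest, not the plant list, as ground truth, and check
non-comp-het candidates against it exactly.

Generation is deterministic given the spec's seed, with one derived RNG
stream per family so a family's data do not depend on how many other
families are generated after it. An X-linked plant in a family whose proband
is not male fails fast with an explanation rather than silently emitting an
impossible genotype.

**What passing tests do and do not show.** The generator emulates annotation
distributions and Mendelian genotype patterns; it does not simulate linkage
disequilibrium, haplotype structure, sequencing reads, caller artefacts or
annotation disagreement between tools. Recovery of 100% of satisfying
plants demonstrates the cascade implements its predicates faithfully, not
that those predicates achieve any particular sensitivity on real exomes —
that evidence comes from the reproduced study numbers on the printed
fixtures.

## Numerical and degenerate-input choices

* All threshold comparisons are strict; boundary values (CADD 15.0, GQ 40,
  a variant exactly 20 bp into an intron) behave as documented in the unit
  tests.
* Output ties are broken lexicographically by variant key.
* Zero paired differences are dropped before the signed-rank test;
  all-zero input is an error (the test is undefined), as is a zero
  assessed-count denominator for a rate (`NA` with a warning).
* Degenerate Fisher margins give p = 1.
* Exact signed-rank enumeration is refused above n = 20 (2^n blow-up);
  `auto` switches to the normal approximation there.
* The cascade never errors on a degenerate trio: an unclassifiable variant
  simply gets model `none` and is dropped.

## Known limitations

* Only one consequence list per variant is carried; transcript-level
  consequence resolution ("any transcript") is approximated by the term
  list the annotation supplies.
* No CNV/SV or STR analysis, no liftover, one genome build assumed; the
  modelled comparison excluded CNVs.
* Carrier-policy subtleties of the upstream tools (how a seqr-style
  dominant search treats affected carrier parents, whether the clinical
  prefilter shares them) are configurable assumptions, not re-implementations
  of those tools.
* REVEL is carried as annotation only; no threshold is applied to it
  anywhere in the cascade.

## Problem sizes used in the checks

The acceptance script evaluates the 14-variant printed fixture (seconds).
The test suite's property checks use synthetic cohorts of 160–1,000
variants, 20 seeds for the recovery sweep, and enumeration oracles up to
n = 10 pairs / N = 40 tables; the whole suite runs in well under five
minutes on one CPU.
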