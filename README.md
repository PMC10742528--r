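# hippotrio

Trio-based prioritisation of rare-disease variants, two ways: a
**panel-agnostic filter cascade** that keeps only variants of high pathogenic
potential, and an emulation of the **panel-based tiering** used for clinical
genome analysis in the UK Genomic Medicine Service (GMS), together with the
statistics needed to compare the two strategies' diagnostic efficiency.

The intended users are rare-disease genomics researchers and diagnostic
bioinformaticians who have an annotated multi-sample VCF for one or more
parent–offspring trios and want to know: *how many variants would a reporting
laboratory have to assess under each strategy, and at what diagnostic yield?*

## The two strategies

**Panel-agnostic cascade** (per affected proband, both search arms):

| filter | dominant arm | recessive arm |
|---|---|---|
| inheritance | de novo / dominant trio search | hom-recessive, X-linked recessive, compound het (in trans) |
| max population AF (gnomAD exomes/genomes, TOPMed, ExAC, 1000G) | < 0.001 | < 0.05 |
| cohort AF | < 0.01 | < 0.01 |
| variant type | coding ± 20 bp, never synonymous-only | same |
| SpliceAI (splicing variants only) | > 0.2 | > 0.2 |
| CADD (all variants) | > 15 | > 15 |
| ClinVar | drop benign/likely benign; P/LP rescues inheritance and score failures (never the AF caps) | same |
| genotype quality | > 40 | > 40 |
| allele balance (het calls) | > 0.2 | > 0.2 |

**Panel-based tiering**: prefilter on inheritance, AF (< 0.001 dominant /
< 0.01 recessive), GQ > 30 and FILTER = PASS, then label variants in *green*
genes of the applied PanelApp-style panels — Tier 1 for predicted
loss-of-function or confirmed de novo variants, Tier 2 for other coding
± 8 bp non-synonymous variants — plus a gene-agnostic branch for any coding
de novo (no quality filter) and Exomiser top-3 variants with score ≥ 0.95.

The comparison module computes, per family and per strategy, the number of
variants assessed, the diagnostic and reportable rates per variant assessed,
paired Wilcoxon signed-rank tests on the assessment burden, and Fisher's
exact tests on the diagnostic yields. Both statistical engines are exact
implementations validated against brute-force enumeration.

## Worked example

The package ships an in-code fixture reconstructing the 14 reported variants
of the published trio-exome study it models (coordinates, CADD, gnomAD AF,
ClinVar status and trio allele counts), plus the study's per-family counts.

```r
library(hippotrio)

fx <- table4_fixture()
cands <- run_hippo(fx$cohort, hippo_config())
nrow(cands)
#> [1] 14

table(cands$model)
#> comp_het_member   de_novo   dominant_inherited
#>               6         5                    3

rep <- build_report(table3_counts(), exclude = "FAM_4")
rep
#> <hippo_comparison> 7 families (excluded: FAM_4 )
#>   hippo        assessed  41  diagnostic 3 (7.32%)  reportable 12 (29.27%)
#>   hippo_gencc  assessed  15  diagnostic 3 (20.00%)  reportable 12 (80.00%)
#>   gms          assessed  63  diagnostic 2 (3.17%)  reportable 5 (7.94%)
#>   Wilcoxon assessed (GenCC vs panel): p = 0.02201
#>   Wilcoxon assessed (all genes vs panel): p = 0.3482
#>   Fisher diagnostic yield (GenCC vs panel): p = 0.0656
```

All 14 curated variants survive the cascade (including the compound
heterozygotes detected in trans and a pathogenic stop-gain carried by an
unaffected parent, retained through the ClinVar override). Restricting to
GenCC definitive/strong disease genes cuts the assessment burden to 15
variants across seven families while keeping all three diagnoses — a 20%
diagnostic rate per variant assessed versus 3.17% for the panel-based
strategy.

Synthetic cohorts with planted causal variants and a truth manifest are one
call away:

```r
res <- generate_cohort(cohort_spec(seed = 7))
run_hippo(res$cohort)          # recovers every satisfying plant
run_gms(res$cohort, res$panels)
```

A command-line wrapper with subcommands `run`, `gms`, `compare`, `simulate`
and `fixtures` is installed at `inst/cli/hippo.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hippo.R",package="hippotrio"))')" \
  fixtures --out fixtures/
```

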