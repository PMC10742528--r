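# Published-study fixtures: the 14 reported exome variants with their
# printed annotations and trio allele counts, the per-family comparison
# counts, and per-proband phenotype-term counts.  These let every module be
# exercised against the published numbers without any download.

#' The 14 reported research-exome variants as a trio cohort fixture
#'
#' Reconstructs the published table of reported variants: coordinates
#' (1-based, `chrom:pos:ref:alt`), gene, consequence, gnomAD AF, CADD, REVEL
#' and classification, with trio genotypes rebuilt from the printed proband
#' and parental allele counts.  The ClinVar status is the printed ClinVar
#' value where present, otherwise the ACMG call when that call is P/LP (the
#' inherited ABCC8 stop-gain is retained by the cascade through its
#' pathogenic classification).  One family was exome-sequenced as father
#' plus affected monozygotic twins with no maternal sample; its shared
#' stop-gain appears once in the VCF and once per affected twin in candidate
#' space.  Genotype quality is set to 99 with balanced allele depths and
#' PASS filter status, matching calls that survived curation, and the
#' within-study cohort AF is set to one heterozygote in ~15,000 samples.
#'
#' Alongside the cohort the fixture carries a gene-validity table for the
#' five established disease genes involved, a minimal applied-panel table, an
#' all-unknown evidence-flag table, and a truth manifest with the diagnostic
#' labels of the three clinically confirmed variants.
#'
#' @param dir Optional directory; when given, `cohort.vcf`, `cohort.ped`,
#'   `gencc.tsv`, `panels.tsv`, `evidence.tsv` and `truth.tsv` are written
#'   there.
#' @return List with `cohort` (a `trio_cohort`), `pedigree`, `gencc`,
#'   `panels`, `evidence`, `truth`, and (when `dir` is given) `paths`.
#' @export
table4_fixture <- function(dir = NULL) {
  v <- tibble::tribble(
    ~chrom, ~pos, ~ref, ~alt, ~gene, ~csq, ~gnomad, ~cadd, ~revel, ~clinvar,
    ~family, ~proband, ~p_ac, ~s2_ac, ~s3_ac,
    "13", 30462666L, "CT", "C", "HMGB1", "frameshift", 0, 38, NA, "none",
    "FAM_1", "1", 1L, 0L, 0L,
    "7", 1480876L, "G", "C", "INTS1", "missense", 5.56e-4, 23.5, 0.243, "none",
    "FAM_2", "4", 1L, 1L, 0L,
    "7", 1497193L, "C", "G", "INTS1", "missense", 7.76e-5, 24, 0.315, "none",
    "FAM_2", "4", 1L, 0L, 1L,
    "2", 28776944L, "C", "G", "PPP1CB", "missense", 0, 26.7, 0.438, "P",
    "FAM_3", "7", 1L, 0L, 0L,
    "1", 31731030L, "G", "A", "ADGRB2", "stop_gained", 0, 38, NA, "none",
    "FAM_4", "13", 1L, 0L, NA,
    "1", 31731030L, "G", "A", "ADGRB2", "stop_gained", 0, 38, NA, "none",
    "FAM_4", "10", 1L, 0L, NA,
    "13", 114325034L, "C", "T", "CHAMP1", "stop_gained", 0, 35, NA, "P",
    "FAM_6", "17", 1L, 0L, 0L,
    "11", 17413408L, "G", "A", "ABCC8", "stop_gained", 0, 43, NA, "LP",
    "FAM_5", "14", 1L, 0L, 1L,
    "16", 71951734L, "T", "G", "PKD1L3", "missense", 5.09e-4, 23.1, NA, "none",
    "FAM_7", "20", 1L, 1L, 0L,
    "16", 71973386L, "C", "T", "PKD1L3", "missense", 1.02e-4, 22, NA, "none",
    "FAM_7", "20", 1L, 0L, 1L,
    "9", 77020700L, "A", "G", "FOXB2", "missense", 0, 25.3, 0.534, "none",
    "FAM_7", "20", 1L, 0L, 0L,
    "19", 23361341L, "G", "C", "ZNF91", "stop_gained", 0, 32, NA, "none",
    "FAM_8", "23", 1L, 0L, 0L,
    "1", 243341070L, "TG", "T", "SDCCAG8", "frameshift", 0, 26, NA, "P",
    "FAM_8", "23", 1L, 1L, 0L,
    "1", 243378799L, "A", "G", "SDCCAG8", "missense", 9.55e-5, 22.2, 0.195, "VUS",
    "FAM_8", "23", 1L, 0L, 1L
  )

  pedigree <- tibble::tibble(
    family_id = c("FAM_1", "FAM_1", "FAM_1", "FAM_2", "FAM_2", "FAM_2",
                  "FAM_3", "FAM_3", "FAM_3", "FAM_4", "FAM_4", "FAM_4",
                  "FAM_5", "FAM_5", "FAM_5", "FAM_6", "FAM_6", "FAM_6",
                  "FAM_7", "FAM_7", "FAM_7", "FAM_8", "FAM_8", "FAM_8"),
    sample_id = c("1", "2", "3", "4", "5", "6", "7", "8", "9",
                  "10", "13", "11", "14", "15", "16", "17", "18", "19",
                  "20", "21", "22", "23", "24", "25"),
    father_id = c("2", NA, NA, "5", NA, NA, "8", NA, NA,
                  "11", "11", NA, "15", NA, NA, "18", NA, NA,
                  "21", NA, NA, "24", NA, NA),
    mother_id = c("3", NA, NA, "6", NA, NA, "9", NA, NA,
                  NA, NA, NA, "16", NA, NA, "19", NA, NA,
                  "22", NA, NA, "25", NA, NA),
    sex = c("male", "male", "female", "male", "male", "female",
            "female", "male", "female", "female", "female", "male",
            "female", "male", "female", "female", "male", "female",
            "male", "male", "female", "female", "male", "female"),
    affected = c("yes", "no", "no", "yes", "no", "no", "yes", "no", "no",
                 "yes", "yes", "no", "yes", "no", "no", "yes", "no", "no",
                 "yes", "no", "no", "yes", "no", "no")
  )

  uniq <- v[!duplicated(variant_key(v$chrom, v$pos, v$ref, v$alt)), ]
  variants <- tibble::tibble(
    key = variant_key(uniq$chrom, uniq$pos, uniq$ref, uniq$alt),
    chrom = uniq$chrom, pos = uniq$pos, ref = uniq$ref, alt = uniq$alt,
    gene = uniq$gene, csq_terms = uniq$csq, csq_dist = 0L,
    af_gnomad_ex = uniq$gnomad, af_gnomad_wg = NA_real_,
    af_topmed = NA_real_, af_exac = NA_real_, af_1kg = NA_real_,
    cohort_af = 3.3e-5, cadd = uniq$cadd, revel = uniq$revel,
    spliceai = NA_real_, clinvar = uniq$clinvar,
    exomiser_rank = ifelse(uniq$gene == "PKD1L3" & uniq$pos == 71951734L,
                           33L, NA_integer_),
    exomiser_score = NA_real_, filter = "PASS"
  )

  ac_to_gt <- function(ac) {
    dplyr::case_match(ac, 0L ~ "hom_ref", 1L ~ "het", 2L ~ "hom_alt",
                      .default = "hom_ref")
  }
  calls <- purrr::map_dfr(seq_len(nrow(v)), function(i) {
    key <- variant_key(v$chrom[i], v$pos[i], v$ref[i], v$alt[i])
    fam <- pedigree[pedigree$family_id == v$family[i], ]
    pro <- v$proband[i]
    fa <- fam$father_id[fam$sample_id == pro]
    mo <- fam$mother_id[fam$sample_id == pro]
    rows <- tibble::tibble(sample_id = pro, ac = v$p_ac[i])
    if (!is.na(fa)) rows <- dplyr::add_row(rows, sample_id = fa, ac = v$s2_ac[i])
    if (!is.na(mo)) rows <- dplyr::add_row(rows, sample_id = mo, ac = v$s3_ac[i])
    rows$key <- key
    rows
  }) |>
    dplyr::distinct(.data$key, .data$sample_id, .keep_all = TRUE)

  all_calls <- tidyr::expand_grid(key = variants$key,
                                  sample_id = pedigree$sample_id) |>
    dplyr::left_join(calls, by = c("key", "sample_id")) |>
    dplyr::mutate(
      ac = tidyr::replace_na(.data$ac, 0L),
      gt = ac_to_gt(.data$ac),
      ad_ref = ifelse(.data$gt == "het", 15L,
                      ifelse(.data$gt == "hom_alt", 0L, 30L)),
      ad_alt = ifelse(.data$gt == "het", 15L,
                      ifelse(.data$gt == "hom_alt", 30L, 0L)),
      gq = 99, filter_pass = TRUE
    ) |>
    dplyr::select("key", "sample_id", "gt", "ad_ref", "ad_alt", "gq",
                  "filter_pass")

  cohort <- new_trio_cohort(variants, all_calls, pedigree$sample_id, pedigree)

  gencc <- tibble::tibble(
    gene = c("PPP1CB", "CHAMP1", "ABCC8", "SDCCAG8", "INTS1"),
    validity = c("definitive", "definitive", "definitive", "definitive",
                 "strong")
  )
  panels <- tibble::tibble(
    panel_id = c("R29", "R29", "R195"),
    gene = c("CHAMP1", "PPP1CB", "SDCCAG8"),
    rating = "green"
  )
  evidence <- evidence_defaults(variants$key)
  truth <- tibble::tibble(
    family_id = c("FAM_3", "FAM_5", "FAM_6"),
    key = c("2:28776944:C:G", "11:17413408:G:A", "13:114325034:C:T"),
    diagnostic = TRUE
  )

  out <- list(cohort = cohort, pedigree = pedigree, gencc = gencc,
              panels = panels, evidence = evidence, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      vcf = file.path(dir, "cohort.vcf"),
      ped = file.path(dir, "cohort.ped"),
      gencc = file.path(dir, "gencc.tsv"),
      panels = file.path(dir, "panels.tsv"),
      evidence = file.path(dir, "evidence.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    write_cohort_vcf(cohort, paths$vcf)
    write_ped(pedigree, paths$ped)
    readr::write_tsv(gencc, paths$gencc, progress = FALSE)
    readr::write_tsv(panels, paths$panels, progress = FALSE)
    write_evidence(evidence, paths$evidence)
    readr::write_tsv(truth, paths$truth, progress = FALSE)
    out$paths <- paths
  }
  out
}

#' Published per-family comparison counts
#'
#' The per-family columns of the published strategy comparison: variants
#' passing the panel-agnostic cascade (all genes and restricted to GenCC
#' definitive/strong genes), variants passing the panel-based tiering
#' strategy, and the diagnostic/reportable labels of the reported variants.
#' One family was exome-sequenced without maternal DNA, inflating its
#' all-genes count (68), and is excluded from the published rate comparison.
#' Reportable counts for the panel-agnostic strategy are the reported
#' variants per family (14 in total, 12 outside the excluded family);
#' reportable counts for the panel-based strategy are the variants on the
#' issued clinical reports (5).
#'
#' @return Tibble with one row per family and the [family_counts()] schema.
#' @export
table3_counts <- function() {
  tibble::tibble(
    family_id = paste0("FAM_", 1:8),
    n_assessed_hippo = c(8L, 4L, 4L, 68L, 8L, 2L, 10L, 5L),
    n_assessed_hippo_gencc = c(3L, 4L, 2L, 23L, 1L, 1L, 1L, 3L),
    n_assessed_gms = c(9L, 5L, 7L, 14L, 5L, 6L, 7L, 24L),
    n_diagnostic_hippo = c(0L, 0L, 1L, 0L, 1L, 1L, 0L, 0L),
    n_diagnostic_hippo_gencc = c(0L, 0L, 1L, 0L, 1L, 1L, 0L, 0L),
    n_diagnostic_gms = c(0L, 0L, 1L, 0L, 0L, 1L, 0L, 0L),
    n_reportable_hippo = c(1L, 2L, 1L, 2L, 1L, 1L, 3L, 3L),
    n_reportable_gms = c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 2L)
  )
}

#' Published per-proband phenotype-term counts
#'
#' Number of Human Phenotype Ontology terms recorded per proband by the
#' research study (extracted from clinical notes) and by the referring
#' clinician at test request.  One family contributes two probands
#' (monozygotic twins).
#'
#' @return Tibble with `family_id`, `proband_id`, `n_hpo_research`,
#'   `n_hpo_clinical`.
#' @export
table1_hpo_counts <- function() {
  tibble::tibble(
    family_id = c("FAM_1", "FAM_2", "FAM_3", "FAM_4", "FAM_4", "FAM_5",
                  "FAM_6", "FAM_7", "FAM_8"),
    proband_id = c("1", "4", "7", "10", "13", "14", "17", "20", "23"),
    n_hpo_research = c(15L, 10L, 9L, 4L, 5L, 11L, 5L, 9L, 5L),
    n_hpo_clinical = c(8L, 5L, 6L, 3L, 4L, 5L, 4L, 7L, 10L)
  )
}
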