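# Consequence-term vocabularies.  Both the bare field shorthand
# ("missense", "frameshift") and the full Sequence Ontology terms are
# accepted, so printed tables and VEP-style annotations both parse.
.coding_terms <- c(
  "missense_variant", "missense", "stop_gained", "stop_lost", "start_lost",
  "frameshift_variant", "frameshift", "inframe_insertion", "inframe_deletion",
  "protein_altering_variant", "coding_sequence_variant", "transcript_ablation",
  "synonymous_variant", "synonymous", "stop_retained_variant",
  "start_retained_variant", "incomplete_terminal_codon_variant"
)
.synonymous_terms <- c("synonymous_variant", "synonymous",
                       "stop_retained_variant", "start_retained_variant")
.splice_terms <- c("splice_donor_variant", "splice_donor",
                   "splice_acceptor_variant", "splice_acceptor",
                   "splice_region_variant", "splice_region",
                   "intron_variant", "intron")
.plof_terms <- c("stop_gained", "frameshift", "frameshift_variant",
                 "splice_donor", "splice_donor_variant",
                 "splice_acceptor", "splice_acceptor_variant",
                 "start_lost", "stop_lost", "transcript_ablation")

split_terms <- function(csq_terms) {
  if (length(csq_terms) == 1) {
    t <- strsplit(csq_terms %||% "", ",", fixed = TRUE)[[1]]
    trimws(t[t != ""])
  } else {
    lapply(strsplit(ifelse(is.na(csq_terms), "", csq_terms), ",", fixed = TRUE),
           function(t) trimws(t[t != ""]))
  }
}

#' Filter-cascade thresholds for the panel-agnostic strategy
#'
#' Defaults are the research-arm filter values: population AF < 0.001
#' (dominant search) / < 0.05 (recessive search), cohort AF < 0.01, all
#' coding consequences +/- 20 bp excluding synonymous-only variants,
#' SpliceAI delta score > 0.2 for splicing variants, CADD PHRED > 15 for all
#' variants, allele balance > 0.2 for heterozygous calls and genotype
#' quality > 40.  All comparisons are strict.  `missing_score_policy`
#' controls variants lacking CADD/SpliceAI/allele-depth annotations:
#' `"retain"` (default) fails open on absent evidence, `"drop"` discards.
#'
#' @param af_dominant,af_recessive,cohort_af_max Allele-frequency caps.
#' @param coding_window_bp Window around coding exons, in bp.
#' @param spliceai_min,cadd_min In-silico score thresholds.
#' @param allele_balance_min Minimum alt-read fraction for het calls.
#' @param gq_min Minimum genotype quality.
#' @param missing_score_policy `"retain"` or `"drop"`.
#' @return A validated list of class `hippo_config`.
#' @export
hippo_config <- function(af_dominant = 0.001, af_recessive = 0.05,
                         cohort_af_max = 0.01, coding_window_bp = 20,
                         spliceai_min = 0.2, cadd_min = 15,
                         allele_balance_min = 0.2, gq_min = 40,
                         missing_score_policy = c("retain", "drop")) {
  missing_score_policy <- match.arg(missing_score_policy)
  cfg <- list(af_dominant = af_dominant, af_recessive = af_recessive,
              cohort_af_max = cohort_af_max,
              coding_window_bp = as.integer(coding_window_bp),
              spliceai_min = spliceai_min, cadd_min = cadd_min,
              allele_balance_min = allele_balance_min,
              gq_min = as.numeric(gq_min),
              missing_score_policy = missing_score_policy)
  stopifnot(all(vapply(cfg[1:8], is.numeric, logical(1))),
            cfg$af_dominant >= 0, cfg$af_dominant <= 1,
            cfg$af_recessive >= 0, cfg$af_recessive <= 1,
            cfg$cohort_af_max >= 0, cfg$cohort_af_max <= 1,
            cfg$coding_window_bp >= 0, cfg$spliceai_min >= 0,
            cfg$allele_balance_min >= 0, cfg$gq_min >= 0)
  structure(cfg, class = "hippo_config")
}

#' Maximum population allele frequency of each variant
#'
#' The maximum over all population AF sources present on the variant
#' (gnomAD exomes/genomes, TOPMed, ExAC, 1000 Genomes); 0 when no source is
#' present (an unobserved variant is treated as novel, not unknown).
#'
#' @param variants Variant tibble with the `af_*` columns of a
#'   [read_cohort_vcf()] cohort.
#' @return Numeric vector of maximum AFs.
#' @export
max_population_af <- function(variants) {
  cols <- intersect(unname(.variant_af_cols), names(variants))
  if (length(cols) == 0 || nrow(variants) == 0) return(rep(0, nrow(variants)))
  af <- as.matrix(variants[, cols, drop = FALSE])
  out <- apply(af, 1, function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
  as.numeric(out)
}

#' Allele balance of a call
#'
#' Alt-read fraction `alt / (ref + alt)`; `NA` when allele depths are absent
#' or sum to zero (the caller applies the missing-score policy).
#'
#' @param ad_ref,ad_alt Reference and alternate read depths.
#' @return Numeric vector in \[0, 1\] or `NA`.
#' @export
allele_balance <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  ifelse(is.na(tot) | tot == 0, NA_real_, ad_alt / tot)
}

#' Variant-type filter: coding within a window, not synonymous-only
#'
#' A variant qualifies when at least one transcript consequence is coding or
#' the variant lies within `window_bp` of a coding exon, and it is not
#' synonymous on every transcript.
#'
#' @param csq_terms Comma-separated consequence term string(s).
#' @param coding_distance Distance in bp to the nearest coding exon (0 for
#'   coding variants).
#' @param window_bp Window size in bp (boundary inclusive).
#' @return Logical vector.
#' @export
passes_variant_type <- function(csq_terms, coding_distance, window_bp = 20) {
  terms <- split_terms(ifelse(is.na(csq_terms), "", csq_terms))
  if (!is.list(terms)) terms <- list(terms)
  vapply(seq_along(terms), function(i) {
    t <- terms[[i]]
    d <- coding_distance[min(i, length(coding_distance))]
    in_scope <- any(t %in% .coding_terms) || (!is.na(d) && d <= window_bp)
    syn_only <- length(t) > 0 && all(t %in% .synonymous_terms)
    in_scope && !syn_only
  }, logical(1))
}

#' Is a variant a "splicing variant" for the SpliceAI rule?
#'
#' True when every consequence term is a splice-site, splice-region or
#' intronic term, i.e. the variant's only route into the cascade is through
#' splicing.
#'
#' @param csq_terms Comma-separated consequence term string(s).
#' @return Logical vector.
#' @export
is_splicing_variant <- function(csq_terms) {
  terms <- split_terms(ifelse(is.na(csq_terms), "", csq_terms))
  if (!is.list(terms)) terms <- list(terms)
  vapply(terms, function(t) length(t) > 0 && all(t %in% .splice_terms),
         logical(1))
}

#' In-silico score rules (CADD for all variants, SpliceAI for splicing ones)
#'
#' The CADD rule requires `cadd > cadd_min` for every variant; the SpliceAI
#' rule applies only to splicing variants and requires
#' `spliceai > spliceai_min`.  A variant classified pathogenic or likely
#' pathogenic in ClinVar has failing score rules marked `overridden` rather
#' than `fail`.  Missing scores follow the config's missing-score policy
#' (`retain` marks the rule `skipped`).
#'
#' @param cadd,spliceai Numeric scores (NA = absent).
#' @param csq_terms Consequence term string (determines the SpliceAI scope).
#' @param clinvar ClinVar classification (`P`, `LP`, `VUS`, `LB`, `B`,
#'   `none`).
#' @param cfg A [hippo_config()].
#' @return List with `pass` (logical) and the `cadd`/`spliceai` rule
#'   outcomes (`pass`, `fail`, `overridden`, `skipped`).
#' @export
passes_insilico <- function(cadd, spliceai, csq_terms, clinvar,
                            cfg = hippo_config()) {
  override <- clinvar %in% c("P", "LP")
  miss_out <- if (cfg$missing_score_policy == "retain") "skipped" else "fail"
  cadd_out <- if (is.na(cadd)) miss_out else if (cadd > cfg$cadd_min) "pass" else "fail"
  if (cadd_out == "fail" && override) cadd_out <- "overridden"
  if (is_splicing_variant(csq_terms)) {
    sp_out <- if (is.na(spliceai)) miss_out
              else if (spliceai > cfg$spliceai_min) "pass" else "fail"
    if (sp_out == "fail" && override) sp_out <- "overridden"
  } else {
    sp_out <- "skipped"
  }
  list(pass = cadd_out != "fail" && sp_out != "fail",
       cadd = cadd_out, spliceai = sp_out)
}

#' ClinVar gate
#'
#' Benign/likely-benign variants fail outright; pathogenic/likely-pathogenic
#' variants return an override token that rescues inheritance-model failures
#' (a pathogenic variant carried by an unaffected parent is retained) and
#' in-silico failures, but never the allele-frequency caps; VUS and
#' unclassified variants pass neutrally.
#'
#' @param clinvar ClinVar classification vector.
#' @return Character vector: `"fail"`, `"override"` or `"pass"`.
#' @export
clinvar_gate <- function(clinvar) {
  dplyr::case_match(clinvar, c("B", "LB") ~ "fail", c("P", "LP") ~ "override",
                    .default = "pass")
}

.hippo_rules <- c("inheritance", "af_population", "af_cohort", "variant_type",
                  "cadd", "spliceai", "clinvar", "genotype_quality",
                  "allele_balance")

encode_trace <- function(outcomes) {
  paste(paste0(names(outcomes), "=", unlist(outcomes)), collapse = ";")
}

#' Cohort allele frequency from founder genotypes
#'
#' Fallback when the `COHORT_AF` INFO field is absent: the alt-allele
#' frequency across all founder (parent-less) samples of the cohort.
#'
#' @param cohort A `trio_cohort`.
#' @return Numeric vector aligned with `cohort$variants`.
#' @export
founder_cohort_af <- function(cohort) {
  ped <- cohort$pedigree
  founders <- ped$sample_id[is.na(ped$father_id) & is.na(ped$mother_id)]
  fc <- cohort$calls[cohort$calls$sample_id %in% founders &
                       cohort$calls$gt != "missing", , drop = FALSE]
  if (nrow(fc) == 0) return(rep(NA_real_, nrow(cohort$variants)))
  counts <- fc |>
    dplyr::mutate(
      alt_n = dplyr::case_match(.data$gt, "hom_alt" ~ 2L, "het" ~ 1L,
                                "hemi" ~ 1L, .default = 0L),
      tot_n = ifelse(.data$gt == "hemi", 1L, 2L)
    ) |>
    dplyr::summarise(af = sum(.data$alt_n) / sum(.data$tot_n), .by = "key")
  counts$af[match(cohort$variants$key, counts$key)]
}

# Per-proband wide table: variants carried by the proband with parental calls.
proband_variant_table <- function(cohort, family, proband) {
  ped <- cohort$pedigree
  row <- ped[ped$family_id == family & ped$sample_id == proband, ]
  fa_id <- row$father_id
  mo_id <- row$mother_id
  calls <- cohort$calls
  pick <- function(id) {
    if (is.na(id) || !(id %in% cohort$samples)) return(NULL)
    calls[calls$sample_id == id, c("key", "gt", "gq", "ad_ref", "ad_alt")]
  }
  pc <- calls[calls$sample_id == proband, ]
  pc <- pc[pc$gt %in% c("het", "hom_alt", "hemi"), , drop = FALSE]
  if (nrow(pc) == 0) return(NULL)
  tab <- dplyr::left_join(pc, cohort$variants, by = "key")
  fa <- pick(fa_id)
  mo <- pick(mo_id)
  tab$father_gt <- if (is.null(fa)) NA_character_ else fa$gt[match(tab$key, fa$key)]
  tab$father_gq <- if (is.null(fa)) NA_real_ else fa$gq[match(tab$key, fa$key)]
  tab$mother_gt <- if (is.null(mo)) NA_character_ else mo$gt[match(tab$key, mo$key)]
  tab$mother_gq <- if (is.null(mo)) NA_real_ else mo$gq[match(tab$key, mo$key)]
  tab$father_affected <- if (nrow(row) && !is.na(fa_id)) {
    ped$affected[match(fa_id, ped$sample_id)]
  } else NA_character_
  tab$mother_affected <- if (nrow(row) && !is.na(mo_id)) {
    ped$affected[match(mo_id, ped$sample_id)]
  } else NA_character_
  tab$proband_sex <- row$sex
  tab
}

# Unaffected carriers per key within one family (parents and siblings).
unaffected_carrier_map <- function(cohort, family, keys) {
  ped <- cohort$pedigree
  fam <- ped[ped$family_id == family & ped$affected == "no", ]
  cc <- cohort$calls[cohort$calls$sample_id %in% fam$sample_id &
                       cohort$calls$key %in% keys &
                       cohort$calls$gt %in% c("het", "hom_alt", "hemi"), ,
                     drop = FALSE]
  split(cc$sample_id, cc$key)
}

#' Run the panel-agnostic filter cascade over a trio cohort
#'
#' Applies, per affected proband, the full cascade: inheritance-model search
#' (de novo/dominant arm and recessive arm including compound heterozygotes
#' and X-linked recessive), population and cohort allele-frequency caps
#' (dominant and recessive arms use different population caps), the
#' variant-type window, CADD and SpliceAI rules, the ClinVar gate, genotype
#' quality and allele balance.  A ClinVar P/LP classification rescues
#' inheritance failures caused by a carrier unaffected parent and failing
#' in-silico rules, but never the AF caps.  The FILTER column is ignored:
#' all variants are considered.  A synonymous-only variant whose SpliceAI
#' score exceeds the threshold is retained with its variant-type rule marked
#' `overridden`.
#'
#' Compound-heterozygous pairs are formed, per gene, among proband-het
#' variants that individually pass every non-inheritance rule at recessive
#' thresholds and are in trans (see [find_comp_het()]); with an unsequenced
#' parent, pairs whose phase cannot exclude cis are retained and flagged
#' `phase_unknown`.
#'
#' @param cohort A `trio_cohort` from [read_cohort_vcf()].
#' @param cfg A [hippo_config()].
#' @return Candidate tibble (one row per proband x variant), ordered by
#'   family, proband, chromosome, position, ref, alt; columns include the
#'   inheritance `model`, `partner_key`/`phase_unknown` for compound-het
#'   members, `confirmed_de_novo`, annotations, `strategy = "hippo"` and the
#'   full `rule_trace`.
#' @export
run_hippo <- function(cohort, cfg = hippo_config()) {
  ped <- cohort$pedigree
  validate_pedigree(ped)

  variants <- cohort$variants
  if (all(is.na(variants$cohort_af))) {
    variants$cohort_af <- founder_cohort_af(cohort)
  }
  cohort$variants <- variants

  out <- list()
  for (family in unique(ped$family_id)) {
    for (proband in family_probands(ped, family)) {
      if (!(proband %in% cohort$samples)) next
      tab <- proband_variant_table(cohort, family, proband)
      if (is.null(tab) || nrow(tab) == 0) next
      cand <- hippo_evaluate_proband(tab, cohort, family, proband, cfg)
      if (!is.null(cand)) out[[length(out) + 1]] <- cand
    }
  }
  cands <- dplyr::bind_rows(out)
  if (nrow(cands) == 0) return(empty_candidates("hippo"))
  dplyr::arrange(cands, .data$family_id, .data$proband_id,
                 chrom_order(.data$chrom), .data$pos, .data$ref, .data$alt,
                 .data$key)
}

empty_candidates <- function(strategy) {
  tibble::tibble(
    family_id = character(), proband_id = character(), key = character(),
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    gene = character(), csq_terms = character(), model = character(),
    partner_key = character(), phase_unknown = logical(),
    confirmed_de_novo = logical(), max_pop_af = numeric(),
    cohort_af = numeric(), cadd = numeric(), revel = numeric(),
    spliceai = numeric(), clinvar = character(), exomiser_rank = integer(),
    exomiser_score = numeric(), strategy = character(),
    tier = character(), reportable = logical(), diagnostic = logical(),
    rule_trace = character()
  )
}

hippo_evaluate_proband <- function(tab, cohort, family, proband, cfg) {
  n <- nrow(tab)
  cls <- chrom_class(tab$chrom)

  inh <- lapply(seq_len(n), function(i) {
    trio <- trio_context(
      proband = list(gt = tab$gt[i], gq = tab$gq[i], affected = "yes"),
      father = if (is.na(tab$father_gt[i])) NULL else
        list(gt = tab$father_gt[i], gq = tab$father_gq[i],
             affected = tab$father_affected[i] %||% "no"),
      mother = if (is.na(tab$mother_gt[i])) NULL else
        list(gt = tab$mother_gt[i], gq = tab$mother_gq[i],
             affected = tab$mother_affected[i] %||% "no"),
      chrom_class = cls[i], proband_sex = tab$proband_sex[i]
    )
    classify_single(trio, min_gq = cfg$gq_min)
  })
  model <- vapply(inh, `[[`, character(1), "model")
  confirmed <- vapply(inh, `[[`, logical(1), "confirmed_de_novo")
  blocked <- vapply(inh, `[[`, logical(1), "blocked_by_unaffected_carrier")

  max_af <- max_population_af(tab)
  gate <- clinvar_gate(tab$clinvar)
  type_pass <- passes_variant_type(tab$csq_terms, tab$csq_dist,
                                   cfg$coding_window_bp)
  terms_list <- split_terms(tab$csq_terms)
  if (!is.list(terms_list)) terms_list <- list(terms_list)
  syn_only <- vapply(terms_list, function(t) {
    length(t) > 0 && all(t %in% .synonymous_terms)
  }, logical(1))
  syn_rescued <- syn_only & !is.na(tab$spliceai) & tab$spliceai > cfg$spliceai_min
  type_out <- ifelse(type_pass, "pass", ifelse(syn_rescued, "overridden", "fail"))

  insil <- lapply(seq_len(n), function(i) {
    passes_insilico(tab$cadd[i], tab$spliceai[i], tab$csq_terms[i],
                    tab$clinvar[i], cfg)
  })
  cadd_out <- vapply(insil, `[[`, character(1), "cadd")
  sp_out <- vapply(insil, `[[`, character(1), "spliceai")

  miss_out <- if (cfg$missing_score_policy == "retain") "skipped" else "fail"
  cohort_out <- ifelse(is.na(tab$cohort_af), miss_out,
                       ifelse(tab$cohort_af < cfg$cohort_af_max, "pass", "fail"))
  gq_out <- ifelse(!is.na(tab$gq) & tab$gq > cfg$gq_min, "pass", "fail")
  ab <- allele_balance(tab$ad_ref, tab$ad_alt)
  ab_out <- ifelse(tab$gt != "het", "skipped",
                   ifelse(is.na(ab), miss_out,
                          ifelse(ab > cfg$allele_balance_min, "pass", "fail")))
  clin_out <- ifelse(gate == "fail", "fail", "pass")

  shared_ok <- type_out != "fail" & cadd_out != "fail" & sp_out != "fail" &
    clin_out != "fail" & cohort_out != "fail" & gq_out != "fail" &
    ab_out != "fail"

  # compound-het pairing among proband-het variants passing every
  # non-inheritance rule at recessive thresholds
  rec_af_ok <- max_af < cfg$af_recessive
  pool <- which(tab$gt == "het" & shared_ok & rec_af_ok & !is.na(tab$gene))
  partner <- rep(NA_character_, n)
  phase_unknown <- rep(NA, n)
  if (length(pool) >= 2) {
    ucar <- unaffected_carrier_map(cohort, family, tab$key[pool])
    for (g in unique(tab$gene[pool])) {
      ix <- pool[tab$gene[pool] == g]
      if (length(ix) < 2) next
      gv <- tibble::tibble(key = tab$key[ix], proband_gt = tab$gt[ix],
                           father_gt = tab$father_gt[ix],
                           mother_gt = tab$mother_gt[ix])
      pairs <- find_comp_het(gv, unaffected_carriers = ucar)
      for (k in seq_len(nrow(pairs))) {
        for (side in c("key1", "key2")) {
          i <- ix[tab$key[ix] == pairs[[side]][k]]
          other <- pairs[[if (side == "key1") "key2" else "key1"]][k]
          if (is.na(partner[i]) || other < partner[i]) {
            partner[i] <- other
            phase_unknown[i] <- pairs$phase_unknown[k]
          } else if (other == partner[i]) {
            phase_unknown[i] <- phase_unknown[i] && pairs$phase_unknown[k]
          }
        }
      }
    }
  }
  comp_member <- !is.na(partner)

  dom_arm <- model %in% c("de_novo", "dominant_inherited") |
    (blocked & gate == "override")
  rec_arm <- model %in% c("hom_recessive", "x_linked_recessive") | comp_member
  inh_out <- ifelse(model != "none", "pass",
                    ifelse(comp_member, "pass",
                           ifelse(blocked & gate == "override", "overridden",
                                  "fail")))
  af_out <- ifelse((dom_arm & max_af < cfg$af_dominant) |
                     (rec_arm & rec_af_ok), "pass", "fail")
  keep <- (dom_arm | rec_arm) & inh_out != "fail" & af_out == "pass" & shared_ok
  if (!any(keep)) return(NULL)

  final_model <- model
  final_model[model == "none" & comp_member] <- "comp_het_member"
  final_model[model == "none" & !comp_member & blocked] <- "dominant_inherited"

  idx <- which(keep)
  trace <- vapply(idx, function(i) {
    encode_trace(list(
      inheritance = inh_out[i], af_population = af_out[i],
      af_cohort = cohort_out[i], variant_type = type_out[i],
      cadd = cadd_out[i], spliceai = sp_out[i], clinvar = clin_out[i],
      genotype_quality = gq_out[i], allele_balance = ab_out[i]
    ))
  }, character(1))

  tibble::tibble(
    family_id = family, proband_id = proband, key = tab$key[idx],
    chrom = tab$chrom[idx], pos = tab$pos[idx], ref = tab$ref[idx],
    alt = tab$alt[idx], gene = tab$gene[idx], csq_terms = tab$csq_terms[idx],
    model = final_model[idx], partner_key = partner[idx],
    phase_unknown = phase_unknown[idx], confirmed_de_novo = confirmed[idx],
    max_pop_af = max_af[idx], cohort_af = tab$cohort_af[idx],
    cadd = tab$cadd[idx], revel = tab$revel[idx], spliceai = tab$spliceai[idx],
    clinvar = tab$clinvar[idx], exomiser_rank = tab$exomiser_rank[idx],
    exomiser_score = tab$exomiser_score[idx], strategy = "hippo",
    tier = NA_character_, reportable = NA, diagnostic = NA,
    rule_trace = trace
  )
}

#' Restrict candidates to GenCC definitive/strong disease genes
#'
#' @param candidates Candidate tibble from [run_hippo()].
#' @param gencc GenCC tibble from [read_gencc()].
#' @return The subset whose gene has a definitive or strong validity record,
#'   relabelled `strategy = "hippo_gencc"`.
#' @export
restrict_to_gencc <- function(candidates, gencc) {
  keep_genes <- unique(gencc$gene[gencc$validity %in% c("definitive", "strong")])
  out <- candidates[!is.na(candidates$gene) &
                      trimws(candidates$gene) %in% keep_genes, , drop = FALSE]
  out$strategy <- "hippo_gencc"
  out
}

#' Apply the reportability exclusion criteria
#'
#' Marks each candidate reportable unless one of six exclusion rules fires,
#' based on curator-supplied evidence flags (an unknown flag never fires a
#' rule):
#' 1. heterozygous single hit in a recessive disease gene with
#'    `second_hit_found = FALSE`;
#' 2. known disease gene (any GenCC record), `phenotype_match = FALSE`, and
#'    the variant is not P/LP in ClinVar;
#' 3. known disease gene with `tissue_expression_ok = FALSE`;
#' 4. novel gene (no GenCC record) with `tissue_expression_ok = FALSE` or
#'    `pathway_plausible = FALSE`;
#' 5. predicted loss-of-function consequence curated `likely_not_LoF` or
#'    `not_LoF`;
#' 6. `igv_artefact = TRUE`.
#'
#' @param candidates Candidate tibble.
#' @param evidence Evidence tibble from [read_evidence()] (may be empty).
#' @param gencc GenCC tibble; genes with any record count as known disease
#'   genes.
#' @return The candidates with `reportable` set and an `excluded_by` column
#'   listing the rules that fired (empty string when reportable).
#' @export
apply_exclusion_criteria <- function(candidates, evidence, gencc) {
  if (nrow(candidates) == 0) {
    candidates$excluded_by <- character()
    return(candidates)
  }
  orphan <- setdiff(evidence$variant_key, candidates$key)
  if (length(orphan) > 0) {
    warning("evidence row(s) match no candidate: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }
  ev <- evidence[match(candidates$key, evidence$variant_key), , drop = FALSE]
  known <- !is.na(candidates$gene) & candidates$gene %in% unique(gencc$gene)
  recessive_model <- candidates$model %in%
    c("hom_recessive", "x_linked_recessive", "comp_het_member")
  plof <- is_plof(candidates$csq_terms)
  p_lp <- candidates$clinvar %in% c("P", "LP")

  isF <- function(x) !is.na(x) & !x
  isT <- function(x) !is.na(x) & x
  fired <- cbind(
    no_second_hit = isF(ev$second_hit_found) & known & !recessive_model,
    phenotype_mismatch = known & isF(ev$phenotype_match) & !p_lp,
    poor_expression_known = known & isF(ev$tissue_expression_ok),
    novel_gene_implausible = !known &
      (isF(ev$tissue_expression_ok) | isF(ev$pathway_plausible)),
    lof_curation = plof & !is.na(ev$lof_curation) &
      ev$lof_curation %in% c("likely_not_LoF", "not_LoF"),
    igv_artefact = isT(ev$igv_artefact)
  )
  fired[is.na(fired)] <- FALSE
  candidates$reportable <- rowSums(fired) == 0
  candidates$excluded_by <- apply(fired, 1, function(r) {
    paste(colnames(fired)[r], collapse = ";")
  })
  candidates
}
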