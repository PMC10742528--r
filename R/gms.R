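#' Filter thresholds for the panel-based tiering strategy
#'
#' Defaults are the clinical-genome filter values: population AF < 0.001
#' (dominant) / < 0.01 (recessive), coding window +/- 8 bp, genotype quality
#' > 30, FILTER column must be PASS, and the gene-agnostic Exomiser branch
#' admits variants ranked in the top 3 with score >= 0.95.  No cohort-AF,
#' ClinVar or in-silico filters are applied by this strategy.
#'
#' @param af_dominant,af_recessive Allele-frequency caps.
#' @param coding_window_bp Window around coding exons, in bp.
#' @param gq_min Minimum genotype quality (strict `>`).
#' @param exomiser_top_rank Maximum Exomiser rank admitted (inclusive).
#' @param exomiser_min_score Minimum Exomiser score (inclusive).
#' @param require_pass_filter Require FILTER == PASS for tiered variants.
#' @return A validated list of class `gms_config`.
#' @export
gms_config <- function(af_dominant = 0.001, af_recessive = 0.01,
                       coding_window_bp = 8, gq_min = 30,
                       exomiser_top_rank = 3, exomiser_min_score = 0.95,
                       require_pass_filter = TRUE) {
  cfg <- list(af_dominant = af_dominant, af_recessive = af_recessive,
              coding_window_bp = as.integer(coding_window_bp),
              gq_min = as.numeric(gq_min),
              exomiser_top_rank = as.integer(exomiser_top_rank),
              exomiser_min_score = exomiser_min_score,
              require_pass_filter = isTRUE(require_pass_filter))
  stopifnot(cfg$af_dominant >= 0, cfg$af_recessive >= 0,
            cfg$coding_window_bp >= 0, cfg$gq_min >= 0,
            cfg$exomiser_top_rank >= 0, cfg$exomiser_min_score >= 0)
  structure(cfg, class = "gms_config")
}

#' Predicted loss-of-function consequence?
#'
#' True when any consequence term is stop-gained, frameshift, an essential
#' splice site (donor/acceptor), start/stop lost or transcript ablation.
#'
#' @param csq_terms Comma-separated consequence term string(s).
#' @return Logical vector.
#' @export
is_plof <- function(csq_terms) {
  terms <- split_terms(ifelse(is.na(csq_terms), "", csq_terms))
  if (!is.list(terms)) terms <- list(terms)
  vapply(terms, function(t) any(t %in% .plof_terms), logical(1))
}

green_gene_set <- function(panels, family = NULL) {
  if (is.null(panels) || nrow(panels) == 0) {
    return(list(genes = character(), panels_of = function(g) character()))
  }
  if ("family_id" %in% names(panels) && !is.null(family)) {
    panels <- panels[panels$family_id == family, , drop = FALSE]
  }
  green <- panels[panels$rating == "green", , drop = FALSE]
  list(
    genes = unique(green$gene),
    panels_of = function(g) {
      sort(unique(green$panel_id[green$gene %in% g]))
    }
  )
}

#' Assign a tiering label to one variant
#'
#' First-match precedence: Tier 1 (predicted LoF or confirmed de novo in a
#' green panel gene), Tier 2 (other coding +/- 8 bp non-synonymous variant in
#' a green panel gene), gene-agnostic de novo (any coding de novo, no quality
#' requirement), gene-agnostic Exomiser (top-rank with qualifying score),
#' untiered.  Tier 1/2 require the variant to have passed the strategy's
#' prefilters; the gene-agnostic branches do not.
#'
#' @param gene Gene symbol (or `NA`).
#' @param csq_terms Consequence term string.
#' @param coding_distance Distance to nearest coding exon in bp.
#' @param plof Predicted LoF? (see [is_plof()]).
#' @param de_novo_confirmed Confirmed de novo at the strategy's quality
#'   threshold?
#' @param de_novo_any De novo with no quality requirement (`min_gq = 0`)?
#' @param exomiser_rank,exomiser_score Exomiser annotations (`NA` = absent;
#'   an unranked variant is never admitted through the Exomiser branch).
#' @param prefilter_ok Did the variant pass inheritance/AF/GQ/PASS
#'   prefilters?
#' @param ga_af_ok Does the variant meet the dominant AF cap (applied to the
#'   gene-agnostic de novo branch)?
#' @param green A green-gene lookup built from the applied panels.
#' @param cfg A [gms_config()].
#' @return List with `tier` (`tier1`, `tier2`, `ga_denovo`, `ga_exomiser`,
#'   `untiered`), `panels_hit`, `assessed`.
#' @export
assign_tier <- function(gene, csq_terms, coding_distance, plof,
                        de_novo_confirmed, de_novo_any,
                        exomiser_rank, exomiser_score,
                        prefilter_ok, ga_af_ok, green, cfg = gms_config()) {
  coding_ok <- passes_variant_type(csq_terms, coding_distance,
                                   cfg$coding_window_bp)
  on_panel <- !is.na(gene) && gene %in% green$genes
  panels_hit <- if (on_panel) green$panels_of(gene) else character()
  tier <- "untiered"
  if (prefilter_ok && coding_ok && on_panel && (plof || de_novo_confirmed)) {
    tier <- "tier1"
  } else if (prefilter_ok && coding_ok && on_panel) {
    tier <- "tier2"
  } else if (de_novo_any && ga_af_ok && coding_ok) {
    tier <- "ga_denovo"
  } else if (!is.na(exomiser_rank) && exomiser_rank <= cfg$exomiser_top_rank &&
             !is.na(exomiser_score) &&
             exomiser_score >= cfg$exomiser_min_score && coding_ok) {
    tier <- "ga_exomiser"
  }
  list(tier = tier,
       panels_hit = if (tier %in% c("tier1", "tier2")) panels_hit else character(),
       assessed = tier != "untiered")
}

#' Run the panel-based tiering strategy over a trio cohort
#'
#' Emulates the clinical-genome workflow: variants are prefiltered on mode of
#' inheritance (same trio search as the panel-agnostic strategy, including
#' compound heterozygotes), allele frequency (dominant/recessive caps),
#' genotype quality and FILTER status, then restricted to green genes on the
#' applied panels for Tier 1/Tier 2 assignment.  A complementary
#' gene-agnostic filter admits any coding de novo variant (not filtered on
#' quality or FILTER status) and Exomiser top-ranked coding variants with a
#' qualifying score.  Synonymous variants never tier.
#'
#' @param cohort A `trio_cohort`.
#' @param panels Panel tibble (`panel_id`, `gene`, `rating`), optionally with
#'   a `family_id` column to apply different panels per family.  Multiple
#'   panels union their green genes.
#' @param cfg A [gms_config()].
#' @return Candidate tibble of assessed variants (tier != untiered), one row
#'   per proband x variant, with `tier`, `strategy = "gms"` and a
#'   `rule_trace`.
#' @export
run_gms <- function(cohort, panels = NULL, cfg = gms_config()) {
  ped <- cohort$pedigree
  validate_pedigree(ped)
  out <- list()
  for (family in unique(ped$family_id)) {
    green <- green_gene_set(panels, family)
    for (proband in family_probands(ped, family)) {
      if (!(proband %in% cohort$samples)) next
      tab <- proband_variant_table(cohort, family, proband)
      if (is.null(tab) || nrow(tab) == 0) next
      cand <- gms_evaluate_proband(tab, cohort, family, proband, green, cfg)
      if (!is.null(cand)) out[[length(out) + 1]] <- cand
    }
  }
  cands <- dplyr::bind_rows(out)
  if (nrow(cands) == 0) return(empty_candidates("gms"))
  dplyr::arrange(cands, .data$family_id, .data$proband_id,
                 chrom_order(.data$chrom), .data$pos, .data$ref, .data$alt,
                 .data$key)
}

gms_evaluate_proband <- function(tab, cohort, family, proband, green, cfg) {
  n <- nrow(tab)
  cls <- chrom_class(tab$chrom)

  classify_at <- function(i, min_gq) {
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
    classify_single(trio, min_gq = min_gq)
  }
  inh <- lapply(seq_len(n), function(i) classify_at(i, cfg$gq_min))
  model <- vapply(inh, `[[`, character(1), "model")
  confirmed <- vapply(inh, `[[`, logical(1), "confirmed_de_novo")
  # gene-agnostic de novo search: no quality requirement at all
  dn_any <- vapply(seq_len(n), function(i) {
    classify_at(i, 0)$model == "de_novo"
  }, logical(1))

  max_af <- max_population_af(tab)
  dom_af_ok <- max_af < cfg$af_dominant
  rec_af_ok <- max_af < cfg$af_recessive
  gq_ok <- !is.na(tab$gq) & tab$gq > cfg$gq_min
  pass_ok <- if (cfg$require_pass_filter) {
    tab$filter %in% c("PASS", ".")
  } else rep(TRUE, n)

  # compound-het pool at the recessive AF cap among quality-passing hets
  pool <- which(tab$gt == "het" & rec_af_ok & gq_ok & pass_ok &
                  !is.na(tab$gene))
  comp_member <- rep(FALSE, n)
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
          comp_member[i] <- TRUE
          other <- pairs[[if (side == "key1") "key2" else "key1"]][k]
          if (is.na(partner[i]) || other < partner[i]) {
            partner[i] <- other
            phase_unknown[i] <- pairs$phase_unknown[k]
          }
        }
      }
    }
  }

  dom_arm <- model %in% c("de_novo", "dominant_inherited")
  rec_arm <- model %in% c("hom_recessive", "x_linked_recessive") | comp_member
  af_ok <- (dom_arm & dom_af_ok) | (rec_arm & rec_af_ok)
  prefilter_ok <- (dom_arm | rec_arm) & af_ok & gq_ok & pass_ok

  plof <- is_plof(tab$csq_terms)
  tiers <- lapply(seq_len(n), function(i) {
    assign_tier(tab$gene[i], tab$csq_terms[i], tab$csq_dist[i], plof[i],
                de_novo_confirmed = confirmed[i], de_novo_any = dn_any[i],
                exomiser_rank = tab$exomiser_rank[i],
                exomiser_score = tab$exomiser_score[i],
                prefilter_ok = prefilter_ok[i], ga_af_ok = dom_af_ok[i],
                green = green, cfg = cfg)
  })
  tier <- vapply(tiers, `[[`, character(1), "tier")
  keep <- tier != "untiered"
  if (!any(keep)) return(NULL)

  final_model <- model
  final_model[model == "none" & comp_member] <- "comp_het_member"
  final_model[model == "none" & !comp_member & dn_any] <- "de_novo"

  idx <- which(keep)
  trace <- vapply(idx, function(i) {
    encode_trace(list(
      inheritance = if (dom_arm[i] | rec_arm[i] | dn_any[i]) "pass" else "skipped",
      af_population = if (af_ok[i] | (tier[i] == "ga_denovo" & dom_af_ok[i]) |
                            tier[i] == "ga_exomiser") "pass" else "skipped",
      genotype_quality = if (gq_ok[i]) "pass" else "skipped",
      filter_pass = if (pass_ok[i]) "pass" else "skipped",
      tier = tier[i]
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
    exomiser_score = tab$exomiser_score[idx], strategy = "gms",
    tier = tier[idx], reportable = NA, diagnostic = NA,
    rule_trace = trace
  )
}
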