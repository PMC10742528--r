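# Synthetic trio-cohort generator.  Emulates the study design — eight
# families, seven full trios plus one family sequenced as father and two
# affected monozygotic twins without maternal DNA — with planted causal
# variants and an overwhelmingly filterable background, so the whole
# pipeline is testable without any download.

#' Specification of a synthetic trio cohort
#'
#' @param n_families Number of families (default 8, the study design; when
#'   `twin_family` is `TRUE` the 4th family is father + affected twins with
#'   no maternal sample).
#' @param variants_per_family Background variants generated per family.
#' @param planted Tibble describing planted causal variants: columns
#'   `family` (1-based family index), `model` (`de_novo`, `comp_het`,
#'   `hom_recessive`, `x_linked`, `clinvar_inherited`), `gene`,
#'   `satisfies_hippo` (construct the variant to pass the full cascade, or
#'   to violate exactly one predicate), `on_panel` (include the gene as
#'   green on the simulated panel).  Defaults mirror the study's findings:
#'   de novo variants in six families, compound heterozygotes in three, and
#'   one pathogenic variant inherited from an unaffected parent.
#' @param seed Mandatory RNG seed; generation is deterministic given the
#'   spec.
#' @param twin_family Include the father + affected-twins family design.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_families = 8, variants_per_family = 150,
                        planted = default_plants(), seed,
                        twin_family = TRUE) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_families >= 1, variants_per_family >= 0)
  if (!is.null(planted) && nrow(planted) > 0) {
    stopifnot(all(c("family", "model", "gene", "satisfies_hippo",
                    "on_panel") %in% names(planted)))
    bad <- setdiff(planted$model, c("de_novo", "comp_het", "hom_recessive",
                                    "x_linked", "clinvar_inherited"))
    if (length(bad) > 0) {
      stop("unknown planted model(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(planted$family > n_families)) {
      stop("planted family index exceeds n_families", call. = FALSE)
    }
  }
  structure(list(n_families = as.integer(n_families),
                 variants_per_family = as.integer(variants_per_family),
                 planted = planted, seed = as.integer(seed),
                 twin_family = isTRUE(twin_family) && n_families >= 4),
            class = "cohort_spec")
}

#' Default planted-variant layout emulating the study's findings
#' @return Planted tibble for [cohort_spec()].
#' @export
default_plants <- function() {
  tibble::tribble(
    ~family, ~model, ~gene, ~satisfies_hippo, ~on_panel,
    1L, "de_novo", "GENE_DN1", TRUE, FALSE,
    2L, "comp_het", "GENE_CH1", TRUE, FALSE,
    3L, "de_novo", "GENE_DN2", TRUE, TRUE,
    4L, "de_novo", "GENE_DN3", TRUE, FALSE,
    5L, "clinvar_inherited", "GENE_CI1", TRUE, FALSE,
    6L, "de_novo", "GENE_DN4", TRUE, TRUE,
    7L, "comp_het", "GENE_CH2", TRUE, FALSE,
    8L, "de_novo", "GENE_DN5", TRUE, FALSE
  )
}

sim_pedigree <- function(spec) {
  rows <- list()
  for (f in seq_len(spec$n_families)) {
    fam <- sprintf("FAM_%d", f)
    pro <- sprintf("%s_P", fam)
    fa <- sprintf("%s_F", fam)
    mo <- sprintf("%s_M", fam)
    # proband sex: male in odd families (so X-linked plants are possible),
    # female in even ones
    sex <- if (f %% 2 == 1) "male" else "female"
    if (spec$twin_family && f == 4) {
      tw <- sprintf("%s_T", fam)
      rows[[f]] <- tibble::tibble(
        family_id = fam,
        sample_id = c(pro, tw, fa),
        father_id = c(fa, fa, NA),
        mother_id = c(NA, NA, NA),
        sex = c("female", "female", "male"),
        affected = c("yes", "yes", "no")
      )
    } else {
      rows[[f]] <- tibble::tibble(
        family_id = fam,
        sample_id = c(pro, fa, mo),
        father_id = c(fa, NA, NA),
        mother_id = c(mo, NA, NA),
        sex = c(sex, "male", "female"),
        affected = c("yes", "no", "no")
      )
    }
  }
  dplyr::bind_rows(rows)
}

# One variant row + family genotypes.  `pattern` fixes the trio genotypes;
# annotation values are drawn from the background distributions unless
# overridden.
sim_gt_patterns <- c("inherited_father", "inherited_mother", "both_het",
                     "denovo_lowgq", "hom_recessive")

#' Generate a synthetic annotated trio cohort
#'
#' Deterministically (given the spec's seed, one RNG stream per family)
#' generates background variants whose annotations are drawn from realistic
#' mixtures — most are common (population AF from a broad Beta), inherited
#' from a single unaffected parent, of modest CADD (mean ~8), and a quarter
#' synonymous — so that well under 5% of the background survives the
#' cascade.  Planted variants are constructed so that every filter predicate
#' holds (or, with `satisfies_hippo = FALSE`, exactly one drawn predicate is
#' violated).  The truth manifest records, per variant, the intended
#' inheritance model and the by-construction value of each predicate.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory for `cohort.vcf`, `cohort.ped`,
#'   `truth.tsv` and `panels.tsv`.
#' @return List with `cohort` (a `trio_cohort`), `pedigree`, `manifest`,
#'   `panels`, and `paths` when `dir` is given.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  ped <- sim_pedigree(spec)
  genes_bg <- sprintf("BG%04d", 1:400)

  fam_out <- vector("list", spec$n_families)
  for (f in seq_len(spec$n_families)) {
    set.seed((spec$seed %% 10000000L) * 100L + f)
    fam_out[[f]] <- sim_family(spec, ped, f, genes_bg)
  }
  variants <- dplyr::bind_rows(lapply(fam_out, `[[`, "variants"))
  calls <- dplyr::bind_rows(lapply(fam_out, `[[`, "calls"))
  manifest <- dplyr::bind_rows(lapply(fam_out, `[[`, "manifest"))

  # samples not genotyped in a variant's family are hom ref
  full_calls <- tidyr::expand_grid(key = variants$key,
                                   sample_id = ped$sample_id) |>
    dplyr::left_join(calls, by = c("key", "sample_id")) |>
    dplyr::mutate(
      gt = tidyr::replace_na(.data$gt, "hom_ref"),
      ad_ref = tidyr::replace_na(.data$ad_ref, 30L),
      ad_alt = tidyr::replace_na(.data$ad_alt, 0L),
      gq = tidyr::replace_na(.data$gq, 99),
      filter_pass = tidyr::replace_na(.data$filter_pass, TRUE)
    )

  cohort <- new_trio_cohort(variants, full_calls, ped$sample_id, ped)

  panel_genes <- character()
  if (!is.null(spec$planted) && nrow(spec$planted) > 0) {
    panel_genes <- spec$planted$gene[spec$planted$on_panel]
  }
  panels <- if (length(panel_genes) > 0) {
    tibble::tibble(panel_id = "SIM1", gene = unique(panel_genes),
                   rating = "green")
  } else {
    tibble::tibble(panel_id = character(), gene = character(),
                   rating = character())
  }

  out <- list(cohort = cohort, pedigree = ped, manifest = manifest,
              panels = panels)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "cohort.vcf"),
                  ped = file.path(dir, "cohort.ped"),
                  truth = file.path(dir, "truth.tsv"),
                  panels = file.path(dir, "panels.tsv"))
    write_cohort_vcf(cohort, paths$vcf)
    write_ped(ped, paths$ped)
    readr::write_tsv(manifest, paths$truth, progress = FALSE)
    readr::write_tsv(panels, paths$panels, progress = FALSE)
    out$paths <- paths
  }
  out
}

sim_family <- function(spec, ped, f, genes_bg) {
  fam <- sprintf("FAM_%d", f)
  members <- ped[ped$family_id == fam, ]
  pro <- members$sample_id[members$affected == "yes"][1]
  fa_id <- members$father_id[members$sample_id == pro]
  mo_id <- members$mother_id[members$sample_id == pro]
  twin <- setdiff(members$sample_id[members$affected == "yes"], pro)
  pro_sex <- members$sex[members$sample_id == pro]

  n_bg <- spec$variants_per_family
  plants <- spec$planted
  plants <- if (is.null(plants)) NULL else plants[plants$family == f, , drop = FALSE]

  rows <- list()
  mk_variant <- function(chrom, pos, gene, csq, dist, af, cohort_af, cadd,
                         spliceai, clinvar, gq_trio, gts, filter = "PASS",
                         planted = FALSE, model = NA_character_) {
    key <- variant_key(chrom, pos, "A", "G")
    var <- tibble::tibble(
      key = key, chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
      gene = gene, csq_terms = csq, csq_dist = as.integer(dist),
      af_gnomad_ex = af, af_gnomad_wg = af * stats::runif(1, 0.7, 1.3),
      af_topmed = NA_real_, af_exac = NA_real_, af_1kg = NA_real_,
      cohort_af = cohort_af, cadd = cadd, revel = NA_real_,
      spliceai = spliceai, clinvar = clinvar,
      exomiser_rank = NA_integer_, exomiser_score = NA_real_, filter = filter
    )
    samples <- c(pro, twin, stats::na.omit(c(fa_id, mo_id)))
    stopifnot(length(gts) == length(samples))
    call <- tibble::tibble(
      key = key, sample_id = samples, gt = gts,
      ad_ref = ifelse(gts == "het", 14L, ifelse(gts %in% c("hom_alt", "hemi"), 1L, 28L)),
      ad_alt = ifelse(gts == "het", 13L, ifelse(gts %in% c("hom_alt", "hemi"), 27L, 1L)),
      gq = gq_trio[seq_along(samples)],
      filter_pass = filter %in% c("PASS", ".")
    )
    list(var = var, call = call, planted = planted, model = model)
  }

  # positions: family f owns its own coordinate block to keep keys unique
  pos_base <- f * 10000000L
  pos_i <- 0L
  next_pos <- function() {
    pos_i <<- pos_i + 1L
    pos_base + pos_i * 17L
  }
  gts_for <- function(p, fa, mo) {
    g <- c(p, if (length(twin) > 0) p else NULL,
           if (!is.na(fa_id)) fa else NULL,
           if (!is.na(mo_id)) mo else NULL)
    g
  }

  # ---- background (vectorised: one draw block for the whole family) ----
  bg <- NULL
  if (n_bg > 0) {
    common <- stats::runif(n_bg) < 0.7
    af <- ifelse(common, stats::rbeta(n_bg, 2, 5), stats::rbeta(n_bg, 0.5, 60))
    cohort_af <- pmin(0.5, af * stats::runif(n_bg, 0.5, 2) + 1e-5)
    cadd <- pmax(0, stats::rnorm(n_bg, 8, 5))
    csq_pick <- stats::runif(n_bg)
    csq <- ifelse(csq_pick < 0.55, "missense_variant",
                  ifelse(csq_pick < 0.8, "synonymous_variant",
                         "intron_variant"))
    dist <- ifelse(csq == "intron_variant",
                   sample(1:200, n_bg, replace = TRUE), 0L)
    spliceai <- ifelse(stats::runif(n_bg) < 0.5,
                       stats::rbeta(n_bg, 0.5, 12), NA_real_)
    clinvar <- sample(c("none", "VUS", "B", "LB"), n_bg, replace = TRUE,
                      prob = c(0.8, 0.1, 0.07, 0.03))
    pattern <- sample(sim_gt_patterns, n_bg, replace = TRUE,
                      prob = c(0.3, 0.3, 0.15, 0.1, 0.15))
    pos <- pos_base + seq_len(n_bg) * 17L
    pos_i <- n_bg
    key <- variant_key(chrom_bg <- as.character(sample(1:22, n_bg, TRUE)),
                       pos, "A", "G")
    bg_variants <- tibble::tibble(
      key = key, chrom = chrom_bg, pos = as.integer(pos), ref = "A", alt = "G",
      gene = sample(genes_bg, n_bg, replace = TRUE), csq_terms = csq,
      csq_dist = as.integer(dist), af_gnomad_ex = af,
      af_gnomad_wg = af * stats::runif(n_bg, 0.7, 1.3),
      af_topmed = NA_real_, af_exac = NA_real_, af_1kg = NA_real_,
      cohort_af = cohort_af, cadd = cadd, revel = NA_real_,
      spliceai = spliceai, clinvar = clinvar,
      exomiser_rank = NA_integer_, exomiser_score = NA_real_, filter = "PASS"
    )
    pro_gt <- ifelse(pattern == "hom_recessive", "hom_alt", "het")
    fa_gt <- ifelse(pattern %in% c("inherited_father", "both_het",
                                   "hom_recessive"), "het", "hom_ref")
    mo_gt <- ifelse(pattern %in% c("inherited_mother", "both_het",
                                   "hom_recessive"), "het", "hom_ref")
    low <- pattern == "denovo_lowgq"
    fa_gq <- ifelse(low, sample(5:35, n_bg, replace = TRUE), 99)
    mo_gq <- ifelse(low, sample(5:35, n_bg, replace = TRUE), 99)
    sample_call <- function(id, gt, gq) {
      tibble::tibble(
        key = key, sample_id = id, gt = gt,
        ad_ref = ifelse(gt == "het", 14L,
                        ifelse(gt %in% c("hom_alt", "hemi"), 1L, 28L)),
        ad_alt = ifelse(gt == "het", 13L,
                        ifelse(gt %in% c("hom_alt", "hemi"), 27L, 1L)),
        gq = gq, filter_pass = TRUE
      )
    }
    bg_calls <- dplyr::bind_rows(c(
      list(sample_call(pro, pro_gt, rep(99, n_bg))),
      if (length(twin) > 0) list(sample_call(twin, pro_gt, rep(99, n_bg))),
      if (!is.na(fa_id)) list(sample_call(fa_id, fa_gt, fa_gq)),
      if (!is.na(mo_id)) list(sample_call(mo_id, mo_gt, mo_gq))
    ))
    bg <- list(variants = bg_variants, calls = bg_calls)
  }

  # ---- planted ----
  if (!is.null(plants) && nrow(plants) > 0) {
    for (j in seq_len(nrow(plants))) {
      p <- plants[j, ]
      if (p$model == "x_linked" && pro_sex != "male") {
        stop("cannot plant an X-linked recessive variant in family ", fam,
             ": proband is not male", call. = FALSE)
      }
      break_rule <- if (!p$satisfies_hippo) {
        sample(c("af", "cadd", "clinvar_benign", "synonymous", "gq"), 1)
      } else "none"
      af <- if (break_rule == "af") 0.1 else min(stats::rbeta(1, 0.5, 2000), 4e-4)
      cadd <- if (break_rule == "cadd") 5 else stats::runif(1, 22, 38)
      clinvar <- if (break_rule == "clinvar_benign") "B" else "none"
      csq <- if (break_rule == "synonymous") "synonymous_variant"
             else "missense_variant"
      gq <- if (break_rule == "gq") rep(25, 4) else rep(99, 4)
      mk_plant <- function(model, gts, clinvar_final, af_val) {
        rows[[length(rows) + 1]] <<- mk_variant(
          chrom = if (model == "x_linked") "X" else as.character(sample(1:22, 1)),
          pos = next_pos(), gene = p$gene, csq = csq, dist = 0L,
          af = af_val, cohort_af = 2e-5, cadd = cadd,
          spliceai = NA_real_, clinvar = clinvar_final, gq_trio = gq,
          gts = gts, planted = TRUE, model = model
        )
      }
      switch(p$model,
        de_novo = mk_plant("de_novo", gts_for("het", "hom_ref", "hom_ref"),
                           clinvar, af),
        clinvar_inherited = mk_plant(
          "clinvar_inherited", gts_for("het", "het", "hom_ref"),
          if (break_rule == "clinvar_benign") "B" else "P", af),
        hom_recessive = mk_plant("hom_recessive",
                                 gts_for("hom_alt", "het", "het"), clinvar, af),
        x_linked = {
          g <- c("hemi", if (length(twin) > 0) "hemi" else NULL,
                 if (!is.na(fa_id)) "hom_ref" else NULL,
                 if (!is.na(mo_id)) "het" else NULL)
          mk_plant("x_linked", g, clinvar, af)
        },
        comp_het = {
          mk_plant("comp_het", gts_for("het", "het", "hom_ref"), clinvar, af)
          mk_plant("comp_het", gts_for("het", "hom_ref", "het"), clinvar, af)
        }
      )
    }
  }

  variants <- dplyr::bind_rows(c(
    if (!is.null(bg)) list(bg$variants),
    lapply(rows, `[[`, "var")
  ))
  calls <- dplyr::bind_rows(c(
    if (!is.null(bg)) list(bg$calls),
    lapply(rows, `[[`, "call")
  ))
  planted_info <- tibble::tibble(
    key = variants$key,
    planted = variants$key %in% vapply(rows, function(r) r$var$key, character(1)),
    model_intended = NA_character_
  )
  for (r in rows) {
    planted_info$model_intended[planted_info$key == r$var$key] <- r$model
  }

  manifest <- build_manifest(variants, calls, planted_info, fam, pro,
                             fa_id, mo_id, pro_sex)
  list(variants = variants, calls = calls, manifest = manifest)
}

# Recompute, per generated variant, the by-construction value of every
# cascade predicate under its intended inheritance arm.
build_manifest <- function(variants, calls, planted_info, fam, pro,
                           fa_id, mo_id, pro_sex) {
  cfg <- hippo_config()
  n <- nrow(variants)
  pick <- function(id, col) {
    if (is.na(id)) return(rep(NA, n))
    cc <- calls[calls$sample_id == id, ]
    cc[[col]][match(variants$key, cc$key)]
  }
  pgt <- as.character(pick(pro, "gt"))
  pgq <- as.numeric(pick(pro, "gq"))
  p_adr <- as.integer(pick(pro, "ad_ref"))
  p_ada <- as.integer(pick(pro, "ad_alt"))
  fgt <- as.character(pick(fa_id, "gt"))
  fgq <- as.numeric(pick(fa_id, "gq"))
  mgt <- as.character(pick(mo_id, "gt"))
  mgq <- as.numeric(pick(mo_id, "gq"))
  cls_chrom <- chrom_class(variants$chrom)
  max_af <- max_population_af(variants)
  comp_half <- !is.na(planted_info$model_intended) &
    planted_info$model_intended == "comp_het"

  dominant_arm <- logical(n)
  recessive_arm <- logical(n)
  insilico_ok <- logical(n)
  for (i in seq_len(n)) {
    trio <- trio_context(
      proband = list(gt = pgt[i], gq = pgq[i], affected = "yes"),
      father = if (is.na(fgt[i])) NULL else
        list(gt = fgt[i], gq = fgq[i], affected = "no"),
      mother = if (is.na(mgt[i])) NULL else
        list(gt = mgt[i], gq = mgq[i], affected = "no"),
      chrom_class = cls_chrom[i], proband_sex = pro_sex
    )
    cls <- classify_single(trio, min_gq = cfg$gq_min)
    dominant_arm[i] <- cls$model %in% c("de_novo", "dominant_inherited") ||
      (cls$blocked_by_unaffected_carrier &&
         variants$clinvar[i] %in% c("P", "LP"))
    recessive_arm[i] <- cls$model %in% c("hom_recessive",
                                         "x_linked_recessive") || comp_half[i]
    insilico_ok[i] <- passes_insilico(variants$cadd[i], variants$spliceai[i],
                                      variants$csq_terms[i],
                                      variants$clinvar[i], cfg)$pass
  }
  ab <- allele_balance(p_adr, p_ada)
  out <- tibble::tibble(
    family_id = fam, proband_id = pro, key = variants$key,
    gene = variants$gene, planted = planted_info$planted,
    model_intended = planted_info$model_intended,
    inheritance_ok = dominant_arm | recessive_arm,
    af_ok = (dominant_arm & max_af < cfg$af_dominant) |
      (recessive_arm & max_af < cfg$af_recessive),
    cohort_ok = variants$cohort_af < cfg$cohort_af_max,
    type_ok = passes_variant_type(variants$csq_terms, variants$csq_dist,
                                  cfg$coding_window_bp),
    insilico_ok = insilico_ok,
    clinvar_ok = clinvar_gate(variants$clinvar) != "fail",
    gq_ok = pgq > cfg$gq_min,
    ab_ok = pgt != "het" | (!is.na(ab) & ab > cfg$allele_balance_min)
  )
  out$satisfies_hippo <- out$inheritance_ok & out$af_ok & out$cohort_ok &
    out$type_ok & out$insilico_ok & out$clinvar_ok & out$gq_ok & out$ab_ok
  out
}
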