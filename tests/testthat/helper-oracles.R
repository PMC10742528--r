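# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code path with the package internals: plain
# loops over rows, direct re-statements of the filter predicates.

# O(1) call lookup: per-sample columns pre-pivoted over the variant keys.
call_lookup <- function(calls, keys) {
  samples <- unique(calls$sample_id)
  tabs <- lapply(samples, function(s) {
    cc <- calls[calls$sample_id == s, ]
    ix <- match(keys, cc$key)
    list(gt = cc$gt[ix], gq = cc$gq[ix],
         ad_ref = cc$ad_ref[ix], ad_alt = cc$ad_alt[ix])
  })
  names(tabs) <- samples
  key_ix <- stats::setNames(seq_along(keys), keys)
  function(sample, key) {
    t <- tabs[[sample]]
    if (is.null(t)) return(NULL)
    i <- key_ix[[key]]
    if (is.null(i) || is.na(t$gt[i])) return(NULL)
    list(gt = t$gt[i], gq = t$gq[i], ad_ref = t$ad_ref[i], ad_alt = t$ad_alt[i])
  }
}

# ---- straight-line re-implementation of the full cascade --------------------
# One predicate at a time, per (proband, variant); compound hets by explicit
# pair enumeration.  Returns tibble(family_id, proband_id, key).
oracle_hippo <- function(cohort, cfg = hippo_config()) {
  ped <- cohort$pedigree
  variants <- cohort$variants
  calls <- cohort$calls
  if (all(is.na(variants$cohort_af))) {
    variants$cohort_af <- founder_cohort_af(cohort)
  }
  lk <- call_lookup(calls, variants$key)
  get_call <- function(sample, key) lk(sample, key)
  coding <- c("missense_variant", "missense", "stop_gained", "stop_lost",
              "start_lost", "frameshift_variant", "frameshift",
              "inframe_insertion", "inframe_deletion",
              "protein_altering_variant", "coding_sequence_variant",
              "transcript_ablation", "synonymous_variant", "synonymous",
              "stop_retained_variant", "start_retained_variant",
              "incomplete_terminal_codon_variant")
  synony <- c("synonymous_variant", "synonymous", "stop_retained_variant",
              "start_retained_variant")
  splicey <- c("splice_donor_variant", "splice_donor",
               "splice_acceptor_variant", "splice_acceptor",
               "splice_region_variant", "splice_region",
               "intron_variant", "intron")

  hits <- list()
  for (fam in unique(ped$family_id)) {
    fam_ped <- ped[ped$family_id == fam, ]
    for (pro in fam_ped$sample_id[fam_ped$affected == "yes"]) {
      fa_id <- fam_ped$father_id[fam_ped$sample_id == pro]
      mo_id <- fam_ped$mother_id[fam_ped$sample_id == pro]
      pro_sex <- fam_ped$sex[fam_ped$sample_id == pro]
      unaff <- fam_ped$sample_id[fam_ped$affected == "no"]

      per_variant <- list()
      for (vi in seq_len(nrow(variants))) {
        v <- as.list(variants[vi, ])
        pc <- get_call(pro, v$key)
        if (is.null(pc) || !(pc$gt %in% c("het", "hom_alt", "hemi"))) next
        fc <- if (is.na(fa_id)) NULL else get_call(fa_id, v$key)
        mc <- if (is.na(mo_id)) NULL else get_call(mo_id, v$key)
        if (!is.null(fc) && fc$gt == "missing") fc <- NULL
        if (!is.null(mc) && mc$gt == "missing") mc <- NULL
        cclass <- if (sub("^chr", "", v$chrom) == "X") "chrX"
                  else if (sub("^chr", "", v$chrom) %in% c("Y")) "chrY"
                  else if (sub("^chr", "", v$chrom) %in% c("MT", "M")) "MT"
                  else "autosome"
        if (cclass %in% c("chrY", "MT")) next

        gq_ok <- function(x) cfg$gq_min <= 0 ||
          (!is.null(x) && !is.na(x$gq) && x$gq > cfg$gq_min)
        carrier <- function(x) !is.null(x) &&
          x$gt %in% c("het", "hom_alt", "hemi")
        hetish <- pc$gt == "het" ||
          (cclass == "chrX" && pro_sex == "male" && pc$gt == "hemi")

        de_novo <- hetish && !is.null(fc) && !is.null(mc) &&
          fc$gt == "hom_ref" && mc$gt == "hom_ref" &&
          gq_ok(pc) && gq_ok(fc) && gq_ok(mc)
        xlr <- cclass == "chrX" && pro_sex == "male" &&
          pc$gt %in% c("hemi", "hom_alt") && !is.null(mc) && mc$gt == "het" &&
          (is.null(fc) || !carrier(fc))
        homrec <- pc$gt == "hom_alt" &&
          (is.null(fc) || fc$gt == "het") && (is.null(mc) || mc$gt == "het")
        blockers <- (carrier(fc) &&
                       fam_ped$affected[fam_ped$sample_id == fa_id] == "no") ||
                    (carrier(mc) &&
                       fam_ped$affected[fam_ped$sample_id == mo_id] == "no")
        dominant <- hetish && !de_novo && !blockers
        override_dom <- hetish && blockers && v$clinvar %in% c("P", "LP")

        terms <- trimws(strsplit(v$csq_terms, ",")[[1]])
        terms <- terms[terms != ""]
        in_scope <- any(terms %in% coding) ||
          (!is.na(v$csq_dist) && v$csq_dist <= cfg$coding_window_bp)
        syn_only <- length(terms) > 0 && all(terms %in% synony)
        type_ok <- (in_scope && !syn_only) ||
          (syn_only && !is.na(v$spliceai) && v$spliceai > cfg$spliceai_min)

        retain <- cfg$missing_score_policy == "retain"
        plp <- v$clinvar %in% c("P", "LP")
        cadd_ok <- if (is.na(v$cadd)) retain else v$cadd > cfg$cadd_min || plp
        splice_only <- length(terms) > 0 && all(terms %in% splicey)
        sp_ok <- if (!splice_only) TRUE
                 else if (is.na(v$spliceai)) retain
                 else v$spliceai > cfg$spliceai_min || plp
        clin_ok <- !(v$clinvar %in% c("B", "LB"))
        coh_ok <- if (is.na(v$cohort_af)) retain
                  else v$cohort_af < cfg$cohort_af_max
        g_ok <- !is.na(pc$gq) && pc$gq > cfg$gq_min
        tot <- pc$ad_ref + pc$ad_alt
        ab_ok <- if (pc$gt != "het") TRUE
                 else if (is.na(tot) || tot == 0) retain
                 else pc$ad_alt / tot > cfg$allele_balance_min
        shared <- type_ok && cadd_ok && sp_ok && clin_ok && coh_ok &&
          g_ok && ab_ok

        af <- suppressWarnings(max(c(v$af_gnomad_ex, v$af_gnomad_wg,
                                     v$af_topmed, v$af_exac, v$af_1kg),
                                   na.rm = TRUE))
        if (!is.finite(af)) af <- 0
        per_variant[[v$key]] <- list(
          gene = v$gene, het = pc$gt == "het",
          fc_gt = if (is.null(fc)) NA else fc$gt,
          mc_gt = if (is.null(mc)) NA else mc$gt,
          dom = de_novo || dominant || override_dom,
          rec_single = homrec || xlr,
          dom_af_ok = af < cfg$af_dominant,
          rec_af_ok = af < cfg$af_recessive,
          shared = shared
        )
      }

      # comp-het pair enumeration among recessive-eligible hets
      eligible <- names(per_variant)[vapply(per_variant, function(x) {
        x$het && x$shared && x$rec_af_ok && !is.na(x$gene)
      }, logical(1))]
      comp_keys <- character()
      if (length(eligible) >= 2) {
        for (i in seq_along(eligible)) for (j in seq_along(eligible)) {
          if (i >= j) next
          a <- per_variant[[eligible[i]]]
          b <- per_variant[[eligible[j]]]
          if (is.na(a$gene) || is.na(b$gene) || a$gene != b$gene) next
          orig <- function(x) {
            f_car <- !is.na(x$fc_gt) && x$fc_gt %in% c("het", "hom_alt", "hemi")
            m_car <- !is.na(x$mc_gt) && x$mc_gt %in% c("het", "hom_alt", "hemi")
            if (f_car && m_car) "ambiguous"
            else if (m_car) "maternal"
            else if (f_car) "paternal"
            else if (is.na(x$fc_gt) || is.na(x$mc_gt)) "unknown"
            else "neither"
          }
          o1 <- orig(a); o2 <- orig(b)
          trans <- (o1 == "maternal" && o2 == "paternal") ||
                   (o1 == "paternal" && o2 == "maternal")
          maybe <- (o1 == "unknown" || o2 == "unknown") &&
            !(o1 == o2 && o1 %in% c("maternal", "paternal"))
          if (!trans && !maybe) next
          k1 <- eligible[i]; k2 <- eligible[j]
          both_unaff <- FALSE
          for (u in unaff) {
            c1 <- get_call(u, k1); c2 <- get_call(u, k2)
            if (!is.null(c1) && c1$gt %in% c("het", "hom_alt", "hemi") &&
                !is.null(c2) && c2$gt %in% c("het", "hom_alt", "hemi")) {
              both_unaff <- TRUE
            }
          }
          if (!both_unaff) comp_keys <- union(comp_keys, c(k1, k2))
        }
      }

      for (k in names(per_variant)) {
        x <- per_variant[[k]]
        dom_pass <- x$dom && x$dom_af_ok
        rec_pass <- (x$rec_single || k %in% comp_keys) && x$rec_af_ok
        if ((dom_pass || rec_pass) && x$shared) {
          hits[[length(hits) + 1]] <- tibble::tibble(
            family_id = fam, proband_id = pro, key = k)
        }
      }
    }
  }
  if (length(hits) == 0) {
    tibble::tibble(family_id = character(), proband_id = character(),
                   key = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(hits), family_id, proband_id, key)
  }
}

# ---- straight-line tier oracle ---------------------------------------------
oracle_gms <- function(cohort, panels, cfg = gms_config()) {
  ped <- cohort$pedigree
  variants <- cohort$variants
  calls <- cohort$calls
  plof_terms <- c("stop_gained", "frameshift", "frameshift_variant",
                  "splice_donor", "splice_donor_variant", "splice_acceptor",
                  "splice_acceptor_variant", "start_lost", "stop_lost",
                  "transcript_ablation")
  coding <- c("missense_variant", "missense", "stop_gained", "stop_lost",
              "start_lost", "frameshift_variant", "frameshift",
              "inframe_insertion", "inframe_deletion",
              "protein_altering_variant", "coding_sequence_variant",
              "transcript_ablation", "synonymous_variant", "synonymous",
              "stop_retained_variant", "start_retained_variant",
              "incomplete_terminal_codon_variant")
  synony <- c("synonymous_variant", "synonymous", "stop_retained_variant",
              "start_retained_variant")
  lk <- call_lookup(calls, variants$key)
  get_call <- function(sample, key) lk(sample, key)
  out <- list()
  for (fam in unique(ped$family_id)) {
    fam_ped <- ped[ped$family_id == fam, ]
    gp <- panels
    if (!is.null(gp) && "family_id" %in% names(gp)) {
      gp <- gp[gp$family_id == fam, ]
    }
    green <- if (is.null(gp)) character() else
      unique(gp$gene[gp$rating == "green"])
    for (pro in fam_ped$sample_id[fam_ped$affected == "yes"]) {
      fa_id <- fam_ped$father_id[fam_ped$sample_id == pro]
      mo_id <- fam_ped$mother_id[fam_ped$sample_id == pro]
      unaff <- fam_ped$sample_id[fam_ped$affected == "no"]

      rec <- list()
      for (vi in seq_len(nrow(variants))) {
        v <- as.list(variants[vi, ])
        pc <- get_call(pro, v$key)
        if (is.null(pc) || !(pc$gt %in% c("het", "hom_alt", "hemi"))) next
        cn <- sub("^chr", "", v$chrom)
        if (cn %in% c("Y", "MT", "M")) next
        fc <- if (is.na(fa_id)) NULL else get_call(fa_id, v$key)
        mc <- if (is.na(mo_id)) NULL else get_call(mo_id, v$key)
        if (!is.null(fc) && fc$gt == "missing") fc <- NULL
        if (!is.null(mc) && mc$gt == "missing") mc <- NULL

        terms <- trimws(strsplit(v$csq_terms, ",")[[1]])
        terms <- terms[terms != ""]
        in_scope <- any(terms %in% coding) ||
          (!is.na(v$csq_dist) && v$csq_dist <= cfg$coding_window_bp)
        syn_only <- length(terms) > 0 && all(terms %in% synony)
        coding_ok <- in_scope && !syn_only
        af <- suppressWarnings(max(c(v$af_gnomad_ex, v$af_gnomad_wg,
                                     v$af_topmed, v$af_exac, v$af_1kg),
                                   na.rm = TRUE))
        if (!is.finite(af)) af <- 0
        parents_ref <- !is.null(fc) && !is.null(mc) &&
          fc$gt == "hom_ref" && mc$gt == "hom_ref"
        hetish <- pc$gt == "het"
        dn_any <- hetish && parents_ref
        dn_strict <- dn_any && !is.na(pc$gq) && pc$gq > cfg$gq_min &&
          !is.na(fc$gq) && fc$gq > cfg$gq_min &&
          !is.na(mc$gq) && mc$gq > cfg$gq_min
        carrier <- function(x) !is.null(x) &&
          x$gt %in% c("het", "hom_alt", "hemi")
        blockers <- (carrier(fc) &&
                       fam_ped$affected[fam_ped$sample_id == fa_id] == "no") ||
                    (carrier(mc) &&
                       fam_ped$affected[fam_ped$sample_id == mo_id] == "no")
        dominant <- hetish && !blockers
        homrec <- pc$gt == "hom_alt" &&
          (is.null(fc) || fc$gt == "het") && (is.null(mc) || mc$gt == "het")
        gq_ok <- !is.na(pc$gq) && pc$gq > cfg$gq_min
        pass_ok <- !cfg$require_pass_filter || v$filter %in% c("PASS", ".")

        rec[[v$key]] <- list(
          gene = v$gene, het = hetish,
          fc_gt = if (is.null(fc)) NA else fc$gt,
          mc_gt = if (is.null(mc)) NA else mc$gt,
          dom_arm = dominant || dn_strict, homrec = homrec,
          dn_any = dn_any, dn_strict = dn_strict,
          af = af, gq_ok = gq_ok, pass_ok = pass_ok,
          coding_ok = coding_ok, plof = any(terms %in% plof_terms),
          exomiser_rank = v$exomiser_rank, exomiser_score = v$exomiser_score
        )
      }

      # comp-het pairs among quality-passing hets at the recessive AF cap
      eligible <- names(rec)[vapply(rec, function(x) {
        x$het && x$gq_ok && x$pass_ok && x$af < cfg$af_recessive &&
          !is.na(x$gene)
      }, logical(1))]
      comp_keys <- character()
      if (length(eligible) >= 2) {
        for (i in seq_along(eligible)) for (j in seq_along(eligible)) {
          if (i >= j) next
          a <- rec[[eligible[i]]]; b <- rec[[eligible[j]]]
          if (is.na(a$gene) || is.na(b$gene) || a$gene != b$gene) next
          orig <- function(x) {
            f_car <- !is.na(x$fc_gt) && x$fc_gt %in% c("het", "hom_alt", "hemi")
            m_car <- !is.na(x$mc_gt) && x$mc_gt %in% c("het", "hom_alt", "hemi")
            if (f_car && m_car) "ambiguous"
            else if (m_car) "maternal"
            else if (f_car) "paternal"
            else if (is.na(x$fc_gt) || is.na(x$mc_gt)) "unknown"
            else "neither"
          }
          o1 <- orig(a); o2 <- orig(b)
          trans <- (o1 == "maternal" && o2 == "paternal") ||
                   (o1 == "paternal" && o2 == "maternal")
          maybe <- (o1 == "unknown" || o2 == "unknown") &&
            !(o1 == o2 && o1 %in% c("maternal", "paternal"))
          if (!trans && !maybe) next
          k1 <- eligible[i]; k2 <- eligible[j]
          both_unaff <- FALSE
          for (u in unaff) {
            c1 <- get_call(u, k1); c2 <- get_call(u, k2)
            if (!is.null(c1) && c1$gt %in% c("het", "hom_alt", "hemi") &&
                !is.null(c2) && c2$gt %in% c("het", "hom_alt", "hemi")) {
              both_unaff <- TRUE
            }
          }
          if (!both_unaff) comp_keys <- union(comp_keys, c(k1, k2))
        }
      }

      for (k in names(rec)) {
        x <- rec[[k]]
        rec_arm <- x$homrec || k %in% comp_keys
        af_ok <- (x$dom_arm && x$af < cfg$af_dominant) ||
          (rec_arm && x$af < cfg$af_recessive)
        prefilter <- (x$dom_arm || rec_arm) && af_ok && x$gq_ok && x$pass_ok
        on_panel <- !is.na(x$gene) && x$gene %in% green
        tier <- "untiered"
        if (prefilter && x$coding_ok && on_panel && (x$plof || x$dn_strict)) {
          tier <- "tier1"
        } else if (prefilter && x$coding_ok && on_panel) {
          tier <- "tier2"
        } else if (x$dn_any && x$af < cfg$af_dominant && x$coding_ok) {
          tier <- "ga_denovo"
        } else if (!is.na(x$exomiser_rank) &&
                   x$exomiser_rank <= cfg$exomiser_top_rank &&
                   !is.na(x$exomiser_score) &&
                   x$exomiser_score >= cfg$exomiser_min_score && x$coding_ok) {
          tier <- "ga_exomiser"
        }
        if (tier != "untiered") {
          out[[length(out) + 1]] <- tibble::tibble(
            family_id = fam, proband_id = pro, key = k, tier = tier)
        }
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(family_id = character(), proband_id = character(),
                   key = character(), tier = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(out), family_id, proband_id, key)
  }
}

# ---- exact signed-rank distribution by generating-function convolution -----
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  # distribution of V over sign flips via polynomial convolution on the
  # doubled-rank lattice (ranks may be half-integers under ties)
  r2 <- as.integer(round(2 * r))
  poly <- c(1)
  for (w in r2) {
    shifted <- c(rep(0, w), poly)
    poly <- c(poly, rep(0, w)) + shifted
  }
  poly <- poly / sum(poly)
  support <- (seq_along(poly) - 1) / 2
  mu <- sum(r) / 2
  sum(poly[abs(support - mu) >= abs(v - mu) - 1e-9])
}

# ---- Fisher two-sided p by direct table enumeration with choose() ----------
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  kmin <- max(0, c1 - r2); kmax <- min(r1, c1)
  prob <- function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  }
  p_obs <- prob(a)
  ks <- kmin:kmax
  sum(vapply(ks, prob, numeric(1))[vapply(ks, prob, numeric(1)) <=
                                     p_obs * (1 + 1e-7)])
}

# canonical order for set comparisons between pipeline and oracles
sorted_hits <- function(df) {
  dplyr::arrange(as.data.frame(df), family_id, proband_id, key)
}

# ---- tiny hand-built cohorts ------------------------------------------------
`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal trio cohort built entirely in code; `rows` is a tibble with one
# row per variant giving annotations and the trio genotypes.
make_trio_cohort <- function(rows, proband_sex = "male",
                             extra_members = NULL) {
  ped <- tibble::tibble(
    family_id = "F1",
    sample_id = c("kid", "dad", "mum"),
    father_id = c("dad", NA, NA),
    mother_id = c("mum", NA, NA),
    sex = c(proband_sex, "male", "female"),
    affected = c("yes", "no", "no")
  )
  if (!is.null(extra_members)) ped <- dplyr::bind_rows(ped, extra_members)
  defaults <- list(
    gene = "GENEA", csq_terms = "missense_variant", csq_dist = 0L,
    af = 0, cohort_af = 1e-4, cadd = 30, revel = NA_real_,
    spliceai = NA_real_, clinvar = "none", exomiser_rank = NA_integer_,
    exomiser_score = NA_real_, filter = "PASS",
    kid_gq = 99, dad_gq = 99, mum_gq = 99, kid_ad = c(15L, 15L)
  )
  n <- nrow(rows)
  col <- function(name) {
    if (name %in% names(rows)) rows[[name]] else rep(defaults[[name]], n)
  }
  chrom <- if ("chrom" %in% names(rows)) rows$chrom else rep("1", n)
  pos <- if ("pos" %in% names(rows)) rows$pos else seq_len(n) * 100L
  key <- variant_key(chrom, pos, "A", "G")
  variants <- tibble::tibble(
    key = key, chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
    gene = col("gene"), csq_terms = col("csq_terms"),
    csq_dist = as.integer(col("csq_dist")),
    af_gnomad_ex = as.numeric(col("af")), af_gnomad_wg = NA_real_,
    af_topmed = NA_real_, af_exac = NA_real_, af_1kg = NA_real_,
    cohort_af = as.numeric(col("cohort_af")), cadd = as.numeric(col("cadd")),
    revel = as.numeric(col("revel")), spliceai = as.numeric(col("spliceai")),
    clinvar = col("clinvar"),
    exomiser_rank = as.integer(col("exomiser_rank")),
    exomiser_score = as.numeric(col("exomiser_score")),
    filter = col("filter")
  )
  mk_calls <- function(sample, gt_col, gq_col, ad = NULL) {
    gt <- rows[[gt_col]]
    tibble::tibble(
      key = key, sample_id = sample, gt = gt,
      ad_ref = if (is.null(ad)) ifelse(gt == "het", 15L,
                                       ifelse(gt %in% c("hom_alt", "hemi"),
                                              0L, 30L)) else ad[1],
      ad_alt = if (is.null(ad)) ifelse(gt == "het", 15L,
                                       ifelse(gt %in% c("hom_alt", "hemi"),
                                              30L, 0L)) else ad[2],
      gq = as.numeric(col(gq_col)),
      filter_pass = col("filter") %in% c("PASS", ".")
    )
  }
  calls <- dplyr::bind_rows(
    mk_calls("kid", "kid_gt", "kid_gq"),
    mk_calls("dad", "dad_gt", "dad_gq"),
    mk_calls("mum", "mum_gt", "mum_gq")
  )
  if ("kid_ad_ref" %in% names(rows)) {
    ix <- calls$sample_id == "kid"
    calls$ad_ref[ix] <- rows$kid_ad_ref
    calls$ad_alt[ix] <- rows$kid_ad_alt
  }
  hippotrio:::new_trio_cohort(variants, calls, ped$sample_id, ped)
}
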