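test_that("maximum population AF takes the max over present sources, else 0", {
  v <- tibble::tibble(
    af_gnomad_ex = c(5.56e-4, NA, 1e-3),
    af_gnomad_wg = c(NA, NA, 2e-3),
    af_topmed = NA_real_, af_exac = NA_real_, af_1kg = NA_real_
  )
  expect_equal(max_population_af(v), c(5.56e-4, 0, 2e-3))
})

test_that("allele balance is the alt-read fraction, undefined on zero depth", {
  expect_equal(allele_balance(10L, 10L), 0.5)
  expect_equal(allele_balance(18L, 2L), 0.1)
  expect_true(is.na(allele_balance(0L, 0L)))
  expect_true(is.na(allele_balance(NA_integer_, 5L)))
})

test_that("variant-type window is boundary-inclusive and synonymous-only fails", {
  expect_true(passes_variant_type("stop_gained", 0L, 20))
  expect_false(passes_variant_type("synonymous_variant", 0L, 20))
  expect_false(passes_variant_type("intron_variant", 21L, 20))
  expect_true(passes_variant_type("intron_variant", 20L, 20))
  # synonymous on one transcript but missense on another still qualifies
  expect_true(passes_variant_type("synonymous_variant,missense_variant", 0L, 20))
})

test_that("in-silico rules: strict CADD cut, SpliceAI only for splicing variants", {
  cfg <- hippo_config()
  expect_true(passes_insilico(43, NA, "stop_gained", "none", cfg)$pass)
  expect_false(passes_insilico(15.0, NA, "missense_variant", "none", cfg)$pass)
  r <- passes_insilico(20, 0.1, "splice_region_variant", "none", cfg)
  expect_false(r$pass)
  expect_equal(r$spliceai, "fail")
  # non-splicing variant skips the SpliceAI rule even with a low score
  r2 <- passes_insilico(20, 0.1, "missense_variant", "none", cfg)
  expect_true(r2$pass)
  expect_equal(r2$spliceai, "skipped")
  # pathogenic classification overrides failing scores
  r3 <- passes_insilico(5, 0.05, "splice_donor_variant", "P", cfg)
  expect_true(r3$pass)
  expect_equal(r3$cadd, "overridden")
  # missing scores follow the policy
  expect_true(passes_insilico(NA, NA, "missense_variant", "none", cfg)$pass)
  drop_cfg <- hippo_config(missing_score_policy = "drop")
  expect_false(passes_insilico(NA, NA, "missense_variant", "none", drop_cfg)$pass)
})

test_that("ClinVar gate fails benign, overrides pathogenic, passes the rest", {
  expect_equal(clinvar_gate(c("B", "LB", "P", "LP", "VUS", "none")),
               c("fail", "fail", "override", "override", "pass", "pass"))
})

test_that("cascade keeps a clean de novo and drops a common benign background variant", {
  rows <- tibble::tibble(
    kid_gt = c("het", "het"),
    dad_gt = c("hom_ref", "het"),
    mum_gt = c("hom_ref", "hom_ref"),
    af = c(0, 0.01),
    clinvar = c("none", "B"),
    gene = c("G1", "G2")
  )
  cohort <- make_trio_cohort(rows)
  cands <- run_hippo(cohort)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$model, "de_novo")
  expect_true(cands$confirmed_de_novo)
})

test_that("pathogenic override rescues inheritance and scores but never the AF caps", {
  base <- tibble::tibble(
    kid_gt = "het", dad_gt = "het", mum_gt = "hom_ref",
    af = 1e-5, cadd = 5, clinvar = "P", gene = "G1"
  )
  # inherited from unaffected father + failing CADD: retained through override
  cands <- run_hippo(make_trio_cohort(base))
  expect_equal(nrow(cands), 1)
  expect_match(cands$rule_trace, "inheritance=overridden")
  expect_match(cands$rule_trace, "cadd=overridden")
  # same variant at dominant-arm AF cap: excluded despite pathogenic status
  common <- base
  common$af <- 0.01
  expect_equal(nrow(run_hippo(make_trio_cohort(common))), 0)
  # benign classification fails outright
  benign <- base
  benign$clinvar <- "B"
  expect_equal(nrow(run_hippo(make_trio_cohort(benign))), 0)
})

test_that("recessive arm admits hom-recessive and X-linked variants at the wider AF cap", {
  rows <- tibble::tibble(
    chrom = c("1", "X"),
    kid_gt = c("hom_alt", "hemi"),
    dad_gt = c("het", "hom_ref"),
    mum_gt = c("het", "het"),
    af = c(0.02, 0.001),
    gene = c("G1", "G2")
  )
  cands <- run_hippo(make_trio_cohort(rows, proband_sex = "male"))
  expect_setequal(cands$model, c("hom_recessive", "x_linked_recessive"))
  # the same AFs fail the dominant arm
  dom <- tibble::tibble(kid_gt = "het", dad_gt = "hom_ref",
                        mum_gt = "hom_ref", af = 0.02, gene = "G1")
  expect_equal(nrow(run_hippo(make_trio_cohort(dom))), 0)
})

test_that("compound-het members are emitted with partners and recessive AF caps", {
  rows <- tibble::tibble(
    kid_gt = c("het", "het"),
    dad_gt = c("het", "hom_ref"),
    mum_gt = c("hom_ref", "het"),
    af = c(0.01, 0.001),
    gene = "G1"
  )
  cands <- run_hippo(make_trio_cohort(rows))
  expect_equal(nrow(cands), 2)
  expect_setequal(cands$model, "comp_het_member")
  expect_equal(sort(cands$partner_key), sort(cands$key))
  # cis pair (both paternal) yields nothing
  cis <- rows
  cis$dad_gt <- c("het", "het")
  cis$mum_gt <- "hom_ref"
  expect_equal(nrow(run_hippo(make_trio_cohort(cis))), 0)
})

test_that("every candidate carries every rule exactly once in its trace", {
  fx <- table4_fixture()
  cands <- run_hippo(fx$cohort)
  rules <- c("inheritance", "af_population", "af_cohort", "variant_type",
             "cadd", "spliceai", "clinvar", "genotype_quality",
             "allele_balance")
  for (tr in cands$rule_trace) {
    parts <- sub("=.*", "", strsplit(tr, ";")[[1]])
    expect_equal(sort(parts), sort(rules))
  }
  expect_false(any(grepl("=fail", cands$rule_trace)))
})

test_that("GenCC restriction is a relabelled subset", {
  fx <- table4_fixture()
  cands <- run_hippo(fx$cohort)
  sub <- restrict_to_gencc(cands, fx$gencc)
  expect_true(all(sub$key %in% cands$key))
  expect_setequal(unique(sub$strategy), "hippo_gencc")
  expect_setequal(unique(sub$gene),
                  c("PPP1CB", "CHAMP1", "ABCC8", "SDCCAG8", "INTS1"))
  # moderate validity does not qualify
  gencc2 <- tibble::tibble(gene = "HMGB1", validity = "moderate")
  expect_equal(nrow(restrict_to_gencc(cands, gencc2)), 0)
})

test_that("exclusion criteria fire only on explicit evidence, default open", {
  fx <- table4_fixture()
  cands <- run_hippo(fx$cohort)
  out <- apply_exclusion_criteria(cands, fx$evidence, fx$gencc)
  expect_true(all(out$reportable))

  # LoF curated not-LoF excludes a stop-gain
  ev <- fx$evidence
  ev$lof_curation[ev$variant_key == "19:23361341:G:C"] <- "not_LoF"
  out2 <- apply_exclusion_criteria(cands, ev, fx$gencc)
  expect_false(out2$reportable[out2$key == "19:23361341:G:C"])
  expect_match(out2$excluded_by[out2$key == "19:23361341:G:C"], "lof_curation")

  # IGV artefact excludes
  ev2 <- fx$evidence
  ev2$igv_artefact[ev2$variant_key == "9:77020700:A:G"] <- TRUE
  out3 <- apply_exclusion_criteria(cands, ev2, fx$gencc)
  expect_false(out3$reportable[out3$key == "9:77020700:A:G"])

  # orphan evidence row warns
  ev3 <- dplyr::add_row(fx$evidence, variant_key = "1:1:A:G",
                        lof_curation = "unknown")
  expect_warning(apply_exclusion_criteria(cands, ev3, fx$gencc), "no candidate")
})

test_that("phenotype-mismatch exclusion spares the pathogenic member of a pair", {
  fx <- table4_fixture()
  cands <- run_hippo(fx$cohort)
  ev <- fx$evidence
  sd_keys <- c("1:243341070:TG:T", "1:243378799:A:G")
  ev$phenotype_match[ev$variant_key %in% sd_keys] <- FALSE
  out <- apply_exclusion_criteria(cands, ev, fx$gencc)
  # P-classified frameshift kept by the ClinVar carve-out; VUS partner excluded
  expect_true(out$reportable[out$key == "1:243341070:TG:T"])
  expect_false(out$reportable[out$key == "1:243378799:A:G"])
  expect_match(out$excluded_by[out$key == "1:243378799:A:G"],
               "phenotype_mismatch")
})

test_that("single het in a recessive gene without a second hit is excluded", {
  rows <- tibble::tibble(
    kid_gt = "het", dad_gt = "het", mum_gt = "hom_ref",
    af = 1e-5, clinvar = "P", gene = "RECGENE"
  )
  cohort <- make_trio_cohort(rows)
  cands <- run_hippo(cohort)
  gencc <- tibble::tibble(gene = "RECGENE", validity = "definitive")
  ev <- evidence_defaults(cands$key)
  ev$second_hit_found <- FALSE
  out <- apply_exclusion_criteria(cands, ev, gencc)
  expect_false(out$reportable)
  # unknown flag never fires
  out_open <- apply_exclusion_criteria(cands, evidence_defaults(cands$key), gencc)
  expect_true(out_open$reportable)
})

test_that("cascade equals the straight-line predicate oracle on random cohorts", {
  for (seed in c(11, 12)) {
    res <- generate_cohort(cohort_spec(variants_per_family = 40, seed = seed))
    got <- run_hippo(res$cohort)[, c("family_id", "proband_id", "key")]
    want <- oracle_hippo(res$cohort)
    expect_equal(sorted_hits(got), sorted_hits(want), info = paste("seed", seed))
  }
})

test_that("cohort AF falls back to founder allele frequency when absent", {
  rows <- tibble::tibble(
    kid_gt = c("het", "het"),
    dad_gt = c("hom_ref", "het"),
    mum_gt = c("hom_ref", "hom_ref"),
    af = 0, gene = c("G1", "G2"), clinvar = c("none", "P")
  )
  cohort <- make_trio_cohort(rows)
  cohort$variants$cohort_af <- NA_real_
  af <- founder_cohort_af(cohort)
  # founders are dad and mum: variant 2 has 1 alt allele in 4
  expect_equal(af, c(0, 0.25))
  cands <- run_hippo(cohort)
  # 0.25 >= 0.01 cohort cap: the inherited pathogenic variant is excluded
  expect_equal(cands$key, cohort$variants$key[1])
})
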