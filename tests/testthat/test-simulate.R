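test_that("generation is byte-identical for a fixed seed", {
  spec <- cohort_spec(variants_per_family = 25, seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(spec, dir = d1)
  generate_cohort(spec, dir = d2)
  expect_identical(readLines(file.path(d1, "cohort.vcf")),
                   readLines(file.path(d2, "cohort.vcf")))
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
  # a different seed yields different data
  d3 <- withr::local_tempdir()
  generate_cohort(cohort_spec(variants_per_family = 25, seed = 4), dir = d3)
  expect_false(identical(readLines(file.path(d1, "cohort.vcf")),
                         readLines(file.path(d3, "cohort.vcf"))))
})

test_that("truth manifest is consistent with the emitted VCF and the cascade", {
  d <- withr::local_tempdir()
  res <- generate_cohort(cohort_spec(variants_per_family = 30, seed = 23),
                         dir = d)
  cohort <- read_cohort_vcf(file.path(d, "cohort.vcf"),
                            read_ped(file.path(d, "cohort.ped")))
  cands <- run_hippo(cohort)
  m <- res$manifest
  sat <- m[m$satisfies_hippo, c("family_id", "key")]
  hits <- dplyr::semi_join(sat, cands, by = c("family_id", "key"))
  # every manifest-satisfying variant is recovered from the on-disk cohort
  expect_equal(nrow(hits), nrow(sat))
  # every non-comp-het candidate of a manifest proband satisfies the manifest
  primary <- cands[cands$proband_id %in% m$proband_id &
                     cands$model != "comp_het_member", ]
  extra <- dplyr::anti_join(primary[, c("family_id", "key")], sat,
                            by = c("family_id", "key"))
  expect_equal(nrow(extra), 0)
})

test_that("background variants pass the cascade at under 5 percent", {
  res <- generate_cohort(cohort_spec(seed = 41))
  cands <- run_hippo(res$cohort)
  bg <- res$manifest[!res$manifest$planted, c("family_id", "key")]
  n_pass <- nrow(dplyr::semi_join(bg, cands, by = c("family_id", "key")))
  expect_lt(n_pass / nrow(bg), 0.05)
})

test_that("an X-linked plant in a female-proband family is fatal with explanation", {
  plants <- tibble::tibble(family = 2L, model = "x_linked", gene = "GX",
                           satisfies_hippo = TRUE, on_panel = FALSE)
  spec <- cohort_spec(variants_per_family = 5, planted = plants, seed = 1)
  expect_error(generate_cohort(spec), "not male")
})

test_that("an X-linked plant in a male proband is recovered as X-linked recessive", {
  plants <- tibble::tibble(family = 1L, model = "x_linked", gene = "GX",
                           satisfies_hippo = TRUE, on_panel = FALSE)
  res <- generate_cohort(cohort_spec(variants_per_family = 10,
                                     planted = plants, seed = 9))
  cands <- run_hippo(res$cohort)
  planted_key <- res$manifest$key[res$manifest$planted]
  hit <- cands[cands$key == planted_key, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$model, "x_linked_recessive")
})

test_that("planted models are recovered under their intended inheritance call", {
  plants <- tibble::tibble(
    family = c(1L, 2L, 3L, 5L),
    model = c("de_novo", "comp_het", "hom_recessive", "clinvar_inherited"),
    gene = c("G1", "G2", "G3", "G4"),
    satisfies_hippo = TRUE, on_panel = FALSE
  )
  res <- generate_cohort(cohort_spec(variants_per_family = 10,
                                     planted = plants, seed = 13))
  cands <- run_hippo(res$cohort)
  pm <- res$manifest[res$manifest$planted, ]
  got <- dplyr::inner_join(pm[, c("family_id", "key", "model_intended")],
                           cands[, c("family_id", "key", "model")],
                           by = c("family_id", "key"))
  expect_equal(nrow(got), nrow(pm))
  expect_equal(got$model[got$model_intended == "de_novo"], "de_novo")
  expect_equal(got$model[got$model_intended == "hom_recessive"],
               "hom_recessive")
  expect_setequal(got$model[got$model_intended == "comp_het"],
                  "comp_het_member")
  # the pathogenic inherited plant passes only through the override
  ci <- dplyr::left_join(pm[pm$model_intended == "clinvar_inherited",
                            c("family_id", "key")],
                         cands, by = c("family_id", "key"))
  expect_match(ci$rule_trace, "inheritance=overridden")
})

test_that("spec validation rejects malformed plant tables and missing seeds", {
  expect_error(cohort_spec(seed = NULL), "seed")
  expect_error(cohort_spec(), "seed")
  bad <- tibble::tibble(family = 1L, model = "magic", gene = "G",
                        satisfies_hippo = TRUE, on_panel = FALSE)
  expect_error(cohort_spec(planted = bad, seed = 1), "unknown planted model")
  far <- tibble::tibble(family = 99L, model = "de_novo", gene = "G",
                        satisfies_hippo = TRUE, on_panel = FALSE)
  expect_error(cohort_spec(planted = far, seed = 1), "exceeds")
})
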