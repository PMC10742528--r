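mk_trio <- function(kid, dad = NULL, mum = NULL, chrom = "autosome",
                    sex = "male", kid_gq = 99, dad_gq = 99, mum_gq = 99,
                    dad_aff = "no", mum_aff = "no") {
  trio_context(
    proband = list(gt = kid, gq = kid_gq, affected = "yes"),
    father = if (is.null(dad)) NULL else
      list(gt = dad, gq = dad_gq, affected = dad_aff),
    mother = if (is.null(mum)) NULL else
      list(gt = mum, gq = mum_gq, affected = mum_aff),
    chrom_class = chrom, proband_sex = sex
  )
}

test_that("single-variant inheritance models classify per the trio search rules", {
  cases <- list(
    # kid dad mum -> expected model, confirmed
    list(mk_trio("het", "hom_ref", "hom_ref"), "de_novo", TRUE),
    list(mk_trio("het", "hom_ref", "hom_ref", kid_gq = 30), "dominant_inherited", FALSE),
    list(mk_trio("het", "hom_ref", "hom_ref", mum_gq = 35), "dominant_inherited", FALSE),
    list(mk_trio("het", "hom_ref", NULL), "dominant_inherited", FALSE),
    list(mk_trio("het", NULL, NULL), "dominant_inherited", FALSE),
    list(mk_trio("hom_alt", "het", "het"), "hom_recessive", FALSE),
    list(mk_trio("hom_alt", "het", NULL), "hom_recessive", FALSE),
    list(mk_trio("hom_alt", "hom_ref", "het"), "none", FALSE),
    list(mk_trio("het", "het", "hom_ref"), "none", FALSE),
    list(mk_trio("het", "het", "hom_ref", dad_aff = "yes"), "dominant_inherited", FALSE),
    list(mk_trio("het", "het", "hom_ref", dad_aff = "unknown"), "dominant_inherited", FALSE),
    list(mk_trio("hemi", "hom_ref", "het", chrom = "chrX"), "x_linked_recessive", FALSE),
    list(mk_trio("hemi", "hom_ref", "hom_ref", chrom = "chrX"), "de_novo", TRUE),
    list(mk_trio("hemi", "hemi", "het", chrom = "chrX"), "none", FALSE),
    list(mk_trio("het", "hom_ref", "hom_ref", chrom = "MT"), "none", FALSE),
    list(mk_trio("het", "hom_ref", "hom_ref", chrom = "chrY"), "none", FALSE),
    list(mk_trio("hom_ref", "het", "het"), "none", FALSE)
  )
  for (i in seq_along(cases)) {
    got <- classify_single(cases[[i]][[1]], min_gq = 40)
    expect_equal(got$model, cases[[i]][[2]], info = paste("case", i))
    expect_equal(got$confirmed_de_novo, cases[[i]][[3]], info = paste("case", i))
  }
})

test_that("genotype-quality threshold is strict and min_gq = 0 disables it", {
  at_thresh <- mk_trio("het", "hom_ref", "hom_ref", kid_gq = 40)
  expect_equal(classify_single(at_thresh, min_gq = 40)$model,
               "dominant_inherited")
  zero_gq <- mk_trio("het", "hom_ref", "hom_ref",
                     kid_gq = 0, dad_gq = 0, mum_gq = 0)
  expect_equal(classify_single(zero_gq, min_gq = 0)$model, "de_novo")
  expect_true(classify_single(zero_gq, min_gq = 0)$confirmed_de_novo)
})

test_that("a confirmed de novo never arises with an absent or low-quality parent", {
  expect_false(classify_single(mk_trio("het", "hom_ref", NULL))$confirmed_de_novo)
  expect_false(classify_single(mk_trio("het", NULL, "hom_ref"))$confirmed_de_novo)
  expect_false(classify_single(
    mk_trio("het", "hom_ref", "hom_ref", dad_gq = 10))$confirmed_de_novo)
  expect_false(classify_single(
    mk_trio("het", "missing", "hom_ref"))$confirmed_de_novo)
})

test_that("unaffected carrier parent blocks dominant and sets the override hook", {
  got <- classify_single(mk_trio("het", "het", "hom_ref"))
  expect_equal(got$model, "none")
  expect_true(got$blocked_by_unaffected_carrier)
  # classification is pure: same input, same output
  expect_identical(got, classify_single(mk_trio("het", "het", "hom_ref")))
})

test_that("compound-het pairing keeps trans pairs and drops cis pairs", {
  gv <- tibble::tibble(
    key = c("1:1:A:G", "1:2:A:G"),
    proband_gt = "het",
    father_gt = c("het", "hom_ref"),
    mother_gt = c("hom_ref", "het")
  )
  pairs <- find_comp_het(gv)
  expect_equal(nrow(pairs), 1)
  expect_false(pairs$phase_unknown)

  cis <- gv
  cis$father_gt <- c("hom_ref", "hom_ref")
  cis$mother_gt <- c("het", "het")
  expect_equal(nrow(find_comp_het(cis)), 0)
})

test_that("two maternal and two paternal variants yield exactly the 4 trans pairs", {
  gv <- tibble::tibble(
    key = sprintf("1:%d:A:G", 1:4),
    proband_gt = "het",
    father_gt = c("het", "het", "hom_ref", "hom_ref"),
    mother_gt = c("hom_ref", "hom_ref", "het", "het")
  )
  pairs <- find_comp_het(gv)
  # exhaustive oracle: all 6 unordered pairs minus the 2 same-parent pairs
  all_pairs <- utils::combn(gv$key, 2, simplify = FALSE)
  orig <- ifelse(gv$father_gt == "het", "paternal", "maternal")
  names(orig) <- gv$key
  oracle <- Filter(function(p) orig[p[1]] != orig[p[2]], all_pairs)
  expect_equal(nrow(pairs), length(oracle))
  expect_equal(nrow(pairs), 4)
  got <- paste(pairs$key1, pairs$key2)
  want <- vapply(oracle, function(p) paste(sort(p), collapse = " "), "")
  expect_setequal(got, want)
})

test_that("an unsequenced parent yields phase-unknown pairs instead of dropping them", {
  gv <- tibble::tibble(
    key = c("1:1:A:G", "1:2:A:G"),
    proband_gt = "het",
    father_gt = NA_character_,
    mother_gt = c("het", "hom_ref")
  )
  pairs <- find_comp_het(gv)
  expect_equal(nrow(pairs), 1)
  expect_true(pairs$phase_unknown)
  # both attributable to the mother only -> provably cis even with absent father
  gv$mother_gt <- c("het", "het")
  expect_equal(nrow(find_comp_het(gv)), 0)
})

test_that("a pair fully carried by an unaffected member is suppressed", {
  gv <- tibble::tibble(
    key = c("1:1:A:G", "1:2:A:G"),
    proband_gt = "het",
    father_gt = c("het", "hom_ref"),
    mother_gt = c("hom_ref", "het")
  )
  ucar <- list("1:1:A:G" = "sibling", "1:2:A:G" = "sibling")
  expect_equal(nrow(find_comp_het(gv, unaffected_carriers = ucar)), 0)
  ucar_one <- list("1:1:A:G" = "sibling")
  expect_equal(nrow(find_comp_het(gv, unaffected_carriers = ucar_one)), 1)
})

test_that("pairing matches the exhaustive-pair oracle on random small genes", {
  set.seed(421)
  gts <- c("hom_ref", "het", "hom_alt")
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    both_parents <- stats::runif(1) < 0.7
    gv <- tibble::tibble(
      key = sprintf("1:%d:A:G", seq_len(n)),
      proband_gt = "het",
      father_gt = if (both_parents) sample(gts, n, TRUE) else NA_character_,
      mother_gt = sample(gts, n, TRUE)
    )
    got <- find_comp_het(gv)
    # independent oracle over all pairs
    origin <- vapply(seq_len(n), function(i) {
      f <- gv$father_gt[i]; m <- gv$mother_gt[i]
      fc <- !is.na(f) && f %in% c("het", "hom_alt")
      mc <- !is.na(m) && m %in% c("het", "hom_alt")
      if (fc && mc) "ambiguous" else if (mc) "maternal"
      else if (fc) "paternal" else if (is.na(f) || is.na(m)) "unknown"
      else "neither"
    }, "")
    want <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      o <- sort(c(origin[i], origin[j]))
      trans <- identical(o, c("maternal", "paternal"))
      maybe <- any(o == "unknown") &&
        !(origin[i] == origin[j] && origin[i] %in% c("maternal", "paternal"))
      if (trans || maybe) want <- want + 1L
    }
    expect_equal(nrow(got), want, info = paste("rep", rep))
  }
})
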