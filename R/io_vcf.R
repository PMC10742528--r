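# Annotated-VCF dialect
#
# INFO keys carried by the cohort VCFs this package reads and writes.  All
# population AF fields are floats in [0,1]; CLNSIG is one of
# P/LP/VUS/LB/B; CSQ_TERMS is a comma list of Sequence Ontology consequence
# terms; CSQ_DIST is the distance in bp to the nearest coding exon (0 for
# coding variants).  FORMAT is GT:AD:GQ.

.info_float_keys <- c("GNOMAD_EX_AF", "GNOMAD_WG_AF", "TOPMED_AF", "EXAC_AF",
                      "KG_AF", "COHORT_AF", "CADD_PHRED", "REVEL",
                      "SPLICEAI_DS", "EXOMISER_SCORE")
.info_int_keys <- c("EXOMISER_RANK", "CSQ_DIST")
.info_char_keys <- c("CLNSIG", "CSQ_GENE", "CSQ_TERMS")
.clnsig_levels <- c("P", "LP", "VUS", "LB", "B", "none")

.variant_af_cols <- c(
  GNOMAD_EX_AF = "af_gnomad_ex", GNOMAD_WG_AF = "af_gnomad_wg",
  TOPMED_AF = "af_topmed", EXAC_AF = "af_exac", KG_AF = "af_1kg"
)

#' Read a multi-sample annotated VCF into a trio cohort
#'
#' Loads a VCF v4.2 file whose INFO fields follow the package's annotation
#' dialect (population allele frequencies, cohort AF, CADD, REVEL, SpliceAI,
#' ClinVar classification, Exomiser rank/score, gene and consequence terms)
#' and whose FORMAT is `GT:AD:GQ`.  Multi-allelic records are decomposed into
#' one variant per alternate allele with AD fields re-indexed per alt; for
#' comma-separated (per-allele) INFO values the i-th element is taken for the
#' i-th alt, scalar values are shared.  Annotations absent from a record are
#' stored as `NA`, never as a numeric default.  An INFO value that fails to
#' parse raises a record-level warning and is stored as `NA`.
#'
#' @param path Path to the VCF file (plain or gzipped).
#' @param pedigree Pedigree tibble (see [read_ped()]); every pedigree sample
#'   must have a genotype column in the VCF, otherwise the read is fatal.
#' @return A `trio_cohort` object: a list with
#'   * `variants`: tibble keyed by `key` (`"chrom:pos:ref:alt"`) with columns
#'     `chrom`, `pos`, `ref`, `alt`, `gene`, `csq_terms` (comma string),
#'     `csq_dist`, the five population AF columns, `cohort_af`, `cadd`,
#'     `revel`, `spliceai`, `clinvar`, `exomiser_rank`, `exomiser_score`,
#'     `filter`;
#'   * `calls`: long tibble with `key`, `sample_id`, `gt` (`hom_ref`, `het`,
#'     `hom_alt`, `hemi`, `missing`), `ad_ref`, `ad_alt`, `gq`, `filter_pass`;
#'   * `samples`: character vector of sample ids;
#'   * `pedigree`: the pedigree passed in.
#' @export
read_cohort_vcf <- function(path, pedigree) {
  validate_pedigree(pedigree)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  missing_samples <- setdiff(pedigree$sample_id, samples)
  if (length(missing_samples) > 0) {
    stop("VCF lacks sample column(s) required by the pedigree: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }

  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    return(empty_cohort(samples, pedigree))
  }

  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec_idx <- rep(seq_len(n_rec), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  info_raw <- vcf@fix[, "INFO"]
  get_info <- function(key) {
    vals <- vcfR::extract.info(vcf, element = key)
    if (is.null(vals)) rep(NA_character_, n_rec) else vals
  }
  per_alt <- function(key, parse) {
    vals <- as.character(get_info(key))
    parts <- strsplit(vals, ",", fixed = TRUE)
    out <- vapply(seq_along(rec_idx), function(i) {
      p <- parts[[rec_idx[i]]]
      if (length(p) == 0 || all(is.na(p))) return(NA_character_)
      if (length(p) == 1) p else if (alt_idx[i] <= length(p)) p[alt_idx[i]] else NA_character_
    }, character(1))
    parse(out, key)
  }
  parse_num <- function(x, key) {
    suppressWarnings(v <- as.numeric(x))
    bad <- !is.na(x) & x != "." & is.na(v)
    if (any(bad)) {
      warning("unparseable INFO ", key, " in ", sum(bad),
              " record(s); stored as absent", call. = FALSE)
    }
    v
  }
  parse_int <- function(x, key) {
    v <- parse_num(x, key)
    as.integer(round(v))
  }
  parse_chr <- function(x, key) ifelse(x == ".", NA_character_, x)

  clin <- per_alt("CLNSIG", parse_chr)
  bad_clin <- !is.na(clin) & !(clin %in% .clnsig_levels)
  if (any(bad_clin)) {
    warning("unrecognised CLNSIG value(s); stored as 'none'", call. = FALSE)
    clin[bad_clin] <- NA_character_
  }
  clin[is.na(clin)] <- "none"

  variants <- tibble::tibble(
    chrom = fix[rec_idx, "CHROM"],
    pos = as.integer(fix[rec_idx, "POS"]),
    ref = fix[rec_idx, "REF"],
    alt = unlist(alt_list, use.names = FALSE),
    gene = per_alt("CSQ_GENE", parse_chr),
    csq_terms = per_alt("CSQ_TERMS", parse_chr),
    csq_dist = per_alt("CSQ_DIST", parse_int),
    af_gnomad_ex = per_alt("GNOMAD_EX_AF", parse_num),
    af_gnomad_wg = per_alt("GNOMAD_WG_AF", parse_num),
    af_topmed = per_alt("TOPMED_AF", parse_num),
    af_exac = per_alt("EXAC_AF", parse_num),
    af_1kg = per_alt("KG_AF", parse_num),
    cohort_af = per_alt("COHORT_AF", parse_num),
    cadd = per_alt("CADD_PHRED", parse_num),
    revel = per_alt("REVEL", parse_num),
    spliceai = per_alt("SPLICEAI_DS", parse_num),
    clinvar = clin,
    exomiser_rank = per_alt("EXOMISER_RANK", parse_int),
    exomiser_score = per_alt("EXOMISER_SCORE", parse_num),
    filter = fix[rec_idx, "FILTER"]
  )
  variants$csq_terms[is.na(variants$csq_terms)] <- ""
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  variants <- dplyr::relocate(variants, "key")

  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  ad_mat <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                     error = function(e) NULL)
  gq_mat <- tryCatch(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE),
                     error = function(e) NULL)
  filter_pass <- fix[, "FILTER"] %in% c("PASS", ".")

  calls <- purrr::map_dfr(samples, function(s) {
    gt_raw <- gt_mat[rec_idx, s]
    ad_raw <- if (is.null(ad_mat)) rep(NA_character_, length(rec_idx)) else ad_mat[rec_idx, s]
    ad_parts <- strsplit(ifelse(is.na(ad_raw), "", ad_raw), ",", fixed = TRUE)
    ad_ref <- vapply(ad_parts, function(p) {
      if (length(p) < 1) NA_integer_ else suppressWarnings(as.integer(p[1]))
    }, integer(1))
    ad_alt <- vapply(seq_along(ad_parts), function(i) {
      p <- ad_parts[[i]]
      j <- alt_idx[i] + 1L
      if (length(p) < j) NA_integer_ else suppressWarnings(as.integer(p[j]))
    }, integer(1))
    tibble::tibble(
      key = variants$key,
      sample_id = s,
      gt = unname(classify_gt(gt_raw, alt_idx)),
      ad_ref = unname(ad_ref),
      ad_alt = unname(ad_alt),
      gq = if (is.null(gq_mat)) NA_real_ else as.numeric(gq_mat[rec_idx, s]),
      filter_pass = filter_pass[rec_idx]
    )
  })

  new_trio_cohort(variants, calls, samples, pedigree)
}

# Map a raw GT string onto a per-alt genotype class.  For decomposed
# multi-allelic records an allele equal to the alt index counts as alt;
# all other alleles (including other alts) count as non-alt.
classify_gt <- function(gt_raw, alt_idx) {
  vapply(seq_along(gt_raw), function(i) {
    g <- gt_raw[i]
    if (is.na(g) || g == ".") return("missing")
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return("missing")
    n_alt <- sum(alleles == as.character(alt_idx[i]))
    if (length(alleles) == 1) {
      if (n_alt == 1) "hemi" else "hom_ref"
    } else if (n_alt >= 2) {
      "hom_alt"
    } else if (n_alt == 1) {
      "het"
    } else {
      "hom_ref"
    }
  }, character(1))
}

new_trio_cohort <- function(variants, calls, samples, pedigree) {
  structure(
    list(variants = variants, calls = calls, samples = samples,
         pedigree = pedigree),
    class = "trio_cohort"
  )
}

empty_cohort <- function(samples, pedigree) {
  variants <- tibble::tibble(
    key = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    csq_terms = character(), csq_dist = integer(),
    af_gnomad_ex = numeric(), af_gnomad_wg = numeric(),
    af_topmed = numeric(), af_exac = numeric(), af_1kg = numeric(),
    cohort_af = numeric(), cadd = numeric(), revel = numeric(),
    spliceai = numeric(), clinvar = character(),
    exomiser_rank = integer(), exomiser_score = numeric(),
    filter = character()
  )
  calls <- tibble::tibble(
    key = character(), sample_id = character(), gt = character(),
    ad_ref = integer(), ad_alt = integer(), gq = numeric(),
    filter_pass = logical()
  )
  new_trio_cohort(variants, calls, samples, pedigree)
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("<trio_cohort>", nrow(x$variants), "variants,",
      length(x$samples), "samples,",
      length(unique(x$pedigree$family_id)), "families\n")
  invisible(x)
}

#' Build a variant key
#'
#' The canonical `"chrom:pos:ref:alt"` identifier used throughout candidate
#' tables, evidence files and truth manifests.
#'
#' @param chrom,pos,ref,alt Variant coordinates (1-based, VCF convention).
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Write a trio cohort to a VCF v4.2 text file
#'
#' Emits the package's annotation dialect: one biallelic record per variant,
#' INFO fields for every non-missing annotation, and `GT:AD:GQ` genotype
#' columns for every sample.  Records are sorted by chromosome (1..22, X, Y,
#' MT) and position.
#'
#' @param cohort A `trio_cohort` (or a list with `variants`, `calls`,
#'   `samples`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  variants <- dplyr::arrange(cohort$variants, chrom_order(.data$chrom),
                             .data$pos, .data$ref, .data$alt)
  calls <- cohort$calls
  samples <- cohort$samples

  fmt_num <- function(x) ifelse(is.na(x), NA_character_,
                                formatC(x, format = "g", digits = 7))
  info_field <- function(key, val) {
    ifelse(is.na(val) | val == "", NA_character_, paste0(key, "=", val))
  }
  info <- cbind(
    info_field("CSQ_GENE", variants$gene),
    info_field("CSQ_TERMS", variants$csq_terms),
    info_field("CSQ_DIST", as.character(variants$csq_dist)),
    info_field("GNOMAD_EX_AF", fmt_num(variants$af_gnomad_ex)),
    info_field("GNOMAD_WG_AF", fmt_num(variants$af_gnomad_wg)),
    info_field("TOPMED_AF", fmt_num(variants$af_topmed)),
    info_field("EXAC_AF", fmt_num(variants$af_exac)),
    info_field("KG_AF", fmt_num(variants$af_1kg)),
    info_field("COHORT_AF", fmt_num(variants$cohort_af)),
    info_field("CADD_PHRED", fmt_num(variants$cadd)),
    info_field("REVEL", fmt_num(variants$revel)),
    info_field("SPLICEAI_DS", fmt_num(variants$spliceai)),
    info_field("CLNSIG", ifelse(variants$clinvar == "none", NA_character_,
                                variants$clinvar)),
    info_field("EXOMISER_RANK", as.character(variants$exomiser_rank)),
    info_field("EXOMISER_SCORE", fmt_num(variants$exomiser_score))
  )
  info_str <- apply(info, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) "." else paste(r, collapse = ";")
  })

  gt_string <- function(gt, ad_ref, ad_alt, gq) {
    g <- dplyr::case_match(gt, "hom_ref" ~ "0/0", "het" ~ "0/1",
                           "hom_alt" ~ "1/1", "hemi" ~ "1", .default = "./.")
    ad <- ifelse(is.na(ad_ref) | is.na(ad_alt), ".",
                 paste0(ad_ref, ",", ad_alt))
    gqs <- ifelse(is.na(gq), ".", as.character(gq))
    paste(g, ad, gqs, sep = ":")
  }
  call_wide <- calls |>
    dplyr::mutate(cell = gt_string(.data$gt, .data$ad_ref, .data$ad_alt,
                                   .data$gq)) |>
    dplyr::select("key", "sample_id", "cell") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cell")
  call_wide <- call_wide[match(variants$key, call_wide$key), , drop = FALSE]
  sample_cells <- as.matrix(call_wide[, samples, drop = FALSE])
  sample_cells[is.na(sample_cells)] <- "./.:.:."

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            .info_float_keys, .info_float_keys),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"%s\">",
            .info_int_keys, .info_int_keys),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
            .info_char_keys, .info_char_keys),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", variants$filter, info_str, "GT:AD:GQ",
                apply(sample_cells, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Chromosome sort order (1..22, X, Y, MT, then others)
#' @param chrom Character vector of chromosome names (with or without "chr").
#' @return Integer rank usable in `dplyr::arrange()`.
#' @keywords internal
chrom_order <- function(chrom) {
  c <- sub("^chr", "", chrom)
  n <- suppressWarnings(as.integer(c))
  rank <- ifelse(!is.na(n), n,
                 dplyr::case_match(c, "X" ~ 23L, "Y" ~ 24L,
                                   c("MT", "M") ~ 25L, .default = 26L))
  rank
}

#' Chromosome class for inheritance modelling
#' @param chrom Chromosome name.
#' @return One of `"autosome"`, `"chrX"`, `"chrY"`, `"MT"`.
#' @export
chrom_class <- function(chrom) {
  c <- sub("^chr", "", chrom)
  dplyr::case_match(c, "X" ~ "chrX", "Y" ~ "chrY", c("MT", "M") ~ "MT",
                    .default = "autosome")
}
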