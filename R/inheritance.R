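#' Construct a trio context for one variant site
#'
#' Bundles the proband call, the (possibly absent) parental calls, the
#' proband's sex and the chromosome class so [classify_single()] is a pure
#' function of one value.  A parent that was not sequenced, or whose genotype
#' at this site is missing (`./.`), is represented as `NULL`: transmission
#' cannot be confirmed through an uncalled parent.
#'
#' @param proband,father,mother Named lists with elements `gt` (one of
#'   `hom_ref`, `het`, `hom_alt`, `hemi`, `missing`), `gq` (numeric or `NA`)
#'   and `affected` (`"yes"`, `"no"`, `"unknown"`); `father`/`mother` may be
#'   `NULL`.
#' @param chrom_class `"autosome"`, `"chrX"`, `"chrY"` or `"MT"`.
#' @param proband_sex `"male"`, `"female"` or `"unknown"`.
#' @return A list of class `trio_context`.
#' @export
trio_context <- function(proband, father = NULL, mother = NULL,
                         chrom_class = "autosome", proband_sex = "unknown") {
  norm <- function(x) {
    if (is.null(x) || is.na(x$gt) || x$gt == "missing") return(NULL)
    list(gt = x$gt, gq = x$gq %||% NA_real_,
         affected = x$affected %||% "no")
  }
  structure(
    list(proband = list(gt = proband$gt, gq = proband$gq %||% NA_real_,
                        affected = proband$affected %||% "yes"),
         father = norm(father), mother = norm(mother),
         chrom_class = chrom_class, proband_sex = proband_sex),
    class = "trio_context"
  )
}

meets_gq <- function(gq, min_gq) {
  if (min_gq <= 0) return(TRUE)
  !is.na(gq) && gq > min_gq
}

is_carrier <- function(gt) gt %in% c("het", "hom_alt", "hemi")

#' Classify the inheritance model of a single variant in a trio
#'
#' Pure classification of one proband call against the available parental
#' calls:
#' * `de_novo`: proband het (or hemizygous on chrX in a male), both parents
#'   present and homozygous reference, and all three calls exceed `min_gq`
#'   (`min_gq = 0` disables the quality requirement, the behaviour of the
#'   gene-agnostic de novo search which is not filtered on quality);
#' * `x_linked_recessive`: chrX, male proband hemizygous (or called hom alt),
#'   mother het, father not a carrier;
#' * `hom_recessive`: proband homozygous alt and every *present* parent het;
#' * `dominant_inherited`: proband het and no present unaffected parent
#'   carries the allele (a carrier parent who is affected or of unknown
#'   status, or an absent parent, does not block the call);
#' * `none` otherwise, including any variant on chrY or the mitochondrial
#'   genome.  A pathogenic-in-ClinVar rescue of variants carried by
#'   unaffected parents is applied downstream by [run_hippo()], never here.
#'
#' `confirmed_de_novo` is `TRUE` only for the `de_novo` model, which requires
#' both parents called hom ref above `min_gq`.
#'
#' @param trio A [trio_context()].
#' @param min_gq Genotype-quality threshold (strict `>`); 0 disables.
#' @return List with `model`, `confirmed_de_novo`, and
#'   `blocked_by_unaffected_carrier` (`TRUE` when the only reason a het call
#'   is not dominant is a carrier unaffected parent; the hook for the ClinVar
#'   override).
#' @export
classify_single <- function(trio, min_gq = 40) {
  none <- list(model = "none", confirmed_de_novo = FALSE,
               blocked_by_unaffected_carrier = FALSE)
  p <- trio$proband
  if (is.null(p) || is.na(p$gt) || p$gt %in% c("missing", "hom_ref")) return(none)
  if (trio$chrom_class %in% c("chrY", "MT")) return(none)

  fa <- trio$father
  mo <- trio$mother
  male_x <- trio$chrom_class == "chrX" && trio$proband_sex == "male"
  het_like <- p$gt == "het" || (male_x && p$gt == "hemi")

  # de novo: both parents present, hom ref, all three calls meet min_gq
  if (het_like && !is.null(fa) && !is.null(mo) &&
      fa$gt == "hom_ref" && mo$gt == "hom_ref" &&
      meets_gq(p$gq, min_gq) && meets_gq(fa$gq, min_gq) && meets_gq(mo$gq, min_gq)) {
    return(list(model = "de_novo", confirmed_de_novo = TRUE,
                blocked_by_unaffected_carrier = FALSE))
  }

  # X-linked recessive: male hemizygous, mother het, father non-carrier
  if (male_x && p$gt %in% c("hemi", "hom_alt") &&
      !is.null(mo) && mo$gt == "het" &&
      (is.null(fa) || !is_carrier(fa$gt))) {
    return(list(model = "x_linked_recessive", confirmed_de_novo = FALSE,
                blocked_by_unaffected_carrier = FALSE))
  }

  # homozygous recessive: each present parent must be het
  if (p$gt == "hom_alt" &&
      (is.null(fa) || fa$gt == "het") && (is.null(mo) || mo$gt == "het")) {
    return(list(model = "hom_recessive", confirmed_de_novo = FALSE,
                blocked_by_unaffected_carrier = FALSE))
  }

  # dominant: no present unaffected parent carries the allele
  if (p$gt == "het" || (male_x && p$gt == "hemi")) {
    blocking <- function(par) {
      !is.null(par) && is_carrier(par$gt) && par$affected == "no"
    }
    if (!blocking(fa) && !blocking(mo)) {
      return(list(model = "dominant_inherited", confirmed_de_novo = FALSE,
                  blocked_by_unaffected_carrier = FALSE))
    }
    return(list(model = "none", confirmed_de_novo = FALSE,
                blocked_by_unaffected_carrier = TRUE))
  }
  none
}

#' Find compound-heterozygous pairs among the proband-het variants of a gene
#'
#' A pair is in trans when one allele is attributable to the mother only and
#' the other to the father only.  With both parents sequenced, only definite
#' maternal x paternal pairs are returned (`phase_unknown = FALSE`).  With an
#' absent parent, a variant not seen in the sequenced parent has unknown
#' origin; pairs involving such variants cannot be phased and are returned
#' with `phase_unknown = TRUE` unless the two variants are provably on the
#' same parental haplotype (both carried by the same single parent).  A pair
#' is suppressed when any unaffected family member listed in
#' `unaffected_carriers` carries both alleles.
#'
#' @param gene_variants Tibble with one row per proband-het variant of one
#'   gene: columns `key`, `proband_gt`, `father_gt`, `mother_gt` (genotype
#'   strings; `NA` = parent absent or uncalled at the site).
#' @param unaffected_carriers Optional named list mapping `key` to the
#'   character vector of unaffected carrier sample ids for that variant.
#' @return Tibble with columns `key1`, `key2` (`key1 < key2`),
#'   `phase_unknown`.
#' @export
find_comp_het <- function(gene_variants, unaffected_carriers = NULL) {
  empty <- tibble::tibble(key1 = character(), key2 = character(),
                          phase_unknown = logical())
  gv <- gene_variants[gene_variants$proband_gt == "het", , drop = FALSE]
  if (nrow(gv) < 2) return(empty)

  origin <- vapply(seq_len(nrow(gv)), function(i) {
    fg <- gv$father_gt[i]
    mg <- gv$mother_gt[i]
    f_abs <- is.na(fg) || fg == "missing"
    m_abs <- is.na(mg) || mg == "missing"
    f_car <- !f_abs && is_carrier(fg)
    m_car <- !m_abs && is_carrier(mg)
    if (f_car && m_car) return("ambiguous")
    if (m_car) return("maternal")
    if (f_car) return("paternal")
    if (f_abs || m_abs) return("unknown")   # could come from the uncalled parent
    "neither"                               # both parents called hom ref
  }, character(1))

  pairs <- utils::combn(seq_len(nrow(gv)), 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(ix) {
    o1 <- origin[ix[1]]; o2 <- origin[ix[2]]
    keep <- FALSE; unknown <- FALSE
    if ((o1 == "maternal" && o2 == "paternal") ||
        (o1 == "paternal" && o2 == "maternal")) {
      keep <- TRUE
    } else if (o1 == "unknown" || o2 == "unknown") {
      # phase cannot exclude cis unless both alleles sit in the same parent
      same_parent <- o1 == o2 && o1 %in% c("maternal", "paternal")
      if (!same_parent) {
        keep <- TRUE; unknown <- TRUE
      }
    }
    if (!keep) return(NULL)
    k <- sort(c(gv$key[ix[1]], gv$key[ix[2]]))
    if (!is.null(unaffected_carriers)) {
      both <- intersect(unaffected_carriers[[k[1]]] %||% character(),
                        unaffected_carriers[[k[2]]] %||% character())
      if (length(both) > 0) return(NULL)
    }
    tibble::tibble(key1 = k[1], key2 = k[2], phase_unknown = unknown)
  })
  if (nrow(out) == 0) empty else dplyr::arrange(out, .data$key1, .data$key2)
}
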