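.gencc_levels <- c("definitive", "strong", "moderate", "limited",
                   "disputed", "refuted", "other")
.panel_ratings <- c("green", "amber", "red")
.lof_levels <- c("LoF", "likely_LoF", "likely_not_LoF", "not_LoF", "unknown")

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  na = c("", "NA"))
}

require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read a GenCC gene-validity table
#'
#' Tab-separated with header columns `gene` and `validity`; validity must be
#' one of definitive, strong, moderate, limited, disputed, refuted, other.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene` (whitespace-stripped) and `validity`.
#' @export
read_gencc <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(.default = readr::col_character()))
  require_cols(df, c("gene", "validity"), "GenCC")
  df <- tibble::tibble(gene = trimws(df$gene), validity = trimws(df$validity))
  if (any(df$gene == "" | is.na(df$gene))) {
    stop("GenCC file contains empty gene symbols", call. = FALSE)
  }
  bad <- setdiff(unique(df$validity), .gencc_levels)
  if (length(bad) > 0) {
    stop("unrecognised GenCC validity value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::distinct(df)
}

#' Read a panel gene list
#'
#' Tab-separated with header columns `panel_id`, `gene`, `rating`
#' (green/amber/red, the PanelApp confidence colours).
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `panel_id`, `gene`, `rating`.
#' @export
read_panels <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(.default = readr::col_character()))
  require_cols(df, c("panel_id", "gene", "rating"), "panel")
  df <- tibble::tibble(panel_id = trimws(df$panel_id),
                       gene = trimws(df$gene),
                       rating = trimws(df$rating))
  bad <- setdiff(unique(df$rating), .panel_ratings)
  if (length(bad) > 0) {
    stop("unrecognised panel rating value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::distinct(df)
}

#' Read curator evidence flags used by the reportability engine
#'
#' Tab-separated with header: `variant_key` plus the six flag columns
#' `second_hit_found`, `phenotype_match`, `tissue_expression_ok`,
#' `pathway_plausible` (logical or `unknown`), `lof_curation`
#' (LoF/likely_LoF/likely_not_LoF/not_LoF/unknown) and `igv_artefact`.
#' `unknown` (or an empty cell) is the default for every field and is stored
#' as `NA`; an unknown flag never fires an exclusion rule.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `variant_key`, four logical flag columns,
#'   `lof_curation`, `igv_artefact`.
#' @export
read_evidence <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(.default = readr::col_character()))
  require_cols(df, c("variant_key", "second_hit_found", "phenotype_match",
                     "tissue_expression_ok", "pathway_plausible",
                     "lof_curation", "igv_artefact"), "evidence")
  as_flag <- function(x) {
    x <- tolower(trimws(x))
    dplyr::case_match(x, c("true", "t", "yes", "1") ~ TRUE,
                      c("false", "f", "no", "0") ~ FALSE,
                      .default = NA)
  }
  lof <- trimws(df$lof_curation)
  lof[is.na(lof) | lof == "" | !(lof %in% .lof_levels)] <- "unknown"
  tibble::tibble(
    variant_key = trimws(df$variant_key),
    second_hit_found = as_flag(df$second_hit_found),
    phenotype_match = as_flag(df$phenotype_match),
    tissue_expression_ok = as_flag(df$tissue_expression_ok),
    pathway_plausible = as_flag(df$pathway_plausible),
    lof_curation = lof,
    igv_artefact = as_flag(df$igv_artefact)
  )
}

#' All-unknown evidence flags for a set of variant keys
#'
#' Convenience constructor for the default (open) state of the reportability
#' engine: every flag unknown, so no exclusion rule can fire.
#'
#' @param keys Character vector of variant keys (may be empty).
#' @return Evidence tibble with the [read_evidence()] schema.
#' @export
evidence_defaults <- function(keys = character()) {
  tibble::tibble(
    variant_key = as.character(keys),
    second_hit_found = NA,
    phenotype_match = NA,
    tissue_expression_ok = NA,
    pathway_plausible = NA,
    lof_curation = "unknown",
    igv_artefact = NA
  )
}

#' Write curator evidence flags to TSV
#' @param evidence Evidence tibble ([read_evidence()] schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  out <- evidence
  for (col in c("second_hit_found", "phenotype_match",
                "tissue_expression_ok", "pathway_plausible",
                "igv_artefact")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "unknown",
                         ifelse(out[[col]], "true", "false"))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write candidate variants to a TSV file
#'
#' Deterministic column order; the per-rule provenance is serialised into a
#' single `rule_trace` column (`rule=outcome` pairs joined with `;`) so the
#' table round-trips through [read_candidates()].
#'
#' @param candidates Candidate tibble as produced by [run_hippo()] or
#'   [run_gms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  readr::write_tsv(candidates, path, progress = FALSE)
  invisible(path)
}

#' Read a candidate TSV written by [write_candidates()]
#' @param path Path to the TSV file.
#' @return Candidate tibble.
#' @export
read_candidates <- function(path) {
  spec <- readr::cols(
    key = readr::col_character(), chrom = readr::col_character(),
    ref = readr::col_character(), alt = readr::col_character(),
    pos = readr::col_integer(),
    family_id = readr::col_character(), proband_id = readr::col_character(),
    gene = readr::col_character(), csq_terms = readr::col_character(),
    model = readr::col_character(), partner_key = readr::col_character(),
    clinvar = readr::col_character(), strategy = readr::col_character(),
    rule_trace = readr::col_character(), tier = readr::col_character(),
    phase_unknown = readr::col_logical(),
    confirmed_de_novo = readr::col_logical(),
    reportable = readr::col_logical(), diagnostic = readr::col_logical(),
    max_pop_af = readr::col_double(), cohort_af = readr::col_double(),
    cadd = readr::col_double(), revel = readr::col_double(),
    spliceai = readr::col_double(), exomiser_score = readr::col_double(),
    exomiser_rank = readr::col_integer(),
    .default = readr::col_guess()
  )
  readr::read_tsv(path, col_types = spec, progress = FALSE,
                  na = c("", "NA"))
}

#' Serialise a comparison report
#'
#' `format = "json"` writes the whole report (per-family counts, totals,
#' rates, test results); `format = "tsv"` writes the per-family counts table
#' only.  Both round-trip deterministically.
#'
#' @param report A `hippo_comparison` object from [build_report()].
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(report$per_family, path, progress = FALSE)
  } else {
    out <- list(
      per_family = report$per_family,
      excluded_families = report$excluded_families,
      totals = report$totals,
      rates = report$rates,
      wilcoxon = report$wilcoxon,
      fisher = report$fisher
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read back a JSON comparison report
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A `hippo_comparison` object.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$per_family <- tibble::as_tibble(raw$per_family)
  raw$rates <- tibble::as_tibble(raw$rates)
  raw$excluded_families <- as.character(raw$excluded_families %||% character())
  structure(raw, class = "hippo_comparison")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
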