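#' Rate per variant assessed, in percent
#'
#' The efficiency metric used to contrast the two strategies: the number of
#' diagnostic (or reportable) variants divided by the number of variants a
#' laboratory had to assess, times 100.
#'
#' @param numerator Count of diagnostic/reportable variants.
#' @param n_assessed Count of variants assessed (must be > 0 for a defined
#'   rate; 0 yields `NA` with a warning).
#' @return Percentage (numeric).
#' @export
rate_per_assessed <- function(numerator, n_assessed) {
  out <- ifelse(n_assessed > 0, 100 * numerator / n_assessed, NA_real_)
  if (any(n_assessed == 0)) {
    warning("rate undefined for zero variants assessed", call. = FALSE)
  }
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired counts.  Zero differences are dropped.  Method
#' `"exact"` enumerates all `2^n` sign assignments of the absolute
#' differences (average ranks for ties), so it remains exact in the presence
#' of ties; `"normal_cc"` uses the normal approximation with tie-corrected
#' variance and continuity correction; `"auto"` (default) selects `exact`
#' unless ties are present among the absolute differences or n exceeds 20,
#' mirroring common statistics-package behaviour.
#'
#' @param a,b Paired numeric vectors (differences `a - b` are tested).
#' @param method `"auto"`, `"exact"` or `"normal_cc"`.
#' @return List with `statistic` (V, the positive-rank sum of `a - b`), `p_value`,
#'   `method` actually used and `n` (non-zero differences used).
#' @export
wilcoxon_signed_rank <- function(a, b, method = c("auto", "exact", "normal_cc")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all differences are zero: test undefined", call. = FALSE)
  }
  if (n < 2) {
    warning("fewer than 2 non-zero differences", call. = FALSE)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (method == "auto") {
    method <- if (!has_ties && n <= 20) "exact" else "normal_cc"
  }
  if (method == "exact") {
    if (n > 20) stop("exact enumeration limited to n <= 20", call. = FALSE)
    # distribution of V over all 2^n sign assignments; symmetric about mu
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.numeric(signs %*% r)
    mu <- sum(r) / 2
    p <- mean(abs(v_all - mu) >= abs(v - mu) - 1e-9)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = v, p_value = p, method = method, n = n)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables (with the observed
#' margins) whose probability does not exceed that of the observed table.
#' A degenerate margin yields p = 1.
#'
#' @param a,b,c,d Cell counts, row-wise: `(a, b)` on top, `(c, d)` below.
#' @return List with `p_value` and the `table` tested.
#' @export
fisher_exact <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  if (row1 == 0 || row2 == 0 || col1 == 0 || b + d == 0) {
    return(list(p_value = 1, table = tab))
  }
  support <- max(0, col1 - row2):min(row1, col1)
  probs <- stats::dhyper(support, row1, row2, col1)
  p_obs <- stats::dhyper(a, row1, row2, col1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p), table = tab)
}

#' Per-family candidate counts for the strategy comparison
#'
#' Aggregates candidate tables from the three strategies into the per-family
#' counts the comparison report consumes.  `truth` supplies the diagnostic
#' labels (clinical causality is an input, never computed): a tibble with
#' `family_id`, `key` and logical `diagnostic`.  Reportable counts are taken
#' from each candidate table's `reportable` column (`NA` counts as not
#' reportable).  A family present in `truth` but absent from the candidates
#' is counted as zero with a warning.
#'
#' @param hippo_cands,gencc_cands,gms_cands Candidate tibbles (the GenCC
#'   table may be `NULL` if the restriction was not run).
#' @param truth Diagnostic truth tibble, or `NULL` for all-zero diagnostic
#'   counts.
#' @return Tibble with one row per family: assessed, diagnostic and
#'   reportable counts per strategy.
#' @export
family_counts <- function(hippo_cands, gencc_cands = NULL, gms_cands = NULL,
                          truth = NULL) {
  count_one <- function(cands, suffix) {
    if (is.null(cands) || nrow(cands) == 0) {
      return(tibble::tibble(family_id = character(),
                            "{paste0('n_assessed_', suffix)}" := integer(),
                            "{paste0('n_diagnostic_', suffix)}" := integer(),
                            "{paste0('n_reportable_', suffix)}" := integer()))
    }
    cc <- cands
    if (!is.null(truth)) {
      cc <- dplyr::left_join(
        dplyr::select(cc, -"diagnostic"),
        dplyr::select(truth, "family_id", "key", "diagnostic"),
        by = c("family_id", "key"))
    }
    cc$diagnostic[is.na(cc$diagnostic)] <- FALSE
    cc$reportable[is.na(cc$reportable)] <- FALSE
    cc |>
      dplyr::summarise(
        "{paste0('n_assessed_', suffix)}" := dplyr::n(),
        "{paste0('n_diagnostic_', suffix)}" := sum(.data$diagnostic),
        "{paste0('n_reportable_', suffix)}" := sum(.data$reportable),
        .by = "family_id")
  }
  out <- count_one(hippo_cands, "hippo")
  out <- dplyr::full_join(out, count_one(gencc_cands, "hippo_gencc"),
                          by = "family_id")
  out <- dplyr::full_join(out, count_one(gms_cands, "gms"), by = "family_id")
  if (!is.null(truth)) {
    missing_fams <- setdiff(unique(truth$family_id), out$family_id)
    if (length(missing_fams) > 0) {
      warning("family in truth but not in candidates: ",
              paste(missing_fams, collapse = ", "), call. = FALSE)
    }
  }
  out[is.na(out)] <- 0L
  dplyr::arrange(out, .data$family_id)
}

#' Build the strategy-comparison report
#'
#' From per-family counts, computes cohort totals over the non-excluded
#' families, the diagnostic and reportable rates per variant assessed for
#' each strategy, paired Wilcoxon signed-rank tests on the per-family
#' assessed counts (GenCC-restricted vs panel-based, and all-genes vs
#' panel-based), and Fisher's exact tests contrasting the diagnostic yields.
#' Fisher tables pair diagnoses with assessed totals per strategy.
#'
#' The reportable numerator for the GenCC-restricted strategy is the
#' reportable count of the unrestricted strategy: the reportability review is
#' applied to all candidates independent of gene-validity status, and its
#' yield is related to the smaller GenCC-restricted assessment burden.
#'
#' @param counts Per-family counts tibble (see [family_counts()]; the
#'   [table3_counts()] fixture has the same schema).  Optional columns
#'   `n_hpo_research`/`n_hpo_clinical` add a phenotype-term Wilcoxon.
#' @param exclude Character vector of family ids excluded from all totals
#'   and tests.
#' @param wilcoxon_method Method passed to [wilcoxon_signed_rank()].
#' @return Object of class `hippo_comparison`: `per_family`,
#'   `excluded_families`, `totals`, `rates` (tibble), `wilcoxon`, `fisher`.
#' @export
build_report <- function(counts, exclude = character(),
                         wilcoxon_method = "auto") {
  stopifnot(is.data.frame(counts), "family_id" %in% names(counts))
  need <- c("n_assessed_hippo", "n_assessed_hippo_gencc", "n_assessed_gms",
            "n_diagnostic_hippo", "n_diagnostic_hippo_gencc",
            "n_diagnostic_gms", "n_reportable_hippo", "n_reportable_gms")
  for (col in setdiff(need, names(counts))) counts[[col]] <- 0L
  kept <- counts[!(counts$family_id %in% exclude), , drop = FALSE]

  tot <- function(col) sum(kept[[col]])
  totals <- tibble::tibble(
    strategy = c("hippo", "hippo_gencc", "gms"),
    n_assessed = c(tot("n_assessed_hippo"), tot("n_assessed_hippo_gencc"),
                   tot("n_assessed_gms")),
    n_diagnostic = c(tot("n_diagnostic_hippo"),
                     tot("n_diagnostic_hippo_gencc"), tot("n_diagnostic_gms")),
    n_reportable = c(tot("n_reportable_hippo"), tot("n_reportable_hippo"),
                     tot("n_reportable_gms"))
  )
  rates <- totals |>
    dplyr::mutate(
      diagnostic_rate_pct = ifelse(.data$n_assessed > 0,
                                   100 * .data$n_diagnostic / .data$n_assessed,
                                   NA_real_),
      reportable_rate_pct = ifelse(.data$n_assessed > 0,
                                   100 * .data$n_reportable / .data$n_assessed,
                                   NA_real_)
    )

  run_wilcox <- function(x, y) {
    if (nrow(kept) < 2 || all(x == y)) return(NULL)
    wilcoxon_signed_rank(x, y, method = wilcoxon_method)
  }
  wilcoxon <- list(
    gencc_vs_gms = run_wilcox(kept$n_assessed_hippo_gencc, kept$n_assessed_gms),
    hippo_vs_gms = run_wilcox(kept$n_assessed_hippo, kept$n_assessed_gms)
  )
  if (all(c("n_hpo_research", "n_hpo_clinical") %in% names(counts))) {
    wilcoxon$hpo <- run_wilcox(kept$n_hpo_research, kept$n_hpo_clinical)
  }

  run_fisher <- function(d1, a1, d2, a2) {
    if (a1 == 0 || a2 == 0) return(NULL)
    fisher_exact(d1, a1, d2, a2)
  }
  fisher <- list(
    gencc_vs_gms = run_fisher(totals$n_diagnostic[2], totals$n_assessed[2],
                              totals$n_diagnostic[3], totals$n_assessed[3]),
    hippo_vs_gms = run_fisher(totals$n_diagnostic[1], totals$n_assessed[1],
                              totals$n_diagnostic[3], totals$n_assessed[3])
  )

  structure(
    list(per_family = kept, excluded_families = as.character(exclude),
         totals = totals, rates = rates, wilcoxon = wilcoxon, fisher = fisher),
    class = "hippo_comparison"
  )
}

#' @export
print.hippo_comparison <- function(x, ...) {
  cat("<hippo_comparison>", nrow(x$per_family), "families")
  if (length(x$excluded_families) > 0) {
    cat(" (excluded:", paste(x$excluded_families, collapse = ", "), ")")
  }
  cat("\n")
  r <- x$rates
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-12s assessed %3d  diagnostic %d (%.2f%%)  reportable %d (%.2f%%)\n",
                r$strategy[i], r$n_assessed[i], r$n_diagnostic[i],
                r$diagnostic_rate_pct[i], r$n_reportable[i],
                r$reportable_rate_pct[i]))
  }
  if (!is.null(x$wilcoxon$gencc_vs_gms)) {
    cat(sprintf("  Wilcoxon assessed (GenCC vs panel): p = %.4g\n",
                x$wilcoxon$gencc_vs_gms$p_value))
  }
  if (!is.null(x$wilcoxon$hippo_vs_gms)) {
    cat(sprintf("  Wilcoxon assessed (all genes vs panel): p = %.4g\n",
                x$wilcoxon$hippo_vs_gms$p_value))
  }
  if (!is.null(x$fisher$gencc_vs_gms)) {
    cat(sprintf("  Fisher diagnostic yield (GenCC vs panel): p = %.4g\n",
                x$fisher$gencc_vs_gms$p_value))
  }
  invisible(x)
}
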