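#' Read a 6-column PED pedigree file
#'
#' Parses the standard PLINK-style pedigree dialect: one row per individual
#' with columns family id, sample id, father id, mother id, sex (1 = male,
#' 2 = female, other = unknown) and affected status (2 = affected,
#' 1 = unaffected, other = unknown). A parent id of `"0"` means the parent is
#' not part of the pedigree and is stored as `NA`.
#'
#' @param path Path to a whitespace-delimited PED file without header.
#' @return A tibble with columns `family_id`, `sample_id`, `father_id`,
#'   `mother_id`, `sex` (`"male"`, `"female"`, `"unknown"`) and `affected`
#'   (`"yes"`, `"no"`, `"unknown"`), validated with [validate_pedigree()].
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 6) {
    stop("PED file must have 6 columns, found ", ncol(raw), call. = FALSE)
  }
  ped <- tibble::tibble(
    family_id = raw[[1]],
    sample_id = raw[[2]],
    father_id = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
    mother_id = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]),
    sex = dplyr::case_match(raw[[5]], "1" ~ "male", "2" ~ "female",
                            .default = "unknown"),
    affected = dplyr::case_match(raw[[6]], "2" ~ "yes", "1" ~ "no",
                                 .default = "unknown")
  )
  validate_pedigree(ped)
}

#' Validate a pedigree tibble
#'
#' Enforces the structural invariants a trio analysis relies on: parent
#' references resolve to pedigree members (or are absent), every family has at
#' least one affected member, and no individual is its own ancestor.
#'
#' @param ped A tibble as returned by [read_ped()].
#' @return The validated pedigree, invisibly unchanged.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  needed <- c("family_id", "sample_id", "father_id", "mother_id", "sex", "affected")
  missing_cols <- setdiff(needed, names(ped))
  if (length(missing_cols) > 0) {
    stop("pedigree is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  # a quad sequenced as two trios lists the parents once per trio, so sample
  # ids may recur across families but never within one
  dup_in_fam <- ped |>
    dplyr::summarise(dup = anyDuplicated(.data$sample_id) > 0,
                     .by = "family_id") |>
    dplyr::filter(.data$dup)
  if (nrow(dup_in_fam) > 0) {
    stop("duplicate sample ids within family: ",
         paste(dup_in_fam$family_id, collapse = ", "), call. = FALSE)
  }
  refs <- stats::na.omit(c(ped$father_id, ped$mother_id))
  unresolved <- setdiff(refs, ped$sample_id)
  if (length(unresolved) > 0) {
    stop("parent id(s) not present in pedigree: ",
         paste(unique(unresolved), collapse = ", "), call. = FALSE)
  }
  no_affected <- ped |>
    dplyr::summarise(any_aff = any(.data$affected == "yes"), .by = "family_id") |>
    dplyr::filter(!.data$any_aff)
  if (nrow(no_affected) > 0) {
    stop("family without an affected member: ",
         paste(no_affected$family_id, collapse = ", "), call. = FALSE)
  }
  # cycle check: walk parent links from every member
  parent_of <- stats::setNames(
    lapply(seq_len(nrow(ped)), function(i) {
      stats::na.omit(c(ped$father_id[i], ped$mother_id[i]))
    }),
    ped$sample_id
  )
  for (s in ped$sample_id) {
    seen <- character()
    frontier <- s
    while (length(frontier) > 0) {
      frontier <- unique(unlist(parent_of[frontier], use.names = FALSE))
      if (s %in% frontier) {
        stop("cyclic parentage involving sample ", s, call. = FALSE)
      }
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
    }
  }
  invisible(ped)
}

#' Write a pedigree to a 6-column PED file
#'
#' @param ped Pedigree tibble (see [read_ped()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  validate_pedigree(ped)
  out <- data.frame(
    fid = ped$family_id,
    iid = ped$sample_id,
    fat = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mot = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = dplyr::case_match(ped$sex, "male" ~ "1", "female" ~ "2", .default = "0"),
    aff = dplyr::case_match(ped$affected, "yes" ~ "2", "no" ~ "1", .default = "0")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Affected members of a family that have at least one sequenced parent or are
#' analysable probands
#'
#' @param ped Pedigree tibble.
#' @param family One family id.
#' @return Character vector of affected sample ids in that family.
#' @keywords internal
family_probands <- function(ped, family) {
  fam <- ped[ped$family_id == family, ]
  fam$sample_id[fam$affected == "yes"]
}
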