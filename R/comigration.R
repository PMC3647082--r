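# Co-migration inference: same-slice partner lookup, profile similarity,
# apex-based grouping into candidate complexes, and the annotation summaries
# (localization, functional category, genome coverage).

#' Proteins detected in the same gel slice as a query
#'
#' The database-style partner lookup: every protein with at least one
#' observed peptide in the given slice, excluding the query itself. The query
#' need not itself be detected in the slice.
#'
#' @param quant Long-format quantification table ([quantify_slices()]).
#' @param accession Query accession (excluded from the result).
#' @param slice_index Gel slice.
#' @return Sorted character vector of partner accessions (possibly empty).
#' @export
find_slice_partners <- function(quant, accession, slice_index) {
  stopifnot(is.data.frame(quant))
  hit <- quant$slice_index == slice_index & quant$n_observed > 0
  sort(setdiff(unique(quant$accession[hit]), accession))
}

#' Pearson similarity of two migration profiles
#'
#' @param a,b Numeric profile vectors of equal length, neither constant.
#' @return Pearson correlation in \[-1, 1\].
#' @export
profile_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("profiles differ in length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("similarity undefined for a constant profile")
  }
  stats::cor(a, b)
}

#' Pairwise profile similarity matrix
#'
#' @param profiles Profile matrix from [build_profiles()]. Constant rows
#'   yield NA against everything, with a warning.
#' @return Symmetric correlation matrix with the profile row names.
#' @export
similarity_matrix <- function(profiles) {
  stopifnot(is.matrix(profiles))
  constant <- apply(profiles, 1L, stats::sd) == 0
  if (any(constant)) {
    warning("constant profile(s), similarity undefined (NA): ",
            paste(rownames(profiles)[constant], collapse = ", "))
  }
  suppressWarnings(stats::cor(t(profiles)))
}

#' Group proteins whose peak apexes co-migrate
#'
#' For every occupied apex slice (a slice where at least one protein has a
#' peak apex), collects the proteins having an apex within `tolerance`
#' slices; member sets of size >= 2 become candidate-complex groups. Groups
#' are deduplicated by member set, and groups whose member set is wholly
#' contained in another group at a neighbouring anchor are dropped (maximal
#' groups only), so one complex whose subunit apexes scatter by a slice is
#' reported once rather than as a family of nested fragments. A protein with
#' several peaks can belong to several groups.
#'
#' @param peaks Peak table from [detect_peaks_all()] (columns `accession`,
#'   `apex_slice`).
#' @param tolerance Nonnegative integer; apexes within `tolerance` slices of
#'   the anchor co-migrate (default 0: strictly the same slice).
#' @param maximal_only Drop groups contained in another group
#'   (default `TRUE`).
#' @return List of class `comigration_groups`; each element is a list with
#'   `members` (sorted accessions), `anchor_slice`, `max_apex_spread`
#'   (largest pairwise apex distance among the grouped peaks).
#' @export
group_comigrating <- function(peaks, tolerance = 0L, maximal_only = TRUE) {
  stopifnot(is.data.frame(peaks),
            all(c("accession", "apex_slice") %in% names(peaks)))
  stop_if_not_scalar_count(tolerance, "tolerance")
  groups <- list()
  seen <- character(0)
  for (s in sort(unique(peaks$apex_slice))) {
    sel <- abs(peaks$apex_slice - s) <= tolerance
    members <- sort(unique(peaks$accession[sel]))
    if (length(members) < 2L) next
    key <- paste(members, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    groups[[length(groups) + 1L]] <- list(
      members = members,
      anchor_slice = as.integer(s),
      max_apex_spread = as.integer(diff(range(peaks$apex_slice[sel]))))
  }
  if (maximal_only && length(groups) > 1L) {
    keys <- lapply(groups, `[[`, "members")
    keep <- vapply(seq_along(groups), function(i) {
      !any(vapply(seq_along(groups), function(j) {
        i != j && length(keys[[i]]) <= length(keys[[j]]) &&
          all(keys[[i]] %in% keys[[j]]) &&
          !identical(keys[[i]], keys[[j]])
      }, logical(1L)))
    }, logical(1L))
    groups <- groups[keep]
  }
  structure(groups, class = "comigration_groups")
}

#' @export
print.comigration_groups <- function(x, ...) {
  cat(length(x), "co-migration group(s)\n")
  for (g in x) {
    cat("  slice ", g$anchor_slice, " (spread ", g$max_apex_spread, "): ",
        paste(g$members, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Summarize identified proteins by subcellular localization
#'
#' Counts identified proteins per localization class, the percentage of the
#' identified set each class represents (full precision plus half-up integer
#' rounding for reporting), and the summed molar percentage per class.
#' Proteins without an annotation are counted as `"unknown"`.
#'
#' @param identified Character vector of identified accessions (nonempty).
#' @param annotations Annotation data.frame ([read_annotation_table()]).
#' @param mol Named mol% vector over `identified`, summing to 100
#'   ([compute_mol_percent()]).
#' @return A data.frame with one row per localization class: `localization`,
#'   `n`, `percent`, `percent_rounded`, `mol_percent`.
#' @export
summarize_localization <- function(identified, annotations, mol) {
  identified <- unique(identified)
  if (length(identified) == 0L) stop("`identified` must be nonempty")
  missing_mol <- setdiff(identified, names(mol))
  if (length(missing_mol) > 0L) {
    stop("mol%% missing for accession(s): ",
         paste(utils::head(missing_mol, 5L), collapse = ", "))
  }
  mol <- mol[identified]
  if (abs(sum(mol) - 100) > 1e-6) {
    stop("`mol` must be normalized to 100 over the identified set")
  }
  loc <- as.character(
    annotations$localization[match(identified, annotations$accession)])
  loc[is.na(loc)] <- "unknown"
  loc <- factor(loc, levels = LOCALIZATION_LEVELS)
  n <- as.integer(table(loc))
  pct <- 100 * n / length(identified)
  molpct <- as.numeric(tapply(mol, loc, sum, default = 0))
  data.frame(localization = LOCALIZATION_LEVELS, n = n, percent = pct,
             percent_rounded = as.integer(round_half_up(pct)),
             mol_percent = molpct, stringsAsFactors = FALSE)
}

#' Tally identified proteins by functional category
#'
#' @param identified Character vector of accessions.
#' @param annotations Annotation data.frame; proteins without an annotation
#'   (or with an empty category) fall into `"Unknown"`.
#' @return Named integer vector of counts, sorted by decreasing count and
#'   then category name; empty input gives an empty vector.
#' @export
tally_categories <- function(identified, annotations) {
  identified <- unique(identified)
  if (length(identified) == 0L) return(integer(0))
  cat_ <- annotations$category[match(identified, annotations$accession)]
  cat_[is.na(cat_) | cat_ == ""] <- "Unknown"
  tab <- table(cat_)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

#' Genome coverage of an identification inventory
#'
#' Fraction of a genome's predicted gene models recovered in the
#' identification set, as a percentage.
#'
#' @param n_identified Number of identified proteins (0..`n_models`).
#' @param n_models Total predicted gene models (> 0).
#' @return List with `percent` (full precision) and `percent_rounded`
#'   (half-up integer, the conventional reporting form).
#' @examples
#' coverage_fraction(1458, 3569)
#' @export
coverage_fraction <- function(n_identified, n_models) {
  stop_if_not_scalar_count(n_identified, "n_identified")
  stop_if_not_scalar_count(n_models, "n_models")
  if (n_models == 0) stop("`n_models` must be positive")
  if (n_identified > n_models) stop("`n_identified` exceeds `n_models`")
  pct <- 100 * n_identified / n_models
  list(percent = pct, percent_rounded = as.integer(round_half_up(pct)))
}
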