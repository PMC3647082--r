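# emPAI quantification: per-slice observed-peptide counts, emPAI values and
# molar-percentage normalization.
#
# emPAI = 10^(N_observed / N_observable) - 1, where N_observed is the number
# of distinct identified peptide sequences of a protein (here: in one gel
# slice) and N_observable the number of distinct tryptic peptides whose m/z
# falls in the scan range. mol% of protein i is 100 * emPAI_i / sum_j emPAI_j.

#' Count observed peptides for a protein in a gel slice
#'
#' Distinct identified peptide sequences attributed to `accession` in slice
#' `slice_index`; charge and score are ignored for distinctness, so the same
#' peptide seen at 2+ and 3+ counts once.
#'
#' @param ids Peptide-identification data.frame
#'   (see [read_peptide_table()]).
#' @param accession Protein accession.
#' @param slice_index Gel slice (1-based from the top).
#' @return Integer count; 0 when the protein is absent from the slice.
#' @export
count_observed_peptides <- function(ids, accession, slice_index) {
  stopifnot(is.data.frame(ids))
  sel <- ids$accession == accession & ids$slice_index == slice_index
  length(unique(ids$peptide[sel]))
}

#' emPAI from observed and observable peptide counts
#'
#' @param n_observed Nonnegative integer(s): distinct observed peptides.
#' @param n_observable Nonnegative integer(s): distinct observable tryptic
#'   peptides (the denominator).
#' @return `10^(n_observed / n_observable) - 1`. Both zero gives 0; a
#'   positive `n_observed` with a zero denominator is an error (a protein
#'   with no in-range tryptic peptide cannot carry identifications).
#' @examples
#' compute_empai(5, 10)  # 10^0.5 - 1
#' @export
compute_empai <- function(n_observed, n_observable) {
  if (any(n_observed < 0) || any(n_observable < 0)) {
    stop("peptide counts must be nonnegative")
  }
  bad <- n_observable == 0 & n_observed > 0
  if (any(bad)) {
    stop("undefined emPAI denominator: n_observable = 0 with n_observed > 0")
  }
  out <- numeric(length(n_observed))
  ok <- n_observable > 0
  out[ok] <- 10^(n_observed[ok] / n_observable[ok]) - 1
  out
}

#' Per-slice emPAI quantification of a whole dataset
#'
#' Joins peptide identifications to the proteome, counts distinct observed
#' peptides per (accession, slice), computes each protein's observable-peptide
#' count once (the denominator is a protein property, not a slice property),
#' and returns the long-format quantification table from which migration
#' profiles are built.
#'
#' @param ids Peptide identifications (validated data.frame).
#' @param proteome Proteome data.frame from [read_fasta()].
#' @param params [digestion_params()].
#' @param n_slices Total number of gel slices.
#' @return A data.frame with one row per (accession, slice) carrying at least
#'   one identification: `accession`, `slice_index`, `n_observed`,
#'   `n_observable`, `empai`.
#' @export
quantify_slices <- function(ids, proteome, params = digestion_params(),
                            n_slices) {
  stop_if_not_scalar_count(n_slices, "n_slices")
  stopifnot(is.data.frame(ids), is.data.frame(proteome))
  if (nrow(ids) == 0L) {
    return(data.frame(accession = character(0), slice_index = integer(0),
                      n_observed = integer(0), n_observable = integer(0),
                      empai = numeric(0), stringsAsFactors = FALSE))
  }
  unknown <- setdiff(unique(ids$accession), proteome$accession)
  if (length(unknown) > 0L) {
    stop("identifications reference accession(s) absent from the proteome: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (any(ids$slice_index < 1L | ids$slice_index > n_slices)) {
    stop("slice indices outside 1..", n_slices)
  }
  dd <- unique(ids[, c("accession", "slice_index", "peptide")])
  agg <- stats::aggregate(peptide ~ accession + slice_index, data = dd,
                          FUN = length)
  names(agg)[names(agg) == "peptide"] <- "n_observed"

  accs <- unique(agg$accession)
  denom <- count_observable_peptides(
    proteome[match(accs, proteome$accession), , drop = FALSE], params)
  agg$n_observable <- as.integer(denom[agg$accession])
  agg$empai <- compute_empai(agg$n_observed, agg$n_observable)
  agg <- agg[order(agg$accession, agg$slice_index),
             c("accession", "slice_index", "n_observed", "n_observable",
               "empai")]
  rownames(agg) <- NULL
  agg
}

#' Per-protein total emPAI across all slices
#'
#' Sums each protein's per-slice emPAI values; this is the dataset-wide
#' abundance estimate that feeds [compute_mol_percent()] for
#' sample-composition summaries.
#'
#' @param quant Output of [quantify_slices()].
#' @return Named numeric vector, one total per accession.
#' @export
protein_empai_totals <- function(quant) {
  stopifnot(is.data.frame(quant), all(c("accession", "empai") %in% names(quant)))
  totals <- tapply(quant$empai, quant$accession, sum)
  out <- as.numeric(totals)
  names(out) <- names(totals)
  out[order(names(out))]
}

#' Molar percentages from emPAI values
#'
#' Normalizes emPAI values to molar percentages:
#' `mol%_i = 100 * emPAI_i / sum_j emPAI_j`. The result sums to 100 (within
#' 1e-9) and is invariant to rescaling all inputs by a positive constant.
#'
#' @param empai Named nonnegative numeric vector of emPAI values (per
#'   protein), at least one of them positive.
#' @return Named numeric vector of molar percentages.
#' @export
compute_mol_percent <- function(empai) {
  if (length(empai) == 0L || is.null(names(empai))) {
    stop("`empai` must be a named numeric vector")
  }
  if (any(empai < 0)) stop("emPAI values must be nonnegative")
  total <- sum(empai)
  if (total <= 0) stop("all emPAI values are zero: nothing to normalize")
  100 * empai / total
}

#' Summed molar percentage over a subset of proteins
#'
#' @param mol Named molar-percentage vector from [compute_mol_percent()].
#' @param subset Character vector of accessions, all present in `mol`.
#' @return The summed mol% of the subset, in \[0, 100\].
#' @export
summed_mol_percent <- function(mol, subset) {
  missing <- setdiff(subset, names(mol))
  if (length(missing) > 0L) {
    stop("accession(s) outside the mol%% map: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (length(subset) == 0L) return(0)
  sum(mol[unique(subset)])
}
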