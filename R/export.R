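# Database-style export: one record per identified protein carrying its
# migration profile, detected peaks with estimated native masses, same-slice
# partners, and profile-similarity ranked candidates; plus a whole-dataset
# JSON writer with a checksummed manifest.

#' Build the database record for one protein
#'
#' @param accession Accession of an identified protein.
#' @param quant Long-format quantification ([quantify_slices()]).
#' @param profiles Profile matrix ([build_profiles()]).
#' @param peaks Peak table ([detect_peaks_all()]), optionally already
#'   annotated with masses ([annotate_peak_masses()]).
#' @param curve Optional [fit_calibration()] curve; if given and `peaks`
#'   lacks mass columns, masses are added.
#' @param n_similar Number of similarity-ranked candidate partners to keep
#'   (default 10).
#' @return A list of class `protein_entry`: `accession`, `profile` (length-S
#'   numeric), `peaks` (data.frame), `partners_by_slice` (named list, one
#'   element per slice where the protein is detected, partners ordered by
#'   descending emPAI in that slice, ties by accession), `similar_proteins`
#'   (data.frame `accession`, `score`, descending score, ties by accession),
#'   and `summary` (total emPAI, slices detected, peak count).
#' @export
build_entry <- function(accession, quant, profiles, peaks, curve = NULL,
                        n_similar = 10L) {
  stopifnot(is.matrix(profiles))
  if (!accession %in% rownames(profiles) ||
      all(profiles[accession, ] == 0)) {
    stop("'", accession, "' is not an identified protein in this dataset")
  }
  profile <- profiles[accession, ]
  my_peaks <- peaks[peaks$accession == accession, , drop = FALSE]
  if (!is.null(curve) && !"est_mass_kda" %in% names(my_peaks)) {
    my_peaks <- annotate_peak_masses(my_peaks, curve)
  }
  rownames(my_peaks) <- NULL

  detected_slices <- which(profile > 0)
  partners_by_slice <- lapply(detected_slices, function(s) {
    others <- quant[quant$slice_index == s & quant$n_observed > 0 &
                      quant$accession != accession, , drop = FALSE]
    others <- others[order(-others$empai, others$accession), ]
    others$accession
  })
  names(partners_by_slice) <- as.character(detected_slices)

  others <- setdiff(rownames(profiles), accession)
  usable <- others[apply(profiles[others, , drop = FALSE], 1L,
                         stats::sd) > 0 & stats::sd(profile) > 0]
  scores <- vapply(usable, function(a) {
    profile_similarity(profile, profiles[a, ])
  }, numeric(1L))
  ord <- order(-scores, usable)
  similar <- data.frame(accession = usable[ord],
                        score = unname(scores[ord]),
                        stringsAsFactors = FALSE)
  similar <- utils::head(similar, n_similar)
  rownames(similar) <- NULL

  structure(list(
    accession = accession,
    profile = unname(profile),
    peaks = my_peaks,
    partners_by_slice = partners_by_slice,
    similar_proteins = similar,
    summary = list(total_empai = sum(profile),
                   n_slices_detected = length(detected_slices),
                   n_peaks = nrow(my_peaks))),
    class = "protein_entry")
}

#' Export a dataset of protein entries to JSON
#'
#' Writes a single schema-versioned JSON document holding the run parameters
#' and every entry. The export is a pure function of its inputs: re-running
#' with the same entries and parameters produces a byte-identical file (no
#' timestamps), which the manifest checksum makes verifiable.
#'
#' @param entries Nonempty list of [build_entry()] records.
#' @param path Output JSON path.
#' @param parameters Named list of run parameters recorded in the document.
#' @return Manifest list: `path`, `n_entries`, `md5`.
#' @export
export_dataset <- function(entries, path, parameters = list()) {
  if (length(entries) == 0L) stop("`entries` must be nonempty")
  for (e in entries) stopifnot(inherits(e, "protein_entry"))
  doc <- list(
    schema_version = "1.0",
    parameters = parameters,
    n_entries = length(entries),
    entries = lapply(entries, unclass)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  list(path = path, n_entries = length(entries),
       md5 = unname(tools::md5sum(path)))
}

#' Read back an exported dataset
#'
#' @param path Path written by [export_dataset()].
#' @return The parsed document (named list).
#' @export
read_dataset <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
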