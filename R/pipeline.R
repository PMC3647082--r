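#' Run the full co-migration analysis pipeline
#'
#' Convenience wrapper chaining quantification, profile construction, peak
#' detection, co-migration grouping and (optionally) mass calibration.
#'
#' @param proteome Proteome data.frame ([read_fasta()] /
#'   [generate_proteome()]).
#' @param ids Peptide identifications ([read_peptide_table()] /
#'   [simulate_peptide_table()]).
#' @param n_slices Number of gel slices.
#' @param params [digestion_params()].
#' @param rel_height,min_value Peak-detection thresholds
#'   (see [detect_peaks()]).
#' @param tolerance Apex tolerance for [group_comigrating()].
#' @param markers Optional marker table for [fit_calibration()].
#' @return List with `quant`, `profiles`, `peaks` (mass-annotated when
#'   markers are given), `groups`, `mol_percent`, and `calibration` (NULL
#'   without markers).
#' @export
run_comigration_pipeline <- function(proteome, ids, n_slices,
                                     params = digestion_params(),
                                     rel_height = 0.1, min_value = 0.01,
                                     tolerance = 0L, markers = NULL) {
  quant <- quantify_slices(ids, proteome, params, n_slices)
  profiles <- build_profiles(quant, n_slices)
  peaks <- detect_peaks_all(profiles, rel_height, min_value)
  curve <- NULL
  if (!is.null(markers)) {
    curve <- fit_calibration(markers)
    peaks <- annotate_peak_masses(peaks, curve)
  }
  groups <- group_comigrating(peaks, tolerance = tolerance)
  totals <- protein_empai_totals(quant)
  mol <- if (length(totals) > 0L && sum(totals) > 0) {
    compute_mol_percent(totals)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  list(quant = quant, profiles = profiles, peaks = peaks, groups = groups,
       mol_percent = mol, calibration = curve)
}
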