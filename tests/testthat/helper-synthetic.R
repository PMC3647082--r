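# Shared builders for synthetic study datasets used across test files.

# Five well-separated complexes of 3-6 members over a 60-slice lane; the
# canonical recovery benchmark. Complex parameters (width 1.2 slices,
# saturation k = 6, apex abundance 0.35) give sharply peaked but
# non-saturated detection, the regime BN-PAGE bands occupy.
recovery_dataset <- function(seed) {
  prot <- generate_proteome(25L, c(200L, 350L), seed = 1L)
  specs <- list(
    complex_spec("C1", prot$accession[1:4],   apex_slice = 8L,
                 width_slices = 1.2, abundance = 0.35),
    complex_spec("C2", prot$accession[5:9],   apex_slice = 18L,
                 width_slices = 1.2, abundance = 0.35),
    complex_spec("C3", prot$accession[10:12], apex_slice = 30L,
                 width_slices = 1.2, abundance = 0.35),
    complex_spec("C4", prot$accession[13:18], apex_slice = 42L,
                 width_slices = 1.2, abundance = 0.35),
    complex_spec("C5", prot$accession[19:22], apex_slice = 53L,
                 width_slices = 1.2, abundance = 0.35))
  noise <- noise_params(detection_rate_k = 6, background_rate = 0,
                        hydrophobicity_penalty = 0.3, seed = seed)
  ids <- simulate_peptide_table(prot, specs, noise, n_slices = 60L)
  list(proteome = prot, specs = specs, ids = ids, n_slices = 60L)
}

# Precision/recall of recovered member sets against ground truth, matching
# groups by exact member-set equality.
group_precision_recall <- function(recovered, truth) {
  key <- function(g) paste(sort(g$members), collapse = "|")
  rk <- vapply(recovered, key, character(1L))
  tk <- vapply(truth, key, character(1L))
  list(precision = if (length(rk) == 0L) 0 else mean(rk %in% tk),
       recall = if (length(tk) == 0L) 1 else mean(tk %in% rk))
}

write_tsv_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
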