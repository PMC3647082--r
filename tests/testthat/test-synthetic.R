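test_that("proteome generation is deterministic and respects length bounds", {
  a <- generate_proteome(5, c(50, 60), seed = 1)
  b <- generate_proteome(5, c(50, 60), seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_proteome(5, c(50, 60), seed = 2)))
  lens <- nchar(a$sequence)
  expect_true(all(lens >= 50 & lens <= 60))
  expect_true(all(grepl("^[A-Z]+$", a$sequence)))
  expect_error(generate_proteome(0, c(50, 60)), ">= 1")
  expect_error(generate_proteome(3, c(5, 60)), "min >= 10")
})

test_that("short random proteins almost always have observable peptides", {
  # regression guard on the composition model: >= 95% of length-50..60
  # proteins carry at least one observable tryptic peptide
  hits <- 0L; total <- 0L
  for (seed in 1:100) {
    prot <- generate_proteome(1, c(50, 60), seed = seed)
    total <- total + 1L
    if (count_observable_peptides(prot$sequence) >= 1L) hits <- hits + 1L
  }
  expect_gte(hits / total, 0.95)
})

test_that("simulation is deterministic and silent without signal", {
  prot <- generate_proteome(4, c(100, 150), seed = 3)
  sp <- complex_spec("C", prot$accession[1:2], apex_slice = 10,
                     width_slices = 1, abundance = 1e-12)
  np <- noise_params(background_rate = 0, seed = 5)
  tab <- simulate_peptide_table(prot, list(sp), np, n_slices = 20)
  expect_equal(nrow(tab), 0L)  # vanishing abundance, no background

  sp2 <- complex_spec("C", prot$accession[1:2], apex_slice = 10,
                      width_slices = 1, abundance = 1)
  t1 <- simulate_peptide_table(prot, list(sp2), np, n_slices = 20)
  t2 <- simulate_peptide_table(prot, list(sp2), np, n_slices = 20)
  expect_identical(t1, t2)
  expect_gt(nrow(t1), 0L)
  # rows are valid identifications of the simulated proteome
  expect_true(all(t1$slice_index >= 1 & t1$slice_index <= 20))
  expect_true(all(t1$accession %in% prot$accession[1:2]))
})

test_that("narrow complexes concentrate detections near the apex", {
  prot <- generate_proteome(3, c(150, 250), seed = 8)
  sp <- complex_spec("C", prot$accession, apex_slice = 25, width_slices = 1,
                     abundance = 2)
  for (seed in 1:5) {
    np <- noise_params(detection_rate_k = 10, background_rate = 0, seed = seed)
    tab <- simulate_peptide_table(prot, list(sp), np, n_slices = 60)
    expect_gt(nrow(tab), 0)
    expect_gte(mean(abs(tab$slice_index - 25) <= 3), 0.99)
  }
})

test_that("simulated tables survive the TSV round trip and validation", {
  prot <- generate_proteome(5, c(100, 200), seed = 4)
  sp <- complex_spec("C", prot$accession[1:3], apex_slice = 8,
                     width_slices = 1.5, abundance = 0.5)
  tab <- simulate_peptide_table(prot, list(sp),
                                noise_params(background_rate = 0.5, seed = 6),
                                n_slices = 15)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(tab, path)
  back <- read_peptide_table(path, n_slices = 15)
  attr(back, "rejected") <- NULL
  expect_equal(back, tab)
  # every simulated peptide is a true tryptic product of its protein
  for (i in sample.int(nrow(tab), min(25, nrow(tab)))) {
    seqs <- prot$sequence[prot$accession == tab$accession[i]]
    expect_true(grepl(tab$peptide[i], seqs, fixed = TRUE))
  }
})

test_that("ground-truth groups mirror the specs", {
  sp1 <- complex_spec("AB", c("A", "B"), apex_slice = 15)
  sp2 <- complex_spec("solo", "C", apex_slice = 20)
  sp3 <- complex_spec("DE", c("D", "E"), apex_slice = 15)
  g <- ground_truth_groups(list(sp1, sp2, sp3))
  expect_length(g, 2L)  # singleton omitted; shared apex stays two groups
  expect_equal(g[[1]]$members, c("A", "B"))
  expect_equal(g[[2]]$members, c("D", "E"))
  expect_equal(g[[1]]$anchor_slice, 15L)
})

test_that("per-slice emPAI tracks true complex abundance", {
  cors <- c()
  for (seed in 1:5) {
    d <- recovery_dataset(seed)
    res <- run_comigration_pipeline(d$proteome, d$ids, d$n_slices)
    for (sp in d$specs) {
      s <- seq_len(d$n_slices)
      a_true <- sp$abundance * exp(-(s - sp$apex_slice)^2 /
                                     (2 * sp$width_slices^2))
      window <- which(a_true >= 0.01 * sp$abundance)
      for (acc in sp$members) {
        if (!acc %in% rownames(res$profiles)) next
        cors <- c(cors, suppressWarnings(
          stats::cor(a_true[window], res$profiles[acc, window],
                     method = "spearman")))
      }
    }
  }
  expect_gte(stats::median(cors, na.rm = TRUE), 0.7)
})

test_that("raising the hydrophobicity penalty depresses emPAI of a hydrophobic protein", {
  # a strongly hydrophobic membrane-like protein: mostly I/L/V/F stretches
  set.seed(99)
  blocks <- replicate(12, paste(sample(c("I", "L", "V", "F", "A"), 12,
                                       replace = TRUE), collapse = ""))
  seqs <- paste0(paste(blocks, collapse = "K"), "K")
  prot <- data.frame(accession = "HYDRO", sequence = seqs, description = "",
                     stringsAsFactors = FALSE)
  sp <- complex_spec("H", "HYDRO", apex_slice = 10, width_slices = 1.5,
                     abundance = 0.5)
  mean_empai <- function(pen) {
    np <- noise_params(detection_rate_k = 6, background_rate = 0,
                       hydrophobicity_penalty = pen, seed = 17)
    tab <- simulate_peptide_table(prot, list(sp), np, n_slices = 20)
    if (nrow(tab) == 0L) return(0)
    q <- quantify_slices(tab, prot, n_slices = 20)
    mean(q$empai)
  }
  e <- vapply(c(0, 0.45, 0.9), mean_empai, numeric(1))
  expect_true(all(diff(e) < 0))
})
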