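test_that("same-slice partner lookup excludes the query and empty slices", {
  quant <- data.frame(accession = c("PsaC", "PsaD", "Other"),
                      slice_index = c(15L, 15L, 40L),
                      n_observed = c(3L, 2L, 1L),
                      n_observable = c(10L, 10L, 10L),
                      empai = compute_empai(c(3, 2, 1), 10))
  expect_equal(find_slice_partners(quant, "PsaC", 15), "PsaD")
  expect_equal(find_slice_partners(quant, "Other", 40), character(0))
  # a query absent from the slice still sees the slice's detected set
  expect_equal(find_slice_partners(quant, "Other", 15), c("PsaC", "PsaD"))
})

test_that("profile similarity is Pearson correlation with guards", {
  expect_equal(profile_similarity(c(0, 2, 5, 1), c(0, 2, 5, 1)), 1)
  expect_equal(profile_similarity(c(1, 0, 0), c(0, 0, 1)), -0.5)
  expect_equal(profile_similarity(c(1, 2), c(2, 4)), 1)
  expect_error(profile_similarity(c(1, 2), c(1, 2, 3)), "length")
  expect_error(profile_similarity(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("profile similarity is symmetric and affine invariant", {
  set.seed(21)
  for (i in 1:20) {
    a <- rexp(30); b <- rexp(30)
    expect_equal(profile_similarity(a, b), profile_similarity(b, a))
    expect_equal(profile_similarity(a * 3.7 + 0.5, b), profile_similarity(a, b),
                 tolerance = 1e-12)
  }
  m <- rbind(A = c(1, 0, 2), B = c(2, 0, 4), C = c(0, 0, 0))
  expect_warning(sm <- similarity_matrix(m), "constant")
  expect_equal(sm["A", "B"], 1)
  expect_true(is.na(sm["A", "C"]))
})

peaks_df <- function(...) {
  rows <- list(...)
  data.frame(accession = vapply(rows, `[[`, "", 1),
             apex_slice = vapply(rows, function(r) as.integer(r[[2]]), 1L),
             stringsAsFactors = FALSE)
}

test_that("co-migration grouping respects the apex tolerance", {
  pk <- peaks_df(list("A", 15), list("B", 15), list("C", 40))
  g <- group_comigrating(pk, tolerance = 0)
  expect_length(g, 1L)
  expect_equal(g[[1]]$members, c("A", "B"))
  expect_equal(g[[1]]$anchor_slice, 15L)

  pk2 <- peaks_df(list("A", 15), list("B", 16))
  expect_length(group_comigrating(pk2, tolerance = 0), 0L)
  g2 <- group_comigrating(pk2, tolerance = 1)
  expect_length(g2, 1L)
  expect_equal(g2[[1]]$members, c("A", "B"))
  expect_equal(g2[[1]]$max_apex_spread, 1L)
})

test_that("a protein with two peaks can join two groups", {
  pk <- peaks_df(list("A", 10), list("B", 10), list("A", 30), list("C", 30))
  g <- group_comigrating(pk, tolerance = 0)
  expect_length(g, 2L)
  expect_equal(g[[1]]$members, c("A", "B"))
  expect_equal(g[[2]]$members, c("A", "C"))
})

test_that("grouping is monotone coarsening in the tolerance", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    pk <- data.frame(accession = paste0("P", seq_len(n)),
                     apex_slice = sample(1:25, n, replace = TRUE),
                     stringsAsFactors = FALSE)
    for (t in 0:2) {
      gt <- group_comigrating(pk, tolerance = t, maximal_only = FALSE)
      gt1 <- group_comigrating(pk, tolerance = t + 1, maximal_only = FALSE)
      u_t <- unique(unlist(lapply(gt, `[[`, "members")))
      u_t1 <- unique(unlist(lapply(gt1, `[[`, "members")))
      expect_true(all(u_t %in% u_t1))
      # every group at tolerance t sits inside some group at t+1
      for (g in gt) {
        expect_true(any(vapply(gt1, function(h) all(g$members %in% h$members),
                               logical(1))))
      }
    }
  }
})

test_that("maximal-only grouping drops nested member sets", {
  pk <- peaks_df(list("A", 10), list("B", 10), list("C", 11))
  g_all <- group_comigrating(pk, tolerance = 1, maximal_only = FALSE)
  g_max <- group_comigrating(pk, tolerance = 1)
  expect_gte(length(g_all), length(g_max))
  expect_length(g_max, 1L)
  expect_equal(g_max[[1]]$members, c("A", "B", "C"))
})

test_that("localization summary counts, percentages and mol% are coherent", {
  accs <- paste0("P", 1:245)
  ann <- data.frame(accession = accs,
                    localization = c(rep("thylakoid", 117),
                                     rep("envelope", 20), rep("stroma", 13),
                                     rep("other", 45), rep("unknown", 50)),
                    category = "x", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_annotation_table(path)
  mol <- compute_mol_percent(stats::setNames(rep(1, 245), accs))
  s <- summarize_localization(accs, ann, mol)
  expect_equal(sum(s$n), 245L)
  expect_equal(s$n[s$localization == "thylakoid"], 117L)
  expect_equal(s$percent_rounded[s$localization == "thylakoid"], 48L)
  expect_equal(sum(s$mol_percent), 100, tolerance = 1e-9)
  # un-annotated proteins fall into "unknown"
  s2 <- summarize_localization(accs, ann[1:200, ], mol)
  expect_equal(s2$n[s2$localization == "unknown"], 5L + 45L)
  expect_error(summarize_localization(character(0), ann, mol), "nonempty")
})

test_that("category tallies default missing annotations to Unknown", {
  ann <- data.frame(accession = c("P1", "P2", "P3"),
                    localization = factor(rep("unknown", 3),
                                          levels = levels(factor("unknown"))),
                    category = c("Hypothetical", "Unknown", "Photosynthesis"),
                    stringsAsFactors = FALSE)
  tc <- tally_categories(c("P1", "P2", "P3", "P4"), ann)
  expect_equal(tc[["Hypothetical"]], 1L)
  expect_equal(tc[["Photosynthesis"]], 1L)
  expect_equal(tc[["Unknown"]], 2L)  # P2 plus unannotated P4
  expect_equal(sum(tc), 4L)
  expect_equal(tally_categories(character(0), ann), integer(0))
})

test_that("coverage fraction reports full precision plus rounded percent", {
  cv <- coverage_fraction(1458, 3569)
  expect_equal(cv$percent, 100 * 1458 / 3569)
  expect_equal(cv$percent_rounded, 41L)
  expect_equal(coverage_fraction(0, 100)$percent, 0)
  expect_equal(coverage_fraction(100, 100)$percent, 100)
  expect_error(coverage_fraction(101, 100), "exceeds")
})
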