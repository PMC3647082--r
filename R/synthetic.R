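# Synthetic-data generator. Emulates the statistical structure the analysis
# assumes: protein complexes migrating as Gaussian peaks over the gel lane,
# with per-peptide detection probability saturating in complex abundance and
# attenuated by peptide hydrophobicity (hydrophobic membrane subunits yield
# depressed peptide recovery in LC-MS/MS).

#' Specification of one synthetic protein complex
#'
#' @param label Complex label.
#' @param members Character vector of member accessions (nonempty).
#' @param apex_slice Gel slice of the complex's migration apex (1..S).
#' @param width_slices Gaussian sigma of the migration band, in slices.
#' @param abundance Abundance scale at the apex (arbitrary units).
#' @param stoichiometry Positive integer copy number per member (recycled).
#' @return An object of class `complex_spec`.
#' @export
complex_spec <- function(label, members, apex_slice, width_slices = 1.5,
                         abundance = 1, stoichiometry = 1L) {
  if (length(members) == 0L) stop("`members` must be nonempty")
  stop_if_not_scalar_count(apex_slice, "apex_slice")
  if (apex_slice < 1L) stop("`apex_slice` must be >= 1")
  if (!is.numeric(width_slices) || width_slices <= 0) {
    stop("`width_slices` must be positive")
  }
  if (!is.numeric(abundance) || abundance <= 0) {
    stop("`abundance` must be positive")
  }
  stoichiometry <- rep_len(as.integer(stoichiometry), length(members))
  if (any(stoichiometry < 1L)) stop("`stoichiometry` must be >= 1")
  structure(list(label = label, members = as.character(members),
                 apex_slice = as.integer(apex_slice),
                 width_slices = width_slices, abundance = abundance,
                 stoichiometry = stoichiometry),
            class = "complex_spec")
}

#' Noise and detection parameters for the simulator
#'
#' Detection of each observable peptide of a member protein in a slice is an
#' independent Bernoulli draw with probability
#' `p = (1 - exp(-k * q * a)) * (1 - penalty * h)`, clamped to \[0, 1\],
#' where `a` is the complex's Gaussian abundance in that slice, `q` the
#' member's stoichiometry, `k` the saturation constant, and `h` the
#' peptide's Kyte-Doolittle hydropathy rescaled to \[0, 1\].
#'
#' @param detection_rate_k Positive saturation constant (default 5: a
#'   unit-abundance complex is detected near-saturation at its apex).
#' @param background_rate Expected number of spurious peptide rows per slice
#'   (Poisson; default 0.2).
#' @param hydrophobicity_penalty Attenuation per unit hydropathy, in
#'   \[0, 1\] (default 0.3).
#' @param seed Master RNG seed; all randomness in the simulator flows from
#'   it through deterministic substreams.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(detection_rate_k = 5, background_rate = 0.2,
                         hydrophobicity_penalty = 0.3, seed = 1L) {
  if (!is.numeric(detection_rate_k) || detection_rate_k <= 0) {
    stop("`detection_rate_k` must be positive")
  }
  if (!is.numeric(background_rate) || background_rate < 0) {
    stop("`background_rate` must be >= 0")
  }
  if (!is.numeric(hydrophobicity_penalty) ||
      hydrophobicity_penalty < 0 || hydrophobicity_penalty > 1) {
    stop("`hydrophobicity_penalty` must be in [0, 1]")
  }
  structure(list(detection_rate_k = detection_rate_k,
                 background_rate = background_rate,
                 hydrophobicity_penalty = hydrophobicity_penalty,
                 seed = as.integer(seed)),
            class = "noise_params")
}

# Residue frequencies for random proteins: typical globular composition with
# K + R ~ 11.3% so tryptic products have realistic lengths.
SYNTH_AA_FREQ <- c(
  A = 0.080, R = 0.055, N = 0.040, D = 0.054, C = 0.014, Q = 0.039,
  E = 0.060, G = 0.070, H = 0.022, I = 0.055, L = 0.090, K = 0.058,
  M = 0.022, F = 0.039, P = 0.047, S = 0.068, T = 0.054, W = 0.011,
  Y = 0.030, V = 0.066
)

#' Generate a random synthetic proteome
#'
#' Random sequences over the 20 standard residues at typical composition
#' (lysine + arginine about 11%, so tryptic peptide lengths are realistic).
#' Deterministic under `seed`.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Integer (min, max) sequence length; min >= 10.
#' @param seed RNG seed.
#' @return A proteome data.frame (`accession`, `sequence`, `description`)
#'   with accessions `SYN0001`, `SYN0002`, ...
#' @export
generate_proteome <- function(n_proteins, length_range = c(150L, 400L),
                              seed = 1L) {
  stop_if_not_scalar_count(n_proteins, "n_proteins")
  if (n_proteins < 1L) stop("`n_proteins` must be >= 1")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1L] < 10L ||
      length_range[1L] > length_range[2L]) {
    stop("`length_range` must be (min, max) with min >= 10")
  }
  freq <- SYNTH_AA_FREQ / sum(SYNTH_AA_FREQ)
  with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n_proteins,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(freq), L, replace = TRUE, prob = freq),
            collapse = "")
    }, character(1L))
    data.frame(accession = sprintf("SYN%04d", seq_len(n_proteins)),
               sequence = seqs,
               description = sprintf("synthetic protein %d", seq_len(n_proteins)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a per-slice peptide-identification table
#'
#' For each complex and slice, the complex abundance follows a Gaussian in
#' slice index, `a(s) = abundance * exp(-(s - apex)^2 / (2 width^2))`. Every
#' observable peptide of every member (tryptic peptides with up to
#' `params$max_missed_observed` missed cleavages, within the scan range) is
#' reported independently with the saturating, hydrophobicity-attenuated
#' probability described in [noise_params()]. Spurious background rows
#' (random true-tryptic peptides of random proteome members) are added at
#' `background_rate` per slice. Deterministic under `noise$seed`.
#'
#' @param proteome Proteome data.frame containing every spec member.
#' @param specs List of [complex_spec()] objects.
#' @param noise A [noise_params()] object.
#' @param n_slices Number of gel slices (default 60).
#' @param params [digestion_params()] governing observable peptides.
#' @return A peptide-identification data.frame (`slice_index`, `accession`,
#'   `peptide`, `score`, `charge`), sorted by slice, accession, peptide,
#'   with duplicate rows removed.
#' @export
simulate_peptide_table <- function(proteome, specs, noise = noise_params(),
                                   n_slices = 60L,
                                   params = digestion_params()) {
  stop_if_not_scalar_count(n_slices, "n_slices")
  stopifnot(is.data.frame(proteome), inherits(noise, "noise_params"))
  if (inherits(specs, "complex_spec")) specs <- list(specs)
  for (sp in specs) {
    stopifnot(inherits(sp, "complex_spec"))
    unknown <- setdiff(sp$members, proteome$accession)
    if (length(unknown) > 0L) {
      stop("complex '", sp$label, "' references unknown accession(s): ",
           paste(unknown, collapse = ", "))
    }
    if (sp$apex_slice > n_slices) {
      stop("complex '", sp$label, "' apex outside 1..", n_slices)
    }
  }

  # observable peptides (identification convention: <= max_missed_observed)
  # and their hydropathies, computed once per protein involved
  involved <- unique(c(unlist(lapply(specs, `[[`, "members")),
                       if (noise$background_rate > 0) proteome$accession))
  pep_pool <- lapply(involved, function(acc) {
    s <- proteome$sequence[match(acc, proteome$accession)]
    peps <- observable_peptides(s, params,
                                max_missed = params$max_missed_observed)
    if (length(peps) == 0L) {
      return(data.frame(peptide = character(0), h = numeric(0)))
    }
    data.frame(peptide = peps, h = peptide_hydropathy(peps),
               stringsAsFactors = FALSE)
  })
  names(pep_pool) <- involved

  rows <- list()
  k <- noise$detection_rate_k
  pen <- noise$hydrophobicity_penalty

  # complex signal
  for (ci in seq_along(specs)) {
    sp <- specs[[ci]]
    for (mi in seq_along(sp$members)) {
      acc <- sp$members[mi]
      q <- sp$stoichiometry[mi]
      pool <- pep_pool[[acc]]
      if (nrow(pool) == 0L) next
      atten <- pmax(0, 1 - pen * pool$h)
      sub_seed <- derive_seed(noise$seed, ci * 1000L + mi)
      detected <- with_seed(sub_seed, {
        lapply(seq_len(n_slices), function(s) {
          a <- sp$abundance *
            exp(-(s - sp$apex_slice)^2 / (2 * sp$width_slices^2))
          p <- pmin(1, pmax(0, (1 - exp(-k * q * a)) * atten))
          u <- stats::runif(nrow(pool))
          pool$peptide[u < p]
        })
      })
      for (s in seq_len(n_slices)) {
        if (length(detected[[s]]) > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            slice_index = s, accession = acc, peptide = detected[[s]],
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  # uniform background of spurious true-tryptic peptides
  if (noise$background_rate > 0) {
    bg <- with_seed(derive_seed(noise$seed, 999983L), {
      nonempty <- involved[vapply(pep_pool, nrow, integer(1L)) > 0L]
      out <- list()
      for (s in seq_len(n_slices)) {
        n_bg <- stats::rpois(1L, noise$background_rate)
        if (n_bg == 0L) next
        accs <- sample(nonempty, n_bg, replace = TRUE)
        peps <- vapply(accs, function(a) {
          pool <- pep_pool[[a]]
          pool$peptide[sample.int(nrow(pool), 1L)]
        }, character(1L), USE.NAMES = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          slice_index = s, accession = accs, peptide = peps,
          stringsAsFactors = FALSE)
      }
      out
    })
    rows <- c(rows, bg)
  }

  if (length(rows) == 0L) {
    return(data.frame(slice_index = integer(0), accession = character(0),
                      peptide = character(0), score = numeric(0),
                      charge = integer(0), stringsAsFactors = FALSE))
  }
  tab <- unique(do.call(rbind, rows))
  tab <- tab[order(tab$slice_index, tab$accession, tab$peptide), ]
  tab$score <- NA_real_
  tab$charge <- NA_integer_
  rownames(tab) <- NULL
  tab
}

#' Ground-truth co-migration groups of a simulation
#'
#' One group per complex with at least two distinct members, anchored at the
#' complex's apex slice. Two complexes sharing an apex remain separate
#' groups.
#'
#' @param specs List of [complex_spec()] objects.
#' @return A `comigration_groups` list in the shape produced by
#'   [group_comigrating()].
#' @export
ground_truth_groups <- function(specs) {
  if (inherits(specs, "complex_spec")) specs <- list(specs)
  groups <- list()
  for (sp in specs) {
    members <- sort(unique(sp$members))
    if (length(members) < 2L) next
    groups[[length(groups) + 1L]] <- list(members = members,
                                          anchor_slice = sp$apex_slice,
                                          max_apex_spread = 0L)
  }
  structure(groups, class = "comigration_groups")
}
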