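# In-silico tryptic digestion and observable-peptide counting. The number of
# observable peptides -- distinct tryptic products whose m/z falls inside the
# instrument scan range at an allowed charge -- is the denominator of emPAI.

#' Digestion and observability parameters
#'
#' Bundles the settings that govern in-silico digestion and the definition of
#' an "observable" peptide. Defaults mirror a typical ion-trap acquisition
#' and search setup: trypsin with up to two missed cleavages for identified
#' (observed) peptides, zero missed cleavages for the observable-peptide
#' denominator, scan range m/z 450-1800, charges 1+ to 3+, proline rule on,
#' and fixed carbamidomethylation of cysteine.
#'
#' @param max_missed_observed Maximum missed cleavages allowed for peptides
#'   accepted as identifications (default 2, the search-engine setting).
#' @param missed_cleavages_observable Missed cleavages used when counting
#'   observable peptides for the emPAI denominator (default 0, the
#'   convention of the original emPAI formulation).
#' @param mz_min,mz_max Instrument scan range in m/z (default 450-1800).
#' @param charges Integer vector of allowed charge states (default 1:3).
#' @param proline_rule If `TRUE` (default), do not cleave after K/R when the
#'   next residue is proline.
#' @param cys_carbamidomethyl If `TRUE` (default), add the fixed
#'   carbamidomethyl mass (+57.021464 Da) per cysteine when computing
#'   peptide masses.
#' @return An object of class `digestion_params`.
#' @export
digestion_params <- function(max_missed_observed = 2L,
                             missed_cleavages_observable = 0L,
                             mz_min = 450, mz_max = 1800,
                             charges = 1:3,
                             proline_rule = TRUE,
                             cys_carbamidomethyl = TRUE) {
  stop_if_not_scalar_count(max_missed_observed, "max_missed_observed")
  stop_if_not_scalar_count(missed_cleavages_observable,
                           "missed_cleavages_observable")
  if (!is.numeric(mz_min) || !is.numeric(mz_max) || mz_min >= mz_max) {
    stop("`mz_min` must be strictly less than `mz_max`")
  }
  charges <- as.integer(charges)
  if (length(charges) == 0L || any(is.na(charges)) || any(charges < 1L)) {
    stop("`charges` must be a nonempty set of integers >= 1")
  }
  structure(list(max_missed_observed = as.integer(max_missed_observed),
                 missed_cleavages_observable =
                   as.integer(missed_cleavages_observable),
                 mz_min = mz_min, mz_max = mz_max,
                 charges = sort(unique(charges)),
                 proline_rule = isTRUE(proline_rule),
                 cys_carbamidomethyl = isTRUE(cys_carbamidomethyl)),
            class = "digestion_params")
}

#' @export
print.digestion_params <- function(x, ...) {
  cat("Digestion parameters (trypsin)\n",
      "  missed cleavages: observed <= ", x$max_missed_observed,
      ", observable = ", x$missed_cleavages_observable, "\n",
      "  scan range: m/z ", x$mz_min, "-", x$mz_max,
      "; charges ", paste(x$charges, collapse = ","), "\n",
      "  proline rule: ", x$proline_rule,
      "; Cys carbamidomethyl: ", x$cys_carbamidomethyl, "\n", sep = "")
  invisible(x)
}

#' Tryptic digest of a protein sequence
#'
#' Cleaves after lysine (K) or arginine (R), optionally suppressed when the
#' next residue is proline, and enumerates every peptide spanning up to
#' `max_missed` internal cleavage sites.
#'
#' @param sequence A single amino-acid string (length >= 1). Nonstandard
#'   letters are allowed here; they only matter later, for mass computation.
#' @param max_missed Maximum number of missed cleavages (default 0).
#' @param proline_rule Suppress cleavage before proline (default `TRUE`).
#' @return A data.frame ordered by (start, end) with columns `peptide`,
#'   `start`, `end` (1-based inclusive coordinates in the parent, so that
#'   `substr(sequence, start, end) == peptide`), and `missed_cleavages`.
#'   A sequence with no cleavage sites yields itself as one peptide.
#' @examples
#' cleave_tryptic("AKRPGRK", max_missed = 1)
#' @export
cleave_tryptic <- function(sequence, max_missed = 0L, proline_rule = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      is.na(sequence) || nchar(sequence) < 1L) {
    stop("`sequence` must be a single nonempty string")
  }
  stop_if_not_scalar_count(max_missed, "max_missed")
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  # cleavage sites: after position i for K/R, not at the C-terminus, and not
  # before proline when the rule is on
  sites <- which(res %in% c("K", "R"))
  sites <- sites[sites < n]
  if (isTRUE(proline_rule) && length(sites) > 0L) {
    sites <- sites[res[sites + 1L] != "P"]
  }
  bounds <- c(0L, sites, n)          # fragment i spans bounds[i]+1..bounds[i+1]
  k <- length(bounds) - 1L           # number of zero-missed fragments
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (i in seq_len(k)) {
    jmax <- min(max_missed, k - i)
    j <- 0:jmax
    starts <- c(starts, rep.int(bounds[i] + 1L, jmax + 1L))
    ends <- c(ends, bounds[i + 1L + j])
    missed <- c(missed, j)
  }
  ord <- order(starts, ends)
  data.frame(peptide = substring(sequence, starts[ord], ends[ord]),
             start = starts[ord], end = ends[ord],
             missed_cleavages = missed[ord], stringsAsFactors = FALSE)
}

#' Monoisotopic mass of a peptide
#'
#' Sum of monoisotopic residue masses plus one water (18.010565 Da), with the
#' fixed carbamidomethyl modification (+57.021464 Da per cysteine) applied
#' when `cys_carbamidomethyl` is `TRUE`.
#'
#' @param sequence Character vector of peptide sequences over the 20 standard
#'   residue letters.
#' @param cys_carbamidomethyl Apply the fixed Cys modification (default
#'   `TRUE`).
#' @return Numeric vector of masses in Da. Nonstandard letters (or an empty
#'   string) raise an undefined-mass error.
#' @examples
#' peptide_monoisotopic_mass("GG")
#' @export
peptide_monoisotopic_mass <- function(sequence, cys_carbamidomethyl = TRUE) {
  m <- peptide_mass_or_na(sequence, cys_carbamidomethyl)
  if (anyNA(m)) {
    stop("mass undefined for peptide(s): ",
         paste(utils::head(sequence[is.na(m)], 5L), collapse = ", "))
  }
  m
}

# Vectorized mass; NA for peptides whose mass is undefined (empty or
# containing a nonstandard letter).
peptide_mass_or_na <- function(sequence, cys_carbamidomethyl = TRUE) {
  vapply(toupper(sequence), function(s) {
    if (is.na(s) || nchar(s) == 0L) return(NA_real_)
    res <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (any(!res %in% STANDARD_AA)) return(NA_real_)
    m <- sum(AA_MONO[res]) + WATER_MONO
    if (cys_carbamidomethyl) m <- m + CARBAMIDOMETHYL_MONO * sum(res == "C")
    m
  }, numeric(1L), USE.NAMES = FALSE)
}

#' m/z of a peptide at a given charge state
#'
#' @param mass Monoisotopic mass in Da (> 0); vectorized.
#' @param z Charge state, integer >= 1.
#' @return `(mass + z * 1.007276) / z`.
#' @export
mz_for_charge <- function(mass, z) {
  if (!is.numeric(z) || length(z) != 1L || is.na(z) || z < 1 || z != floor(z)) {
    stop("`z` must be a single integer >= 1")
  }
  if (!is.numeric(mass) || any(is.na(mass)) || any(mass <= 0)) {
    stop("`mass` must be positive")
  }
  (mass + z * PROTON_MONO) / z
}

#' Observable tryptic peptides of a protein
#'
#' Enumerates the distinct tryptic peptide sequences of a protein that fall
#' inside the instrument scan range at at least one allowed charge state.
#' Peptides containing nonstandard residue letters are excluded (their mass
#' is undefined). Distinctness is by sequence string: two positions yielding
#' the same peptide count once.
#'
#' @param sequence A single protein sequence.
#' @param params A [digestion_params()] object.
#' @param max_missed Missed cleavages to enumerate; defaults to
#'   `params$missed_cleavages_observable` (the emPAI-denominator convention).
#' @return Character vector of distinct in-range peptide sequences.
#' @export
observable_peptides <- function(sequence, params = digestion_params(),
                                max_missed = params$missed_cleavages_observable) {
  stopifnot(inherits(params, "digestion_params"))
  peps <- unique(cleave_tryptic(sequence, max_missed = max_missed,
                                proline_rule = params$proline_rule)$peptide)
  mass <- peptide_mass_or_na(peps, params$cys_carbamidomethyl)
  keep <- !is.na(mass)
  peps <- peps[keep]; mass <- mass[keep]
  if (length(peps) == 0L) return(character(0))
  in_range <- rep(FALSE, length(peps))
  for (z in params$charges) {
    mz <- (mass + z * PROTON_MONO) / z
    in_range <- in_range | (mz >= params$mz_min & mz <= params$mz_max)
  }
  peps[in_range]
}

#' Count observable peptides (the emPAI denominator)
#'
#' @param sequence A single protein sequence, or a proteome data.frame from
#'   [read_fasta()] (then a named integer vector is returned, one count per
#'   accession).
#' @param params A [digestion_params()] object.
#' @return Integer count(s) of distinct observable peptides; can be 0, in
#'   which case emPAI is undefined for any observed identification.
#' @seealso [compute_empai()]
#' @export
count_observable_peptides <- function(sequence, params = digestion_params()) {
  if (is.data.frame(sequence)) {
    stopifnot(all(c("accession", "sequence") %in% names(sequence)))
    counts <- vapply(sequence$sequence, function(s) {
      length(observable_peptides(s, params))
    }, integer(1L), USE.NAMES = FALSE)
    names(counts) <- sequence$accession
    return(counts)
  }
  length(observable_peptides(sequence, params))
}
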