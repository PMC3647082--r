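# Migration profiles over gel slices, peak detection, paralog aggregation,
# and native-mass estimation from a marker calibration curve.

#' Build dense migration profiles
#'
#' Converts the long-format quantification table into a dense matrix of
#' emPAI values: one row per protein, one column per gel slice (1 = top of
#' the gel), zeros where a protein was not identified.
#'
#' @param quant Output of [quantify_slices()] (columns `accession`,
#'   `slice_index`, `empai`).
#' @param n_slices Total number of slices S.
#' @return Numeric matrix (accessions x S) with row names sorted by
#'   accession and column names `"1".."S"`.
#' @export
build_profiles <- function(quant, n_slices) {
  stop_if_not_scalar_count(n_slices, "n_slices")
  stopifnot(is.data.frame(quant),
            all(c("accession", "slice_index", "empai") %in% names(quant)))
  accs <- sort(unique(quant$accession))
  m <- matrix(0, nrow = length(accs), ncol = n_slices,
              dimnames = list(accs, as.character(seq_len(n_slices))))
  if (nrow(quant) > 0L) {
    if (any(quant$slice_index < 1L | quant$slice_index > n_slices)) {
      stop("slice indices outside 1..", n_slices)
    }
    m[cbind(match(quant$accession, accs), quant$slice_index)] <- quant$empai
  }
  m
}

#' Sum the profiles of a paralog (or subunit) group
#'
#' Element-wise sum of member profiles, e.g. merging two paralogous subunits
#' that share a role in a complex into one trace.
#'
#' @param profiles Profile matrix from [build_profiles()].
#' @param members Nonempty character vector of row names to sum.
#' @param label Label for the aggregated profile.
#' @return Named numeric vector of length S; `names(attr(,"label"))` not
#'   used, the label is attached as attribute `"label"`.
#' @export
aggregate_group <- function(profiles, members, label) {
  stopifnot(is.matrix(profiles))
  if (length(members) == 0L) stop("`members` must be nonempty")
  missing <- setdiff(members, rownames(profiles))
  if (length(missing) > 0L) {
    stop("unknown member accession(s): ", paste(missing, collapse = ", "))
  }
  v <- colSums(profiles[members, , drop = FALSE])
  attr(v, "label") <- label
  v
}

#' Replace paralog groups by their aggregated profiles
#'
#' Convenience wrapper around [aggregate_group()]: drops the member rows and
#' adds one aggregate row per group.
#'
#' @param profiles Profile matrix.
#' @param groups Named list; each element is a character vector of member
#'   accessions, the element name is the aggregate label.
#' @return A new profile matrix.
#' @export
aggregate_groups <- function(profiles, groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  drop_rows <- unique(unlist(groups))
  agg <- t(vapply(names(groups), function(lab) {
    as.numeric(aggregate_group(profiles, groups[[lab]], lab))
  }, numeric(ncol(profiles))))
  rownames(agg) <- names(groups)
  colnames(agg) <- colnames(profiles)
  out <- rbind(profiles[setdiff(rownames(profiles), drop_rows), , drop = FALSE],
               agg)
  out[order(rownames(out)), , drop = FALSE]
}

#' Detect peaks in a migration profile
#'
#' Finds local maxima of the profile vector. A slice is an apex if its value
#' exceeds the nearest differing neighbours on both sides (profile ends count
#' as minus infinity, so boundary slices are eligible); runs of equal values
#' (plateaus) are merged into one peak whose apex is the topmost (leftmost)
#' plateau slice. Apexes below `max(min_value, rel_height * max(profile))`
#' are discarded. Peak support extends from the apex to the nearest slice
#' whose value drops below 50% of the apex or to a local minimum, whichever
#' comes first; supports of neighbouring peaks are trimmed at the
#' inter-apex minimum so reported intervals are disjoint.
#'
#' @param profile Numeric vector of nonnegative emPAI values (one per slice),
#'   or a single row of a profile matrix.
#' @param rel_height Minimum apex height as a fraction of the profile
#'   maximum, in (0, 1] (default 0.1).
#' @param min_value Absolute minimum apex height in emPAI units (default
#'   0.01); suppresses one-peptide trailing noise.
#' @return A data.frame with columns `apex_slice`, `left_slice`,
#'   `right_slice`, `apex_value`, sorted by apex; zero rows for an all-zero
#'   profile.
#' @export
detect_peaks <- function(profile, rel_height = 0.1, min_value = 0.01) {
  v <- as.numeric(profile)
  if (length(v) == 0L || any(is.na(v)) || any(v < 0)) {
    stop("`profile` must be a nonnegative numeric vector")
  }
  if (!is.numeric(rel_height) || rel_height <= 0 || rel_height > 1) {
    stop("`rel_height` must be in (0, 1]")
  }
  empty <- data.frame(apex_slice = integer(0), left_slice = integer(0),
                      right_slice = integer(0), apex_value = numeric(0))
  if (all(v == 0)) return(empty)
  thr <- max(min_value, rel_height * max(v))

  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  apex <- integer(0); aval <- numeric(0)
  for (i in seq_len(nr)) {
    left <- if (i == 1L) -Inf else r$values[i - 1L]
    right <- if (i == nr) -Inf else r$values[i + 1L]
    if (r$values[i] > left && r$values[i] > right &&
        r$values[i] > 0 && r$values[i] >= thr) {
      apex <- c(apex, starts[i])   # plateau apex at the top of the gel
      aval <- c(aval, r$values[i])
    }
  }
  if (length(apex) == 0L) return(empty)

  n <- length(v)
  lefts <- integer(length(apex)); rights <- integer(length(apex))
  for (p in seq_along(apex)) {
    a <- apex[p]; h <- aval[p]
    l <- a
    while (l > 1L) {
      if (v[l] < 0.5 * h) break          # fell below half height
      if (v[l - 1L] > v[l]) break        # l is a local minimum
      l <- l - 1L
    }
    r_ <- a
    while (r_ < n) {
      if (v[r_] < 0.5 * h) break
      if (v[r_ + 1L] > v[r_]) break
      r_ <- r_ + 1L
    }
    lefts[p] <- l; rights[p] <- r_
  }
  # trim overlapping supports at the inter-apex minimum (valley goes with the
  # upper peak, deterministically)
  if (length(apex) > 1L) {
    for (p in seq_len(length(apex) - 1L)) {
      if (rights[p] >= lefts[p + 1L]) {
        between <- apex[p]:apex[p + 1L]
        valley <- between[which.min(v[between])]
        rights[p] <- min(rights[p], valley)
        lefts[p + 1L] <- max(lefts[p + 1L], valley + 1L)
      }
    }
  }
  data.frame(apex_slice = apex, left_slice = lefts, right_slice = rights,
             apex_value = aval)
}

#' Detect peaks for every profile in a matrix
#'
#' @param profiles Profile matrix from [build_profiles()].
#' @inheritParams detect_peaks
#' @return A data.frame with an `accession` column prepended to the
#'   [detect_peaks()] columns; proteins without peaks contribute no rows.
#' @export
detect_peaks_all <- function(profiles, rel_height = 0.1, min_value = 0.01) {
  stopifnot(is.matrix(profiles))
  out <- lapply(rownames(profiles), function(acc) {
    pk <- detect_peaks(profiles[acc, ], rel_height, min_value)
    if (nrow(pk) == 0L) return(NULL)
    cbind(data.frame(accession = acc, stringsAsFactors = FALSE), pk)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(accession = character(0), apex_slice = integer(0),
                      left_slice = integer(0), right_slice = integer(0),
                      apex_value = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Fit a log-linear mass calibration curve
#'
#' Least-squares fit of `log10(mass_kda) = slope * slice + intercept` on
#' marker proteins of known native mass. Because slices are cut at regular
#' intervals, slice index is a linear proxy for migration distance, and
#' native gel migration is approximately log-linear in mass.
#'
#' @param markers Data.frame with columns `slice_index`, `mass_kda`
#'   (see [read_marker_table()]); at least two markers with distinct slices
#'   and positive masses.
#' @return An object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `marker_count`, `residuals` (per-marker, in log10 kDa),
#'   `slice_range`.
#' @export
fit_calibration <- function(markers) {
  stopifnot(is.data.frame(markers),
            all(c("slice_index", "mass_kda") %in% names(markers)))
  if (nrow(markers) < 2L || length(unique(markers$slice_index)) < 2L) {
    stop("need at least 2 markers with distinct slice indices")
  }
  if (any(markers$mass_kda <= 0)) stop("marker masses must be positive")
  fit <- stats::lm(log10(mass_kda) ~ slice_index, data = markers)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) {
    warning("calibration slope is nonnegative; mass should decrease down the gel")
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 marker_count = nrow(markers),
                 residuals = unname(stats::residuals(fit)),
                 slice_range = range(markers$slice_index)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Mass calibration: log10(kDa) = ", format(x$slope, digits = 4),
      " * slice + ", format(x$intercept, digits = 4),
      "  (", x$marker_count, " markers, RMS residual ",
      format(sqrt(mean(x$residuals^2)), digits = 3), " log10 kDa)\n",
      sep = "")
  invisible(x)
}

#' Estimate the native mass of a complex from its peak position
#'
#' @param apex_slice Integer vector of peak apex slices.
#' @param curve A [fit_calibration()] curve.
#' @return Numeric vector of masses in kDa (`10^(slope * slice +
#'   intercept)`), with a logical attribute `"extrapolated"` flagging apexes
#'   outside the marker slice range.
#' @export
estimate_complex_mass <- function(apex_slice, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  mass <- 10^(curve$slope * apex_slice + curve$intercept)
  attr(mass, "extrapolated") <-
    apex_slice < curve$slice_range[1L] | apex_slice > curve$slice_range[2L]
  mass
}

#' Annotate a peak table with estimated complex masses
#'
#' @param peaks Peak data.frame from [detect_peaks_all()].
#' @param curve A [fit_calibration()] curve.
#' @return `peaks` with added columns `est_mass_kda` and `extrapolated`.
#' @export
annotate_peak_masses <- function(peaks, curve) {
  m <- estimate_complex_mass(peaks$apex_slice, curve)
  peaks$est_mass_kda <- as.numeric(m)
  peaks$extrapolated <- attr(m, "extrapolated")
  peaks
}
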