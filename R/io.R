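# Readers and writers for the external formats: FASTA proteome, per-slice
# peptide-identification TSV, annotation TSV, and mass-marker TSV. All TSVs
# are tab-separated UTF-8 with a mandatory header row; "." or an empty field
# means a missing optional value.

MISSING_FIELD <- "."

#' Read a proteome from a FASTA file
#'
#' Parses an amino-acid FASTA file into a protein table. The accession is the
#' first whitespace-delimited token of each header; the remainder of the
#' header becomes the description. Sequences are uppercased. Nonstandard
#' residue letters (B, J, O, U, X, Z) are retained in the sequence; peptides
#' containing them are later excluded from observable-peptide counting
#' because their mass is undefined.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `accession`, `sequence`, `description`,
#'   one row per FASTA entry (zero rows for an empty file).
#' @seealso [write_fasta()], [count_observable_peptides()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  seq_line <- !startsWith(lines, ">")
  bad <- which(seq_line & grepl("[^A-Za-z[:space:]]", lines))
  if (length(bad) > 0L) {
    stop("malformed FASTA in '", path, "': invalid sequence character at line ",
         bad[1L], call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    return(data.frame(accession = character(0), sequence = character(0),
                      description = character(0), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (any(accession == "")) stop("FASTA entry with empty header in ", path)
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0L) {
    stop("duplicate accession(s) in '", path, "': ",
         paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("zero-length sequence for accession(s): ",
         paste(accession[nchar(seqs) == 0L], collapse = ", "))
  }
  allowed <- c(STANDARD_AA, NONSTANDARD_AA)
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "", fixed = TRUE)[[1L]] %in% allowed)
  }, logical(1L), USE.NAMES = FALSE)
  if (any(bad)) {
    stop("sequence with non-amino-acid characters for accession(s): ",
         paste(accession[bad], collapse = ", "))
  }
  data.frame(accession = accession, sequence = unname(seqs),
             description = unname(description), stringsAsFactors = FALSE)
}

#' Write a proteome table to FASTA
#'
#' @param proteome A data.frame as returned by [read_fasta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(is.data.frame(proteome),
            all(c("accession", "sequence") %in% names(proteome)))
  desc <- if ("description" %in% names(proteome)) proteome$description else ""
  headers <- ifelse(is.na(desc) | desc == "", proteome$accession,
                    paste(proteome$accession, desc))
  set <- Biostrings::AAStringSet(proteome$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a per-slice peptide-identification table
#'
#' Reads the tab-separated table of peptide identifications (one row per
#' identified peptide per gel slice per protein) that stands in for per-slice
#' search-engine output. Mandatory columns: `slice_index`, `accession`,
#' `peptide`; optional: `score` (nonnegative real), `charge` (1, 2 or 3).
#' Peptide strings are uppercased on ingest.
#'
#' Rows failing validation (slice index outside `1..n_slices`, non-integer
#' slice, empty peptide, out-of-range charge or score) are rejected with
#' their row numbers. With `strict = TRUE` (default) any rejected row is an
#' error; with `strict = FALSE` rejected rows are dropped with a warning and
#' reported in the `"rejected"` attribute, so that accepted + rejected always
#' accounts for every input row.
#'
#' @param path Path to the TSV file.
#' @param n_slices Total number of gel slices S; slice indices are 1-based
#'   from the top of the gel.
#' @param strict Error on invalid rows (default) instead of dropping them.
#' @return A data.frame with columns `slice_index` (integer), `accession`,
#'   `peptide`, `score` (numeric, NA if absent), `charge` (integer, NA if
#'   absent). Attribute `"rejected"` holds the rejected row numbers.
#' @export
read_peptide_table <- function(path, n_slices, strict = TRUE) {
  stop_if_not_scalar_count(n_slices, "n_slices")
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE)
  required <- c("slice_index", "accession", "peptide")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("peptide table '", path, "' is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  slice <- suppressWarnings(as.numeric(raw$slice_index))
  peptide <- toupper(trimws(raw$peptide))
  accession <- trimws(raw$accession)
  score <- rep(NA_real_, n)
  if ("score" %in% names(raw)) {
    has <- !(raw$score %in% c("", MISSING_FIELD))
    score[has] <- suppressWarnings(as.numeric(raw$score[has]))
  }
  charge <- rep(NA_integer_, n)
  if ("charge" %in% names(raw)) {
    has <- !(raw$charge %in% c("", MISSING_FIELD))
    charge[has] <- suppressWarnings(as.integer(raw$charge[has]))
  }

  bad_slice <- is.na(slice) | slice != floor(slice) | slice < 1 | slice > n_slices
  bad_pep <- accession == "" | peptide == "" |
    !grepl("^[A-Z]+$", peptide)
  bad_opt <- (!is.na(score) & score < 0) | (!is.na(charge) & !charge %in% 1:3)
  bad <- which(bad_slice | bad_pep | bad_opt)
  if (length(bad) > 0L) {
    msg <- paste0("invalid peptide row(s) at line(s) ",
                  paste(utils::head(bad, 20L), collapse = ", "),
                  if (length(bad) > 20L) ", ..." else "",
                  " (slice index outside 1..", n_slices,
                  ", malformed peptide/accession, or bad optional field)")
    if (strict) stop(msg) else warning(msg)
  }
  keep <- setdiff(seq_len(n), bad)
  out <- data.frame(slice_index = as.integer(slice[keep]),
                    accession = accession[keep],
                    peptide = peptide[keep],
                    score = score[keep],
                    charge = charge[keep],
                    stringsAsFactors = FALSE)
  attr(out, "rejected") <- bad
  out
}

#' Write a peptide-identification table as TSV
#'
#' Inverse of [read_peptide_table()]; missing optional values are written
#' as ".".
#'
#' @param ids Peptide-identification data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(ids, path) {
  out <- ids[, c("slice_index", "accession", "peptide", "score", "charge")]
  out$score <- ifelse(is.na(out$score), MISSING_FIELD,
                      format(out$score, trim = TRUE))
  out$charge <- ifelse(is.na(out$charge), MISSING_FIELD,
                       as.character(out$charge))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein annotation table
#'
#' Reads a TSV with columns `accession`, `localization`, `category`.
#' Localization must be one of thylakoid, envelope, stroma, other, unknown
#' (case-insensitive); any other string is mapped to `"unknown"` with a
#' warning, so foreign vocabularies degrade gracefully rather than fail.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `accession`, `localization` (factor over
#'   the five levels), `category`.
#' @export
read_annotation_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE)
  required <- c("accession", "localization", "category")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("annotation table '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(data.frame(accession = character(0),
                      localization = factor(character(0),
                                            levels = LOCALIZATION_LEVELS),
                      category = character(0), stringsAsFactors = FALSE))
  }
  accession <- trimws(raw$accession)
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0L) {
    stop("duplicate accession(s) in annotation table: ",
         paste(dup, collapse = ", "))
  }
  loc <- tolower(trimws(raw$localization))
  unknown <- !loc %in% LOCALIZATION_LEVELS
  if (any(unknown)) {
    warning("unrecognized localization value(s) mapped to \"unknown\": ",
            paste(unique(loc[unknown]), collapse = ", "))
    loc[unknown] <- "unknown"
  }
  data.frame(accession = accession,
             localization = factor(loc, levels = LOCALIZATION_LEVELS),
             category = raw$category, stringsAsFactors = FALSE)
}

#' Read a mass-calibration marker table
#'
#' Markers map gel slice indices to known native masses (kDa) and feed the
#' log-linear calibration fit of [fit_calibration()].
#'
#' @param path TSV with columns `slice_index`, `mass_kda`.
#' @return A data.frame with integer `slice_index` and numeric `mass_kda`.
#' @export
read_marker_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("slice_index", "mass_kda")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("marker table '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  slice <- suppressWarnings(as.numeric(raw$slice_index))
  mass <- suppressWarnings(as.numeric(raw$mass_kda))
  if (any(is.na(slice)) || any(is.na(mass)) || any(slice != floor(slice))) {
    stop("marker table has non-numeric or non-integer-slice rows")
  }
  data.frame(slice_index = as.integer(slice), mass_kda = mass,
             stringsAsFactors = FALSE)
}
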