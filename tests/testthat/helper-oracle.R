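# Independent brute-force reference implementations used as oracles. These
# deliberately share no code with the package: naive enumeration over all
# fragment pairs, a separately transcribed residue-mass table, and a direct
# positional scan for local maxima.

ORACLE_AA_MASS <- c(
  A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
  T = 101.047679, W = 186.079313, Y = 163.063329, V = 99.068414
)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.007276
ORACLE_CAM <- 57.021464

# Enumerate every tryptic peptide with <= max_missed missed cleavages by
# taking all pairs of cleavage boundaries.
oracle_cleave <- function(seq, max_missed = 0L, proline_rule = TRUE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  sites <- integer(0)
  for (i in seq_len(max(0L, n - 1L))) {
    if (chars[i] %in% c("K", "R")) {
      if (!proline_rule || chars[i + 1L] != "P") sites <- c(sites, i)
    }
  }
  b <- c(0L, sites, n)
  rows <- list()
  for (i in seq_len(length(b) - 1L)) {
    for (j in (i + 1L):length(b)) {
      m <- j - i - 1L
      if (m > max_missed) next
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = substr(seq, b[i] + 1L, b[j]),
        start = b[i] + 1L, end = b[j], missed_cleavages = m,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

oracle_mass <- function(pep, cam = TRUE) {
  res <- strsplit(pep, "", fixed = TRUE)[[1L]]
  if (length(res) == 0L || any(!res %in% names(ORACLE_AA_MASS))) return(NA_real_)
  m <- sum(ORACLE_AA_MASS[res]) + ORACLE_WATER
  if (cam) m <- m + ORACLE_CAM * sum(res == "C")
  m
}

oracle_observable_count <- function(seq, mz_min = 450, mz_max = 1800,
                                    charges = 1:3, max_missed = 0L,
                                    proline_rule = TRUE, cam = TRUE) {
  peps <- unique(oracle_cleave(seq, max_missed, proline_rule)$peptide)
  ok <- 0L
  for (p in peps) {
    m <- oracle_mass(p, cam)
    if (is.na(m)) next
    for (z in charges) {
      mz <- (m + z * ORACLE_PROTON) / z
      if (mz >= mz_min && mz <= mz_max) { ok <- ok + 1L; break }
    }
  }
  ok
}

# Direct scan for plateau-merged local maxima: slice s is an apex when it
# starts a run whose value beats the nearest differing value on both sides
# (vector ends count as -Inf) and clears the height thresholds.
oracle_local_maxima <- function(v, rel_height = 0.1, min_value = 0.01) {
  n <- length(v)
  if (all(v == 0)) return(integer(0))
  thr <- max(min_value, rel_height * max(v))
  apexes <- integer(0)
  for (s in seq_len(n)) {
    if (s > 1L && v[s] == v[s - 1L]) next  # not the leftmost of its run
    i <- s - 1L
    left <- -Inf
    if (i >= 1L) left <- v[i]
    j <- s
    while (j < n && v[j + 1L] == v[s]) j <- j + 1L
    right <- if (j == n) -Inf else v[j + 1L]
    if (v[s] > left && v[s] > right && v[s] > 0 && v[s] >= thr) {
      apexes <- c(apexes, s)
    }
  }
  apexes
}

random_protein <- function(len, letters = names(ORACLE_AA_MASS)) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}
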