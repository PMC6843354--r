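# Independent oracles and fixture builders, deliberately avoiding the
# package's elemental-composition route.

# literature (Unimod) residue monoisotopic masses, summed directly
ORACLE_AA <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764, V = 99.068414,
  T = 101.047679, C = 103.009185, L = 113.084064, I = 113.084064,
  N = 114.042927, D = 115.026943, Q = 128.058578, K = 128.094963,
  E = 129.042593, M = 131.040485, H = 137.058912, F = 147.068414,
  R = 156.101111, Y = 163.063329, W = 186.079313
)
ORACLE_WATER <- 18.0105646
ORACLE_HPO3 <- 79.96633

oracle_peptide_mass <- function(seq) {
  sum(ORACLE_AA[strsplit(seq, "")[[1]]]) + ORACLE_WATER
}

# literature 2'-deoxynucleoside-5'-monophosphate masses
ORACLE_DNMP <- c(A = 331.068170, C = 307.056937, G = 347.063084, T = 322.056608)

# 5'-phosphate/3'-OH chain = sum(dNMP) - (n-1) waters; strip HPO3 for 5'-OH
oracle_oligo_mass <- function(seq, p5 = "OH", p3 = "OH") {
  nt <- strsplit(seq, "")[[1]]
  m <- sum(ORACLE_DNMP[nt]) - (length(nt) - 1) * ORACLE_WATER - ORACLE_HPO3
  if (p5 == "phosphate") m <- m + ORACLE_HPO3
  if (p3 == "phosphate") m <- m + ORACLE_HPO3
  m
}

# brute-force trypsin: scan every bond, cut after K/R unless next is P,
# then enumerate all runs of <= k+1 consecutive fragments
oracle_trypsin <- function(seq, missed = 0) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  cuts <- integer(0)
  for (i in seq_len(n - 1)) {
    if (res[i] %in% c("K", "R") && res[i + 1] != "P") cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  out <- list()
  for (k in 0:missed) {
    for (i in seq_len(length(starts) - k)) {
      if (i + k > length(ends)) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(res[starts[i]:ends[i + k]], collapse = ""),
        start = starts[i], end = ends[i + k], missed = k,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# brute-force all-pairs ppm scan over a candidate library
oracle_match <- function(peaks, lib, ppm_tol) {
  hits <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(lib))) {
      ppm <- (peaks$mass[i] - lib$mass[j]) / lib$mass[j] * 1e6
      if (abs(ppm) <= ppm_tol) {
        hits[[length(hits) + 1L]] <- data.frame(peak = i, lib = j, ppm = ppm)
      }
    }
  }
  if (length(hits) == 0) return(data.frame(peak = integer(0), lib = integer(0)))
  do.call(rbind, hits)
}

random_peptide <- function(len) {
  paste(sample(names(ORACLE_AA), len, replace = TRUE), collapse = "")
}

random_oligo <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# the duplex strands used throughout (construct inputs, 5'->3')
DBE_FORWARD <- "TTGGGTAAACAAG"
DBE_REVERSE <- "CTTGTTTACCCAA"

# minimal synthetic structure on disk: Calpha trace at given coordinates
write_ca_pdb <- function(coords, sequence, path, start_pos = 1L, dna = NULL) {
  write_fold_pdb(coords, sequence, path, start_pos = start_pos, dna = dna)
}
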