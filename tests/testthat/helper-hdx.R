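# Designed proline-free construct numbered from residue 74, with a peptide
# pool whose boundaries resolve the 103-130 protection window exactly.
HDX_PROTEIN <- paste(rep("ACDEFGHIKLMNQRSTVWY", 5), collapse = "")
HDX_START <- 74L

hdx_pool <- function() {
  b <- data.frame(start = c(90L, 90L, 103L, 103L, 131L, 151L),
                  end = c(102L, 130L, 130L, 140L, 150L, 163L))
  b$sequence <- substr(rep(HDX_PROTEIN, nrow(b)),
                       b$start - HDX_START + 1L, b$end - HDX_START + 1L)
  b$mass <- vapply(b$sequence, peptide_mass, numeric(1), USE.NAMES = FALSE)
  b
}

hdx_pf <- function(window = 103:130, factor = 100) {
  n <- nchar(HDX_PROTEIN)
  free <- rep(100, n)
  complex <- free
  idx <- window - HDX_START + 1L
  complex[idx] <- complex[idx] * factor
  list(free = free, complex = complex)
}
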