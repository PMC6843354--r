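#' Digest configuration
#'
#' @param missed Maximum missed cleavages for trypsin (default 2).
#' @param min_length,max_length Peptide length bounds.
#' @param min_oligo_length Minimum oligonucleotide fragment length.
#' @param bal31_model Fragment model for the nuclease: `"substring"`
#'   (all contiguous subsequences, the permissive default) or
#'   `"truncation"` (end-truncations only, the strict exonuclease picture).
#' @return A list of class `digest_config`.
#' @export
digest_config <- function(missed = 2L, min_length = 1L, max_length = Inf,
                          min_oligo_length = 1L,
                          bal31_model = c("substring", "truncation")) {
  bal31_model <- match.arg(bal31_model)
  stopifnot(missed >= 0, min_length >= 0, min_length <= max_length,
            min_oligo_length >= 0)
  structure(
    list(missed = as.integer(missed), min_length = min_length,
         max_length = max_length, min_oligo_length = min_oligo_length,
         bal31_model = bal31_model),
    class = "digest_config"
  )
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R, suppressed when the next residue is proline.
#' Peptides are generated for 0 up to `cfg$missed` missed cleavages, with
#' 1-based inclusive positions and neutral monoisotopic masses.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param cfg A [digest_config()].
#' @param start_pos Construct-numbering position of the first residue.
#' @return Data frame with columns `sequence`, `start`, `end`, `missed`,
#'   `mass`.
#' @examples
#' trypsin_digest("AKRPGK", digest_config(missed = 1))
#' @export
trypsin_digest <- function(sequence, cfg = digest_config(), start_pos = 1L) {
  stopifnot(inherits(cfg, "digest_config"))
  if (!is.character(sequence) || nchar(sequence) == 0) {
    stop("protein sequence must be non-empty")
  }
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), names(.AA_COMP))
  if (length(bad) > 0) {
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  }
  n <- length(res)
  # cleavage sites: after position i when res[i] in K/R and res[i+1] != P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!(n %in% cut_after)) n)
  bounds <- unique(bounds)
  nseg <- length(bounds) - 1L
  out <- list()
  for (k in 0:min(cfg$missed, nseg - 1L)) {
    for (i in seq_len(nseg - k)) {
      s <- bounds[i] + 1L
      e <- bounds[i + 1L + k]
      len <- e - s + 1L
      if (len < cfg$min_length || len > cfg$max_length) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(res[s:e], collapse = ""),
        start = s + start_pos - 1L, end = e + start_pos - 1L,
        missed = k, stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$missed, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab$mass <- vapply(tab$sequence, function(s) peptide_mass(s), numeric(1),
                     USE.NAMES = FALSE)
  tab
}

#' Nuclease fragment enumeration (Bal-31 model)
#'
#' Under the default substring model every contiguous subsequence of length
#' at least `cfg$min_oligo_length` is produced (a deliberate superset of the
#' exonuclease's products, so that library matching cannot miss a true
#' conjugate); the truncation model keeps only fragments that retain at
#' least one original strand terminus.
#'
#' @param strand DNA string (the intact strand).
#' @param cfg A [digest_config()].
#' @param strand_label `"forward"` or `"reverse"`.
#' @param p5,p3 Terminus chemistry given to every fragment.
#' @return Data frame with columns `sequence`, `start`, `end`, `length`,
#'   `mass`. Empty when no fragment reaches the minimum length.
#' @examples
#' nrow(bal31_fragments("ACGTT", digest_config(min_oligo_length = 3))) # 6
#' @export
bal31_fragments <- function(strand, cfg = digest_config(),
                            strand_label = c("forward", "reverse"),
                            p5 = "OH", p3 = "OH") {
  stopifnot(inherits(cfg, "digest_config"))
  strand_label <- match.arg(strand_label)
  n <- nchar(strand)
  m <- cfg$min_oligo_length
  out <- list()
  if (m <= n && m >= 1) {
    for (s in 1:(n - m + 1)) {
      for (e in (s + m - 1):n) {
        if (cfg$bal31_model == "truncation" && !(s == 1 || e == n)) next
        out[[length(out) + 1L]] <- data.frame(
          sequence = substr(strand, s, e), start = s, end = e,
          length = e - s + 1L, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sequence = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), mass = numeric(0)))
  }
  tab <- do.call(rbind, out)
  tab$strand <- strand_label
  tab$mass <- vapply(tab$sequence, function(s) {
    oligo_mass(oligo_species(s, strand = strand_label, p5 = p5, p3 = p3))
  }, numeric(1), USE.NAMES = FALSE)
  tab[, c("sequence", "strand", "start", "end", "length", "mass")]
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Anneal two DNA strands
#'
#' Finds the ungapped alignment of the forward strand against the reverse
#' complement of the reverse strand that maximizes Watson-Crick paired
#' positions (antiparallel pairing), and reports the pair count.
#'
#' @param forward,reverse DNA strings, both written 5' to 3'.
#' @return A list of class `duplex_record`: `forward`, `reverse`, `offset`
#'   (shift of the reverse complement relative to the forward strand) and
#'   `bp` (paired-position count).
#' @examples
#' anneal("TTGGGTAAACAAG", "CTTGTTTACCCAA")$bp # 13
#' @export
anneal <- function(forward, reverse) {
  f <- strsplit(toupper(forward), "")[[1]]
  rc <- strsplit(.revcomp(toupper(reverse)), "")[[1]]
  nf <- length(f); nr <- length(rc)
  best_bp <- 0L; best_off <- 0L
  for (off in seq(-(nr - 1L), nf - 1L)) {
    i <- seq_len(nf)
    j <- i - off
    ok <- j >= 1 & j <= nr
    bp <- sum(f[i[ok]] == rc[j[ok]])
    if (bp > best_bp) { best_bp <- bp; best_off <- off }
  }
  structure(
    list(forward = forward, reverse = reverse,
         offset = best_off, bp = as.integer(best_bp)),
    class = "duplex_record"
  )
}

#' @export
print.duplex_record <- function(x, ...) {
  cat(sprintf("<duplex: %d bp (offset %d)>\n", x$bp, x$offset))
  invisible(x)
}

#' Locate a motif on a strand
#'
#' Exact, overlapping occurrences of `motif` on the strand as written; set
#' `revcomp = TRUE` to also scan the reverse complement (positions still
#' reported on the given strand).
#'
#' @param strand,motif DNA strings.
#' @param revcomp Also search the reverse complement of the motif.
#' @return Integer vector of 1-based start positions (possibly empty).
#' @examples
#' find_motif("CTTGTTTACCCAA", "TTGTTTAC") # 2
#' @export
find_motif <- function(strand, motif, revcomp = FALSE) {
  if (nchar(motif) == 0) stop("motif must be non-empty")
  if (nchar(motif) > nchar(strand)) return(integer(0))
  hit <- function(m) {
    v <- Biostrings::matchPattern(m, Biostrings::DNAString(strand))
    BiocGenerics::start(v)
  }
  pos <- hit(motif)
  if (revcomp) pos <- sort(unique(c(pos, hit(.revcomp(motif)))))
  as.integer(pos)
}

#' Peptide-map coverage statistics
#'
#' Per-residue identification depth, percent coverage, and mean redundancy
#' of a peptide set over a protein sequence.
#'
#' @param peptides Data frame with `start` and `end` columns (construct
#'   numbering), e.g. a [trypsin_digest()] table.
#' @param sequence Protein sequence covered.
#' @param start_pos Construct-numbering position of the first residue.
#' @return List with `depth` (integer vector, one per residue),
#'   `coverage` (percent of residues with depth >= 1) and `redundancy`
#'   (mean depth).
#' @export
coverage_map <- function(peptides, sequence, start_pos = 1L) {
  n <- nchar(sequence)
  depth <- integer(n)
  for (i in seq_len(nrow(peptides))) {
    s <- peptides$start[i] - start_pos + 1L
    e <- peptides$end[i] - start_pos + 1L
    if (s < 1 || e > n || s > e) {
      stop("peptide out of sequence bounds: ",
           peptides$sequence[i] %||% paste0(peptides$start[i], "-", peptides$end[i]))
    }
    depth[s:e] <- depth[s:e] + 1L
  }
  list(depth = depth,
       coverage = 100 * sum(depth >= 1) / n,
       redundancy = mean(depth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param type `"protein"` or `"dna"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  set <- if (type == "protein") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}

#' Write a digest table to TSV
#'
#' @param tab Digest data frame ([trypsin_digest()] or [bal31_fragments()]).
#' @param path Output path.
#' @export
write_digest_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
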