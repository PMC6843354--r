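# Reactive-site enumeration.
#
# NHS-ester linkers target lysine and serine side chains plus the protein
# N-terminal amine; the N-terminus only counts for the peptide that carries
# it. Pt adducts target electron-rich side chains (Cys, Met, His, Thr by
# default) and, on DNA, guanine (N7).

nhs_sites <- function(sequence, start, classes, protein_start) {
  res <- strsplit(sequence, "")[[1]]
  pos <- start + which(res %in% setdiff(classes, "nterm")) - 1L
  lab <- res[pos - start + 1L]
  if ("nterm" %in% classes && start == protein_start) {
    pos <- c(start, pos)
    lab <- c("nterm", lab)
  }
  data.frame(pos = as.integer(pos), site = lab, stringsAsFactors = FALSE)
}

pt_protein_sites <- function(sequence, start, adduct, protein_start, protein_end) {
  res <- strsplit(sequence, "")[[1]]
  pos <- start + which(res %in% adduct$protein_reactive) - 1L
  lab <- res[pos - start + 1L]
  if (isTRUE(adduct$include_termini)) {
    e <- start + length(res) - 1L
    if (start == protein_start) { pos <- c(start, pos); lab <- c("nterm", lab) }
    if (e == protein_end) { pos <- c(pos, e); lab <- c(lab, "cterm") }
  }
  data.frame(pos = as.integer(pos), site = lab, stringsAsFactors = FALSE)
}

pt_dna_sites <- function(sequence, start, adduct) {
  nt <- strsplit(sequence, "")[[1]]
  pos <- start + which(nt == adduct$dna_reactive) - 1L
  data.frame(pos = as.integer(pos), site = rep(adduct$dna_reactive, length(pos)),
             stringsAsFactors = FALSE)
}

.site_string <- function(sites) paste(paste0(sites$site, sites$pos), collapse = ",")

.empty_library <- function() {
  data.frame(type = character(0), linker = character(0), form = character(0),
             seq1 = character(0), start1 = integer(0), end1 = integer(0),
             seq2 = character(0), strand2 = character(0), start2 = integer(0),
             end2 = integer(0), sites1 = character(0), sites2 = character(0),
             n_components = integer(0), mass = numeric(0),
             stringsAsFactors = FALSE)
}

.lib_row <- function(type, linker, form, seq1, start1, end1, sites1, mass,
                     seq2 = NA_character_, strand2 = NA_character_,
                     start2 = NA_integer_, end2 = NA_integer_,
                     sites2 = NA_character_, n_components = 1L) {
  data.frame(type = type, linker = linker, form = form,
             seq1 = seq1, start1 = start1, end1 = end1,
             seq2 = seq2, strand2 = strand2, start2 = start2, end2 = end2,
             sites1 = sites1, sites2 = sites2,
             n_components = n_components, mass = mass, stringsAsFactors = FALSE)
}

#' Build the theoretical cross-linked species library
#'
#' Enumerates all type-valid candidate conjugates whose components carry the
#' required reactive sites: inter-peptide cross-links, intra-peptide loop
#' links, hydrolyzed mono-links (each in both isotope forms when the linker
#' has a heavy form), and peptide-DNA conjugates bridged by a bifunctional
#' Pt adduct. Candidates are deduplicated by type, components and linker
#' form.
#'
#' @param peptides Digest table ([trypsin_digest()]): columns `sequence`,
#'   `start`, `end`, `mass`.
#' @param oligos Optional nuclease fragment table ([bal31_fragments()]):
#'   columns `sequence`, `strand`, `start`, `end`, `mass`.
#' @param linkers List of [crosslinker()] objects (default [xl_linkers()]).
#' @param pt Optional [pt_adduct()] enabling peptide-DNA candidates.
#' @param types Candidate types to generate.
#' @param protein_start Construct-numbering position of the protein
#'   N-terminus (defines which peptide carries the N-terminal amine).
#' @param protein_end Position of the protein C-terminus (used only when the
#'   Pt adduct is configured to treat termini as reactive).
#' @return Candidate data frame (one row per candidate); zero rows, with a
#'   warning, when no component carries a reactive site.
#' @export
build_library <- function(peptides, oligos = NULL, linkers = xl_linkers(),
                          pt = NULL,
                          types = c("inter", "loop", "mono", "peptide_dna"),
                          protein_start = min(peptides$start),
                          protein_end = max(peptides$end)) {
  types <- match.arg(types, several.ok = TRUE)
  if (length(linkers) == 0 && is.null(pt)) stop("at least one linker is required")
  if (inherits(linkers, "crosslinker")) linkers <- list(linkers)
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  np <- nrow(peptides)
  for (lk in linkers) {
    forms <- if (is.null(lk$heavy)) "light" else c("light", "heavy")
    sites <- lapply(seq_len(np), function(i) {
      nhs_sites(peptides$sequence[i], peptides$start[i], lk$reactive, protein_start)
    })
    n_sites <- vapply(sites, nrow, integer(1))
    for (form in forms) {
      bd <- bridge_delta(lk, form)
      bd_mono <- bridge_delta(lk, paste0("mono_", form))
      if ("inter" %in% types && np >= 2) {
        for (i in seq_len(np - 1)) {
          if (n_sites[i] == 0) next
          for (j in (i + 1):np) {
            if (n_sites[j] == 0) next
            add(.lib_row("inter", lk$name, form,
                         peptides$sequence[i], peptides$start[i], peptides$end[i],
                         .site_string(sites[[i]]),
                         peptides$mass[i] + peptides$mass[j] + bd,
                         seq2 = peptides$sequence[j], start2 = peptides$start[j],
                         end2 = peptides$end[j], sites2 = .site_string(sites[[j]]),
                         n_components = 2L))
          }
        }
      }
      if ("loop" %in% types) {
        for (i in which(n_sites >= 2)) {
          add(.lib_row("loop", lk$name, form,
                       peptides$sequence[i], peptides$start[i], peptides$end[i],
                       .site_string(sites[[i]]), peptides$mass[i] + bd))
        }
      }
      if ("mono" %in% types) {
        for (i in which(n_sites >= 1)) {
          add(.lib_row("mono", lk$name, form,
                       peptides$sequence[i], peptides$start[i], peptides$end[i],
                       .site_string(sites[[i]]), peptides$mass[i] + bd_mono))
        }
      }
    }
  }

  if ("peptide_dna" %in% types && !is.null(pt) && !is.null(oligos) && nrow(oligos) > 0) {
    d_bi <- pt_delta(pt, "bifunctional")
    for (i in seq_len(np)) {
      ps <- pt_protein_sites(peptides$sequence[i], peptides$start[i], pt,
                             protein_start, protein_end)
      if (nrow(ps) == 0) next
      for (j in seq_len(nrow(oligos))) {
        ds <- pt_dna_sites(oligos$sequence[j], oligos$start[j], pt)
        if (nrow(ds) == 0) next
        add(.lib_row("peptide_dna", pt$name, "bifunctional",
                     peptides$sequence[i], peptides$start[i], peptides$end[i],
                     .site_string(ps),
                     peptides$mass[i] + oligos$mass[j] + d_bi,
                     seq2 = oligos$sequence[j], strand2 = oligos$strand[j],
                     start2 = oligos$start[j], end2 = oligos$end[j],
                     sites2 = .site_string(ds), n_components = 2L))
      }
    }
  }

  if (length(rows) == 0) {
    warning("no reactive sites found; library is empty")
    return(.empty_library())
  }
  lib <- do.call(rbind, rows)
  key <- with(lib, paste(type, linker, form, seq1, start1, seq2, strand2, start2))
  lib <- lib[!duplicated(key), , drop = FALSE]
  lib <- lib[order(lib$type, lib$linker, lib$form, lib$start1, lib$start2,
                   method = "radix"), , drop = FALSE]
  rownames(lib) <- NULL
  lib
}

#' Constant-unit peptide-DNA library
#'
#' Treats one designated oligonucleotide fragment plus a bifunctional Pt
#' equivalent as a fixed mass unit appended to every Pt-reactive peptide, so
#' that peptide-DNA conjugates can be sought without enumerating the full
#' oligonucleotide fragment space.
#'
#' @param peptides Digest table.
#' @param fixed_oligo An [oligo_species()] (or bare numeric mass) used as
#'   the constant unit.
#' @param pt A [pt_adduct()].
#' @param protein_start,protein_end Construct numbering bounds.
#' @return Candidate data frame of type `peptide_dna` (flagged
#'   `constant_unit = TRUE`), one row per peptide carrying at least one
#'   Pt-reactive site.
#' @export
constant_unit_library <- function(peptides, fixed_oligo, pt = pt_adduct(),
                                  protein_start = if (nrow(peptides)) min(peptides$start) else 1L,
                                  protein_end = if (nrow(peptides)) max(peptides$end) else 1L) {
  unit_mass <- species_mass(fixed_oligo) + pt_delta(pt, "bifunctional")
  is_oligo <- inherits(fixed_oligo, "oligo_species")
  rows <- list()
  for (i in seq_len(nrow(peptides))) {
    ps <- pt_protein_sites(peptides$sequence[i], peptides$start[i], pt,
                           protein_start, protein_end)
    if (nrow(ps) == 0) next
    r <- .lib_row("peptide_dna", pt$name, "bifunctional",
                  peptides$sequence[i], peptides$start[i], peptides$end[i],
                  .site_string(ps), peptides$mass[i] + unit_mass,
                  seq2 = if (is_oligo) fixed_oligo$sequence else NA_character_,
                  strand2 = if (is_oligo) fixed_oligo$strand else NA_character_,
                  start2 = if (is_oligo) fixed_oligo$start else NA_integer_,
                  end2 = if (is_oligo) fixed_oligo$end else NA_integer_,
                  sites2 = if (is_oligo)
                    .site_string(pt_dna_sites(fixed_oligo$sequence, fixed_oligo$start, pt))
                  else NA_character_,
                  n_components = 2L)
    rows[[length(rows) + 1L]] <- r
  }
  lib <- if (length(rows) == 0) .empty_library() else do.call(rbind, rows)
  lib$constant_unit <- rep(TRUE, nrow(lib))
  rownames(lib) <- NULL
  lib
}

#' Match deconvoluted masses against a candidate library
#'
#' Mass-only matching: each peak collects every candidate within the ppm
#' tolerance. Ambiguity is preserved; within a peak, matches are ranked by
#' absolute ppm error, then fewer components, then lexicographic component
#' order, so output tables are byte-stable.
#'
#' @param peaks Data frame with columns `mass` and (optionally)
#'   `intensity`.
#' @param library Candidate table from [build_library()] or
#'   [constant_unit_library()].
#' @param ppm_tol Tolerance in ppm (default 5, reflecting ~1 ppm calibrated
#'   accuracy with margin).
#' @return Identification data frame (`peak`, `observed`, `intensity`,
#'   candidate columns, `ppm`, `rank`, `ambiguity`); unmatched peaks are
#'   attached as `attr(, "unmatched")`.
#' @export
match_peaks <- function(peaks, library, ppm_tol = 5) {
  stopifnot(ppm_tol > 0)
  if (is.null(library) || nrow(library) == 0) stop("candidate library is empty")
  if (is.null(peaks$intensity)) peaks$intensity <- 1
  out <- list()
  matched <- logical(nrow(peaks))
  comp_key <- paste(library$seq1, library$seq2, library$strand2)
  for (i in seq_len(nrow(peaks))) {
    obs <- peaks$mass[i]
    ppm <- (obs - library$mass) / library$mass * 1e6
    hit <- which(abs(ppm) <= ppm_tol)
    if (length(hit) == 0) next
    matched[i] <- TRUE
    ord <- hit[order(abs(ppm[hit]), library$n_components[hit],
                     comp_key[hit], method = "radix")]
    o <- library[ord, , drop = FALSE]
    o$peak <- i
    o$observed <- obs
    o$intensity <- peaks$intensity[i]
    o$ppm <- ppm[ord]
    o$rank <- seq_along(ord)
    o$ambiguity <- length(ord)
    out[[length(out) + 1L]] <- o
  }
  res <- if (length(out) == 0) {
    cbind(.empty_library()[0, ],
          data.frame(peak = integer(0), observed = numeric(0),
                     intensity = numeric(0), ppm = numeric(0),
                     rank = integer(0), ambiguity = integer(0)))
  } else {
    do.call(rbind, out)
  }
  rownames(res) <- NULL
  front <- c("peak", "observed", "intensity")
  res <- res[, c(front, setdiff(names(res), front)), drop = FALSE]
  attr(res, "unmatched") <- peaks[!matched, , drop = FALSE]
  res
}

#' Site-localization status of identifications
#'
#' Pt-bridged peptide-DNA identifications are flagged composition-only:
#' gas-phase dissociation around the bridging Pt atom yields no backbone
#' fragments, so only component-level localization is claimed. NHS-ester
#' identifications are localized to their reactive-class residues; when a
#' component carries several candidate sites, all are listed and the
#' identification is marked ambiguous.
#'
#' @param ids Identification table from [match_peaks()].
#' @return The table with added `localization` column
#'   (`"composition-only"`, `"localized"`, `"ambiguous"`).
#' @export
site_localization_report <- function(ids) {
  n_sites <- function(s) {
    ifelse(is.na(s) | s == "", 0L,
           lengths(strsplit(as.character(s), ",", fixed = TRUE)))
  }
  loc <- character(nrow(ids))
  for (i in seq_len(nrow(ids))) {
    if (ids$type[i] == "peptide_dna") { loc[i] <- "composition-only"; next }
    k1 <- n_sites(ids$sites1[i])
    k2 <- if (ids$type[i] == "inter") n_sites(ids$sites2[i]) else 1L
    # a loop-link needs an ordered pair of distinct sites within one peptide
    if (ids$type[i] == "loop") k1 <- if (k1 == 2) 1L else k1
    loc[i] <- if (k1 == 1 && k2 == 1) "localized" else "ambiguous"
  }
  ids$localization <- loc
  ids
}

#' Write an identification table to TSV
#' @param ids Identification data frame.
#' @param path Output path.
#' @export
write_identifications_tsv <- function(ids, path) {
  utils::write.table(ids, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
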