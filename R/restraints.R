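.restraint_cols <- c("group", "member", "chain_a", "res_a", "atom_a",
                     "chain_b", "res_b", "atom_b", "span", "tol",
                     "linker", "type")

.empty_restraints <- function() {
  data.frame(group = integer(0), member = integer(0),
             chain_a = character(0), res_a = integer(0), atom_a = character(0),
             chain_b = character(0), res_b = integer(0), atom_b = character(0),
             span = numeric(0), tol = numeric(0),
             linker = character(0), type = character(0),
             stringsAsFactors = FALSE)
}

.parse_sites <- function(s) {
  if (is.na(s) || s == "") return(data.frame(pos = integer(0), site = character(0)))
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  data.frame(pos = as.integer(gsub("[^0-9]", "", parts)),
             site = gsub("[0-9]", "", parts), stringsAsFactors = FALSE)
}

#' Convert identifications into distance restraints
#'
#' Each identification becomes one restraint group. Uniquely localized site
#' pairs give a single member; class-ambiguous sites expand to every site
#' combination within the same group (a group is satisfied if any member
#' is). Pt-bridged peptide-DNA identifications expand over all Pt-reactive
#' residues of the peptide times all reactive bases of the oligonucleotide.
#' Restraint spans come from the linker definitions (heteroatom span with
#' side-chain allowance folded into span + tolerance); the Pt bridging span
#' is a package default reflecting trans coordination geometry, not an
#' experimentally derived value.
#'
#' @param ids Identification table from [match_peaks()] (best-rank rows are
#'   typically supplied; every row becomes a group).
#' @param linkers Named list of [crosslinker()] objects supplying spans.
#' @param pt A [pt_adduct()] supplying the Pt span.
#' @param chain_protein Chain identifier of the protein in target
#'   structures.
#' @param chain_forward,chain_reverse Chain identifiers of the duplex
#'   strands.
#' @param offset Added to construct numbering to reach structure-file
#'   numbering (the numbering-offset facility).
#' @return Restraint data frame, one row per group member, with `atom_a`
#'   `"CA"` for protein residues and `atom_b` `"N7"` for guanine bases.
#' @export
xl_to_restraints <- function(ids, linkers = xl_linkers(), pt = pt_adduct(),
                             chain_protein = "A", chain_forward = "B",
                             chain_reverse = "C", offset = 0L) {
  rows <- list()
  for (i in seq_len(nrow(ids))) {
    type <- ids$type[i]
    if (type == "mono") next  # a mono-link constrains no residue pair
    s1 <- .parse_sites(ids$sites1[i])
    if (nrow(s1) == 0) stop("identification ", i, " carries no reactive site")
    if (type == "peptide_dna") {
      lk <- pt
      s2 <- .parse_sites(ids$sites2[i])
      chain_b <- switch(ids$strand2[i], forward = chain_forward,
                        reverse = chain_reverse, chain_forward)
      atom_b <- "N7"
    } else {
      lk <- linkers[[ids$linker[i]]]
      if (is.null(lk)) stop("unknown linker in identifications: ", ids$linker[i])
      if (type == "inter") {
        s2 <- .parse_sites(ids$sites2[i])
      } else {  # loop: pairs of distinct sites within the peptide
        s2 <- s1
      }
      if (nrow(s2) == 0) stop("identification ", i, " carries no reactive site")
      chain_b <- chain_protein
      atom_b <- "CA"
    }
    grid <- expand.grid(a = seq_len(nrow(s1)), b = seq_len(nrow(s2)))
    if (type == "loop") grid <- grid[s1$pos[grid$a] < s2$pos[grid$b], , drop = FALSE]
    if (nrow(grid) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      group = i, member = seq_len(nrow(grid)),
      chain_a = chain_protein, res_a = s1$pos[grid$a] + offset, atom_a = "CA",
      chain_b = chain_b, res_b = s2$pos[grid$b] + offset, atom_b = atom_b,
      span = lk$span, tol = lk$span_tol,
      linker = ids$linker[i], type = type, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(.empty_restraints())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# locate one atom in a bio3d pdb object; NA when unresolvable
.atom_xyz <- function(pdb, chain, resno, atom) {
  sel <- which(pdb$atom$chain == chain & pdb$atom$resno == resno &
                 trimws(pdb$atom$elety) == atom)
  if (length(sel) == 0) return(rep(NA_real_, 3))
  as.numeric(pdb$atom[sel[1], c("x", "y", "z")])
}

.read_structure <- function(structure) {
  if (is.character(structure)) {
    pdb <- tryCatch(bio3d::read.pdb(structure),
                    error = function(e) stop("cannot parse structure file '",
                                             structure, "': ", conditionMessage(e)))
    return(pdb)
  }
  structure
}

#' Measure restraints against a structure
#'
#' Euclidean distances between the restraint endpoints (Calpha for protein
#' residues, guanine N7 for DNA by default, as recorded in the restraint
#' table). A restraint member is satisfied when its measured distance does
#' not exceed span + tolerance; an ambiguous group is satisfied when any of
#' its members is. Endpoints missing from the coordinates are reported as
#' not evaluable, never silently dropped.
#'
#' @param structure A bio3d `pdb` object or path to a PDB file.
#' @param restraints Table from [xl_to_restraints()] or
#'   [read_restraints_tsv()].
#' @return List with `members` (per-member `measured`, `evaluable`,
#'   `satisfied`, `violation`) and `groups` (per-group satisfaction with
#'   minimum measured distance).
#' @export
measure_restraints <- function(structure, restraints) {
  pdb <- .read_structure(structure)
  n <- nrow(restraints)
  measured <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- .atom_xyz(pdb, restraints$chain_a[i], restraints$res_a[i], restraints$atom_a[i])
    b <- .atom_xyz(pdb, restraints$chain_b[i], restraints$res_b[i], restraints$atom_b[i])
    if (anyNA(a) || anyNA(b)) next
    measured[i] <- sqrt(sum((a - b)^2))
  }
  members <- restraints
  members$measured <- measured
  members$evaluable <- !is.na(measured)
  limit <- restraints$span + restraints$tol
  members$satisfied <- members$evaluable & measured <= limit
  members$violation <- ifelse(members$evaluable, pmax(measured - limit, 0), NA_real_)
  grp <- split(seq_len(n), restraints$group)
  groups <- do.call(rbind, lapply(names(grp), function(g) {
    idx <- grp[[g]]
    ev <- members$evaluable[idx]
    data.frame(group = as.integer(g),
               n_members = length(idx),
               n_evaluable = sum(ev),
               satisfied = any(members$satisfied[idx]),
               min_measured = if (any(ev)) min(measured[idx][ev]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(members = members, groups = groups)
}

#' Compare residue-pair distances between two structures
#'
#' Measures the same residue pairs in both structures and summarizes their
#' agreement as per-pair deltas and an RMSD. Pairs unresolvable in either
#' structure are excluded from the RMSD and reported.
#'
#' @param struct_a,struct_b bio3d `pdb` objects or PDB file paths.
#' @param pairs Data frame with columns `chain_a`, `res_a`, `atom_a`,
#'   `chain_b`, `res_b`, `atom_b`.
#' @return List with `pairs` (distances `d_a`, `d_b`, `delta`, `evaluable`)
#'   and `rmsd` in Angstrom.
#' @export
compare_distance_sets <- function(struct_a, struct_b, pairs) {
  pa <- .read_structure(struct_a)
  pb <- .read_structure(struct_b)
  d_for <- function(pdb, i) {
    a <- .atom_xyz(pdb, pairs$chain_a[i], pairs$res_a[i], pairs$atom_a[i])
    b <- .atom_xyz(pdb, pairs$chain_b[i], pairs$res_b[i], pairs$atom_b[i])
    if (anyNA(a) || anyNA(b)) NA_real_ else sqrt(sum((a - b)^2))
  }
  pairs$d_a <- vapply(seq_len(nrow(pairs)), function(i) d_for(pa, i), numeric(1))
  pairs$d_b <- vapply(seq_len(nrow(pairs)), function(i) d_for(pb, i), numeric(1))
  pairs$delta <- pairs$d_a - pairs$d_b
  pairs$evaluable <- !is.na(pairs$delta)
  rmsd <- if (any(pairs$evaluable)) {
    sqrt(mean(pairs$delta[pairs$evaluable]^2))
  } else {
    NA_real_
  }
  list(pairs = pairs, rmsd = rmsd)
}

#' Export restraints
#'
#' Writes restraints as a plain TSV, as simulated-annealing style `assign`
#' records (target distance with minus/plus tolerances), or as
#' docking-style ambiguous restraint blocks grouping the members of each
#' restraint group. Output ordering is byte-stable.
#'
#' @param restraints Restraint table.
#' @param path Output file.
#' @param format `"tsv"`, `"assign"` or `"ambig"`.
#' @return `path`, invisibly.
#' @export
export_restraints <- function(restraints, path, format = c("tsv", "assign", "ambig")) {
  if (!format[1] %in% c("tsv", "assign", "ambig")) {
    stop("unsupported restraint format '", format[1],
         "'; supported: tsv, assign, ambig")
  }
  format <- match.arg(format)
  rs <- restraints[order(restraints$group, restraints$member), , drop = FALSE]
  if (format == "tsv") {
    utils::write.table(rs[, .restraint_cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "assign") {
    lines <- sprintf(
      "assign (segid %s and resid %d and name %s) (segid %s and resid %d and name %s) %.1f %.1f %.1f",
      rs$chain_a, rs$res_a, rs$atom_a, rs$chain_b, rs$res_b, rs$atom_b,
      rs$span, rs$tol, rs$tol)
    writeLines(c("! distance restraints", lines), path)
  } else {
    out <- c("! ambiguous restraint groups")
    for (g in unique(rs$group)) {
      m <- rs[rs$group == g, , drop = FALSE]
      out <- c(out, sprintf("group %d (%d members, %s %.1f +/- %.1f A)",
                            g, nrow(m), m$linker[1], m$span[1], m$tol[1]))
      out <- c(out, sprintf("  or (segid %s and resid %d and name %s) (segid %s and resid %d and name %s)",
                            m$chain_a, m$res_a, m$atom_a,
                            m$chain_b, m$res_b, m$atom_b))
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Read a restraint TSV written by [export_restraints()]
#'
#' @param path TSV path.
#' @return Restraint data frame.
#' @export
read_restraints_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(group = "integer", member = "integer",
                                          chain_a = "character", res_a = "integer",
                                          atom_a = "character",
                                          chain_b = "character", res_b = "integer",
                                          atom_b = "character",
                                          span = "numeric", tol = "numeric",
                                          linker = "character", type = "character"))
  tab[, .restraint_cols]
}
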