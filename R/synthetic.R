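#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every knob of a ground-truth scenario. Defaults emulate the study
#' conditions of the real workflow: a ~130-residue DNA-binding domain
#' construct numbered from residue 74, the printed 13-mer duplex strands,
#' 1 ppm mass noise (calibrated FTICR accuracy), 200 decoy masses kept at
#' least 50 ppm from any library mass, triplicate measurements, and the
#' eight-point exchange schedule 0.33-300 min.
#'
#' @param seed Random seed governing the whole scenario.
#' @param protein_length Length of the generated protein when no sequence
#'   is supplied.
#' @param protein Optional explicit protein sequence.
#' @param protein_start Construct-numbering position of the first residue.
#' @param dna_forward,dna_reverse Duplex strands (5'->3').
#' @param bond_length Consecutive Calpha distance of the toy fold (A).
#' @param min_sep Excluded-volume radius between non-consecutive Calpha (A).
#' @param ppm_sd Gaussian mass-noise sd in ppm.
#' @param n_decoys Decoy peak count per peak list.
#' @param decoy_min_ppm Minimum ppm offset of decoys from every library mass.
#' @param n_planted Planted cross-links per linker.
#' @param mixing Light-channel mixing fraction(s) for planted doublets.
#' @param intensity_cv Multiplicative log-normal intensity noise (cv).
#' @param replicates Replicate count.
#' @param schedule HDX timepoints in minutes.
#' @param k_int Intrinsic exchange rate constant (1/min).
#' @param pf_base Baseline protection factor.
#' @param protected_range Residue window whose protection factor is raised
#'   in the complexed state.
#' @param protection_factor Fold-increase of protection in that window.
#' @param hdx_noise_sd Gaussian centroid noise (Da).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            protein_length = 134L,
                            protein = NULL,
                            protein_start = 74L,
                            dna_forward = "TTGGGTAAACAAG",
                            dna_reverse = "CTTGTTTACCCAA",
                            bond_length = 3.8,
                            min_sep = 3.8,
                            ppm_sd = 1,
                            n_decoys = 200L,
                            decoy_min_ppm = 50,
                            n_planted = 10L,
                            mixing = 0.5,
                            intensity_cv = 0.05,
                            replicates = 3L,
                            schedule = c(0.33, 2, 5, 10, 30, 60, 180, 300),
                            k_int = 10,
                            pf_base = 100,
                            protected_range = c(103L, 130L),
                            protection_factor = 100,
                            hdx_noise_sd = 0) {
  stopifnot(ppm_sd >= 0, hdx_noise_sd >= 0, intensity_cv >= 0)
  structure(as.list(environment()), class = "scenario_config")
}

#' Generate a random protein sequence
#'
#' Amino-acid composition is biased to guarantee cross-linkable (K, S) and
#' Pt-reactive (C, M, H, T) residues at realistic densities.
#'
#' @param length Sequence length.
#' @param seed Random seed.
#' @return Protein sequence string.
#' @export
gen_protein <- function(length = 134L, seed = 1L) {
  set.seed(seed)
  aa <- names(.AA_COMP)
  w <- rep(1, 20); names(w) <- aa
  w[c("K", "S")] <- 2.5          # lysine/serine-rich, as DNA-binding domains are
  w[c("C", "M", "H", "T")] <- 1.5
  w["P"] <- 0.6
  paste(sample(aa, length, replace = TRUE, prob = w / sum(w)), collapse = "")
}

#' Generate a self-avoiding toy fold
#'
#' A random chain with fixed consecutive Calpha distance and excluded
#' volume, used as the ground-truth structure for planting cross-links and
#' validating restraints.
#'
#' @param n Residue count (>= 3).
#' @param seed Random seed.
#' @param bond Consecutive Calpha distance (A).
#' @param min_sep Minimum distance between non-consecutive residues (A).
#' @param max_retry Restart budget before giving up.
#' @return `n x 3` coordinate matrix.
#' @export
gen_fold <- function(n, seed = 1L, bond = 3.8, min_sep = 3.8, max_retry = 200L) {
  stopifnot(n >= 3)
  set.seed(seed)
  for (attempt in seq_len(max_retry)) {
    xyz <- matrix(NA_real_, n, 3)
    xyz[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:50) {
        v <- stats::rnorm(3)
        step <- v / sqrt(sum(v^2)) * bond
        cand <- xyz[i - 1, ] + step
        if (i > 2) {
          d2 <- rowSums((xyz[1:(i - 2), , drop = FALSE] -
                           matrix(cand, i - 2, 3, byrow = TRUE))^2)
          if (min(d2) < min_sep^2) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
  stop("self-avoiding fold generation failed after ", max_retry,
       " restarts; try another seed")
}

#' Ideal B-form duplex pseudo-coordinates
#'
#' Places each base pair on a helix with 3.4 A rise and 36 degree twist.
#' Per nucleotide a backbone phosphorus (`P`) and, for guanine, the `N7`
#' pseudo-atom are emitted - enough to measure Pt-restraint distances.
#'
#' @param forward,reverse Duplex strands (5'->3'), equal length, annealed
#'   end to end.
#' @param origin 3-vector giving the helix-axis start.
#' @param rise,twist,radius_p,radius_b Helical parameters (A, degrees).
#' @return Data frame `chain`, `resno`, `base`, `atom`, `x`, `y`, `z` with
#'   chains `B` (forward) and `C` (reverse).
#' @export
gen_bdna <- function(forward, reverse, origin = c(0, 0, 0),
                     rise = 3.4, twist = 36, radius_p = 9.0, radius_b = 4.0) {
  f <- strsplit(forward, "")[[1]]
  r <- strsplit(reverse, "")[[1]]
  stopifnot(length(f) == length(r))
  n <- length(f)
  rows <- list()
  for (k in seq_len(n)) {
    theta <- (k - 1) * twist * pi / 180
    z <- origin[3] + (k - 1) * rise
    # forward strand base k pairs with reverse strand base n - k + 1
    for (strand in c("f", "r")) {
      phase <- if (strand == "f") 0 else pi * 0.85  # minor-groove asymmetry
      base <- if (strand == "f") f[k] else r[n - k + 1]
      resno <- if (strand == "f") k else n - k + 1
      chain <- if (strand == "f") "B" else "C"
      atoms <- data.frame(
        chain = chain, resno = resno, base = base,
        atom = c("P", if (base == "G") "N7"),
        x = origin[1] + c(radius_p, if (base == "G") radius_b) * cos(theta + phase),
        y = origin[2] + c(radius_p, if (base == "G") radius_b) * sin(theta + phase),
        z = z, stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- atoms
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
          Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

#' Write a synthetic structure to PDB
#'
#' Emits the toy fold as a Calpha trace on chain `A` (construct numbering)
#' plus, optionally, duplex pseudo-atoms from [gen_bdna()].
#'
#' @param fold Coordinate matrix from [gen_fold()].
#' @param sequence Protein sequence matching the fold.
#' @param path Output PDB path.
#' @param start_pos Construct-numbering position of the first residue.
#' @param dna Optional [gen_bdna()] table.
#' @return `path`, invisibly.
#' @export
write_fold_pdb <- function(fold, sequence, path, start_pos = 1L, dna = NULL) {
  res <- strsplit(sequence, "")[[1]]
  stopifnot(length(res) == nrow(fold))
  xyz <- as.numeric(t(fold))
  resno <- start_pos + seq_along(res) - 1L
  resid <- unname(.AA3[res])
  chain <- rep("A", length(res))
  elety <- rep("CA", length(res))
  if (!is.null(dna)) {
    xyz <- c(xyz, as.numeric(t(as.matrix(dna[, c("x", "y", "z")]))))
    resno <- c(resno, dna$resno)
    resid <- c(resid, paste0("D", dna$base))
    chain <- c(chain, dna$chain)
    elety <- c(elety, dna$atom)
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   chain = chain, elety = elety,
                   eleno = seq_along(resno))
  invisible(path)
}

#' Plant cross-links consistent with a fold
#'
#' Samples residue pairs of the linker's reactive classes whose Calpha
#' distance on the fold lies within span + tolerance, and maps each pair to
#' the tryptic (0 missed cleavage) peptides that carry it, recording the
#' light and heavy conjugate masses. Pairs falling in the same peptide are
#' skipped so every planted conjugate is an inter-peptide species.
#'
#' @param fold Coordinates from [gen_fold()].
#' @param sequence Protein sequence.
#' @param linker A [crosslinker()].
#' @param n Number of cross-links to plant (fewer if fewer pairs are
#'   eligible; zero eligible pairs yields an empty table with a warning).
#' @param seed Random seed.
#' @param start_pos Construct numbering of residue 1 of the fold.
#' @param digest Optional precomputed [trypsin_digest()] table.
#' @return Truth data frame: `res_a`, `res_b`, `distance`, `linker`,
#'   peptide columns (`seq1`, `start1`, `end1`, `seq2`, `start2`, `end2`)
#'   and `mass_light`, `mass_heavy`.
#' @export
plant_crosslinks <- function(fold, sequence, linker, n = 10L, seed = 1L,
                             start_pos = 1L, digest = NULL) {
  set.seed(seed)
  res <- strsplit(sequence, "")[[1]]
  classes <- setdiff(linker$reactive, "nterm")
  sites <- which(res %in% classes)
  if ("nterm" %in% linker$reactive) sites <- unique(c(1L, sites))
  if (is.null(digest)) {
    digest <- trypsin_digest(sequence, digest_config(missed = 0),
                             start_pos = start_pos)
  }
  digest0 <- digest[digest$missed == 0, , drop = FALSE]
  pep_of <- function(pos) {
    which(digest0$start <= pos + start_pos - 1L & digest0$end >= pos + start_pos - 1L)[1]
  }
  eligible <- list()
  if (length(sites) >= 2) {
    cmb <- utils::combn(sites, 2)
    for (c_i in seq_len(ncol(cmb))) {
      i <- cmb[1, c_i]; j <- cmb[2, c_i]
      d <- sqrt(sum((fold[i, ] - fold[j, ])^2))
      if (d > linker$span + linker$span_tol) next
      pi_ <- pep_of(i); pj <- pep_of(j)
      if (is.na(pi_) || is.na(pj) || pi_ == pj) next
      eligible[[length(eligible) + 1L]] <- c(i, j, d, pi_, pj)
    }
  }
  if (length(eligible) == 0) {
    warning("no residue pair eligible for linker ", linker$name)
    return(data.frame(res_a = integer(0), res_b = integer(0),
                      distance = numeric(0), linker = character(0),
                      seq1 = character(0), start1 = integer(0), end1 = integer(0),
                      seq2 = character(0), start2 = integer(0), end2 = integer(0),
                      mass_light = numeric(0), mass_heavy = numeric(0)))
  }
  el <- do.call(rbind, eligible)
  pick <- sample(nrow(el), min(n, nrow(el)))
  el <- el[pick, , drop = FALSE]
  pa <- digest0[el[, 4], ]; pb <- digest0[el[, 5], ]
  # order components by position for a canonical description
  swap <- pa$start > pb$start
  tmp <- pa[swap, ]; pa[swap, ] <- pb[swap, ]; pb[swap, ] <- tmp
  out <- data.frame(
    res_a = as.integer(el[, 1]) + start_pos - 1L,
    res_b = as.integer(el[, 2]) + start_pos - 1L,
    distance = el[, 3], linker = linker$name,
    seq1 = pa$sequence, start1 = pa$start, end1 = pa$end,
    seq2 = pb$sequence, start2 = pb$start, end2 = pb$end,
    mass_light = pa$mass + pb$mass + bridge_delta(linker, "light"),
    mass_heavy = pa$mass + pb$mass + bridge_delta(linker, "heavy"),
    stringsAsFactors = FALSE
  )
  out[order(out$start1, out$start2), , drop = FALSE]
}

#' Generate noisy doublet peak lists from planted truth
#'
#' For each replicate, every planted conjugate contributes a light and a
#' heavy peak (theoretical mass perturbed by Gaussian ppm noise) whose
#' intensities realize the configured mixing fraction under multiplicative
#' log-normal noise, plus decoy peaks kept at least `decoy_min_ppm` away
#' from every reference mass.
#'
#' @param truth Table from [plant_crosslinks()].
#' @param cfg A [scenario_config()].
#' @param reference_masses Masses decoys must avoid (default: all library
#'   masses if supplied, else the truth masses).
#' @return Named list of peak-list data frames, one per replicate, each
#'   with a logical `decoy` column alongside `mass` and `intensity`.
#' @export
gen_peaklists <- function(truth, cfg, reference_masses = NULL) {
  if (is.null(reference_masses)) {
    reference_masses <- c(truth$mass_light, truth$mass_heavy)
  }
  f <- rep_len(cfg$mixing, nrow(truth))
  lo <- min(reference_masses) * 0.9
  hi <- max(reference_masses) * 1.1
  out <- vector("list", cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    set.seed(cfg$seed * 1000L + r)
    noise <- function(m) m * (1 + stats::rnorm(length(m), 0, cfg$ppm_sd * 1e-6))
    base_int <- stats::rlnorm(nrow(truth), log(1e4), 0.3)
    jitter <- function(n) exp(stats::rnorm(n, 0, cfg$intensity_cv))
    light_i <- base_int * f * jitter(nrow(truth))
    heavy_i <- base_int * (1 - f) * jitter(nrow(truth))
    peaks <- data.frame(
      mass = c(noise(truth$mass_light), noise(truth$mass_heavy)),
      intensity = c(light_i, heavy_i),
      decoy = FALSE
    )
    decoys <- numeric(0)
    guard <- 0L
    while (cfg$n_decoys > 0 && length(decoys) < cfg$n_decoys) {
      guard <- guard + 1L
      if (guard > 200L) stop("decoy placement infeasible with the configured offsets")
      cand <- stats::runif(cfg$n_decoys, lo, hi)
      keep <- vapply(cand, function(m) {
        all(abs(m - reference_masses) / reference_masses * 1e6 >= cfg$decoy_min_ppm)
      }, logical(1))
      decoys <- c(decoys, cand[keep])
    }
    if (cfg$n_decoys > 0) {
      decoys <- decoys[seq_len(cfg$n_decoys)]
      peaks <- rbind(peaks, data.frame(mass = decoys,
                                       intensity = stats::rlnorm(cfg$n_decoys, log(500), 0.5),
                                       decoy = TRUE))
    }
    peaks <- peaks[order(peaks$mass), , drop = FALSE]
    rownames(peaks) <- NULL
    out[[r]] <- peaks
  }
  names(out) <- paste0("replicate", seq_len(cfg$replicates))
  out
}

#' Simulate two-state HDX centroid tables
#'
#' Per-residue uptake follows first-order kinetics
#' `u_i(t) = 1 - exp(-k_int * t / P_i)` with state-specific protection
#' factors; a peptide's centroid is its neutral mass plus the summed uptake
#' of its covered (amide-bearing, non-proline, non-N-terminal) residues,
#' with optional Gaussian noise. Time-0 reference rows are included.
#'
#' @param sequence Protein sequence.
#' @param peptides Peptide table (`sequence`, `start`, `end`, `mass`), e.g.
#'   from [trypsin_digest()] or a custom overlapping pool.
#' @param pf_free,pf_complex Per-residue protection factors, one value per
#'   residue of `sequence` (all > 0).
#' @param cfg A [scenario_config()] (schedule, replicates, k_int, noise,
#'   seed).
#' @param start_pos Construct numbering of the first residue.
#' @param rule Exchangeable-amide rule.
#' @return Centroid data frame: `sequence`, `start`, `end`, `state`,
#'   `time`, `replicate`, `centroid`.
#' @export
gen_hdx <- function(sequence, peptides, pf_free, pf_complex, cfg,
                    start_pos = 1L, rule = "skip_first") {
  n <- nchar(sequence)
  stopifnot(length(pf_free) == n, length(pf_complex) == n)
  if (any(pf_free <= 0) || any(pf_complex <= 0)) {
    stop("protection factors must be > 0")
  }
  set.seed(cfg$seed + 7L)
  states <- list(free = pf_free, complex = pf_complex)
  rows <- list()
  for (state in names(states)) {
    pf <- states[[state]]
    for (i in seq_len(nrow(peptides))) {
      cov <- covered_residues(peptides$sequence[i], peptides$start[i], rule) -
        start_pos + 1L
      for (r in seq_len(cfg$replicates)) {
        for (t in c(0, cfg$schedule)) {
          u <- if (t == 0) 0 else sum(1 - exp(-cfg$k_int * t / pf[cov]))
          noise <- if (t == 0 || cfg$hdx_noise_sd == 0) 0 else
            stats::rnorm(1, 0, cfg$hdx_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = peptides$sequence[i], start = peptides$start[i],
            end = peptides$end[i], state = state, time = t, replicate = r,
            centroid = peptides$mass[i] + u + noise, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Materialize a complete synthetic scenario
#'
#' Generates protein, fold, duplex, digest, planted cross-links, doublet
#' peak lists and HDX centroid tables, writes them in the same plain-text
#' dialects the analysis functions read, and records the ground truth and
#' configuration in a JSON manifest. Fully deterministic under the config
#' seed.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [scenario_config()].
#' @return Invisibly, a list with the in-memory scenario objects
#'   (`protein`, `fold`, `digest`, `truth`, `peaklists`, `hdx`, paths).
#' @export
simulate_scenario <- function(dir, cfg = scenario_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  protein <- cfg$protein
  if (is.null(protein)) protein <- gen_protein(cfg$protein_length, cfg$seed)
  n <- nchar(protein)
  fold <- gen_fold(n, seed = cfg$seed, bond = cfg$bond_length,
                   min_sep = cfg$min_sep)
  dna <- gen_bdna(cfg$dna_forward, cfg$dna_reverse,
                  origin = c(max(fold[, 1]) + 10, 0, 0))
  dg <- trypsin_digest(protein, digest_config(missed = 0),
                       start_pos = cfg$protein_start)
  linkers <- xl_linkers()
  truth <- do.call(rbind, lapply(linkers, function(lk) {
    plant_crosslinks(fold, protein, lk, n = cfg$n_planted, seed = cfg$seed,
                     start_pos = cfg$protein_start, digest = dg)
  }))
  rownames(truth) <- NULL
  lib <- build_library(dg, linkers = linkers,
                       types = c("inter", "loop", "mono"),
                       protein_start = cfg$protein_start)
  peaklists <- gen_peaklists(truth, cfg, reference_masses = lib$mass)
  pf_free <- rep(cfg$pf_base, n)
  pf_complex <- pf_free
  win <- (cfg$protected_range[1]:cfg$protected_range[2]) - cfg$protein_start + 1L
  win <- win[win >= 1 & win <= n]
  pf_complex[win] <- pf_complex[win] * cfg$protection_factor
  hdx <- gen_hdx(protein, dg[dg$end - dg$start >= 2, , drop = FALSE],
                 pf_free, pf_complex, cfg, start_pos = cfg$protein_start)

  paths <- list(
    protein_fasta = file.path(dir, "protein.fasta"),
    fold_pdb = file.path(dir, "fold.pdb"),
    digest_tsv = file.path(dir, "digest.tsv"),
    hdx_csv = file.path(dir, "hdx_centroids.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  writeLines(c(">synthetic_construct", protein), paths$protein_fasta)
  write_fold_pdb(fold, protein, paths$fold_pdb,
                 start_pos = cfg$protein_start, dna = dna)
  write_digest_tsv(dg, paths$digest_tsv)
  utils::write.csv(hdx, paths$hdx_csv, row.names = FALSE, quote = FALSE)
  peak_paths <- character(0)
  for (r in seq_along(peaklists)) {
    p <- file.path(dir, sprintf("peaks_rep%d.csv", r))
    utils::write.csv(peaklists[[r]], p, row.names = FALSE, quote = FALSE)
    peak_paths <- c(peak_paths, p)
  }
  manifest <- list(seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "protein")],
                   protein = protein,
                   truth = truth)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(protein = protein, fold = fold, dna = dna, digest = dg,
                 library = lib, truth = truth, peaklists = peaklists,
                 hdx = hdx, pf_free = pf_free, pf_complex = pf_complex,
                 paths = c(paths, list(peaks = peak_paths)), cfg = cfg))
}
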