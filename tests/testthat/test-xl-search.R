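small_peptides <- function(seqs, starts) {
  data.frame(sequence = seqs, start = starts,
             end = starts + nchar(seqs) - 1L,
             missed = rep(0L, length(seqs)),
             mass = vapply(seqs, peptide_mass, numeric(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

test_that("library generation respects reactive-class rules", {
  peps <- small_peptides(c("AK", "GS"), c(1L, 3L))
  lib <- build_library(peps, linkers = xl_linkers()["DSS"],
                       types = c("inter", "loop", "mono"))
  inter <- lib[lib$type == "inter", ]
  expect_true(any(inter$seq1 == "AK" & inter$seq2 == "GS"))
  # a site-free peptide only participates through the protein N-terminus
  peps2 <- small_peptides(c("GG", "AK"), c(1L, 3L))
  lib2 <- build_library(peps2, linkers = xl_linkers()["DSS"],
                        types = c("inter", "mono"))
  expect_true(any(lib2$seq1 == "GG"))  # N-terminal peptide is reactive
  peps3 <- small_peptides(c("AK", "GG"), c(1L, 3L))
  lib3 <- build_library(peps3, linkers = xl_linkers()["DSS"],
                        types = c("inter", "mono"))
  expect_false(any(lib3$seq1 == "GG" | lib3$seq2 == "GG", na.rm = TRUE))
  # candidates carry exact conjugate masses
  i <- which(inter$seq1 == "AK" & inter$seq2 == "GS" & inter$form == "light")[1]
  expect_equal(inter$mass[i],
               conjugate_mass(list("AK" |> peptide_mass(), "GS" |> peptide_mass()),
                              xl_linkers()$DSS, "light"),
               tolerance = 1e-9)
  # away from the protein N-terminus, a K/S-free peptide has no site at all
  expect_warning(
    build_library(small_peptides("GG", 5L), linkers = xl_linkers()["DSS"],
                  types = "mono", protein_start = 1L),
    "no reactive sites")
})

test_that("peptide-DNA candidates pair Pt-reactive peptides with G-bearing oligos", {
  peps <- small_peptides(c("ACMK", "AGGK"), c(1L, 5L))
  oligos <- bal31_fragments("TAGT", digest_config(min_oligo_length = 3),
                            strand_label = "reverse")
  lib <- build_library(peps, oligos, linkers = list(), pt = pt_adduct(),
                       types = "peptide_dna")
  expect_true(all(lib$seq1 == "ACMK"))        # AGGK has no C/M/H/T
  expect_true(all(grepl("G", lib$seq2)))
  expect_true(all(lib$form == "bifunctional"))
})

test_that("the constant-unit path adds one fixed mass to reactive peptides", {
  peps <- small_peptides(c("ACMK", "AGGK", "TTTK"), c(1L, 5L, 9L))
  unit <- oligo_species("TGTT", strand = "reverse", start = 3L)
  lib <- constant_unit_library(peps, unit, pt_adduct())
  expect_equal(nrow(lib), 2L)  # ACMK (C, M) and TTTK (T) carry Pt sites
  expect_true(all(lib$constant_unit))
  expect_equal(lib$mass,
               peps$mass[c(1, 3)] + oligo_mass(unit) +
                 pt_delta(pt_adduct(), "bifunctional"),
               tolerance = 1e-9)
  expect_equal(conjugate_mass(list(1000, 2000), pt_adduct(), "bifunctional"),
               1000 + 2000 + pt_delta(pt_adduct(), "bifunctional"))
  empty <- constant_unit_library(small_peptides(character(0), integer(0))[0, ],
                                 unit, pt_adduct())
  expect_equal(nrow(empty), 0L)
})

test_that("ppm matching accepts within tolerance and rejects outside", {
  lib <- small_peptides("AKAAAAAAAAKR", 1L)
  lib <- build_library(lib, linkers = xl_linkers()["DSG"], types = "mono")
  lib$mass <- 2000.0000  # pin the candidate mass for the arithmetic check
  ids <- match_peaks(data.frame(mass = 2000.0040), lib[1, ], ppm_tol = 5)
  expect_equal(nrow(ids), 1L)
  expect_equal(ids$ppm, 2.0, tolerance = 1e-6)
  ids2 <- match_peaks(data.frame(mass = 2000.0500), lib[1, ], ppm_tol = 5)
  expect_equal(nrow(ids2), 0L)
  expect_equal(nrow(attr(ids2, "unmatched")), 1L)
  expect_error(match_peaks(data.frame(mass = 1), lib[0, ]), "empty")
})

test_that("matching equals the brute-force all-pairs oracle", {
  set.seed(33)
  prot <- gen_protein(60, seed = 33)
  dg <- trypsin_digest(prot, digest_config(missed = 1))
  lib <- build_library(dg, linkers = xl_linkers(),
                       types = c("inter", "loop", "mono"))
  peaks <- data.frame(mass = c(sample(lib$mass, 15) * (1 + runif(15, -3e-6, 3e-6)),
                               runif(30, min(lib$mass), max(lib$mass))))
  ids <- match_peaks(peaks, lib, ppm_tol = 5)
  want <- oracle_match(peaks, lib, 5)
  expect_equal(nrow(ids), nrow(want))
  expect_equal(sort(unique(ids$peak)), sort(unique(want$peak)))
  # determinism: byte-identical output on a second run
  ids_again <- match_peaks(peaks, lib, ppm_tol = 5)
  expect_identical(ids, ids_again)
})

test_that("planted conjugates are fully recovered with zero decoy hits", {
  cfg <- scenario_config(seed = 19, n_planted = 10)
  scen <- simulate_scenario(tempfile("scen"), cfg)
  expect_equal(nrow(scen$truth), 20L)  # 10 per linker
  pk <- scen$peaklists[[1]]
  ids <- match_peaks(pk, scen$library, ppm_tol = 5)
  expect_equal(sum(pk$decoy[ids$peak]), 0L)
  key_t <- with(scen$truth, paste("inter", linker, seq1, start1, seq2, start2))
  key_i <- with(ids, paste(type, linker, seq1, start1, seq2, start2))
  expect_true(all(key_t %in% key_i[ids$form == "light"]))
  expect_true(all(key_t %in% key_i[ids$form == "heavy"]))
})

test_that("site localization distinguishes unique, ambiguous and Pt cases", {
  peps <- small_peptides(c("AKG", "GSA", "AKSG"), c(1L, 10L, 20L))
  lib <- build_library(peps, linkers = xl_linkers()["DSS"], types = "inter",
                       protein_start = 100L)  # no peptide is N-terminal
  peaks <- data.frame(mass = lib$mass[lib$form == "light"])
  ids <- site_localization_report(match_peaks(peaks, lib, ppm_tol = 1))
  one_each <- ids[ids$seq1 == "AKG" & ids$seq2 == "GSA", ]
  expect_true(all(one_each$localization == "localized"))
  multi <- ids[ids$seq1 == "AKG" & ids$seq2 == "AKSG", ]
  expect_true(all(multi$localization == "ambiguous"))
  expect_true(all(grepl("K21", multi$sites2) & grepl("S22", multi$sites2)))
  # Pt-bridged identifications never claim residue-level sites
  oligos <- bal31_fragments("TGT", digest_config(min_oligo_length = 3))
  plib <- build_library(small_peptides("ACMK", 1L), oligos, linkers = list(),
                        pt = pt_adduct(), types = "peptide_dna")
  pids <- site_localization_report(
    match_peaks(data.frame(mass = plib$mass), plib, ppm_tol = 1))
  expect_true(all(pids$localization == "composition-only"))
})
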