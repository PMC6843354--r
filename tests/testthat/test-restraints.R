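make_ids <- function() {
  data.frame(
    type = c("inter", "inter", "inter", "peptide_dna"),
    linker = c("DSG", "DSS", "DSG", "transplatin"),
    form = c("light", "light", "light", "bifunctional"),
    seq1 = c("NAK", "NAK", "AKSG", "ACMK"),
    start1 = c(145L, 145L, 145L, 171L), end1 = c(147L, 147L, 148L, 174L),
    seq2 = c("GKV", "GKV", "GKV", "TGGT"),
    strand2 = c(NA, NA, NA, "reverse"),
    start2 = c(169L, 169L, 169L, 2L), end2 = c(171L, 171L, 171L, 5L),
    sites1 = c("K147", "K147", "K146,S147", "C172,M173"),
    sites2 = c("K170", "K170", "K170", "G3,G4"),
    n_components = 2L, mass = 0,
    stringsAsFactors = FALSE
  )
}

test_that("identifications expand to restraints with linker-specific spans", {
  rs <- xl_to_restraints(make_ids())
  g1 <- rs[rs$group == 1, ]
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$span, 20.5)
  expect_equal(g1$tol, 3.0)
  expect_equal(c(g1$res_a, g1$res_b), c(147L, 170L))
  g2 <- rs[rs$group == 2, ]
  expect_equal(g2$span, 24.2)
  expect_equal(g2$tol, 3.0)
  # class ambiguity expands within one group
  g3 <- rs[rs$group == 3, ]
  expect_equal(nrow(g3), 2L)
  expect_setequal(g3$res_a, c(146L, 147L))
  # Pt identifications cross reactive residues with reactive bases
  g4 <- rs[rs$group == 4, ]
  expect_equal(nrow(g4), 4L)
  expect_true(all(g4$atom_b == "N7"))
  expect_true(all(g4$chain_b == "C"))
  expect_error(
    xl_to_restraints(within(make_ids()[1, ], sites1 <- "")),
    "no reactive site")
})

line_fold <- function() {
  # residues on a line: 147 at origin, 170 at 10 A, 200 at 40 A
  coords <- rbind(c(0, 0, 0), c(10, 0, 0), c(40, 0, 0))
  seq <- "KKK"
  path <- tempfile(fileext = ".pdb")
  write_fold_pdb(coords, seq, path, start_pos = 1L)
  pdb <- bio3d::read.pdb(path)
  pdb$atom$resno <- c(147L, 170L, 200L)
  pdb
}

test_that("restraint satisfaction compares distance against span plus tolerance", {
  pdb <- line_fold()
  rs <- data.frame(group = 1:3, member = 1L,
                   chain_a = "A", res_a = c(147L, 170L, 147L), atom_a = "CA",
                   chain_b = "A", res_b = c(170L, 200L, 999L), atom_b = "CA",
                   span = c(20.5, 24.2, 20.5), tol = 3.0,
                   linker = c("DSG", "DSS", "DSG"), type = "inter",
                   stringsAsFactors = FALSE)
  rep_ <- measure_restraints(pdb, rs)
  m <- rep_$members
  expect_equal(m$measured[1], 10)
  expect_true(m$satisfied[1])
  expect_equal(m$measured[2], 30)
  expect_false(m$satisfied[2])
  expect_equal(m$violation[2], 2.8, tolerance = 1e-9)
  expect_false(m$evaluable[3])   # missing residue is reported, not dropped
  expect_equal(rep_$groups$n_evaluable, c(1L, 1L, 0L))
  expect_error(measure_restraints(tempfile(fileext = ".pdb"), rs), "structure")
})

test_that("distance-set comparison yields per-pair deltas and RMSD", {
  seq6 <- "KKKKKK"
  mk <- function(x2, x4, x6) {
    rbind(c(0, 0, 0), c(x2, 0, 0), c(0, 10, 0), c(x4, 10, 0),
          c(0, 20, 0), c(x6, 20, 0))
  }
  pa <- tempfile(fileext = ".pdb"); pb <- tempfile(fileext = ".pdb")
  write_fold_pdb(mk(10, 13, 14), seq6, pa)
  write_fold_pdb(mk(10, 10, 10), seq6, pb)
  pairs <- data.frame(chain_a = "A", res_a = c(1L, 3L, 5L), atom_a = "CA",
                      chain_b = "A", res_b = c(2L, 4L, 6L), atom_b = "CA",
                      stringsAsFactors = FALSE)
  cmp <- compare_distance_sets(pa, pb, pairs)
  expect_equal(cmp$pairs$delta, c(0, 3, 4))
  expect_equal(cmp$rmsd, sqrt(25 / 3), tolerance = 1e-9)
  # identical structures agree exactly
  expect_equal(compare_distance_sets(pa, pa, pairs)$rmsd, 0)
  # rigid translation leaves all distances unchanged
  shifted <- mk(10, 13, 14) + matrix(c(7, -2, 5), 6, 3, byrow = TRUE)
  ps <- tempfile(fileext = ".pdb")
  write_fold_pdb(shifted, seq6, ps)
  expect_equal(compare_distance_sets(pa, ps, pairs)$rmsd, 0, tolerance = 1e-6)
})

test_that("measured distances are invariant under rotation to 1e-6 A", {
  scen <- simulate_scenario(tempfile("rig"), scenario_config(seed = 3, n_planted = 5))
  ids <- match_peaks(scen$peaklists[[1]], scen$library, ppm_tol = 5)
  ids <- ids[ids$rank == 1 & ids$type == "inter" & ids$form == "light", ]
  rs <- xl_to_restraints(site_localization_report(ids))
  pdb <- bio3d::read.pdb(scen$paths$fold_pdb)
  m1 <- measure_restraints(pdb, rs)$members$measured
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE) %*% R +
    matrix(c(3, 14, -6), length(pdb$xyz) / 3, 3, byrow = TRUE)
  pdb2 <- pdb
  pdb2$atom[, c("x", "y", "z")] <- xyz
  m2 <- measure_restraints(pdb2, rs)$members$measured
  expect_lt(max(abs(m1 - m2), na.rm = TRUE), 1e-6)
  # brute-force oracle: distances recomputed directly from coordinates
  ca <- pdb$atom[trimws(pdb$atom$elety) == "CA", ]
  for (i in seq_len(nrow(rs))) {
    a <- ca[ca$resno == rs$res_a[i], c("x", "y", "z")]
    b <- ca[ca$resno == rs$res_b[i], c("x", "y", "z")]
    if (nrow(a) == 0 || nrow(b) == 0) next
    d <- sqrt(sum((as.numeric(a[1, ]) - as.numeric(b[1, ]))^2))
    expect_equal(m1[i], d, tolerance = 1e-9)
  }
})

test_that("restraint export round-trips and rejects unknown formats", {
  rs <- xl_to_restraints(make_ids())
  tsv1 <- tempfile(fileext = ".tsv"); tsv2 <- tempfile(fileext = ".tsv")
  export_restraints(rs, tsv1, "tsv")
  back <- read_restraints_tsv(tsv1)
  export_restraints(back, tsv2, "tsv")
  expect_identical(readLines(tsv1), readLines(tsv2))
  # assign records carry target and symmetric tolerances
  asn <- tempfile(fileext = ".tbl")
  export_restraints(rs[rs$group == 1, ], asn, "assign")
  expect_match(readLines(asn)[2], "20.5 3.0 3.0")
  # ambiguous blocks preserve group structure
  amb <- tempfile(fileext = ".tbl")
  export_restraints(rs[rs$group == 4, ], amb, "ambig")
  lines <- readLines(amb)
  expect_match(lines[2], "4 members")
  expect_equal(sum(grepl("^  or ", lines)), 4L)
  # empty restraint set still writes a valid header
  empt <- tempfile(fileext = ".tsv")
  export_restraints(rs[0, ], empt, "tsv")
  expect_equal(length(readLines(empt)), 1L)
  expect_error(export_restraints(rs, tempfile(), "xplor"), "unsupported")
})
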