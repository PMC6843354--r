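test_that("exchangeable amide counts exclude the N-terminal residue and prolines", {
  expect_equal(exchangeable_count("AGPLK"), 3L)
  expect_equal(exchangeable_count("PPPP"), 0L)
  expect_equal(exchangeable_count("GK"), 1L)
  expect_warning(expect_equal(exchangeable_count("G"), 0L), "no observable")
  expect_equal(exchangeable_count("AAPK", rule = "skip_first_two"), 1L)
})

test_that("relative uptake is the centroid shift per exchangeable amide", {
  expect_equal(as.numeric(relative_uptake(1003, 1000, 6)), 0.5)
  expect_equal(as.numeric(relative_uptake(1000, 1000, 6)), 0)
  clamped <- relative_uptake(1006.038, 1000, 6)
  expect_equal(as.numeric(clamped), 1.0)
  expect_equal(attr(clamped, "n_clamped"), 1L)
  expect_error(relative_uptake(1, 1, 0), "n_ex")
})

test_that("shortest-fragment subtraction resolves nested peptide differences", {
  prot <- paste(rep("A", 12), collapse = "")
  tab <- data.frame(sequence = c(substr(prot, 1, 10), substr(prot, 1, 8)),
                    start = c(1L, 1L), end = c(10L, 8L), uptake = c(5, 4))
  cons <- residue_consolidation(tab, prot)
  seg <- cons$segments
  expect_equal(seg$uptake[seg$seg_start == 9 & seg$seg_end == 10], 1.0)
  expect_equal(cons$n_clamped, 0L)
  # single peptide: all its residues share the peptide DR
  single <- residue_consolidation(tab[1, ], prot)
  expect_equal(length(unique(single$residues$dr)), 1L)
  expect_equal(unique(single$residues$dr), 5 / 9)
  # contradictory overlap (inner uptake exceeds outer) clamps to zero
  bad <- tab; bad$uptake <- c(3, 4)
  consb <- residue_consolidation(bad, prot)
  expect_equal(consb$n_clamped, 1L)
  expect_equal(consb$segments$uptake[consb$segments$seg_start == 9], 0)
  # least-squares mode agrees on this fully determined system
  ls <- residue_consolidation(tab, prot, method = "least_squares")
  expect_equal(ls$segments$uptake, cons$segments$uptake, tolerance = 1e-9)
})

test_that("consolidation inverts forward-simulated uptake and conserves totals", {
  pool <- hdx_pool()
  pf <- hdx_pf()
  cfg <- scenario_config(seed = 21, replicates = 1, hdx_noise_sd = 0)
  cent <- gen_hdx(HDX_PROTEIN, pool, pf$free, pf$complex, cfg,
                  start_pos = HDX_START)
  upt <- peptide_uptake(cent)
  for (state in c("free", "complex")) {
    one <- upt[upt$state == state & upt$time == 30 & upt$replicate == 1, ]
    cons <- residue_consolidation(one, HDX_PROTEIN, start_pos = HDX_START)
    expect_lt(max(abs(cons$residuals$residual)), 1e-6)
    # segment DR matches the generating kinetics where segments are resolved
    k <- cfg$k_int; t <- 30
    truth_dr <- function(p) 1 - exp(-k * t / p)
    seg <- cons$segments
    in_win <- seg$seg_start >= 104 & seg$seg_end <= 130
    expected <- truth_dr(if (state == "complex") 100 * 100 else 100)
    expect_equal(seg$dr[in_win], rep(expected, sum(in_win)), tolerance = 1e-9)
  }
  # noiseless DR is non-decreasing in time for every peptide
  for (key in unique(paste(upt$sequence, upt$state))) {
    g <- upt[paste(upt$sequence, upt$state) == key, ]
    expect_false(is.unsorted(g$dr[order(g$time)]))
  }
})

test_that("differential profiles subtract states and flag planted protection", {
  pool <- hdx_pool()
  pf <- hdx_pf()
  cfg <- scenario_config(seed = 21, replicates = 3, hdx_noise_sd = 0)
  cent <- gen_hdx(HDX_PROTEIN, pool, pf$free, pf$complex, cfg,
                  start_pos = HDX_START)
  upt <- peptide_uptake(cent)
  rdr <- residue_dr_table(upt, HDX_PROTEIN, start_pos = HDX_START)
  free <- rdr[rdr$state == "free", ]
  complex <- rdr[rdr$state == "complex", ]
  dif <- hdx_differential(free, complex)
  expect_true(all(dif$ddr >= -1 & dif$ddr <= 1))
  # antisymmetry: swapping the states negates every difference
  rev <- hdx_differential(complex, free)
  expect_equal(rev$ddr, -dif$ddr)
  # protection confined to the planted window
  act <- export_active_residues(dif)
  expect_equal(act, 103:130)
  # identical states give a null profile
  null <- hdx_differential(free, free)
  expect_true(all(null$ddr == 0))
  expect_equal(export_active_residues(null), integer(0))
  # threshold above the maximum difference empties the list
  expect_equal(export_active_residues(dif, threshold = 2), integer(0))
  # mismatched grids are rejected with the missing cells named
  expect_error(hdx_differential(free[-1, ], complex), "missing cells")
})

test_that("worked differential arithmetic holds", {
  f <- data.frame(residue = 1L, time = 5, dr = 0.6, sd = 0, n = 3)
  c_ <- data.frame(residue = 1L, time = 5, dr = 0.2, sd = 0, n = 3)
  expect_equal(hdx_differential(f, c_)$ddr, 0.4)
})

test_that("time-course shapes are classified from sign patterns", {
  expect_equal(classify_time_course(c(0.05, 0.15, 0.30, 0.38, 0.40, 0.40)),
               "rising-saturating")
  expect_equal(classify_time_course(c(0.05, 0.35, 0.40, 0.20, 0.08, 0.05)),
               "rise-then-fall")
  expect_equal(classify_time_course(c(0.01, -0.02, 0.03, 0.01)), "flat")
  expect_error(classify_time_course(c(0.1, 0.2, 0.3)), "4 timepoints")
})

test_that("uptake tables require a time-zero reference", {
  pool <- hdx_pool()[1, ]
  cfg <- scenario_config(seed = 3, replicates = 1, hdx_noise_sd = 0)
  pf <- hdx_pf()
  cent <- gen_hdx(HDX_PROTEIN, pool, pf$free, pf$complex, cfg,
                  start_pos = HDX_START)
  expect_error(peptide_uptake(cent[cent$time > 0, ]), "time == 0")
  upt <- peptide_uptake(cent)
  expect_true(all(upt$time > 0))
  expect_true(all(upt$uptake >= 0))
})
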