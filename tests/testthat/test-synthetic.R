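test_that("folds are self-avoiding chains with fixed bond geometry", {
  xyz <- gen_fold(80, seed = 2)
  d <- sqrt(rowSums((xyz[-1, ] - xyz[-80, ])^2))
  expect_true(all(d >= 3.79 & d <= 3.81))
  # excluded volume between non-consecutive residues
  dm <- as.matrix(dist(xyz))
  diag(dm) <- NA
  far <- dm[abs(row(dm) - col(dm)) > 1]
  expect_true(all(far >= 3.8 - 1e-9, na.rm = TRUE))
  # determinism under the seed
  expect_identical(xyz, gen_fold(80, seed = 2))
  expect_false(identical(xyz, gen_fold(80, seed = 3)))
})

test_that("the ideal duplex rises 3.4 A per base pair", {
  dna <- gen_bdna(DBE_FORWARD, DBE_REVERSE)
  fwd_p <- dna[dna$chain == "B" & dna$atom == "P", ]
  expect_equal(max(fwd_p$z) - min(fwd_p$z), 12 * 3.4, tolerance = 1e-9)
  expect_true(any(dna$atom == "N7"))
  expect_true(all(dna$base[dna$atom == "N7"] == "G"))
})

test_that("noiseless peak lists reproduce theoretical masses exactly", {
  scen <- simulate_scenario(tempfile("nl"), scenario_config(seed = 8, n_planted = 4))
  truth <- scen$truth
  cfg0 <- scenario_config(seed = 8, ppm_sd = 0, n_decoys = 0L, replicates = 1)
  pk <- gen_peaklists(truth, cfg0)[[1]]
  expect_setequal(round(pk$mass, 9),
                  round(c(truth$mass_light, truth$mass_heavy), 9))
  # decoys stay at least the configured offset from every reference mass
  cfgd <- scenario_config(seed = 8, replicates = 1)
  pkd <- gen_peaklists(truth, cfgd, reference_masses = scen$library$mass)[[1]]
  dec <- pkd$mass[pkd$decoy]
  min_off <- vapply(dec, function(m) {
    min(abs(m - scen$library$mass) / scen$library$mass * 1e6)
  }, numeric(1))
  expect_true(all(min_off >= 50))
})

test_that("planted cross-links lie within span on the generating fold", {
  prot <- gen_protein(100, seed = 6)
  fold <- gen_fold(100, seed = 6)
  lk <- xl_linkers()$DSG
  tr <- plant_crosslinks(fold, prot, lk, n = 8, seed = 6)
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$distance <= lk$span + lk$span_tol))
  # zero span admits no pair
  lk0 <- crosslinker("null", light = c(C = 5, H = 4, O = 2),
                     heavy = c(C = 5, D = 4, O = 2),
                     span = 1e-6, span_tol = 0)
  expect_warning(tr0 <- plant_crosslinks(fold, prot, lk0, n = 5, seed = 6),
                 "no residue pair")
  expect_equal(nrow(tr0), 0L)
})

test_that("exchange kinetics respect protection-factor limits", {
  pool <- data.frame(sequence = "ACDEFGHIK", start = 1L, end = 9L,
                     mass = peptide_mass("ACDEFGHIK"))
  cfg <- scenario_config(seed = 2, replicates = 1, hdx_noise_sd = 0,
                         schedule = c(1, 10, 1e6))
  n <- nchar("ACDEFGHIK")
  # infinite protection freezes exchange
  frozen <- gen_hdx("ACDEFGHIK", pool, rep(1e12, n), rep(1e12, n), cfg)
  expect_equal(frozen$centroid, rep(pool$mass, nrow(frozen)), tolerance = 1e-4)
  # k_int * t / P >> 1 saturates at the exchangeable amide count
  sat <- gen_hdx("ACDEFGHIK", pool, rep(1, n), rep(1, n), cfg)
  last <- sat[sat$time == 1e6, ]
  expect_equal(unique(round(last$centroid - pool$mass, 6)),
               exchangeable_count("ACDEFGHIK"))
  expect_error(gen_hdx("ACDEFGHIK", pool, rep(0, n), rep(1, n), cfg),
               "protection factors")
})

test_that("a scenario is fully deterministic under its seed", {
  d1 <- tempfile("s1"); d2 <- tempfile("s2")
  s1 <- simulate_scenario(d1, scenario_config(seed = 14, n_planted = 5))
  s2 <- simulate_scenario(d2, scenario_config(seed = 14, n_planted = 5))
  expect_identical(s1$protein, s2$protein)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$peaklists, s2$peaklists)
  for (f in c("digest.tsv", "hdx_centroids.csv", "peaks_rep1.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("the pipeline closes on synthetic truth end to end", {
  scen <- simulate_scenario(tempfile("e2e"), scenario_config(seed = 3, n_planted = 10))
  ids <- match_peaks(scen$peaklists[[1]], scen$library, ppm_tol = 5)
  key_t <- with(scen$truth, paste("inter", linker, seq1, start1, seq2, start2))
  key_i <- with(ids, paste(type, linker, seq1, start1, seq2, start2))
  expect_true(all(key_t %in% key_i))                        # recall 1.0
  expect_equal(sum(scen$peaklists[[1]]$decoy[ids$peak]), 0L) # no decoy hits
  sel <- ids[key_i %in% key_t & ids$form == "light", ]
  sel <- sel[!duplicated(paste(sel$seq1, sel$start1, sel$seq2, sel$start2,
                               sel$linker)), ]
  rs <- xl_to_restraints(site_localization_report(sel))
  rep_ <- measure_restraints(scen$paths$fold_pdb, rs)
  expect_true(all(rep_$groups$satisfied))                   # 100% on the fold
})
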