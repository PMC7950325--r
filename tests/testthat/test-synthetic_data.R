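test_that("identical seeds give identical simulated outputs", {
  spec <- simulation_spec(seed = 41, n_replicates = 2L)
  t1 <- generate_truth(spec); t2 <- generate_truth(spec)
  expect_identical(t1, t2)
  s1 <- simulate_features(t1, spec); s2 <- simulate_features(t2, spec)
  expect_identical(s1, s2)
  expect_identical(simulate_spectra(t1, spec), simulate_spectra(t2, spec))
  s3 <- simulate_features(t1, simulation_spec(seed = 42, n_replicates = 2L))
  expect_false(identical(s1$features$mz, s3$features$mz))
})

test_that("the truth tables list the planted sites and exactly four cross-links", {
  spec <- simulation_spec(seed = 1)
  truth <- generate_truth(spec)
  expect_equal(nrow(truth$crosslinks), 4L)
  expect_setequal(truth$crosslinks$link_type, c("YY", "WW", "WW", "YW"))
  expect_true(all(truth$sites$occupancy >= 0 & truth$sites$occupancy <= 100))
  # occupancy outside [0, 100] rejected
  fx <- mini_fibronectin(); fx$site_occupancy$occupancy[1] <- 120
  expect_error(simulation_spec(fixture = fx))
})

test_that("zero occupancy produces no modified features", {
  fx <- mini_fibronectin()
  fx$site_occupancy$occupancy <- 0
  spec <- noiseless_spec(fixture = fx, seed = 2)
  sim <- simulate_features(generate_truth(spec), spec)
  lin <- sim$feature_truth[sim$feature_truth$kind == "linear", ]
  expect_false(any(grepl("nitration|met_oxidation", lin$mods)))
})

test_that("simulated mass errors have the configured ppm spread", {
  spec <- simulation_spec(seed = 43, n_replicates = 8L, noise_frac = 0)
  truth <- generate_truth(spec)
  sim <- simulate_features(truth, spec)
  m <- merge(sim$features, sim$feature_truth, by = "feature_id")
  m <- m[m$kind == "linear" & m$channel == "16O", ]
  expect_gt(nrow(m), 400L)
  theo <- vapply(seq_len(nrow(m)), function(k)
    peptide_mass(m$sequence[k], mods = oxlink:::decode_mods(m$mods[k])),
    numeric(1))
  obs <- mass_from_mz(m$mz, m$charge)
  ppm <- ppm_error(obs, theo)
  expect_equal(sd(ppm), 2, tolerance = 0.1)
  expect_lt(abs(mean(ppm)), 0.3)
})

test_that("noise-free simulation closes the loop: RSO equals the planted truth", {
  spec <- noiseless_spec(seed = 3)
  truth <- generate_truth(spec)
  sim <- simulate_features(truth, spec)
  rt <- rso_table(records_from_features(sim))
  m <- merge(rt, truth$sites, by = c("protein_id", "residue_number",
                                     "modification"))
  expect_equal(nrow(m), nrow(truth$sites))
  expect_equal(m$rso_percent, m$occupancy, tolerance = 1e-9)
})

test_that("spectrum dropout spans the full evidence range", {
  spec <- simulation_spec(seed = 4, n_replicates = 1L)
  truth <- generate_truth(spec)
  xl <- truth$crosslinks[1, ]
  pair <- pair_from_candidate(data.frame(
    alpha_seq = xl$alpha_seq, alpha_protein = "miniFN",
    alpha_start = xl$alpha_start,
    alpha_mods = oxlink:::encode_mods(oxlink:::.planted_peptide(
      xl$alpha_seq, xl$alpha_start, xl$alpha_nitration_pos, "miniFN")$mods),
    alpha_mc = 0L, beta_seq = xl$beta_seq, beta_protein = "miniFN",
    beta_start = xl$beta_start,
    beta_mods = oxlink:::encode_mods(oxlink:::.planted_peptide(
      xl$beta_seq, xl$beta_start, xl$beta_nitration_pos, "miniFN")$mods),
    beta_mc = 0L, link_alpha_pos = xl$alpha_link_pos,
    link_beta_pos = xl$beta_link_pos, stringsAsFactors = FALSE))
  fr <- fragment_ions(pair, c("b", "y"), 2L)
  sp_full <- simulate_spectra(truth, spec, dropout = 0, n_noise_peaks = 0L)
  expect_equal(score_match(sp_full[[1]], fr), 100)
  sp_none <- simulate_spectra(truth, spec, dropout = 1, n_noise_peaks = 0L)
  expect_equal(score_match(sp_none[[1]], fr), 0)
})

test_that("planted occupancies are recovered within two points over twenty replicates", {
  spec <- simulation_spec(seed = 11, n_replicates = 20L)
  truth <- generate_truth(spec)
  sim <- simulate_features(truth, spec)
  rt <- rso_table(records_from_features(sim))
  m <- merge(rt, truth$sites, by = c("protein_id", "residue_number",
                                     "modification"))
  # the planted map includes sites at 5, 15, 30 and 50 percent
  expect_true(all(c(5, 15, 30, 50) %in% m$occupancy))
  expect_lt(max(abs(m$rso_percent - m$occupancy)), 2)
})
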