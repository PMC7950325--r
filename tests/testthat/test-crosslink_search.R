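test_that("candidate enumeration pairs every eligible Tyr/Trp combination once", {
  f1 <- forms_of(c("AYK", "GWR"))
  expect_equal(nrow(enumerate_candidates(f1, "YW")), 1L)
  f2 <- forms_of(c("AYYK", "GYR"))
  cands <- enumerate_candidates(f2, "YY")
  expect_equal(nrow(cands), 2L)
  # benchmark di-Tyr pair appears among candidates from the fixture digest
  fx <- mini_fibronectin()
  d <- digest(fx$sequence, digest_spec(2L, "full", 6L, 45L),
              protein_id = fx$protein_id)
  forms <- modified_forms(d)
  all_c <- enumerate_candidates(forms)
  hit <- all_c[all_c$alpha_seq == "YSFCTDHTVLVQTR" &
                 all_c$beta_seq == "TFYSCTTEGR" &
                 all_c$link_alpha_pos == 1L & all_c$link_beta_pos == 3L, ]
  expect_gte(nrow(hit), 1L)
})

test_that("a form is never paired with itself and pairs are unordered", {
  f <- forms_of("AYYK")
  expect_equal(nrow(enumerate_candidates(f, "YY")), 0L)
  f2 <- forms_of(c("AYYK", "GYWR"))
  cands <- enumerate_candidates(f2, c("YY", "YW"))
  # YY: Y2/Y3 x Y2; YW: Y2/Y3 of the first x W3 of the second
  expect_equal(sum(cands$link_type == "YY"), 2L)
  expect_equal(sum(cands$link_type == "YW"), 2L)
})

test_that("precursor matching applies the ppm tolerance and ranks by error", {
  a <- cam_peptide("TFYSCTTEGR"); b <- cam_peptide("YSFCTDHTVLVQTR")
  cands <- data.frame(alpha_protein = "p", alpha_seq = b$sequence,
                      alpha_start = 1L, alpha_mods = "", alpha_mc = 0L,
                      beta_protein = "p", beta_seq = a$sequence,
                      beta_start = 1L, beta_mods = "", beta_mc = 0L,
                      link_alpha_pos = 1L, link_beta_pos = 3L,
                      link_type = "YY",
                      mass = crosslink_mass(crosslink_pair(a, b, 3, 1)),
                      decoy = FALSE, stringsAsFactors = FALSE)
  hit <- match_precursor(cands, neutral_mass = 2944.312, tol_ppm = 10)
  expect_equal(nrow(hit), 1L)
  expect_lt(abs(hit$ppm_error), 1)
  expect_equal(nrow(match_precursor(cands, neutral_mass = 2944.50,
                                    tol_ppm = 10)), 0L)
  # observed 4980.235 vs theoretical 4980.267: ~6.4 ppm, inside 10 ppm
  mods_b <- rbind(cam_mods("WCHDNGVNYK"),
                  data.frame(pos = 9, name = "nitration", delta = NIT_DELTA))
  yw <- crosslink_pair(peptide("VEYELSEEGDEPQYLDLPSTATSVNIPDLLPGR"),
                       peptide("WCHDNGVNYK", mods = mods_b), 3, 1)
  cands$mass <- crosslink_mass(yw)
  hit2 <- match_precursor(cands, neutral_mass = 4980.235, tol_ppm = 10)
  expect_equal(nrow(hit2), 1L)
  expect_equal(abs(hit2$ppm_error), 6.4, tolerance = 0.02)
})

test_that("b/y ladders are complementary and match direct arithmetic", {
  fr_gr <- fragment_ions(peptide("GR"), "b", 1L)
  expect_equal(fr_gr$mz[fr_gr$series == "b" & fr_gr$index == 2],
               214.129851, tolerance = 1e-7)
  set.seed(11)
  for (i in 1:5) {
    s <- random_sequence(sample(6:15, 1))
    mods <- if (grepl("C", s)) cam_mods(s) else NULL
    p <- peptide(s, mods = mods)
    fr <- fragment_ions(p, c("b", "y"), 1L)
    n <- nchar(s)
    for (k in 1:(n - 1)) {
      bk <- fr$neutral_mass[fr$series == "b" & fr$index == k][1]
      ynk <- fr$neutral_mass[fr$series == "y" & fr$index == n - k][1]
      expect_equal(bk + ynk, peptide_mass(p), tolerance = 1e-9)
    }
  }
})

test_that("link-retaining fragments carry the partner mass plus the link delta", {
  a <- cam_peptide("YSFCTDHTVLVQTR"); b <- cam_peptide("TFYSCTTEGR")
  pr <- crosslink_pair(a, b, 1, 3)
  fr <- fragment_ions(pr, c("b", "y"), 1L)
  b1 <- fr[fr$chain == "alpha" & fr$series == "b" & fr$index == 1, ]
  expect_true(b1$retains_link)
  expect_equal(b1$neutral_mass, 1381.560867, tolerance = 1e-6)
  # alpha y ions up to index 13 exclude the link at position 1
  y13 <- fr[fr$chain == "alpha" & fr$series == "y" & fr$index == 13, ]
  expect_false(y13$retains_link)
})

test_that("scoring weighs link-retaining fragments 2:1 and ignores intensity scale", {
  frags <- data.frame(chain = "alpha", series = "b", index = 1:8,
                      retains_link = rep(c(FALSE, TRUE), each = 4),
                      neutral_mass = NA_real_, charge = 1L,
                      mz = seq(200, 900, by = 100))
  sp_all <- spectrum_of(frags$mz)
  expect_equal(score_match(sp_all, frags), 100)
  sp_none <- spectrum_of(frags$mz + 5)
  expect_equal(score_match(sp_none, frags), 0)
  # all plain matched, no link-retaining, equal counts: 4/(4+8) of the weight
  sp_plain <- spectrum_of(frags$mz[1:4])
  expect_equal(score_match(sp_plain, frags), 100 / 3, tolerance = 1e-9)
  sp_scaled <- ms2_spectrum(1000, 3L, data.frame(mz = frags$mz[1:4],
                                                 intensity = 1e7))
  expect_equal(score_match(sp_scaled, frags), score_match(sp_plain, frags))
  empty <- ms2_spectrum(1000, 3L, data.frame(mz = numeric(), intensity = numeric()))
  expect_equal(score_match(empty, frags), 0)
})

test_that("match filtering enforces score, intensity floor and replicate consistency", {
  base <- data.frame(alpha_seq = "AYK", alpha_mods = "", link_alpha_pos = 2L,
                     beta_seq = "GWR", beta_mods = "", link_beta_pos = 2L,
                     ppm_error = 0.5, decoy = FALSE,
                     stringsAsFactors = FALSE)
  m <- rbind(cbind(base, score = 49.9, intensity = 1e5, replicate = 1L),
             cbind(base, score = 80, intensity = 1500, replicate = 1L))
  expect_equal(nrow(filter_matches(m, 50, 2000, 1L)), 0L)
  m2 <- cbind(base, score = 80, intensity = 1e5, replicate = 1L)
  expect_equal(nrow(filter_matches(m2, 50, 2000, 2L)), 0L)
  m3 <- rbind(cbind(base, score = 80, intensity = 1e5, replicate = 1L),
              cbind(base, score = 70, intensity = 1e5, replicate = 2L))
  out <- filter_matches(m3, 50, 2000, 2L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$score, 80)
  expect_equal(out$n_replicates, 2L)
})

test_that("decoy matches stay below the configured FDR on synthetic data", {
  r <- run_fixture_search(seed = 5, with_decoys = TRUE)
  acc <- r$res$accepted
  expect_gte(nrow(acc[!acc$decoy, ]), 4L - 0L)
  expect_lte(estimate_fdr(acc), 0.05)
})
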