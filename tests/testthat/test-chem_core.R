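test_that("peptide masses match hand-summed residue arithmetic", {
  expect_equal(peptide_mass("G"), 75.032029, tolerance = 1e-8)
  expect_equal(peptide_mass("GR"), 231.133140, tolerance = 1e-8)
  # beta chain of the benchmark di-Tyr pair, Cys carbamidomethylated
  expect_equal(peptide_mass(cam_peptide("TFYSCTTEGR")), 1220.513188,
               tolerance = 1e-8)
  expect_error(peptide_mass("GXZ"), "unknown residue letter 'X' at position 2")
})

test_that("m/z conversion round-trips and matches the direct formula", {
  expect_equal(mz_from_mass(0, 1), 1.007276, tolerance = 1e-9)
  expect_equal(mz_from_mass(2944.31197, 5), 589.86967, tolerance = 1e-7)
  expect_error(mz_from_mass(1000, 0))
  set.seed(1)
  for (m in runif(20, 300, 8000)) {
    z <- sample(1:6, 1)
    expect_equal(mass_from_mz(mz_from_mass(m, z), z), m, tolerance = 1e-9)
  }
})

test_that("cross-link masses reproduce the -2 H arithmetic on benchmark pairs", {
  a <- cam_peptide("TFYSCTTEGR")
  b <- cam_peptide("YSFCTDHTVLVQTR")
  di_tyr <- crosslink_pair(a, b, 3, 1)
  expect_equal(di_tyr$link_type, "YY")
  m <- crosslink_mass(di_tyr)
  expect_equal(m, 2944.31199, tolerance = 1e-7)
  expect_lt(abs(m - 2944.311), 0.002)           # printed theoretical value
  # Tyr-Trp pair with one nitration
  mods_b <- rbind(cam_mods("WCHDNGVNYK"),
                  data.frame(pos = 9, name = "nitration", delta = NIT_DELTA))
  yw <- crosslink_pair(peptide("VEYELSEEGDEPQYLDLPSTATSVNIPDLLPGR"),
                       peptide("WCHDNGVNYK", mods = mods_b), 3, 1)
  expect_equal(yw$link_type, "YW")
  expect_equal(crosslink_mass(yw), 4980.26722, tolerance = 1e-7)
  gg <- crosslink_pair(peptide("GGYGG"), peptide("GGYGG"), 3, 3)
  expect_equal(crosslink_mass(gg), 2 * peptide_mass("GGYGG") - 2.015650,
               tolerance = 1e-9)
  expect_error(crosslink_pair(peptide("AGK"), peptide("AYK"), 1, 2),
               "not Y or W")
})

test_that("18O label shifts give the +4/+8 Da linear/cross-linked signatures", {
  expect_equal(label_shift(1, 2), 4.008492, tolerance = 1e-6)
  expect_equal(label_shift(2, 2), 8.016984, tolerance = 1e-6)
  expect_identical(label_shift(1, 0), 0)
  expect_error(label_shift(3, 2))
  expect_error(label_shift(1, 3))
})

test_that("mass additivity, concatenation and ppm properties hold on random peptides", {
  set.seed(42)
  for (i in 1:20) {
    sa <- random_sequence(sample(4:20, 1))
    sb <- random_sequence(sample(4:20, 1))
    pa <- peptide(paste0(sa, "Y"))   # guaranteed link residues at the ends
    pb <- peptide(paste0(sb, "W"))
    pr <- crosslink_pair(pa, pb, nchar(pa$sequence), nchar(pb$sequence))
    expect_equal(crosslink_mass(pr),
                 peptide_mass(pa) + peptide_mass(pb) - 2.015650,
                 tolerance = 1e-12)
    expect_equal(peptide_mass(paste0(sa, sb)),
                 peptide_mass(sa) + peptide_mass(sb) - mass_constants()$water,
                 tolerance = 1e-9)
    m <- runif(1, 500, 5000)
    expect_equal(ppm_error(m * (1 + 1e-6), m), 1.0, tolerance = 1e-6)
    expect_equal(ppm_error(m, m * (1 + 1e-6)), -1.0, tolerance = 1e-5)
  }
})

test_that("modification sets load from config lists", {
  mods <- modifications_from_config(list(
    list(name = "nitration", targets = list("Y", "W"), delta = 44.985078,
         kind = "variable", max_per_peptide = 2),
    list(name = "carbamidomethyl", targets = "C", delta = 57.021464,
         kind = "fixed")))
  expect_equal(mods$nitration$targets, c("Y", "W"))
  expect_equal(mods$carbamidomethyl$kind, "fixed")
  expect_equal(mods$nitration$max_per_peptide, 2L)
})

test_that("residue census counts oxidant-target residues", {
  expect_equal(residue_census("YYWMA"), c(Y = 2L, W = 1L, M = 1L))
  fx <- mini_fibronectin()
  cen <- residue_census(fx$sequence)
  expect_equal(unname(cen["Y"]), 6L)   # planted Tyr sites of the fixture
  expect_equal(unname(cen["W"]), 4L)
})
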