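rec_row <- function(start, sequence, mods = "", area = 1e6, condition = "ox",
                    replicate = 1L) {
  data.frame(protein_id = "p", start = start, sequence = sequence,
             mods = mods, area = area, condition = condition,
             replicate = replicate, stringsAsFactors = FALSE)
}
nit <- function(pos) sprintf("%d:nitration:%.6f", pos, NIT_DELTA)

test_that("RSO is the modified fraction of the summed covering areas", {
  r <- rbind(rec_row(10, "AYSK", nit(2), area = 1e6),
             rec_row(10, "AYSK", "", area = 1e6))
  s <- rso(r, "p", 11, "nitration")
  expect_equal(s$rso_percent, 50)
  expect_equal(s$residue, "Y")
  # no modified forms detected -> 0 percent, still identified
  s0 <- rso(rec_row(10, "AYSK", ""), "p", 11, "nitration")
  expect_equal(s0$rso_percent, 0)
  # modified areas {30, 20}, unmodified {50} -> 50%
  r2 <- rbind(rec_row(10, "AYSK", nit(2), area = 30),
              rec_row(8, "GGAYSKR", nit(4), area = 20),
              rec_row(10, "AYSK", "", area = 50))
  expect_equal(rso(r2, "p", 11, "nitration")$rso_percent, 50)
  # uncovered site is not identified, not 0%
  expect_null(rso(rec_row(10, "AYSK"), "p", 30, "nitration"))
})

test_that("sites seen only in modified form report 100% with a low-confidence flag", {
  s <- rso(rec_row(10, "AYSK", nit(2)), "p", 11, "nitration")
  expect_equal(s$rso_percent, 100)
  expect_true(s$low_confidence)
})

test_that("RSO is invariant under uniform area scaling and matches the brute-force oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    starts <- sample(5:10, n, replace = TRUE)
    recs <- do.call(rbind, lapply(seq_len(n), function(k) {
      seq <- "GAYSMK"
      has_nit <- runif(1) < 0.5
      rec_row(starts[k], seq, if (has_nit) nit(3) else "",
              area = runif(1, 10, 1e6))
    }))
    site <- 7 + sample(0:3, 1)   # may or may not be the Tyr of some records
    got <- rso(recs, "p", site, "nitration")
    want <- oracle_rso(recs, site, "nitration")
    if (is.null(got)) {
      expect_true(is.na(want))
    } else {
      expect_equal(got$rso_percent, want, tolerance = 1e-12)
      scaled <- recs; scaled$area <- scaled$area * 137.5
      expect_equal(rso(scaled, "p", site, "nitration")$rso_percent,
                   got$rso_percent, tolerance = 1e-12)
    }
  }
})

test_that("replicates are averaged at the RSO level", {
  r <- rbind(rec_row(10, "AYSK", nit(2), area = 2e6, replicate = 1L),
             rec_row(10, "AYSK", "", area = 2e6, replicate = 1L),
             rec_row(10, "AYSK", nit(2), area = 1e6, replicate = 2L),
             rec_row(10, "AYSK", "", area = 3e6, replicate = 2L))
  s <- rso(r, "p", 11, "nitration")
  expect_equal(s$rso_percent, mean(c(50, 25)))
  expect_equal(s$n_replicates, 2L)
  expect_equal(s$rso_sd, sd(c(50, 25)))
})

test_that("coverage statistics follow the percent-of-total and percent-of-identified conventions", {
  pc <- class_percentages(8, 25, 6)
  expect_equal(pc$pct_of_total, 20.5, tolerance = 0.05)
  expect_equal(pc$pct_of_identified, 24.2, tolerance = 0.05)
  expect_equal(100 * 33 / 39, 84.6, tolerance = 0.05)
  # from records on a toy chain: 10 residues, peptide covers 6
  seqs <- "AYKMWTSGRA"
  recs <- rbind(rec_row(1, "AYKMWT", nit(2)), rec_row(1, "AYKMWT", ""))
  cov <- coverage_stats(recs, seqs)
  expect_equal(cov$coverage_percent, 60)
  ycl <- cov$residue_classes[cov$residue_classes$residue == "Y", ]
  expect_equal(ycl$modified, 1L)
  expect_equal(ycl$pct_of_identified, 100)
  wcl <- cov$residue_classes[cov$residue_classes$residue == "W", ]
  expect_equal(wcl$modified, 0L)
  expect_equal(wcl$not_identified, 0L)
  # glycosylation exclusion removes sites from numerator and denominator
  cov2 <- coverage_stats(recs, seqs, glyco_exclusion_sites = c(7, 8))
  expect_equal(cov2$coverage_percent_excluding_glyco, 100 * 6 / 8)
  # no peptides: zero coverage, everything unidentified
  cov0 <- coverage_stats(recs[0, ], seqs)
  expect_equal(cov0$coverage_percent, 0)
  expect_true(all(cov0$residue_classes$not_identified ==
                    cov0$residue_classes$total))
})

test_that("condition comparison subtracts with assumed zeros and is antisymmetric", {
  mk <- function(res_num, rso_val) {
    data.frame(protein_id = "p", residue_number = res_num, residue = "Y",
               modification = "nitration", rso_percent = rso_val,
               stringsAsFactors = FALSE)
  }
  a <- mk(c(10, 20), c(10, 5))
  b <- mk(c(10, 30), c(25, 39))
  d <- compare_conditions(a, b)
  expect_equal(d$delta[d$residue_number == 10], -15)
  expect_equal(d$delta[d$residue_number == 20], 5)
  expect_equal(d$assumed_zero[d$residue_number == 20], "b")
  # site absent from A with B = 39% contributes -39 with the flag set
  expect_equal(d$delta[d$residue_number == 30], -39)
  expect_equal(d$assumed_zero[d$residue_number == 30], "a")
  d_rev <- compare_conditions(b, a)
  m <- merge(d, d_rev, by = c("protein_id", "residue_number", "modification"))
  expect_equal(m$delta.x, -m$delta.y)
  expect_equal(compare_conditions(a, a)$delta, c(0, 0))
})

test_that("summaries report mean RSO over modified sites and flag large changes", {
  tab <- data.frame(protein_id = "p", residue_number = 1:4, residue = "Y",
                    modification = "nitration",
                    rso_percent = c(10, 20, 30, 0), stringsAsFactors = FALSE)
  s <- summarize_rso(tab)
  expect_equal(s$mean_rso_modified, 20)
  tab0 <- tab; tab0$rso_percent <- 0
  expect_true(is.na(summarize_rso(tab0)$mean_rso_modified))
  deltas <- data.frame(protein_id = "p", residue_number = 1:2,
                       modification = "nitration", delta = c(12, -5))
  s2 <- summarize_rso(tab, deltas = deltas, min_change_percent = 10)
  expect_equal(nrow(s2$changed_sites), 1L)
  expect_equal(s2$changed_sites$delta, 12)
})
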