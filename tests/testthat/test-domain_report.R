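test_that("sites map to their modules and linkers by interval lookup", {
  fx <- mini_fibronectin()
  asg <- assign_site(c(20L, 43L, 74L, 178L, 192L), fx$annotations)
  expect_equal(asg$module_name, c("FNII_1", "FNII_1", "FNI_3", "FNI_11",
                                  "FNI_11"))
  expect_equal(asg$functional_domain[3], "fibrin-binding-1")
  # residues in the gaps between modules are linker/interdomain
  expect_equal(assign_site(5L, fx$annotations)$module_name,
               "linker/interdomain")
  expect_error(assign_site(301L, fx$annotations, chain_length = 300L),
               "beyond chain length")
  # assignment is single-valued and idempotent over the whole chain
  a1 <- assign_site(1:300, fx$annotations)
  a2 <- assign_site(1:300, fx$annotations)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 300L)
})

test_that("annotation tables reject overlapping or inverted intervals", {
  bad <- data.frame(module_name = c("a", "b"), start = c(1, 5),
                    end = c(10, 8), functional_domain = "x")
  expect_error(domain_annotations(bad), "overlap")
  bad2 <- data.frame(module_name = "a", start = 10, end = 2,
                     functional_domain = "x")
  expect_error(domain_annotations(bad2), "start <= end")
})

test_that("topology calls match the fraction-provenance truth table", {
  subsets <- list("monomer", "dimer", "unfractionated",
                  c("monomer", "dimer"), c("monomer", "unfractionated"),
                  c("dimer", "unfractionated"),
                  c("monomer", "dimer", "unfractionated"))
  want <- c("intramolecular", "intermolecular", "ambiguous",
            "intermolecular", "intramolecular", "intermolecular",
            "intermolecular")
  got <- vapply(subsets, classify_topology, character(1))
  expect_equal(got, want)
  expect_error(classify_topology(character(0)), "empty")
  expect_error(classify_topology("pellet"), "unknown fraction")
})

test_that("RSO bins are half-open with the documented boundaries", {
  expect_equal(as.character(rso_bin(c(31, 10, 10.01, 25, 2))),
               c(">30%", "1-10%", "10-20%", "20-30%", "1-10%"))
  expect_true(is.na(rso_bin(0)))
  expect_true(is.na(rso_bin(1)))   # 1% and below unbinned
})

test_that("the domain report joins sites, bins and cross-link module pairs", {
  fx <- mini_fibronectin()
  sites <- data.frame(protein_id = "miniFN",
                      residue_number = c(20L, 74L, 143L),
                      residue = c("Y", "W", "Y"), modification = "nitration",
                      rso_percent = c(35, 0.5, 12), stringsAsFactors = FALSE)
  xl <- data.frame(alpha_residue = 43L, beta_residue = 20L,
                   link_type = "YY", topology = "intermolecular",
                   stringsAsFactors = FALSE)
  rep_ <- render_report(sites, xl, fx$annotations)
  expect_equal(nrow(rep_$site_report), 2L)     # 0.5% site unbinned
  expect_equal(as.character(rep_$site_report$bin), c(">30%", "10-20%"))
  expect_equal(rep_$crosslink_report$alpha_module, "FNII_1")
  expect_true(any(grepl("FNII_1", rep_$schematic)))
  expect_true(any(grepl("intermolecular", rep_$schematic)))
})
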