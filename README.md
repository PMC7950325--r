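# oxlink

Mapping oxidant-induced protein modifications and cross-links from
bottom-up mass spectrometry data.

Inflammatory oxidants such as peroxynitrous acid (ONOOH) nitrate Tyr and
Trp side chains (3-nitrotyrosine / 6-nitrotryptophan, +44.985 Da), oxidize
Met to the sulfoxide (+15.995 Da), and dimerize Tyr/Trp radicals into
covalent di-tyrosine, di-tryptophan and tyrosine–tryptophan cross-links.
These modifications rewire the structure of extracellular-matrix proteins
such as fibronectin, and mapping them — which residues, how much, and
which pairs of sites become covalently joined — is a conformational
footprint of the oxidized protein. oxlink is for proteomics analysts who
have MS1 feature tables and MS2 peak lists in hand and need a transparent,
testable pipeline for that mapping.

## The model at the core

A direct side-chain cross-link loses two hydrogens, so a candidate pair
must satisfy, within the precursor tolerance,

    M(α×β) = M(α) + M(β) − 2.01565 Da

while ¹⁶O/¹⁸O proteolytic labeling separates species classes by the
charge-corrected shift of co-eluting feature doublets: +4.008 Da for a
linear peptide (one new C-terminus, two ¹⁸O) and +8.017 Da for a
cross-linked pair (two new termini). Per-residue modification extent is
the relative site occupancy

    RSO(site) = 100 × Σ area(modified forms covering site)
                    / Σ area(all forms covering site)

and two-condition comparisons are per-site RSO differences. The package
covers tryptic digestion, candidate enumeration, fragment-ion scoring with
target–decoy FDR estimation, doublet classification, RSO quantification,
coverage statistics, footprint comparison and domain-level reporting,
plus a seeded synthetic-data generator with known ground truth. See the
methods vignette (`vignettes/oxlink-methods.Rmd`) for the full model.

## Worked example

```r
library(oxlink)

# the benchmark di-Tyr pair, both chains carbamidomethylated on Cys
a <- peptide("TFYSCTTEGR",     mods = data.frame(pos = 5, name = "carbamidomethyl", delta = 57.021464))
b <- peptide("YSFCTDHTVLVQTR", mods = data.frame(pos = 4, name = "carbamidomethyl", delta = 57.021464))
pair <- crosslink_pair(a, b, 3, 1)   # linked through Y3 and Y1
crosslink_mass(pair)                 # 2944.312 Da
mz_from_mass(crosslink_mass(pair), 5)  # 589.8697
label_shift(1, 2); label_shift(2, 2)   # +4.008 Da linear, +8.017 Da cross-linked

# end-to-end on the synthetic mini-fibronectin fixture
spec    <- simulation_spec(seed = 1)
truth   <- generate_truth(spec)
sim     <- simulate_features(truth, spec)
spectra <- simulate_spectra(truth, spec)
res <- run_crosslink_search(sim$features, spectra, spec$fixture$sequence,
                            pipeline_config(), protein_id = "miniFN")
res$accepted[, c("alpha_residue", "beta_residue", "link_type", "score", "n_replicates")]
```

```
  alpha_residue beta_residue link_type    score n_replicates
1           132          178        YW 93.70079            2
2           178           74        WW 97.56098            3
3           192          100        WW 93.81443            2
4            43           20        YY 95.71429            3
```

All four planted cross-links are recovered — one di-Tyr (Y43×Y20), two
di-Trp and one Tyr–Trp — each with its correct linked residues, fragment
score (0–100) and replicate support. Site quantification on the same run:

```r
rt <- rso_table(records_from_features(sim))
head(rt[order(-rt$rso_percent),
        c("residue_number", "residue", "modification", "rso_percent", "rso_sd")], 5)
```

```
   residue_number residue  modification rso_percent rso_sd
4             100       W     nitration        48.2   1.86
12            201       M met_oxidation        40.2   2.11
1              20       Y     nitration        31.1   1.44
14            286       M met_oxidation        30.1   0.99
9             186       Y     nitration        24.1   1.13
```

The estimates sit within two percentage points of the planted occupancies
(W100 = 50%, M201 = 40%, Y20 = 30%, M286 = 30%, Y186 = 25%): each value is
the mean over three replicates of the modified-over-total MS1 area ratio
at that residue.

A thin command-line wrapper around the same functions is installed at
`system.file("scripts", "oxlink.R", package = "oxlink")`, with
subcommands `digest`, `simulate`, `classify-18o`, `search-xl`,
`quantify`, `compare` and `report`.

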