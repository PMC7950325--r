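---
title: "Methods: mapping oxidant-induced modifications and cross-links"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping oxidant-induced modifications and cross-links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxlink)
```

## The analysis problem

Inflammatory oxidants such as peroxynitrous acid nitrate Tyr and Trp side
chains (+44.985 Da), oxidize Met to the sulfoxide (+15.995 Da), and couple
Tyr/Trp radicals into covalent di-tyrosine, di-tryptophan and
tyrosine-tryptophan cross-links. A direct side-chain coupling loses two
hydrogen atoms, so a cross-linked peptide pair has neutral mass

$$M_{\alpha\times\beta} = M_\alpha + M_\beta - 2.01565\ \mathrm{Da}.$$

oxlink implements the full bottom-up workflow around this arithmetic:
in-silico tryptic digestion, candidate enumeration and fragment-ion scoring
for cross-linked pairs, ^16^O/^18^O proteolytic-label doublet
classification, relative site occupancy (RSO) quantification from MS1
areas, two-condition footprint comparison, and domain-level mapping.

## Mass model

Neutral monoisotopic peptide masses are the sum of standard residue masses
(six decimal places), water (18.010565 Da), modification deltas and the
^18^O label shift; $m/z = (M + z \cdot 1.007276)/z$. Modification deltas
are fixed at +57.021464 (carbamidomethyl Cys, fixed), +44.985078
(nitration of Tyr/Trp), +15.994915 (Met sulfoxide) and optionally
+33.961028 (chlorination of Tyr, for hypochlorite-style comparisons).
Printed literature values for these quantities typically carry 2--3
decimals; recomputation from standard residue masses can differ from a
source tool's printed theoretical mass by about 1 mDa, so agreement within
0.002 Da is the appropriate expectation when comparing against published
tables. All internal computation is at full double precision; rounding
(masses to 3 decimals, m/z to 4) happens only in report writers.

## Digestion

Trypsin cleaves C-terminal to K/R except before Pro. Fully specific
peptides are unions of 1 to (max missed cleavages + 1) consecutive
zero-missed-cleavage fragments; semispecific digestion adds peptides with
exactly one ragged terminus. Chain ends count as tryptic termini. Defaults
(missed cleavages ≤ 2, length 6--45, at most 3 variable modifications per
peptide) mirror common search-engine settings; the missed-cleavage bound
of two is the value used in the experimental searches this workflow
emulates. The implementation is validated against a brute-force oracle
that tests every substring of random chains against the cleavage-site
list.

## Cross-link search

Candidates are all unordered pairs of *distinct* peptide forms in which
each partner contributes one Tyr or Trp consistent with the requested link
chemistry (YY, WW, YW); the longer chain is reported as alpha. Two design
choices deserve note:

* A residue carrying a nitro group may still serve as the link site:
  6-nitrotryptophan is nitrated on the indole ring at a position distinct
  from the carbon that forms the cross-link, so co-occurrence is
  chemically admissible, and one of the benchmark di-Trp pairs requires
  two nitrations on a pair whose shorter chain offers no other Tyr/Trp.
* Pairing a peptide form with itself (a homodimer of the identical
  tryptic peptide) is excluded from enumeration; the supported chemistries
  link two distinct digest products.

Precursor matching uses a 10 ppm tolerance (4.5 ppm is the default for
linear-peptide searches), charges 2--6, and mass caps of 6000 Da per chain
and 8000 Da per pair to control candidate explosion.

Fragment ions are standard b/y (and c/z for ETD-style spectra) ladders,
including the full-length b ion; any fragment containing the linked
residue carries the partner peptide's full mass plus the link delta.
The match score is 100 times the weighted fraction of theoretical
fragments matched within the MS2 tolerance (0.02 m/z), with
cross-link-retaining fragments weighted 2:1 over plain fragments. The
score is deterministic and invariant to uniform intensity scaling; the
published workflow relied on an undocumented vendor score with an accept
threshold of 50, so this package defines a transparent score and exposes
the threshold (default 50, strictly greater) in the configuration.
Isobaric link-position and modification-position isomers compete on
fragment evidence and only the rank-1 candidate per doublet is retained,
as search engines report rank-1 peptide-spectrum matches. Acceptance
additionally requires a precursor intensity of at least 2000 and, by
default, identification in at least 2 replicates. Decoys are
reversed-sequence peptides with a C-terminal K/R held in place; the FDR
estimate is the decoy/target ratio in the accepted set.

## ^16^O/^18^O doublet classification

Digestion in heavy-oxygen water installs up to two ^18^O atoms
(+2.004246 Da each) at every newly formed C-terminus, so a fully labeled
linear peptide shifts +4.0085 Da and a cross-linked pair (two new termini)
+8.0170 Da; +2.0042 and +6.0127 Da indicate incomplete incorporation.
Classification operates on the charge-corrected neutral shift
$z \cdot (m/z_{heavy} - m/z_{light})$ of co-eluting, same-charge
light/heavy pairs, assigning the nearest admissible shift within
tolerance; negative shifts are never classified. Doublet assembly is
greedy by combined intensity, ties broken by shift error, each feature
used at most once.

The minimum tolerance is ±0.015 Da, but because the shift is a difference
of two independently measured masses its error grows with precursor mass
(about 14 mDa SD at 5 kDa for 2 ppm instruments). The effective tolerance
is therefore `max(0.015, 2e-6 * ppm_tolerance * neutral mass)` with a
10 ppm per-measurement guard. Since admissible shifts are 2 Da apart, the
widened window cannot cause cross-category confusion; it only admits
slightly more random pairings, which downstream precursor matching and
scoring remove.

## Relative site occupancy

For a residue and modification, RSO is 100 times the summed MS1 area of
all peptide forms carrying the modification at that site divided by the
summed area of every form covering the site -- pooling charge states,
missed-cleavage variants, overlapping species and forms carrying other
modifications (including Met oxidation). Sites with no covering record
are reported as *not identified*, which is distinct from 0%. Sites seen
only in modified form report 100% with a low-confidence flag, since the
denominator contains no unmodified evidence. Replicates are averaged at
the RSO level (mean ± SD), not pooled at the area level, matching how
mean ± SD across independent experiments is reported in practice.

Two-condition comparison subtracts per-site RSO (A − B, positive meaning
more modification in A); a site quantified in only one condition enters
with the other condition assumed 0% and is flagged. Coverage statistics
report percent of residues covered (optionally excluding a configured
glycosylation-site list from numerator and denominator) and per residue
class the nitrated / not nitrated / not identified counts, with
percent-of-identified defined as modified/(modified + unmodified).

## Domain mapping

Sites are assigned to modules by interval lookup in a user-supplied
annotation table (module name, start, end, functional domain; 1-based
inclusive mature-chain coordinates); residues between modules are labeled
linker/interdomain. Module boundary coordinates are not part of the
package's claims: a synthetic table ships with the fixture, and users
should substitute coordinates from a sequence-feature database. SEC
provenance determines topology: presence in the dimer fraction implies an
intermolecular link, presence only in the monomer fraction an
intramolecular one, and only-unfractionated is ambiguous. The site
schematic bins RSO into half-open intervals (1,10], (10,20], (20,30],
(30,100]; values of 1% or below are unbinned. The boundary membership of
the published color bins is undefined, so the lower-exclusive convention
is documented rather than inferred.

## The synthetic-data generator

The generator emulates the data level of a 1:1-mixed ^16^O/^18^O
experiment on a 300-residue synthetic "mini-fibronectin" chain that embeds
the eight benchmark peptide sequences with native tryptic flanks (the
two overlapping Trp peptides share their WDR segment, reproducing the
printed 2- and 1-missed-cleavage structures) separated by Tyr/Trp-free
filler. Four cross-linked pairs are planted with the benchmark link
chemistries and SEC provenance; nitration occupancies spanning 5--50% and
Met-sulfoxide occupancies are planted across the fixture sites.

The noise model, chosen for realism and fixed:

* Peptide abundance is log-normal (sigma 0.5 natural-log units, median
  area 10^6^), drawn once per peptide and replicate and **shared** by the
  modified and unmodified forms of that peptide -- the occupancy split is
  chemical, not an independent draw. Each feature area then receives
  independent log-normal measurement noise (sigma 0.1, a typical MS1
  label-free CV). This decomposition is what makes site occupancy
  estimable: were each form's area an independent sigma-0.5 draw, the
  occupancy ratio itself would fluctuate far beyond what replicate
  averaging can remove, which does not match how co-eluting forms of a
  common precursor pool behave.
* m/z error is Gaussian with 2 ppm sigma; charges are drawn from a 2--6
  distribution; missed-cleavage forms are retained with probabilities
  1/0.4/0.15; the heavy channel draws 0/1/2 ^18^O per terminus with 5%
  single-label contamination; 10% of features are unpaired noise.

What the generator does **not** emulate: chromatographic peak shapes,
isotope envelopes, retention-time drift between runs, co-isolation
chimeras, and real ionization-efficiency differences between modified and
unmodified forms. Passing closed-loop tests therefore demonstrates the
correctness of the arithmetic, the classifiers and the estimators under
the stated statistical assumptions -- not robustness to every artifact of
real LC-MS data.

All randomness flows from a single integer seed; identical seeds give
byte-identical outputs.

## Problem sizes and numerical choices in the test suite

The suite validates digestion against the brute-force oracle on random
chains up to 150 residues; cross-link recall/precision end to end on the
300-residue fixture (about 500 MS1 features, 12 spectra per run); and
occupancy recovery with 20 replicates, where planted occupancies of 5,
15, 30 and 50% are recovered within ±2 percentage points. Equalities on
masses are asserted to 10^-9^ Da for additivity identities and to the
printed precision (±0.002 Da) against published table values. Degenerate
inputs are defined rather than left to chance: empty spectra score 0, an
empty digest is a valid result, uncovered sites are not-identified, and
an empty SEC fraction set is an error.

## Known limitations

* Identification of *linear* modified peptides from MS2 is out of scope;
  quantification consumes peptide-level areas and identities produced by
  an upstream search engine (or the simulator).
* Disulfide and MS-cleavable cross-link chemistries, open modification
  searches, protein-level FDR and retention-time alignment are not
  implemented.
* The mass model is monoisotopic only; no average masses or isotope fine
  structure beyond the ^18^O label count.
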