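# Shared fixtures and independent oracles used across the suite.

CAM_DELTA <- 57.021464
NIT_DELTA <- 44.985078

cam_mods <- function(sequence) {
  pos <- which(strsplit(sequence, "")[[1]] == "C")
  if (!length(pos)) return(NULL)
  data.frame(pos = pos, name = "carbamidomethyl", delta = CAM_DELTA)
}

# peptide with fixed Cys carbamidomethylation
cam_peptide <- function(sequence, ...) {
  peptide(sequence, mods = cam_mods(sequence), ...)
}

# plain (unmodified) form rows for enumerate_candidates()
forms_of <- function(sequences, start = 1L) {
  data.frame(protein_id = "p", start = start,
             end = start + nchar(sequences) - 1L, sequence = sequences,
             missed_cleavages = 0L, mods = "", n_var_mods = 0L,
             mass = vapply(sequences, peptide_mass, numeric(1)),
             stringsAsFactors = FALSE)
}

# random peptide sequence without forbidden-letter worries
random_sequence <- function(n, letters = c("G","A","S","P","V","T","C","L",
                                           "I","N","D","Q","K","E","M","H",
                                           "F","R","Y","W")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# brute-force digestion oracle: test every substring against the site list
oracle_digest <- function(sequence, max_mc, specificity, min_len, max_len) {
  n <- nchar(sequence)
  sites <- cleavage_sites(sequence)
  res <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      len <- e - s + 1L
      if (len < min_len) next
      if (len > max_len) break
      nt <- s == 1L || (s - 1L) %in% sites
      ct <- e %in% sites
      mc <- sum(sites >= s & sites <= e - 1L)
      if (mc > max_mc) break
      ok <- if (specificity == "full") nt && ct else nt || ct
      if (ok) res[[length(res) + 1L]] <- c(s, e, mc)
    }
  }
  m <- do.call(rbind, res)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2], missed_cleavages = m[, 3])
}

# brute-force RSO oracle: explicit enumeration over every covering record
oracle_rso <- function(records, residue_number, mod_name) {
  records$end <- records$start + nchar(records$sequence) - 1L
  num <- 0; den <- 0
  for (k in seq_len(nrow(records))) {
    if (records$start[k] > residue_number || records$end[k] < residue_number)
      next
    md <- oxlink:::decode_mods(records$mods[k])
    lp <- residue_number - records$start[k] + 1L
    if (any(md$pos == lp & md$name == mod_name)) num <- num + records$area[k]
    den <- den + records$area[k]
  }
  if (den == 0) return(NA_real_)
  100 * num / den
}

# a spectrum holding exactly the given fragment m/z values
spectrum_of <- function(mzs, precursor_mz = 1000, charge = 3L,
                        intensity = 1e4) {
  ms2_spectrum(precursor_mz, charge,
               data.frame(mz = mzs, intensity = intensity))
}

run_fixture_search <- function(seed, with_decoys = FALSE, ...) {
  spec <- simulation_spec(seed = seed, ...)
  truth <- generate_truth(spec)
  sim <- simulate_features(truth, spec)
  sp <- simulate_spectra(truth, spec)
  res <- run_crosslink_search(sim$features, sp, spec$fixture$sequence,
                              pipeline_config(), protein_id = "miniFN",
                              with_decoys = with_decoys)
  list(spec = spec, truth = truth, sim = sim, res = res)
}

unordered_pairs <- function(a, b) sort(paste(pmin(a, b), pmax(a, b)))
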