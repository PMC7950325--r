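# Ground-truth-known synthetic data: a mini-fibronectin fixture chain, MS1
# feature tables in two 16O/18O channels, and MGF fragment spectra, with
# the statistical structure the analysis assumes.

#' Synthetic mini-fibronectin fixture
#'
#' A 300-residue synthetic chain that embeds, with native tryptic flanks and
#' missed-cleavage structure, the eight peptide sequences that form the four
#' benchmark Tyr-Tyr / Trp-Trp / Tyr-Trp cross-linked pairs, separated by
#' Tyr/Trp-free filler peptides. Module annotations mirror the FN module
#' nomenclature (FNI/FNII/FNIII) so domain mapping is testable end to end.
#' The chain is synthetic: it is not a fragment of the real fibronectin
#' sequence.
#'
#' @return List with `protein_id`, `sequence` (300 residues), `annotations`
#'   ([domain_annotations()] table), `site_occupancy` (default planted
#'   nitration / Met-oxidation occupancies, percent), and `crosslinks`
#'   (the four planted pairs with peptide-local link and nitration
#'   positions, SEC fraction provenance and abundances).
#' @export
mini_fibronectin <- function() {
  segs <- c(
    "MLTEGSANQLASDHVGK",                    # filler
    "TFYSCTTEGR",                           # di-Tyr alpha', Y at chain pos 20
    "AGDSTLHEANSVQGK",
    "YSFCTDHTVLVQTR",                       # di-Tyr partner, Y43
    "LNDAGSQEHVTSLAK",
    "GEWTCKPIAEK",                          # W74; internal K before P uncut
    "SGTDLNHAEVSQGTSLR",
    "WCGTTQNYDADQK",                        # W100, Y107
    "VGSDNTLQAHESGVLSK",
    "VEYELSEEGDEPQYLDLPSTATSVNIPDLLPGR",    # Y132, Y143
    "ASGDTLNEHVQSGTK",
    "WCHDNGVNYKIGEKWDRQGENGQMMSCTCLGNGK",   # W178, Y186, W192, M201/202
    "AGSDTLHEVNSQK",
    "TGELSANDHVSGQLK",
    "QGSDTNALEHVSGTK",
    "SNDGTLEAHVQGSDK",
    "LSDGTNAHEVSQGTLSMDHAGSVTELNQGSA"       # tail, M286
  )
  sequence <- paste(segs, collapse = "")
  stopifnot(nchar(sequence) == 300L)
  annotations <- data.frame(
    module_name = c("FNII_1", "FNI_3", "FNII_2", "FNIII_2", "FNI_11"),
    start = c(18L, 72L, 100L, 130L, 178L),
    end = c(56L, 82L, 112L, 162L, 211L),
    functional_domain = c("collagen-binding", "fibrin-binding-1",
                          "collagen-binding", "matrix-assembly",
                          "fibrin-binding-2"),
    stringsAsFactors = FALSE)
  site_occupancy <- data.frame(
    residue_number = c(20L, 43L, 74L, 100L, 107L, 132L, 143L, 178L, 186L,
                       192L, 201L, 202L, 286L),
    modification = c(rep("nitration", 10L),
                     rep("met_oxidation", 3L)),
    occupancy = c(30, 15, 5, 50, 10, 20, 5, 15, 25, 8, 40, 12, 30),
    stringsAsFactors = FALSE)
  crosslinks <- data.frame(
    xl_id = c("XL1", "XL2", "XL3", "XL4"),
    alpha_seq = c("TFYSCTTEGR", "WCHDNGVNYKIGEKWDR",
                  "WDRQGENGQMMSCTCLGNGK",
                  "VEYELSEEGDEPQYLDLPSTATSVNIPDLLPGR"),
    alpha_start = c(18L, 178L, 192L, 130L),
    alpha_link_pos = c(3L, 1L, 1L, 3L),
    alpha_nitration_pos = c("", "9", "1", ""),
    beta_seq = c("YSFCTDHTVLVQTR", "GEWTCKPIAEK", "WCGTTQNYDADQK",
                 "WCHDNGVNYK"),
    beta_start = c(43L, 72L, 100L, 178L),
    beta_link_pos = c(1L, 3L, 1L, 1L),
    beta_nitration_pos = c("", "", "8", "9"),
    link_type = c("YY", "WW", "WW", "YW"),
    fraction = c("dimer", "dimer", "dimer", "unfractionated"),
    abundance = c(8e5, 6e5, 6e5, 5e5),
    stringsAsFactors = FALSE)
  list(protein_id = "miniFN", sequence = sequence, annotations = annotations,
       site_occupancy = site_occupancy, crosslinks = crosslinks)
}

#' Simulation specification
#'
#' Parameters of the synthetic experiment: the chain and planted truth, the
#' intensity and mass-error models, the charge and 18O-incorporation
#' distributions, and the seed. Defaults emulate a well-behaved bottom-up
#' run: log-normal peptide abundances (sigma 0.5 natural-log units) shared
#' between the modified and unmodified forms of a peptide within a
#' replicate, 10% multiplicative measurement noise per feature area, 2 ppm
#' Gaussian m/z error, 5% single-18O (incomplete) incorporation, and 10% of
#' features as unpaired noise.
#'
#' @param fixture A [mini_fibronectin()]-style list (chain plus truth).
#' @param n_replicates Replicates per condition.
#' @param condition Condition label.
#' @param abundance_median Median MS1 area of a peptide.
#' @param abundance_sigma Log-normal sigma of peptide abundances (natural
#'   log), drawn per peptide and replicate.
#' @param measurement_sigma Log-normal sigma of per-feature area noise.
#' @param ppm_sigma Gaussian m/z error, ppm.
#' @param charge_probs Named probabilities over charges 2..6.
#' @param mc_retention Probability that a peptide form with 0, 1, 2 missed
#'   cleavages is observed.
#' @param o18_probs Probabilities of 0, 1 or 2 18O atoms per new C-terminus
#'   in the heavy channel.
#' @param noise_frac Unpaired random features as a fraction of signal
#'   features.
#' @param rt_range Retention-time range (minutes) features are placed in.
#' @param seed Integer seed; identical seeds give identical outputs.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(fixture = mini_fibronectin(),
                            n_replicates = 3L, condition = "oxidized",
                            abundance_median = 1e6, abundance_sigma = 0.5,
                            measurement_sigma = 0.1, ppm_sigma = 2,
                            charge_probs = c(`2` = 0.35, `3` = 0.35,
                                             `4` = 0.15, `5` = 0.10,
                                             `6` = 0.05),
                            mc_retention = c(1, 0.4, 0.15),
                            o18_probs = c(`0` = 0, `1` = 0.05, `2` = 0.95),
                            noise_frac = 0.10, rt_range = c(10, 110),
                            seed = 1L) {
  stopifnot(all(fixture$site_occupancy$occupancy >= 0),
            all(fixture$site_occupancy$occupancy <= 100),
            abs(sum(charge_probs) - 1) < 1e-8,
            abs(sum(o18_probs) - 1) < 1e-8)
  structure(list(fixture = fixture, n_replicates = as.integer(n_replicates),
                 condition = condition, abundance_median = abundance_median,
                 abundance_sigma = abundance_sigma,
                 measurement_sigma = measurement_sigma, ppm_sigma = ppm_sigma,
                 charge_probs = charge_probs, mc_retention = mc_retention,
                 o18_probs = o18_probs, noise_frac = noise_frac,
                 rt_range = rt_range, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Noise-free simulation specification
#'
#' Convenience preset: no abundance or measurement noise, no m/z error,
#' full double-18O incorporation, every missed-cleavage form retained and no
#' noise features, so the pipeline must recover the planted truth exactly.
#'
#' @param ... Passed to [simulation_spec()].
#' @return A `simulation_spec`.
#' @export
noiseless_spec <- function(...) {
  simulation_spec(abundance_sigma = 0, measurement_sigma = 0, ppm_sigma = 0,
                  mc_retention = c(1, 1, 1),
                  o18_probs = c(`0` = 0, `1` = 0, `2` = 1),
                  noise_frac = 0, ...)
}

#' Ground-truth tables for a simulation
#'
#' @param spec A [simulation_spec()].
#' @return List with `sites` (protein, residue number and letter,
#'   modification, true RSO percent) and `crosslinks` (planted pairs with
#'   mature-chain link-residue numbers and theoretical neutral masses,
#'   carbamidomethyl-Cys fixed and planted nitrations included).
#' @export
generate_truth <- function(spec) {
  fx <- spec$fixture
  if (any(fx$site_occupancy$occupancy < 0 | fx$site_occupancy$occupancy > 100))
    stop("site occupancies must be within [0, 100]")
  aa <- strsplit(fx$sequence, "", fixed = TRUE)[[1]]
  sites <- fx$site_occupancy
  sites$protein_id <- fx$protein_id
  sites$residue <- aa[sites$residue_number]
  xl <- fx$crosslinks
  xl$alpha_residue <- xl$alpha_start + xl$alpha_link_pos - 1L
  xl$beta_residue <- xl$beta_start + xl$beta_link_pos - 1L
  xl$mass <- vapply(seq_len(nrow(xl)), function(k) {
    a <- .planted_peptide(xl$alpha_seq[k], xl$alpha_start[k],
                          xl$alpha_nitration_pos[k], fx$protein_id)
    b <- .planted_peptide(xl$beta_seq[k], xl$beta_start[k],
                          xl$beta_nitration_pos[k], fx$protein_id)
    crosslink_mass(crosslink_pair(a, b, xl$alpha_link_pos[k],
                                  xl$beta_link_pos[k]))
  }, numeric(1))
  list(sites = sites[, c("protein_id", "residue_number", "residue",
                         "modification", "occupancy")],
       crosslinks = xl)
}

# peptide with fixed carbamidomethyl-Cys plus planted nitrations at the
# given peptide-local positions ("" or "3;7")
.planted_peptide <- function(sequence, start, nitration_pos, protein_id,
                             label = 0L) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  mods <- .empty_mods()
  cpos <- which(aa == "C")
  if (length(cpos))
    mods <- rbind(mods, data.frame(pos = cpos, name = "carbamidomethyl",
                                   delta = 57.021464))
  if (nzchar(nitration_pos)) {
    np <- as.integer(strsplit(nitration_pos, ";", fixed = TRUE)[[1]])
    mods <- rbind(mods, data.frame(pos = np, name = "nitration",
                                   delta = 44.985078))
  }
  peptide(sequence, protein_id = protein_id, start = start,
          mods = mods[order(mods$pos), , drop = FALSE], label = label)
}

.sample_charge <- function(spec, n = 1L) {
  as.integer(sample(names(spec$charge_probs), n, replace = TRUE,
                    prob = spec$charge_probs))
}

.lognorm <- function(n, sigma) if (sigma > 0) exp(stats::rnorm(n, 0, sigma)) else rep(1, n)

.ppm_perturb <- function(mass, sigma) {
  if (sigma > 0) mass * (1 + stats::rnorm(length(mass), 0, sigma) * 1e-6)
  else mass
}

#' Simulate MS1 feature tables
#'
#' Digests the fixture chain, splits each peptide's abundance between its
#' modification forms according to the planted occupancies, and emits
#' co-eluting 16O (light) and 18O (heavy) channel features with Gaussian
#' ppm mass error, log-normal areas, sampled charges and 18O label states,
#' plus the planted cross-linked pairs and unpaired noise features.
#'
#' @param truth Output of [generate_truth()].
#' @param spec The [simulation_spec()] used for `truth`.
#' @return List with `features` (MS1 feature table: `feature_id`, `mz`,
#'   `charge`, `area`, `rt_start`, `rt_end`, `channel`, `condition`,
#'   `replicate`) and `feature_truth` (feature provenance: `kind`
#'   linear/crosslink/noise, `sequence`, `start`, `mods`, `xl_id`).
#' @export
simulate_features <- function(truth, spec) {
  set.seed(spec$seed)
  fx <- spec$fixture
  peptides <- digest(fx$sequence, digest_spec(2L, "full", 6L, 45L),
                     protein_id = fx$protein_id)
  sites <- truth$sites
  feat <- list(); tru <- list(); fi <- 0L
  new_id <- function() sprintf("f%06d", fi)
  emit <- function(mz, z, area, rt, channel, rep_, kind, sequence, start,
                   mods, xl_id) {
    fi <<- fi + 1L
    feat[[fi]] <<- data.frame(feature_id = new_id(), mz = mz, charge = z,
                              area = area, rt_start = rt, rt_end = rt + 0.8,
                              channel = channel, condition = spec$condition,
                              replicate = rep_, stringsAsFactors = FALSE)
    tru[[fi]] <<- data.frame(feature_id = feat[[fi]]$feature_id, kind = kind,
                             sequence = sequence, start = start, mods = mods,
                             xl_id = xl_id, stringsAsFactors = FALSE)
  }
  for (r in seq_len(spec$n_replicates)) {
    for (k in seq_len(nrow(peptides))) {
      p <- peptides[k, ]
      if (stats::runif(1) > spec$mc_retention[p$missed_cleavages + 1L]) next
      A <- spec$abundance_median * .lognorm(1L, spec$abundance_sigma)
      z <- .sample_charge(spec)
      aa <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
      cam <- if (any(aa == "C"))
        data.frame(pos = which(aa == "C"), name = "carbamidomethyl",
                   delta = 57.021464) else .empty_mods()
      # planted modifiable sites covered by this peptide
      cov <- sites[sites$residue_number >= p$start &
                     sites$residue_number <= p$end &
                     sites$occupancy > 0, , drop = FALSE]
      combos <- .site_combos(cov)
      for (cb in combos) {
        frac <- cb$frac
        if (frac <= 0) next
        vmods <- cb$mods
        if (nrow(vmods)) vmods$pos <- vmods$pos - p$start + 1L
        mods <- rbind(cam, vmods)
        mods <- mods[order(mods$pos), , drop = FALSE]
        m16 <- peptide_mass(p$sequence, mods = mods)
        rt <- stats::runif(1, spec$rt_range[1], spec$rt_range[2])
        emit(mz_from_mass(.ppm_perturb(m16, spec$ppm_sigma), z), z,
             A * frac * .lognorm(1L, spec$measurement_sigma), rt, "16O", r,
             "linear", p$sequence, p$start, encode_mods(mods), NA_character_)
        n18 <- as.integer(sample(names(spec$o18_probs), 1L,
                                 prob = spec$o18_probs))
        m18 <- m16 + label_shift(1L, 2L) / 2 * n18
        emit(mz_from_mass(.ppm_perturb(m18, spec$ppm_sigma), z), z,
             A * frac * .lognorm(1L, spec$measurement_sigma), rt, "18O", r,
             "linear", p$sequence, p$start, encode_mods(mods), NA_character_)
      }
    }
    # planted cross-linked pairs
    xl <- truth$crosslinks
    for (k in seq_len(nrow(xl))) {
      A <- xl$abundance[k] * .lognorm(1L, spec$abundance_sigma)
      z <- max(3L, .sample_charge(spec))
      rt <- stats::runif(1, spec$rt_range[1], spec$rt_range[2])
      m16 <- xl$mass[k]
      emit(mz_from_mass(.ppm_perturb(m16, spec$ppm_sigma), z), z,
           A * .lognorm(1L, spec$measurement_sigma), rt, "16O", r,
           "crosslink", paste(xl$alpha_seq[k], xl$beta_seq[k], sep = "x"),
           xl$alpha_start[k], "", xl$xl_id[k])
      n18 <- as.integer(sample(names(spec$o18_probs), 2L, replace = TRUE,
                               prob = spec$o18_probs))
      m18 <- m16 + sum(n18) * label_shift(1L, 2L) / 2
      emit(mz_from_mass(.ppm_perturb(m18, spec$ppm_sigma), z), z,
           A * .lognorm(1L, spec$measurement_sigma), rt, "18O", r,
           "crosslink", paste(xl$alpha_seq[k], xl$beta_seq[k], sep = "x"),
           xl$alpha_start[k], "", xl$xl_id[k])
    }
  }
  n_noise <- round(spec$noise_frac * fi)
  if (n_noise > 0) {
    for (i in seq_len(n_noise)) {
      z <- .sample_charge(spec)
      emit(stats::runif(1, 300, 1400), z,
           spec$abundance_median * 0.05 * .lognorm(1L, 1),
           stats::runif(1, spec$rt_range[1], spec$rt_range[2]),
           sample(c("16O", "18O"), 1L),
           sample.int(spec$n_replicates, 1L), "noise", NA_character_,
           NA_integer_, "", NA_character_)
    }
  }
  features <- do.call(rbind, feat)
  feature_truth <- do.call(rbind, tru)
  rownames(features) <- rownames(feature_truth) <- NULL
  list(features = features, feature_truth = feature_truth)
}

# enumerate modification subsets of the covered planted sites with their
# occupancy-model fractions; cov has residue_number / modification / occupancy
.site_combos <- function(cov) {
  if (!nrow(cov)) {
    return(list(list(frac = 1, mods = .empty_mods())))
  }
  n <- nrow(cov)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    theta <- cov$occupancy / 100
    frac <- prod(ifelse(on, theta, 1 - theta))
    deltas <- c(nitration = 44.985078, met_oxidation = 15.994915)
    mods <- if (any(on)) {
      data.frame(pos = cov$residue_number[on],   # chain coords; caller shifts
                 name = cov$modification[on],
                 delta = unname(deltas[cov$modification[on]]))
    } else .empty_mods()
    out[[length(out) + 1L]] <- list(frac = frac, mods = mods)
  }
  out
}

#' Simulate MS2 spectra for the planted cross-links
#'
#' One spectrum per planted pair and replicate: theoretical b/y fragments of
#' the 16O species with configurable random peak dropout, log-normal peak
#' intensities and additive noise peaks.
#'
#' @param truth Output of [generate_truth()].
#' @param spec The matching [simulation_spec()].
#' @param dropout Probability that a theoretical fragment peak is absent.
#' @param n_noise_peaks Random peaks added per spectrum.
#' @return List of [ms2_spectrum] objects, titled `"<xl_id>/rep<k>"`.
#' @export
simulate_spectra <- function(truth, spec, dropout = 0.3,
                             n_noise_peaks = 30L) {
  set.seed(spec$seed + 104729L)
  fx <- spec$fixture
  xl <- truth$crosslinks
  out <- list()
  for (r in seq_len(spec$n_replicates)) {
    for (k in seq_len(nrow(xl))) {
      a <- .planted_peptide(xl$alpha_seq[k], xl$alpha_start[k],
                            xl$alpha_nitration_pos[k], fx$protein_id)
      b <- .planted_peptide(xl$beta_seq[k], xl$beta_start[k],
                            xl$beta_nitration_pos[k], fx$protein_id)
      pair <- crosslink_pair(a, b, xl$alpha_link_pos[k], xl$beta_link_pos[k])
      fr <- fragment_ions(pair, series = c("b", "y"),
                          max_fragment_charge = 2L)
      keep <- stats::runif(nrow(fr)) >= dropout
      pk <- data.frame(mz = fr$mz[keep],
                       intensity = 1e4 * .lognorm(sum(keep), 0.7))
      if (n_noise_peaks > 0) {
        pk <- rbind(pk, data.frame(
          mz = stats::runif(n_noise_peaks, 150, 1600),
          intensity = 3e3 * .lognorm(n_noise_peaks, 0.7)))
      }
      z <- 4L
      out[[length(out) + 1L]] <-
        ms2_spectrum(mz_from_mass(xl$mass[k], z), z, pk, method_tag = "HCD",
                     title = sprintf("%s/rep%d", xl$xl_id[k], r))
    }
  }
  out
}

#' Build quantification records from simulated features
#'
#' Joins the feature table to its provenance and returns the linear-peptide
#' rows as a [quant_records()] table (both label channels pooled).
#'
#' @param sim Output of [simulate_features()].
#' @param protein_id Chain identifier for the records.
#' @return A [quant_records()] table.
#' @export
records_from_features <- function(sim, protein_id = "miniFN") {
  m <- merge(sim$features, sim$feature_truth, by = "feature_id")
  m <- m[m$kind == "linear", , drop = FALSE]
  quant_records(data.frame(protein_id = protein_id, start = m$start,
                           sequence = m$sequence, mods = m$mods,
                           area = m$area, condition = m$condition,
                           replicate = m$replicate, stringsAsFactors = FALSE))
}
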