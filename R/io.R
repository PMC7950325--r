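# Readers and writers: FASTA (via Biostrings), MGF peak lists, CSV tables
# and the YAML pipeline configuration.

#' Read protein sequences from FASTA
#'
#' Lowercase residues are normalized to uppercase with a warning.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  raw <- readLines(path)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")])))
    warning("lowercase residues normalized to uppercase")
  x <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an MGF peak-list file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS, CHARGE and
#' RTINSECONDS headers. Records without a CHARGE field are rejected with a
#' diagnostic naming the offending line.
#'
#' @param path MGF file.
#' @return List of [ms2_spectrum] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) != "BEGIN IONS") { i <- i + 1L; next }
    begin_line <- i
    title <- ""; pepmass <- NA_real_; charge <- NA_integer_; rt <- NA_real_
    mzs <- numeric(); ints <- numeric()
    i <- i + 1L
    while (i <= n && trimws(lines[i]) != "END IONS") {
      ln <- trimws(lines[i])
      if (grepl("^TITLE=", ln)) title <- sub("^TITLE=", "", ln)
      else if (grepl("^PEPMASS=", ln))
        pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
      else if (grepl("^CHARGE=", ln))
        charge <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
      else if (grepl("^RTINSECONDS=", ln))
        rt <- as.numeric(sub("^RTINSECONDS=", "", ln))
      else if (nzchar(ln) && !grepl("=", ln, fixed = TRUE)) {
        v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
        if (length(v) < 2L || anyNA(v))
          stop(sprintf("malformed peak line %d: '%s'", i, ln))
        mzs <- c(mzs, v[1]); ints <- c(ints, v[2])
      }
      i <- i + 1L
    }
    if (i > n) stop(sprintf("unterminated spectrum starting at line %d", begin_line))
    if (is.na(charge))
      stop(sprintf("spectrum starting at line %d has no CHARGE field", begin_line))
    if (is.na(pepmass))
      stop(sprintf("spectrum starting at line %d has no PEPMASS field", begin_line))
    out[[length(out) + 1L]] <-
      ms2_spectrum(pepmass, charge, data.frame(mz = mzs, intensity = ints),
                   title = title)
    i <- i + 1L
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra List of [ms2_spectrum] objects.
#' @param path Output file.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$title),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$precursor_charge),
                 sprintf("%.6f %.2f", s$peaks$mz, s$peaks$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read / write the flat CSV tables used by the pipeline
#'
#' Thin wrappers over [utils::read.csv()] / [utils::write.csv()] that keep
#' strings as characters and round-trip tables losslessly.
#'
#' @param path CSV file.
#' @return `read_table_csv`: a `data.frame`.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_table_csv
#' @param x `data.frame` to write.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunable settings in one list: digestion constraints, the
#' modification set, search tolerances (4.5 ppm precursor / 20 ppm MS2 for
#' linear peptides; 10 ppm precursor / 0.02 m/z MS2 for the cross-link
#' search), the cross-link acceptance score threshold (50) and MS1
#' intensity floor (2000), the replicate-consistency requirement, the 18O
#' doublet-shift tolerance, and the report bins.
#'
#' @param digest A [digest_spec()].
#' @param modifications List of [modification] objects.
#' @param precursor_ppm_linear,precursor_ppm_xl Precursor tolerances (ppm).
#' @param ms2_tol_ppm_linear MS2 tolerance for linear peptides (ppm).
#' @param ms2_tol_mz_xl MS2 tolerance for the cross-link search (m/z).
#' @param score_threshold Cross-link matches must score strictly above this.
#' @param intensity_floor Minimum MS1 intensity.
#' @param require_replicates Replicates a cross-link must appear in.
#' @param label_tolerance 18O doublet neutral-shift tolerance (Da).
#' @param max_var_mods Variable modifications per peptide form.
#' @param peptide_mass_cap,pair_mass_cap Candidate mass caps (Da).
#' @param link_rules Cross-link chemistries searched.
#' @param report_bins RSO bin edges for the domain report.
#' @param seed Default seed for simulation subcommands.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(digest = digest_spec(),
                            modifications = default_modifications(),
                            precursor_ppm_linear = 4.5,
                            precursor_ppm_xl = 10,
                            ms2_tol_ppm_linear = 20,
                            ms2_tol_mz_xl = 0.02,
                            score_threshold = 50,
                            intensity_floor = 2000,
                            require_replicates = 2L,
                            label_tolerance = 0.015,
                            max_var_mods = 3L,
                            peptide_mass_cap = 6000,
                            pair_mass_cap = 8000,
                            link_rules = c("YY", "WW", "YW"),
                            report_bins = c(1, 10, 20, 30, 100),
                            seed = 1L) {
  structure(list(digest = digest, modifications = modifications,
                 precursor_ppm_linear = precursor_ppm_linear,
                 precursor_ppm_xl = precursor_ppm_xl,
                 ms2_tol_ppm_linear = ms2_tol_ppm_linear,
                 ms2_tol_mz_xl = ms2_tol_mz_xl,
                 score_threshold = score_threshold,
                 intensity_floor = intensity_floor,
                 require_replicates = as.integer(require_replicates),
                 label_tolerance = label_tolerance,
                 max_var_mods = as.integer(max_var_mods),
                 peptide_mass_cap = peptide_mass_cap,
                 pair_mass_cap = pair_mass_cap,
                 link_rules = link_rules, report_bins = report_bins,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$digest <- unclass(x$digest)
  x$modifications <- lapply(x$modifications, function(m) {
    list(name = m$name, targets = as.list(m$targets), delta = m$delta,
         kind = m$kind, max_per_peptide = m$max_per_peptide)
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file written by [write_config()] (or hand-edited).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    digest = digest_spec(x$digest$max_missed_cleavages, x$digest$specificity,
                         x$digest$min_length, x$digest$max_length),
    modifications = modifications_from_config(x$modifications),
    precursor_ppm_linear = x$precursor_ppm_linear,
    precursor_ppm_xl = x$precursor_ppm_xl,
    ms2_tol_ppm_linear = x$ms2_tol_ppm_linear,
    ms2_tol_mz_xl = x$ms2_tol_mz_xl,
    score_threshold = x$score_threshold,
    intensity_floor = x$intensity_floor,
    require_replicates = x$require_replicates,
    label_tolerance = x$label_tolerance,
    max_var_mods = x$max_var_mods,
    peptide_mass_cap = x$peptide_mass_cap,
    pair_mass_cap = x$pair_mass_cap,
    link_rules = unlist(x$link_rules),
    report_bins = unlist(x$report_bins),
    seed = x$seed)
}
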