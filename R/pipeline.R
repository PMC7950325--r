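# The two analysis pipelines (site mapping; cross-link identification) and
# the command-line entry point that ties the stages together.

#' Cross-link identification pipeline
#'
#' From an MS1 feature table (two 16O/18O channels) and MS2 spectra:
#' pairs label doublets, keeps the +8 Da (cross-linked) calls, enumerates
#' Tyr/Trp cross-link candidates from an in-silico digest of the chain
#' (optionally with reversed-sequence decoys), matches precursors within the
#' ppm tolerance, scores fragment evidence, and applies the score,
#' intensity-floor and replicate-consistency filters.
#'
#' @param features MS1 feature `data.frame` (see [simulate_features()]).
#' @param spectra List of [ms2_spectrum] objects.
#' @param sequence Mature-chain sequence.
#' @param config A [pipeline_config()].
#' @param protein_id Chain identifier.
#' @param with_decoys Add reversed-sequence decoy candidates.
#' @return List: `doublets` (all doublet calls), `matches` (all scored
#'   precursor matches) and `accepted` (filtered cross-links with
#'   mature-chain `alpha_residue` / `beta_residue`).
#' @export
run_crosslink_search <- function(features, spectra, sequence,
                                 config = pipeline_config(),
                                 protein_id = "protein",
                                 with_decoys = FALSE) {
  doublets <- pair_doublets(features, tolerance = config$label_tolerance)
  xl_doublets <- doublets[doublets$call == "crosslinked", , drop = FALSE]
  peptides <- digest(sequence, config$digest, protein_id = protein_id)
  forms <- modified_forms(peptides, config$modifications,
                          max_var_mods = config$max_var_mods)
  cands <- enumerate_candidates(forms, link_rules = config$link_rules,
                                peptide_mass_cap = config$peptide_mass_cap,
                                pair_mass_cap = config$pair_mass_cap)
  if (with_decoys) {
    dforms <- modified_forms(reverse_peptides(peptides),
                             config$modifications,
                             max_var_mods = config$max_var_mods)
    dcands <- enumerate_candidates(dforms, link_rules = config$link_rules,
                                   peptide_mass_cap = config$peptide_mass_cap,
                                   pair_mass_cap = config$pair_mass_cap,
                                   decoy = TRUE)
    cands <- rbind(cands, dcands)
  }
  spec_mz <- vapply(spectra, `[[`, numeric(1), "precursor_mz")
  spec_z <- vapply(spectra, `[[`, integer(1), "precursor_charge")
  rows <- list()
  for (k in seq_len(nrow(xl_doublets))) {
    d <- xl_doublets[k, ]
    neutral <- mass_from_mz(d$light_mz, d$charge)
    hits <- match_precursor(cands, neutral_mass = neutral,
                            tol_ppm = config$precursor_ppm_xl)
    if (!nrow(hits)) next
    # spectra acquired on the light species: match by precursor neutral mass
    sp_i <- which(abs(mass_from_mz(spec_mz, spec_z) - neutral) <
                    2 * config$precursor_ppm_xl * 1e-6 * neutral + 0.05)
    hits$score <- vapply(seq_len(nrow(hits)), function(h) {
      pair <- pair_from_candidate(hits[h, ])
      fr <- fragment_ions(pair, series = c("b", "y"),
                          max_fragment_charge = 2L)
      if (!length(sp_i)) return(0)
      max(vapply(sp_i, function(si)
        score_match(spectra[[si]], fr, ms2_tol = config$ms2_tol_mz_xl),
        numeric(1)))
    }, numeric(1))
    hits$intensity <- d$light_area
    hits$replicate <- if (!is.null(d$replicate)) d$replicate else 1L
    hits$doublet_light <- d$light_id
    # rank-1 identification per doublet: isobaric link-position and
    # modification-position isomers compete on fragment evidence
    hits <- hits[order(-hits$score, abs(hits$ppm_error), hits$alpha_mods,
                       hits$beta_mods, hits$link_alpha_pos,
                       hits$link_beta_pos), , drop = FALSE]
    rows[[length(rows) + 1L]] <- hits[1L, , drop = FALSE]
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    cbind(cands[0, ], observed_mass = numeric(0), ppm_error = numeric(0),
          score = numeric(0), intensity = numeric(0), replicate = integer(0),
          doublet_light = character(0))
  accepted <- filter_matches(matches,
                             score_threshold = config$score_threshold,
                             intensity_floor = config$intensity_floor,
                             require_replicates = config$require_replicates)
  if (nrow(accepted)) {
    accepted$alpha_residue <- accepted$alpha_start + accepted$link_alpha_pos - 1L
    accepted$beta_residue <- accepted$beta_start + accepted$link_beta_pos - 1L
  } else {
    accepted$alpha_residue <- integer(0)
    accepted$beta_residue <- integer(0)
  }
  list(doublets = doublets, matches = matches, accepted = accepted)
}

#' Site-mapping pipeline
#'
#' Relative site occupancies, coverage statistics and the summary for one
#' condition from a peptide quantification table.
#'
#' @param records A [quant_records()] table.
#' @param sequence Mature-chain sequence.
#' @param config A [pipeline_config()].
#' @param glyco_exclusion_sites Residues excluded from the secondary
#'   coverage figure.
#' @return List: `rso` ([rso_table()]), `coverage` ([coverage_stats()]),
#'   `summary` ([summarize_rso()]).
#' @export
run_site_mapping <- function(records, sequence, config = pipeline_config(),
                             glyco_exclusion_sites = integer()) {
  rt <- rso_table(records, config$modifications)
  cov <- coverage_stats(records, sequence,
                        glyco_exclusion_sites = glyco_exclusion_sites)
  list(rso = rt, coverage = cov, summary = summarize_rso(rt))
}

.cli_usage <- "usage: oxlink <subcommand> [options]
subcommands:
  digest       --fasta F --out CSV [--config YAML]
  simulate     --out-dir DIR [--seed N] [--noiseless]
  classify-18o --features CSV --out CSV [--config YAML]
  search-xl    --features CSV --mgf MGF --fasta F --out CSV [--config YAML]
  quantify     --records CSV --fasta F --out CSV [--config YAML]
  compare      --rso-a CSV --rso-b CSV --out CSV
  report       --rso CSV --crosslinks CSV --domains CSV --out-dir DIR
"

.cli_opts <- function(args) {
  opts <- list(); i <- 1L
  while (i <= length(args)) {
    if (grepl("^--", args[i])) {
      key <- sub("^--", "", args[i])
      if (i < length(args) && !grepl("^--", args[i + 1L])) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else {
        opts[[key]] <- TRUE; i <- i + 1L
      }
    } else i <- i + 1L
  }
  opts
}

.cli_config <- function(opts) {
  if (!is.null(opts$config)) read_config(opts$config) else pipeline_config()
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`digest`, `simulate`,
#' `classify-18o`, `search-xl`, `quantify`, `compare`, `report`). A thin
#' `Rscript` wrapper is installed under `system.file("scripts", "oxlink.R",
#' package = "oxlink")`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (invisibly); 0 on success.
#' @export
oxlink_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { message(.cli_usage); return(invisible(1L)) }
  sub <- args[1L]
  opts <- .cli_opts(args[-1L])
  config <- .cli_config(opts)
  status <- tryCatch({
    switch(sub,
      digest = {
        seqs <- read_fasta(opts$fasta)
        out <- do.call(rbind, lapply(names(seqs), function(id)
          digest(seqs[[id]], config$digest, protein_id = id)))
        write_table_csv(out, opts$out)
      },
      simulate = {
        seed <- as.integer(opts$seed %||% config$seed)
        spec <- if (isTRUE(opts$noiseless)) noiseless_spec(seed = seed)
                else simulation_spec(seed = seed)
        truth <- generate_truth(spec)
        sim <- simulate_features(truth, spec)
        sp <- simulate_spectra(truth, spec)
        dir.create(opts$`out-dir`, showWarnings = FALSE, recursive = TRUE)
        od <- opts$`out-dir`
        write_fasta(stats::setNames(spec$fixture$sequence,
                                    spec$fixture$protein_id),
                    file.path(od, "fixture.fasta"))
        write_table_csv(sim$features, file.path(od, "features.csv"))
        write_table_csv(sim$feature_truth, file.path(od, "feature_truth.csv"))
        write_table_csv(truth$sites, file.path(od, "truth_sites.csv"))
        write_table_csv(truth$crosslinks, file.path(od, "truth_crosslinks.csv"))
        write_table_csv(spec$fixture$annotations, file.path(od, "domains.csv"))
        write_mgf(sp, file.path(od, "spectra.mgf"))
      },
      `classify-18o` = {
        features <- read_table_csv(opts$features)
        write_table_csv(pair_doublets(features,
                                      tolerance = config$label_tolerance),
                        opts$out)
      },
      `search-xl` = {
        features <- read_table_csv(opts$features)
        spectra <- read_mgf(opts$mgf)
        seqs <- read_fasta(opts$fasta)
        res <- run_crosslink_search(features, spectra, seqs[[1L]], config,
                                    protein_id = names(seqs)[1L])
        write_table_csv(res$accepted, opts$out)
      },
      quantify = {
        records <- quant_records(read_table_csv(opts$records))
        seqs <- read_fasta(opts$fasta)
        res <- run_site_mapping(records, seqs[[1L]], config)
        write_table_csv(res$rso, opts$out)
      },
      compare = {
        a <- read_table_csv(opts$`rso-a`)
        b <- read_table_csv(opts$`rso-b`)
        write_table_csv(compare_conditions(a, b), opts$out)
      },
      report = {
        sites <- read_table_csv(opts$rso)
        xl <- read_table_csv(opts$crosslinks)
        ann <- read_table_csv(opts$domains)
        rep_ <- render_report(sites, xl, ann)
        dir.create(opts$`out-dir`, showWarnings = FALSE, recursive = TRUE)
        write_table_csv(rep_$site_report,
                        file.path(opts$`out-dir`, "site_report.csv"))
        write_table_csv(rep_$crosslink_report,
                        file.path(opts$`out-dir`, "crosslink_report.csv"))
        writeLines(rep_$schematic,
                   file.path(opts$`out-dir`, "schematic.txt"))
      },
      stop("unknown subcommand: ", sub)
    )
    0L
  }, error = function(e) {
    message("oxlink error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
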