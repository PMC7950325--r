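# Mapping of modification sites and cross-links onto protein module/domain
# architecture, cross-link topology from SEC-fraction provenance, and the
# binned site report.

#' Validate a domain-annotation table
#'
#' @param annotations `data.frame` with columns `module_name`, `start`,
#'   `end` (1-based, inclusive, mature-chain numbering) and
#'   `functional_domain`.
#' @return The validated table, sorted by `start`.
#' @export
domain_annotations <- function(annotations) {
  need <- c("module_name", "start", "end", "functional_domain")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop("missing annotation columns: ", paste(miss, collapse = ", "))
  if (any(annotations$start > annotations$end))
    stop("annotation intervals must have start <= end")
  ann <- annotations[order(annotations$start), , drop = FALSE]
  if (nrow(ann) > 1L && any(ann$start[-1L] <= ann$end[-nrow(ann)]))
    stop("annotation intervals must not overlap")
  rownames(ann) <- NULL
  ann
}

#' Assign residues to modules
#'
#' Interval lookup of residue numbers in the module annotation; residues
#' falling between modules are labeled `"linker/interdomain"`.
#'
#' @param residue_number Integer vector of 1-based residue numbers.
#' @param annotations A [domain_annotations()] table.
#' @param chain_length Optional chain length; residues beyond it error.
#' @return `data.frame` with `residue_number`, `module_name`,
#'   `functional_domain`.
#' @export
assign_site <- function(residue_number, annotations, chain_length = NULL) {
  ann <- domain_annotations(annotations)
  if (!is.null(chain_length) && any(residue_number > chain_length))
    stop("residue number beyond chain length")
  if (any(residue_number < 1L)) stop("residue numbers are 1-based")
  idx <- vapply(residue_number, function(r) {
    i <- which(ann$start <= r & ann$end >= r)
    if (length(i)) i[1L] else NA_integer_
  }, integer(1))
  data.frame(residue_number = residue_number,
             module_name = ifelse(is.na(idx), "linker/interdomain",
                                  ann$module_name[idx]),
             functional_domain = ifelse(is.na(idx), "linker/interdomain",
                                        ann$functional_domain[idx]),
             stringsAsFactors = FALSE)
}

#' Cross-link topology from SEC-fraction provenance
#'
#' Cross-links observed in the dimer fraction are inter-molecular; those
#' observed only in the monomer fraction are intra-molecular; species seen
#' only in the unfractionated sample are ambiguous.
#'
#' @param fractions_observed Non-empty character subset of
#'   `c("monomer", "dimer", "unfractionated")`.
#' @return `"intermolecular"`, `"intramolecular"` or `"ambiguous"`.
#' @export
classify_topology <- function(fractions_observed) {
  fr <- unique(fractions_observed)
  if (!length(fr)) stop("empty fraction set")
  bad <- setdiff(fr, c("monomer", "dimer", "unfractionated"))
  if (length(bad)) stop("unknown fraction: ", paste(bad, collapse = ", "))
  if ("dimer" %in% fr) "intermolecular"
  else if ("monomer" %in% fr) "intramolecular"
  else "ambiguous"
}

#' Bin RSO values for the site schematic
#'
#' Half-open bins (1,10], (10,20], (20,30], (30,100]; values of 1% or below
#' are unbinned (`NA`).
#'
#' @param rso_percent Numeric vector of RSO percentages.
#' @return Factor with levels `"1-10%"`, `"10-20%"`, `"20-30%"`, `">30%"`.
#' @export
rso_bin <- function(rso_percent) {
  cut(rso_percent, breaks = c(1, 10, 20, 30, 100),
      labels = c("1-10%", "10-20%", "20-30%", ">30%"), right = TRUE)
}

#' Domain-level site and cross-link report
#'
#' Joins quantified sites and accepted cross-links to the module
#' architecture: per-site module assignment with RSO bins, cross-links keyed
#' by module pairs with topology calls, and a plain-text schematic.
#'
#' @param sites [rso_table()] output.
#' @param crosslinks `data.frame` of accepted cross-links with columns
#'   `alpha_residue`, `beta_residue` (mature-chain numbers), `link_type`
#'   and optionally `topology`.
#' @param annotations A [domain_annotations()] table.
#' @return List of `site_report` (sites with RSO > 1% plus module and bin),
#'   `crosslink_report`, and `schematic` (character vector of text lines).
#' @export
render_report <- function(sites, crosslinks, annotations) {
  ann <- domain_annotations(annotations)
  site_rep <- sites
  asg <- assign_site(site_rep$residue_number, ann)
  site_rep$module_name <- asg$module_name
  site_rep$functional_domain <- asg$functional_domain
  site_rep$bin <- rso_bin(site_rep$rso_percent)
  site_rep <- site_rep[!is.na(site_rep$bin), , drop = FALSE]
  xl_rep <- crosslinks
  if (nrow(xl_rep)) {
    xl_rep$alpha_module <- assign_site(xl_rep$alpha_residue, ann)$module_name
    xl_rep$beta_module <- assign_site(xl_rep$beta_residue, ann)$module_name
  } else {
    xl_rep$alpha_module <- character(0)
    xl_rep$beta_module <- character(0)
  }
  lines <- c("Domain report", "=============")
  for (k in seq_len(nrow(ann))) {
    in_mod <- site_rep[site_rep$module_name == ann$module_name[k], , drop = FALSE]
    lines <- c(lines, sprintf("%s (%d-%d; %s):", ann$module_name[k],
                              ann$start[k], ann$end[k],
                              ann$functional_domain[k]))
    if (nrow(in_mod)) {
      lines <- c(lines, sprintf("  %s%d %s RSO %.1f%% [%s]", in_mod$residue,
                                in_mod$residue_number, in_mod$modification,
                                in_mod$rso_percent, as.character(in_mod$bin)))
    } else {
      lines <- c(lines, "  (no binned sites)")
    }
  }
  if (nrow(xl_rep)) {
    lines <- c(lines, "Cross-links:",
               sprintf("  %s: %d (%s) x %d (%s)%s", xl_rep$link_type,
                       xl_rep$alpha_residue, xl_rep$alpha_module,
                       xl_rep$beta_residue, xl_rep$beta_module,
                       if (!is.null(xl_rep$topology))
                         paste0(" [", xl_rep$topology, "]") else ""))
  }
  list(site_report = site_rep, crosslink_report = xl_rep, schematic = lines)
}
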