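# Relative site occupancy (RSO) from MS1 areas, sequence-coverage
# statistics, and two-condition footprint comparison.

#' Quant-record table constructor / validator
#'
#' A peptide quantification record is one observed peptide form with its MS1
#' area: columns `protein_id`, `start` (1-based on the mature chain),
#' `sequence`, `mods` (encoded `"pos:name:delta"` string, peptide-local
#' positions), `area`, `condition`, `replicate`.
#'
#' @param records `data.frame` to validate.
#' @return The validated table with an `end` column added.
#' @export
quant_records <- function(records) {
  need <- c("protein_id", "start", "sequence", "mods", "area",
            "condition", "replicate")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing quant-record columns: ", paste(miss, collapse = ", "))
  if (any(records$area < 0)) stop("areas must be >= 0")
  records$end <- records$start + nchar(records$sequence) - 1L
  records
}

.site_areas <- function(records, residue_number, mod_name) {
  cov <- records[records$start <= residue_number &
                   records$end >= residue_number, , drop = FALSE]
  if (!nrow(cov)) return(NULL)
  local_pos <- residue_number - cov$start + 1L
  has_mod <- mapply(function(mods, lp) {
    md <- decode_mods(mods)
    any(md$pos == lp & md$name == mod_name)
  }, cov$mods, local_pos)
  list(modified = sum(cov$area[has_mod]), total = sum(cov$area),
       residue = substr(cov$sequence[1L], local_pos[1L], local_pos[1L]))
}

#' Relative site occupancy at one residue
#'
#' RSO is 100 times the summed MS1 area of all peptide forms carrying the
#' modification at the site, divided by the summed area of every form
#' covering the site (modified or not, including forms carrying other
#' modifications such as Met oxidation). Sums pool charge states and
#' overlapping peptide species. Replicates are averaged at the RSO level.
#'
#' @param records A [quant_records()] table (one condition; any number of
#'   replicates).
#' @param protein_id,residue_number Site key (1-based, mature chain).
#' @param modification Modification name.
#' @return One-row `data.frame` (`SiteOccupancy`): `protein_id`,
#'   `residue_number`, `residue`, `modification`, `rso_percent` (mean over
#'   replicates), `rso_sd`, `modified_area`, `total_area` (pooled),
#'   `n_replicates`, `low_confidence` (no unmodified evidence), or `NULL`
#'   when no record covers the site (not identified, distinct from 0%).
#' @export
rso <- function(records, protein_id, residue_number, modification) {
  records <- quant_records(records)
  records <- records[records$protein_id == protein_id, , drop = FALSE]
  reps <- sort(unique(records$replicate))
  per_rep <- list(); residue <- NA_character_
  mod_tot <- 0; all_tot <- 0
  for (r in reps) {
    sa <- .site_areas(records[records$replicate == r, , drop = FALSE],
                      residue_number, modification)
    if (is.null(sa)) next
    per_rep[[length(per_rep) + 1L]] <-
      if (sa$total > 0) 100 * sa$modified / sa$total else NA_real_
    residue <- sa$residue
    mod_tot <- mod_tot + sa$modified
    all_tot <- all_tot + sa$total
  }
  vals <- unlist(per_rep)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NULL)          # site not identified
  data.frame(protein_id = protein_id, residue_number = residue_number,
             residue = residue, modification = modification,
             rso_percent = mean(vals),
             rso_sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
             modified_area = mod_tot, total_area = all_tot,
             n_replicates = length(vals),
             low_confidence = mod_tot > 0 && mod_tot == all_tot,
             stringsAsFactors = FALSE)
}

#' Relative site occupancy for all sites of a condition
#'
#' Computes [rso()] at every residue targeted by the given modifications and
#' covered by at least one record. Sites covered only by modified forms
#' report 100% with `low_confidence = TRUE`.
#'
#' @param records A [quant_records()] table.
#' @param modifications List of [modification] objects whose variable
#'   members define the site classes to quantify.
#' @param condition Restrict to one condition (default: all records).
#' @return `data.frame` of site occupancies (see [rso()]), one row per
#'   (protein, residue, modification).
#' @export
rso_table <- function(records, modifications = default_modifications(),
                      condition = NULL) {
  records <- quant_records(records)
  if (!is.null(condition))
    records <- records[records$condition == condition, , drop = FALSE]
  varb <- Filter(function(m) m$kind == "variable", modifications)
  out <- list()
  for (pid in unique(records$protein_id)) {
    rp <- records[records$protein_id == pid, , drop = FALSE]
    for (m in varb) {
      sites <- unique(unlist(mapply(function(seq, st) {
        aa <- strsplit(seq, "", fixed = TRUE)[[1]]
        st + which(aa %in% m$targets) - 1L
      }, rp$sequence, rp$start, SIMPLIFY = FALSE)))
      for (s in sort(sites)) {
        row <- rso(rp, pid, s, m$name)
        if (!is.null(row)) out[[length(out) + 1L]] <- row
      }
    }
  }
  if (!length(out)) {
    return(data.frame(protein_id = character(), residue_number = integer(),
                      residue = character(), modification = character(),
                      rso_percent = numeric(), rso_sd = numeric(),
                      modified_area = numeric(), total_area = numeric(),
                      n_replicates = integer(), low_confidence = logical(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Percentages for a residue modification census
#'
#' Given counts of modified, identified-but-unmodified and unidentified
#' residues of one class, returns the percent-of-total and
#' percent-of-identified conventions used in coverage reporting.
#'
#' @param n_modified,n_not_modified,n_not_identified Integer counts.
#' @return List with `total`, `identified`, `pct_of_total`,
#'   `pct_of_identified` (NA when nothing was identified).
#' @export
#' @examples
#' class_percentages(8, 25, 6)  # 20.5% of total, 24.2% of identified
class_percentages <- function(n_modified, n_not_modified, n_not_identified) {
  total <- n_modified + n_not_modified + n_not_identified
  ident <- n_modified + n_not_modified
  list(total = total, identified = ident,
       pct_of_total = if (total > 0) 100 * n_modified / total else NA_real_,
       pct_of_identified = if (ident > 0) 100 * n_modified / ident else NA_real_)
}

#' Sequence coverage and residue-class statistics
#'
#' Percent of chain residues covered by identified peptides (optionally
#' excluding a configured list of glycosylation sites from both numerator
#' and denominator), and per residue class (Tyr, Trp, Met) the counts and
#' percentages of modified / not modified / not identified residues.
#'
#' @param records A [quant_records()] table (or any table with `start`,
#'   `sequence`, `mods`).
#' @param sequence Mature-chain sequence.
#' @param glyco_exclusion_sites Residue numbers excluded from coverage.
#' @param classes Named character vector mapping residue letter to the
#'   modification counted as "modified" for that class.
#' @return List with `coverage_percent`, `coverage_percent_excluding_glyco`
#'   and `residue_classes` (`data.frame`: residue, total, modified,
#'   not_modified, not_identified, pct_of_total, pct_of_identified).
#' @export
coverage_stats <- function(records, sequence,
                           glyco_exclusion_sites = integer(),
                           classes = c(Y = "nitration", W = "nitration",
                                       M = "met_oxidation")) {
  n <- nchar(sequence)
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  covered <- rep(FALSE, n)
  modded <- vector("list", length(classes))
  names(modded) <- names(classes)
  for (cl in names(classes)) modded[[cl]] <- rep(FALSE, n)
  if (nrow(records)) {
    records$end <- records$start + nchar(records$sequence) - 1L
    for (k in seq_len(nrow(records))) {
      covered[records$start[k]:records$end[k]] <- TRUE
      md <- decode_mods(records$mods[k])
      if (nrow(md)) {
        gpos <- records$start[k] + md$pos - 1L
        for (cl in names(classes)) {
          sel <- md$name == classes[[cl]] & aa[gpos] == cl
          modded[[cl]][gpos[sel]] <- TRUE
        }
      }
    }
  }
  keep <- setdiff(seq_len(n), glyco_exclusion_sites)
  cov_pct <- 100 * sum(covered) / n
  cov_pct_ex <- 100 * sum(covered[keep]) / length(keep)
  cls <- lapply(names(classes), function(cl) {
    pos <- which(aa == cl)
    nm <- sum(modded[[cl]][pos])
    nid <- sum(covered[pos])
    pc <- class_percentages(nm, nid - nm, length(pos) - nid)
    data.frame(residue = cl, total = length(pos), modified = nm,
               not_modified = nid - nm, not_identified = length(pos) - nid,
               pct_of_total = pc$pct_of_total,
               pct_of_identified = pc$pct_of_identified,
               stringsAsFactors = FALSE)
  })
  list(coverage_percent = cov_pct,
       coverage_percent_excluding_glyco = cov_pct_ex,
       residue_classes = do.call(rbind, cls))
}

#' Two-condition footprint comparison
#'
#' Per-site RSO difference `condition A - condition B`. A site quantified in
#' only one condition contributes with the missing condition assumed 0% and
#' is flagged; positive deltas mean more modification under condition A.
#'
#' @param rso_a,rso_b [rso_table()] outputs for the two conditions.
#' @return `data.frame` keyed by (protein, residue, modification) with
#'   `rso_a`, `rso_b`, `delta`, `assumed_zero` (`""`, `"a"` or `"b"`).
#' @export
compare_conditions <- function(rso_a, rso_b) {
  keys <- c("protein_id", "residue_number", "modification")
  a <- rso_a[, c(keys, "residue", "rso_percent")]
  b <- rso_b[, c(keys, "residue", "rso_percent")]
  names(a)[names(a) == "rso_percent"] <- "rso_a"
  names(b)[names(b) == "rso_percent"] <- "rso_b"
  m <- merge(a, b, by = c(keys, "residue"), all = TRUE)
  m$assumed_zero <- ifelse(is.na(m$rso_a), "a",
                           ifelse(is.na(m$rso_b), "b", ""))
  m$rso_a[is.na(m$rso_a)] <- 0
  m$rso_b[is.na(m$rso_b)] <- 0
  m$delta <- m$rso_a - m$rso_b
  m <- m[order(m$protein_id, m$residue_number), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Summarize an RSO table (and optional condition deltas)
#'
#' @param rso_tab An [rso_table()] output.
#' @param deltas Optional [compare_conditions()] output.
#' @param min_change_percent Sites with `|delta|` strictly above this are
#'   flagged as changed.
#' @return List: `mean_rso_modified` (mean RSO over sites with RSO > 0, NA
#'   when none), `n_sites_per_modification`, `mean_rso_per_modification`,
#'   and, when `deltas` is given, `changed_sites`.
#' @export
summarize_rso <- function(rso_tab, deltas = NULL, min_change_percent = 10) {
  nz <- rso_tab[rso_tab$rso_percent > 0, , drop = FALSE]
  out <- list(
    mean_rso_modified = if (nrow(nz)) mean(nz$rso_percent) else NA_real_,
    n_sites_per_modification = if (nrow(nz))
      as.data.frame(table(modification = nz$modification),
                    stringsAsFactors = FALSE)
      else data.frame(modification = character(), Freq = integer()),
    mean_rso_per_modification = if (nrow(nz))
      stats::aggregate(rso_percent ~ modification, nz, mean)
      else data.frame(modification = character(), rso_percent = numeric())
  )
  if (!is.null(deltas)) {
    out$changed_sites <-
      deltas[abs(deltas$delta) > min_change_percent, , drop = FALSE]
  }
  out
}
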