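# Candidate enumeration, precursor/fragment matching, scoring and filtering
# for Tyr-Tyr, Trp-Trp and Tyr-Trp cross-linked peptides.

.C_MINUS_B <- 17.026549   # c ion = b + NH3
.Y_MINUS_Z <- 16.018724   # z(dot) ion = y - NH3 + H

#' Enumerate modified peptide forms
#'
#' Applies fixed modifications to every target residue and enumerates
#' variable-modification combinations (at most one modification per residue,
#' per-modification caps, and a global cap per peptide).
#'
#' @param peptides `data.frame` from [digest()].
#' @param modifications List of [modification] objects.
#' @param max_var_mods Global cap on variable modifications per peptide form.
#' @return `data.frame` with one row per form: peptide columns plus `mods`
#'   (encoded `"pos:name:delta"` string), `n_var_mods` and neutral `mass`.
#' @export
modified_forms <- function(peptides, modifications = default_modifications(),
                           max_var_mods = 3L) {
  fixed <- Filter(function(m) m$kind == "fixed", modifications)
  varb <- Filter(function(m) m$kind == "variable", modifications)
  rows <- vector("list", nrow(peptides) * 2L); ri <- 0L
  for (k in seq_len(nrow(peptides))) {
    p <- peptides[k, ]
    aa <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
    fixed_df <- do.call(rbind, lapply(fixed, function(m) {
      pos <- which(aa %in% m$targets)
      if (!length(pos)) return(NULL)
      data.frame(pos = pos, name = m$name, delta = m$delta,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(fixed_df)) fixed_df <- .empty_mods()
    # candidate variable-mod placements
    sites <- do.call(rbind, lapply(varb, function(m) {
      pos <- which(aa %in% m$targets)
      if (!length(pos)) return(NULL)
      data.frame(pos = pos, name = m$name, delta = m$delta,
                 cap = m$max_per_peptide, stringsAsFactors = FALSE)
    }))
    combos <- list(integer(0))
    if (!is.null(sites) && nrow(sites)) {
      ns <- nrow(sites)
      for (size in seq_len(min(max_var_mods, ns))) {
        cc <- utils::combn(ns, size, simplify = FALSE)
        keep <- Filter(function(ix) {
          !anyDuplicated(sites$pos[ix]) &&
            all(table(sites$name[ix]) <= sites$cap[match(names(table(sites$name[ix])), sites$name)])
        }, cc)
        combos <- c(combos, keep)
      }
    }
    base_mass <- sum(.residue_vector(p$sequence)) + .WATER + sum(fixed_df$delta)
    for (ix in combos) {
      vdf <- if (length(ix)) sites[ix, c("pos", "name", "delta")] else .empty_mods()
      mods <- rbind(fixed_df, vdf)
      mods <- mods[order(mods$pos), , drop = FALSE]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        protein_id = p$protein_id, start = p$start, end = p$end,
        sequence = p$sequence, missed_cleavages = p$missed_cleavages,
        mods = encode_mods(mods), n_var_mods = length(ix),
        mass = base_mass + sum(vdf$delta), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows[seq_len(ri)])
  rownames(df) <- NULL
  df
}

#' Build a peptide object from a form row
#'
#' @param form One row of a [modified_forms()] table.
#' @param label 18O atoms at the C-terminus.
#' @return A [peptide].
#' @export
peptide_from_form <- function(form, label = 0L) {
  peptide(form$sequence, protein_id = form$protein_id, start = form$start,
          missed_cleavages = form$missed_cleavages,
          mods = decode_mods(form$mods), label = label)
}

#' Reversed-sequence decoy peptides
#'
#' Reverses each sequence while keeping a C-terminal K/R in place, the
#' standard decoy construction for tryptic searches.
#'
#' @param peptides `data.frame` from [digest()].
#' @return The same table with reversed sequences and `protein_id` prefixed
#'   `"decoy_"`.
#' @export
reverse_peptides <- function(peptides) {
  rev1 <- function(s) {
    n <- nchar(s)
    last <- substr(s, n, n)
    if (last %in% c("K", "R") && n > 1L) {
      paste0(paste(rev(strsplit(substr(s, 1L, n - 1L), "")[[1]]), collapse = ""), last)
    } else {
      paste(rev(strsplit(s, "")[[1]]), collapse = "")
    }
  }
  peptides$sequence <- vapply(peptides$sequence, rev1, "")
  peptides$protein_id <- paste0("decoy_", peptides$protein_id)
  peptides
}

.link_rule_pairs <- function(link_rules) {
  out <- list()
  if ("YY" %in% link_rules) out <- c(out, list(c("Y", "Y")))
  if ("WW" %in% link_rules) out <- c(out, list(c("W", "W")))
  if ("YW" %in% link_rules) out <- c(out, list(c("Y", "W"), c("W", "Y")))
  out
}

#' Enumerate candidate cross-linked pairs
#'
#' All unordered pairs of peptide forms in which each partner contributes one
#' Tyr or Trp link residue consistent with the requested link chemistries.
#' The longer chain is reported as alpha. A residue carrying a variable
#' modification may still serve as the link site.
#'
#' @param forms `data.frame` from [modified_forms()].
#' @param link_rules Subset of `c("YY", "WW", "YW")`.
#' @param peptide_mass_cap,pair_mass_cap Mass caps (Da) controlling candidate
#'   explosion.
#' @param decoy Flag recorded on every candidate row.
#' @return `data.frame` of candidates: `alpha_seq`, `alpha_start`,
#'   `alpha_mods`, `beta_*` likewise, `link_alpha_pos`, `link_beta_pos`
#'   (1-based within each peptide), `link_type`, neutral `mass`, `decoy`.
#' @export
enumerate_candidates <- function(forms, link_rules = c("YY", "WW", "YW"),
                                 peptide_mass_cap = 6000,
                                 pair_mass_cap = 8000, decoy = FALSE) {
  forms <- forms[forms$mass <= peptide_mass_cap, , drop = FALSE]
  rules <- .link_rule_pairs(link_rules)
  letters_needed <- unique(unlist(rules))
  has_site <- vapply(forms$sequence, function(s)
    any(strsplit(s, "")[[1]] %in% letters_needed), logical(1))
  forms <- forms[has_site, , drop = FALSE]
  n <- nrow(forms)
  pos_of <- lapply(forms$sequence, function(s) {
    aa <- strsplit(s, "")[[1]]
    list(Y = which(aa == "Y"), W = which(aa == "W"))
  })
  acc_ia <- list(); acc_ib <- list(); acc_la <- list(); acc_lb <- list()
  k <- 0L
  for (i in seq_len(n)) {
    if (i + 1L > n) break
    for (j in (i + 1L):n) {
      if (forms$mass[i] + forms$mass[j] + .LINK_DELTA > pair_mass_cap) next
      swap <- nchar(forms$sequence[j]) > nchar(forms$sequence[i])
      for (rule in rules) {
        pa <- pos_of[[i]][[rule[1L]]]
        pb <- pos_of[[j]][[rule[2L]]]
        if (!length(pa) || !length(pb)) next
        a <- rep(pa, each = length(pb))
        b <- rep(pb, times = length(pa))
        k <- k + 1L
        if (swap) {
          acc_ia[[k]] <- rep.int(j, length(a)); acc_ib[[k]] <- rep.int(i, length(a))
          acc_la[[k]] <- b; acc_lb[[k]] <- a
        } else {
          acc_ia[[k]] <- rep.int(i, length(a)); acc_ib[[k]] <- rep.int(j, length(a))
          acc_la[[k]] <- a; acc_lb[[k]] <- b
        }
      }
    }
  }
  if (k == 0L) {
    return(data.frame(alpha_protein = character(), alpha_seq = character(),
                      alpha_start = integer(), alpha_mods = character(),
                      alpha_mc = integer(), beta_protein = character(),
                      beta_seq = character(), beta_start = integer(),
                      beta_mods = character(), beta_mc = integer(),
                      link_alpha_pos = integer(), link_beta_pos = integer(),
                      link_type = character(), mass = numeric(),
                      decoy = logical(), stringsAsFactors = FALSE))
  }
  ia <- unlist(acc_ia); ib <- unlist(acc_ib)
  la <- unlist(acc_la); lb <- unlist(acc_lb)
  ra <- substring(forms$sequence[ia], la, la)
  rb <- substring(forms$sequence[ib], lb, lb)
  df <- data.frame(
    alpha_protein = forms$protein_id[ia], alpha_seq = forms$sequence[ia],
    alpha_start = forms$start[ia], alpha_mods = forms$mods[ia],
    alpha_mc = forms$missed_cleavages[ia],
    beta_protein = forms$protein_id[ib], beta_seq = forms$sequence[ib],
    beta_start = forms$start[ib], beta_mods = forms$mods[ib],
    beta_mc = forms$missed_cleavages[ib],
    link_alpha_pos = la, link_beta_pos = lb,
    link_type = ifelse(ra == "Y" & rb == "Y", "YY",
                       ifelse(ra == "W" & rb == "W", "WW", "YW")),
    mass = forms$mass[ia] + forms$mass[ib] + .LINK_DELTA,
    decoy = decoy, stringsAsFactors = FALSE)
  # canonicalize within-form pairs (two copies of the same form) so the
  # unordered position pair appears once
  same <- df$alpha_seq == df$beta_seq & df$alpha_mods == df$beta_mods &
    df$alpha_start == df$beta_start
  if (any(same)) {
    lo <- pmin(df$link_alpha_pos[same], df$link_beta_pos[same])
    hi <- pmax(df$link_alpha_pos[same], df$link_beta_pos[same])
    df$link_alpha_pos[same] <- lo
    df$link_beta_pos[same] <- hi
  }
  df <- df[!duplicated(paste(df$alpha_seq, df$alpha_mods, df$link_alpha_pos,
                             df$beta_seq, df$beta_mods, df$link_beta_pos)), ]
  rownames(df) <- NULL
  df
}

#' Reconstruct the crosslink_pair object for a candidate row
#'
#' @param cand One row of an [enumerate_candidates()] table.
#' @param alpha_label,beta_label 18O atoms at each C-terminus.
#' @return A [crosslink_pair].
#' @export
pair_from_candidate <- function(cand, alpha_label = 0L, beta_label = 0L) {
  a <- peptide(cand$alpha_seq, protein_id = cand$alpha_protein,
               start = cand$alpha_start, missed_cleavages = cand$alpha_mc,
               mods = decode_mods(cand$alpha_mods), label = alpha_label)
  b <- peptide(cand$beta_seq, protein_id = cand$beta_protein,
               start = cand$beta_start, missed_cleavages = cand$beta_mc,
               mods = decode_mods(cand$beta_mods), label = beta_label)
  crosslink_pair(a, b, cand$link_alpha_pos, cand$link_beta_pos)
}

#' Match an observed precursor against cross-link candidates
#'
#' @param candidates `data.frame` from [enumerate_candidates()].
#' @param mz,charge Observed precursor m/z and charge (used when
#'   `neutral_mass` is not given).
#' @param neutral_mass Observed neutral mass in Da, if already computed.
#' @param tol_ppm Precursor tolerance in ppm.
#' @return Candidates within tolerance, with `observed_mass` and
#'   `ppm_error`, sorted by absolute ppm error.
#' @export
match_precursor <- function(candidates, mz = NULL, charge = NULL,
                            neutral_mass = NULL, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  if (is.null(neutral_mass)) {
    stopifnot(!is.null(mz), !is.null(charge))
    neutral_mass <- mass_from_mz(mz, charge)
  }
  ppm <- ppm_error(neutral_mass, candidates$mass)
  keep <- which(abs(ppm) <= tol_ppm)
  out <- candidates[keep, , drop = FALSE]
  out$observed_mass <- rep_len(neutral_mass, nrow(out))
  out$ppm_error <- ppm[keep]
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.ladder <- function(pep, partner_mass = NULL, link_pos = NULL,
                    series = c("b", "y"), max_fragment_charge = 2L,
                    chain = "peptide") {
  aa_mass <- .residue_vector(pep$sequence)
  nres <- length(aa_mass)
  mod_at <- numeric(nres)
  if (nrow(pep$mods)) {
    for (k in seq_len(nrow(pep$mods)))
      mod_at[pep$mods$pos[k]] <- mod_at[pep$mods$pos[k]] + pep$mods$delta[k]
  }
  pref <- cumsum(aa_mass + mod_at)
  total <- pref[nres] + .WATER + pep$label * .O18_MINUS_O16
  linked <- !is.null(link_pos)
  partner_add <- if (linked) partner_mass + .LINK_DELTA else 0
  rows <- list(); ri <- 0L
  for (i in seq_len(max(nres - 1L, 0L))) {
    bn <- pref[i]                                  # neutral b fragment
    yn <- total - pref[nres - i]                   # neutral y fragment
    b_link <- linked && link_pos <= i
    y_link <- linked && link_pos > nres - i
    emit <- function(ser, idx, neutral, retains) {
      ri <<- ri + 1L
      rows[[ri]] <<- data.frame(chain = chain, series = ser, index = idx,
                                retains_link = retains, neutral_mass = neutral,
                                stringsAsFactors = FALSE)
    }
    if ("b" %in% series) emit("b", i, bn + if (b_link) partner_add else 0, b_link)
    if ("y" %in% series) emit("y", i, yn + if (y_link) partner_add else 0, y_link)
    if ("c" %in% series) emit("c", i, bn + .C_MINUS_B + if (b_link) partner_add else 0, b_link)
    if ("z" %in% series) emit("z", i, yn - .Y_MINUS_Z + if (y_link) partner_add else 0, y_link)
  }
  # full-length b (acylium of the whole chain); no y0 counterpart
  bn_full <- pref[nres] + if (linked) partner_add else 0
  if ("b" %in% series) emit("b", nres, bn_full, linked)
  if ("c" %in% series) emit("c", nres, bn_full + .C_MINUS_B, linked)
  df <- do.call(rbind, rows)
  zs <- seq_len(max_fragment_charge)
  df <- df[rep(seq_len(nrow(df)), each = length(zs)), , drop = FALSE]
  df$charge <- rep(zs, times = nrow(df) / length(zs))
  df$mz <- mz_from_mass(df$neutral_mass, df$charge)
  rownames(df) <- NULL
  df
}

#' Theoretical fragment ions
#'
#' Standard b/y (and c/z) ladders for a peptide or a cross-linked pair. Any
#' fragment of one chain that contains the linked residue additionally
#' carries the full mass of the partner peptide plus the -2 H link delta.
#' C-terminus-containing fragments include each peptide's 18O label shift.
#'
#' @param x A [peptide] or [crosslink_pair].
#' @param series Ion series to generate, subset of `c("b","y","c","z")`.
#' @param max_fragment_charge Fragment charges 1..this are emitted.
#' @return `data.frame` with columns `chain` (`"alpha"`/`"beta"` for a pair),
#'   `series`, `index`, `retains_link`, `neutral_mass`, `charge`, `mz`.
#' @export
fragment_ions <- function(x, series = c("b", "y"), max_fragment_charge = 2L) {
  if (inherits(x, "peptide")) {
    return(.ladder(x, series = series,
                   max_fragment_charge = max_fragment_charge))
  }
  stopifnot(inherits(x, "crosslink_pair"))
  a <- .ladder(x$alpha, partner_mass = peptide_mass(x$beta),
               link_pos = x$link_alpha_pos, series = series,
               max_fragment_charge = max_fragment_charge, chain = "alpha")
  b <- .ladder(x$beta, partner_mass = peptide_mass(x$alpha),
               link_pos = x$link_beta_pos, series = series,
               max_fragment_charge = max_fragment_charge, chain = "beta")
  rbind(a, b)
}

#' Construct an MS2 spectrum
#'
#' @param precursor_mz,precursor_charge Precursor coordinates.
#' @param peaks `data.frame` with columns `mz` and `intensity`.
#' @param method_tag Fragmentation method label (`"HCD"`, `"EThcD"`, ...).
#' @param title Free-text identifier.
#' @return An object of class `ms2_spectrum` (peaks sorted by m/z).
#' @export
ms2_spectrum <- function(precursor_mz, precursor_charge, peaks,
                         method_tag = "HCD", title = "") {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) stop("negative peak intensity")
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 peaks = peaks, method_tag = method_tag, title = title),
            class = "ms2_spectrum")
}

#' Score a spectrum against theoretical fragments
#'
#' The score is 100 times the weighted fraction of theoretical fragments
#' (unique chain/series/index) matched by at least one peak within the MS2
#' tolerance, with cross-link-retaining fragments weighted 2 and plain
#' fragments weighted 1. The score is deterministic and invariant to uniform
#' intensity scaling.
#'
#' @param spectrum An [ms2_spectrum].
#' @param fragments `data.frame` from [fragment_ions()].
#' @param ms2_tol MS2 peak tolerance in m/z units.
#' @param intensity_floor Peaks at or below this intensity are ignored.
#' @return Score in `[0, 100]`.
#' @export
score_match <- function(spectrum, fragments, ms2_tol = 0.02,
                        intensity_floor = 0) {
  pk <- spectrum$peaks
  pk <- pk[pk$intensity > intensity_floor, , drop = FALSE]
  key <- paste(fragments$chain, fragments$series, fragments$index)
  ukey <- unique(key)
  if (!nrow(pk)) return(0)
  hit <- vapply(fragments$mz, function(m) {
    i <- findInterval(m, pk$mz)
    (i >= 1L && abs(pk$mz[i] - m) <= ms2_tol) ||
      (i < nrow(pk) && abs(pk$mz[i + 1L] - m) <= ms2_tol)
  }, logical(1))
  w <- ifelse(tapply(fragments$retains_link, key, any)[ukey], 2, 1)
  matched <- tapply(hit, key, any)[ukey]
  100 * sum(w * matched) / sum(w)
}

#' Filter scored cross-link matches
#'
#' Removes matches at or below the score threshold or below the precursor
#' intensity floor, and (when replicate information is present) keeps only
#' pairs identified in at least `require_replicates` replicates. One row per
#' unique pair is returned (best score, ties broken by smaller absolute ppm
#' error).
#'
#' @param matches `data.frame` with at least `alpha_seq`, `alpha_mods`,
#'   `link_alpha_pos`, `beta_seq`, `beta_mods`, `link_beta_pos`, `score`;
#'   optionally `intensity`, `replicate`, `ppm_error`, `decoy`.
#' @param score_threshold Matches must score strictly above this.
#' @param intensity_floor Minimum precursor intensity.
#' @param require_replicates Minimum number of distinct replicates.
#' @return Filtered `data.frame` with an `n_replicates` column.
#' @export
filter_matches <- function(matches, score_threshold = 50,
                           intensity_floor = 2000, require_replicates = 1L) {
  if (!nrow(matches)) return(cbind(matches, n_replicates = integer(0)))
  keep <- matches$score > score_threshold
  if (!is.null(matches$intensity))
    keep <- keep & (is.na(matches$intensity) | matches$intensity >= intensity_floor)
  m <- matches[keep, , drop = FALSE]
  if (!nrow(m)) return(cbind(m, n_replicates = integer(0)))
  key <- paste(m$alpha_seq, m$alpha_mods, m$link_alpha_pos,
               m$beta_seq, m$beta_mods, m$link_beta_pos, sep = "|")
  reps <- if (!is.null(m$replicate)) {
    tapply(m$replicate, key, function(r) length(unique(r)))
  } else {
    tapply(rep(1L, nrow(m)), key, sum) * 0L + 1L
  }
  ok_keys <- names(reps)[reps >= require_replicates]
  m <- m[key %in% ok_keys, , drop = FALSE]
  key <- key[key %in% ok_keys]
  ppm <- if (!is.null(m$ppm_error)) abs(m$ppm_error) else rep(0, nrow(m))
  ord <- order(key, -m$score, ppm)
  m <- m[ord, , drop = FALSE]; key <- key[ord]
  m <- m[!duplicated(key), , drop = FALSE]
  key <- key[!duplicated(key)]
  m$n_replicates <- as.integer(reps[key])
  rownames(m) <- NULL
  m
}

#' Target-decoy false discovery estimate
#'
#' @param matches `data.frame` with a logical `decoy` column (an accepted
#'   match set).
#' @return Estimated FDR: number of decoy matches divided by number of
#'   target matches (0 when there are no target matches and no decoys).
#' @export
estimate_fdr <- function(matches) {
  nd <- sum(matches$decoy)
  nt <- sum(!matches$decoy)
  if (nt == 0L) return(if (nd > 0L) Inf else 0)
  nd / nt
}
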