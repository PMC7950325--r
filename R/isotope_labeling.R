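# 16O/18O doublet classification: co-eluting light/heavy feature pairs whose
# charge-corrected (neutral) mass shift identifies linear (+4 Da),
# cross-linked (+8 Da) or partially labeled species.

.ADMISSIBLE_SHIFTS <- c(partial = 1 * 2.004246, linear = 2 * 2.004246,
                        partial = 3 * 2.004246, crosslinked = 4 * 2.004246)

#' Classify a neutral 18O mass shift
#'
#' A fully labeled linear peptide (one new C-terminus, two 18O) shifts by
#' +4.0085 Da and a fully labeled cross-linked pair (two new termini) by
#' +8.0170 Da; +2.0042 and +6.0127 Da indicate incomplete incorporation.
#' The nearest admissible shift within tolerance decides the call; negative
#' shifts (heavy channel lighter than light) are never classified.
#'
#' @param neutral_shift Charge-corrected mass shift(s) in Da
#'   (`charge * (heavy m/z - light m/z)`).
#' @param tolerance Absolute tolerance in Da (neutral-mass space).
#' @return Character vector: `"linear"`, `"crosslinked"`, `"partial"` or
#'   `"unclassified"`.
#' @export
#' @examples
#' classify_shift(c(4.008, 8.017, 6.013, 0.5))
classify_shift <- function(neutral_shift, tolerance = 0.015) {
  stopifnot(tolerance > 0)
  vapply(neutral_shift, function(s) {
    d <- abs(s - .ADMISSIBLE_SHIFTS)
    i <- which.min(d)
    if (s > 0 && d[i] <= tolerance) names(.ADMISSIBLE_SHIFTS)[i]
    else "unclassified"
  }, character(1))
}

#' Pair 16O/18O feature doublets
#'
#' Pairs co-eluting features of the same charge (and sample/replicate, when
#' those columns are present) from the light (16O) and heavy (18O) channels
#' whose neutral shift is within tolerance of an admissible 18O label shift.
#' Each feature enters at most one doublet; assembly is greedy by combined
#' intensity with ties broken by smaller shift error.
#'
#' Because the shift is the difference of two independently measured m/z
#' values, its error grows with precursor mass; the effective tolerance for
#' a pair is therefore `max(tolerance, 2e-6 * ppm_tolerance * neutral
#' mass)`. The admissible shifts are 2 Da apart, so the widened window
#' cannot produce cross-category confusions.
#'
#' @param features `data.frame` of MS1 features with columns `feature_id`,
#'   `mz`, `charge`, `area`, `rt_start`, `rt_end`, `channel` (`"16O"` /
#'   `"18O"`), optionally `sample` and `replicate`.
#' @param tolerance Minimum neutral-shift tolerance in Da.
#' @param ppm_tolerance Per-measurement mass accuracy (ppm) used to scale
#'   the tolerance with precursor mass.
#' @return `data.frame` of doublet calls: `light_id`, `heavy_id`, `charge`,
#'   `light_mz`, `light_area`, `heavy_area`, `neutral_shift`, `call` plus
#'   any grouping columns.
#' @export
pair_doublets <- function(features, tolerance = 0.015, ppm_tolerance = 10) {
  stopifnot(all(c("feature_id", "mz", "charge", "area", "rt_start",
                  "rt_end", "channel") %in% names(features)))
  grp_cols <- intersect(c("sample", "condition", "replicate"), names(features))
  light <- features[features$channel == "16O", , drop = FALSE]
  heavy <- features[features$channel == "18O", , drop = FALSE]
  if (!nrow(light) || !nrow(heavy)) {
    return(data.frame(light_id = character(), heavy_id = character(),
                      charge = integer(), light_mz = numeric(),
                      light_area = numeric(), heavy_area = numeric(),
                      neutral_shift = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  }
  lk <- do.call(paste, c(light[c("charge", grp_cols)], sep = "|"))
  hk <- do.call(paste, c(heavy[c("charge", grp_cols)], sep = "|"))
  cand <- list(); ci <- 0L
  for (k in intersect(unique(lk), unique(hk))) {
    li <- which(lk == k); hi <- which(hk == k)
    for (a in li) for (b in hi) {
      if (heavy$rt_start[b] > light$rt_end[a] ||
          heavy$rt_end[b] < light$rt_start[a]) next      # must co-elute
      shift <- light$charge[a] * (heavy$mz[b] - light$mz[a])
      neutral <- mass_from_mz(light$mz[a], light$charge[a])
      tol_eff <- max(tolerance, 2e-6 * ppm_tolerance * neutral)
      call <- classify_shift(shift, tol_eff)
      if (call == "unclassified") next
      err <- min(abs(shift - .ADMISSIBLE_SHIFTS))
      ci <- ci + 1L
      cand[[ci]] <- data.frame(a = a, b = b, shift = shift, call = call,
                               err = err,
                               strength = light$area[a] + heavy$area[b],
                               stringsAsFactors = FALSE)
    }
  }
  if (ci == 0L) {
    return(data.frame(light_id = character(), heavy_id = character(),
                      charge = integer(), light_mz = numeric(),
                      light_area = numeric(), heavy_area = numeric(),
                      neutral_shift = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$strength, cand$err), , drop = FALSE]
  used_l <- logical(nrow(light)); used_h <- logical(nrow(heavy))
  take <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used_l[cand$a[r]] && !used_h[cand$b[r]]) {
      take[r] <- TRUE
      used_l[cand$a[r]] <- TRUE
      used_h[cand$b[r]] <- TRUE
    }
  }
  cand <- cand[take, , drop = FALSE]
  out <- data.frame(light_id = light$feature_id[cand$a],
                    heavy_id = heavy$feature_id[cand$b],
                    charge = light$charge[cand$a],
                    light_mz = light$mz[cand$a],
                    light_area = light$area[cand$a],
                    heavy_area = heavy$area[cand$b],
                    neutral_shift = cand$shift, call = cand$call,
                    stringsAsFactors = FALSE)
  for (g in grp_cols) out[[g]] <- light[[g]][cand$a]
  rownames(out) <- NULL
  out
}
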