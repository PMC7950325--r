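# In-silico tryptic proteolysis: fully specific and semispecific peptides
# with bounded missed cleavages.

#' Digestion specification
#'
#' @param max_missed_cleavages Maximum internal uncut K/R sites per peptide.
#' @param specificity `"full"` (both termini tryptic) or `"semi"` (at least
#'   one tryptic terminus). Chain ends count as tryptic termini.
#' @param min_length,max_length Peptide length bounds (residues), inclusive.
#' @return A list of class `digest_spec`.
#' @export
digest_spec <- function(max_missed_cleavages = 2L,
                        specificity = c("full", "semi"),
                        min_length = 6L, max_length = 45L) {
  specificity <- match.arg(specificity)
  stopifnot(max_missed_cleavages >= 0L, min_length >= 1L,
            min_length <= max_length)
  structure(list(enzyme = "trypsin",
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 specificity = specificity,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digest_spec")
}

#' Tryptic cleavage sites
#'
#' Positions after which trypsin cuts: C-terminal to K or R, suppressed when
#' the next residue is P. The chain C-terminus is always a boundary and is
#' included in the returned vector.
#'
#' @param sequence Protein sequence string.
#' @return Sorted integer vector of cut positions (cut occurs after each).
#' @export
#' @examples
#' cleavage_sites("AKRPAK")  # 2, 6
cleavage_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(aa)
  cut <- which(aa %in% c("K", "R"))
  cut <- cut[cut == n | aa[pmin(cut + 1L, n)] != "P"]
  sort(unique(c(cut, n)))
}

#' In-silico tryptic digest
#'
#' Fully specific peptides are unions of 1 to (max missed cleavages + 1)
#' consecutive zero-missed-cleavage fragments; semispecific digestion
#' additionally yields peptides with exactly one non-tryptic terminus.
#'
#' @param sequence Protein sequence string (mature chain, 1-based numbering).
#' @param spec A [digest_spec()].
#' @param protein_id Identifier recorded on each peptide row.
#' @return `data.frame` with columns `protein_id`, `start`, `end`,
#'   `sequence`, `missed_cleavages`, `nterm_tryptic`, `cterm_tryptic`.
#' @export
#' @examples
#' digest("AKRPAK", digest_spec(1, "full", min_length = 1, max_length = 10))
digest <- function(sequence, spec = digest_spec(), protein_id = "protein") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  sites <- cleavage_sites(sequence)
  bounds <- c(0L, sites)                    # fragment k spans bounds[k]+1 .. bounds[k+1]
  nfrag <- length(bounds) - 1L
  out <- list(); oi <- 0L
  add <- function(s, e, mc, nt, ct) {
    len <- e - s + 1L
    if (len < spec$min_length || len > spec$max_length) return()
    oi <<- oi + 1L
    out[[oi]] <<- c(s, e, mc, nt, ct)
  }
  # fully specific: unions of consecutive fragments
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + spec$max_missed_cleavages)
    for (j in i:jmax) {
      add(bounds[i] + 1L, bounds[j + 1L], j - i, 1L, 1L)
    }
  }
  if (spec$specificity == "semi") {
    internal <- setdiff(sites, n)           # sites strictly inside the chain
    tryptic_starts <- c(1L, internal + 1L)
    tryptic_ends <- c(internal, n)
    # tryptic N-terminus, ragged C-terminus
    for (s in tryptic_starts) {
      emax <- min(n, s + spec$max_length - 1L)
      for (e in s:emax) {
        mc <- sum(sites >= s & sites <= e - 1L)
        if (mc > spec$max_missed_cleavages) break
        if (!(e %in% tryptic_ends)) add(s, e, mc, 1L, 0L)
      }
    }
    # ragged N-terminus, tryptic C-terminus
    for (e in tryptic_ends) {
      smin <- max(1L, e - spec$max_length + 1L)
      for (s in e:smin) {
        mc <- sum(sites >= s & sites <= e - 1L)
        if (mc > spec$max_missed_cleavages) break
        if (!(s %in% tryptic_starts)) add(s, e, mc, 0L, 1L)
      }
    }
  }
  if (oi == 0L)
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      missed_cleavages = integer(), nterm_tryptic = logical(),
                      cterm_tryptic = logical(), stringsAsFactors = FALSE))
  m <- do.call(rbind, out[seq_len(oi)])
  df <- data.frame(protein_id = protein_id, start = m[, 1L], end = m[, 2L],
                   sequence = substring(sequence, m[, 1L], m[, 2L]),
                   missed_cleavages = m[, 3L],
                   nterm_tryptic = m[, 4L] == 1L,
                   cterm_tryptic = m[, 5L] == 1L,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}
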