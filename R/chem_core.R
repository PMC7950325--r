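# Monoisotopic mass tables and all neutral-mass / m/z / cross-link /
# isotope-label arithmetic. Everything downstream funnels through these
# functions, so internal computation is kept at full double precision;
# rounding happens only in report writers.

.residue_masses <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.WATER  <- 18.010565
.PROTON <- 1.007276
.O18_MINUS_O16 <- 2.004246   # one 18O-for-16O substitution
.LINK_DELTA <- -2.015650     # loss of two H on direct side-chain coupling

#' Monoisotopic mass constants
#'
#' Residue monoisotopic masses (Da) for the 20 standard amino acids, plus the
#' masses of water, a proton, and the single 18O-for-16O substitution used in
#' proteolytic labeling.
#'
#' @return A list with elements `residues` (named numeric vector, Da),
#'   `water`, `proton`, `o18_minus_o16` and `link_delta` (the -2 H mass
#'   change of a direct Tyr/Trp side-chain cross-link).
#' @export
#' @examples
#' mass_constants()$water
mass_constants <- function() {
  list(residues = .residue_masses, water = .WATER, proton = .PROTON,
       o18_minus_o16 = .O18_MINUS_O16, link_delta = .LINK_DELTA)
}

#' Define a modification
#'
#' @param name Modification name.
#' @param targets Character vector of single-letter residue codes the
#'   modification applies to.
#' @param delta Monoisotopic mass change in Da.
#' @param kind `"fixed"` (applied to every target residue) or `"variable"`
#'   (applied combinatorially).
#' @param max_per_peptide Maximum number of variable occurrences considered
#'   per peptide.
#' @return An object of class `modification`.
#' @export
modification <- function(name, targets, delta, kind = c("variable", "fixed"),
                         max_per_peptide = 3L) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L,
            all(nchar(targets) == 1L), is.numeric(delta), length(delta) == 1L,
            max_per_peptide >= 0L)
  structure(list(name = name, targets = toupper(targets), delta = delta,
                 kind = kind, max_per_peptide = as.integer(max_per_peptide)),
            class = "modification")
}

#' @export
print.modification <- function(x, ...) {
  cat(sprintf("<modification> %s (%+.6f Da) on %s [%s, max %d]\n",
              x$name, x$delta, paste(x$targets, collapse = ","),
              x$kind, x$max_per_peptide))
  invisible(x)
}

#' Default modification set
#'
#' Carbamidomethylation of Cys (fixed, +57.021464 Da), nitration of Tyr/Trp
#' (variable, +44.985078 Da; 3-nitrotyrosine / 6-nitrotryptophan) and Met
#' oxidation to the sulfoxide (variable, +15.994915 Da). Chlorination of Tyr
#' (+33.961028 Da) can be added for hypochlorous-acid style comparisons.
#'
#' @param include_chlorination Add 3-chlorotyrosine as a variable modification.
#' @return Named list of [modification] objects.
#' @export
default_modifications <- function(include_chlorination = FALSE) {
  mods <- list(
    carbamidomethyl = modification("carbamidomethyl", "C", 57.021464, "fixed"),
    nitration = modification("nitration", c("Y", "W"), 44.985078, "variable"),
    met_oxidation = modification("met_oxidation", "M", 15.994915, "variable")
  )
  if (include_chlorination)
    mods$chlorination <- modification("chlorination", "Y", 33.961028, "variable")
  mods
}

#' Load modification definitions from a config list
#'
#' @param x A list of lists with fields `name`, `targets`, `delta`, `kind`,
#'   `max_per_peptide` (as produced by [read_config()]).
#' @return Named list of [modification] objects.
#' @export
modifications_from_config <- function(x) {
  mods <- lapply(x, function(m) {
    modification(m$name, unlist(m$targets), m$delta,
                 kind = m$kind %||% "variable",
                 max_per_peptide = m$max_per_peptide %||% 3L)
  })
  names(mods) <- vapply(mods, `[[`, "", "name")
  mods
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.empty_mods <- function() {
  data.frame(pos = integer(), name = character(), delta = numeric(),
             stringsAsFactors = FALSE)
}

#' Construct a peptide
#'
#' A located subsequence of a protein chain, with modifications and an
#' 18O label state at its (single, proteolytic) C-terminus.
#'
#' @param sequence Residue letters (uppercase single-letter codes).
#' @param protein_id Identifier of the parent chain.
#' @param start 1-based position of the first residue on the mature chain.
#' @param missed_cleavages Number of internal uncut K/R sites.
#' @param mods `data.frame` with columns `pos` (1-based within the peptide),
#'   `name`, `delta` (Da), or `NULL` for none.
#' @param label Number of 18O atoms at the C-terminus (0, 1 or 2).
#' @return An object of class `peptide`.
#' @export
#' @examples
#' peptide("TFYSCTTEGR")
peptide <- function(sequence, protein_id = NA_character_, start = 1L,
                    missed_cleavages = 0L, mods = NULL, label = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  if (is.null(mods)) mods <- .empty_mods()
  mods <- as.data.frame(mods)
  if (nrow(mods)) {
    if (any(mods$pos < 1L | mods$pos > nchar(sequence)))
      stop("modification position outside peptide")
  }
  if (!label %in% 0:2) stop("label must be 0, 1 or 2 18O atoms")
  structure(list(protein_id = protein_id, start = as.integer(start),
                 end = as.integer(start) + nchar(sequence) - 1L,
                 sequence = sequence,
                 missed_cleavages = as.integer(missed_cleavages),
                 mods = mods, label = as.integer(label)),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  m <- if (nrow(x$mods)) paste(sprintf("%s@%d", x$mods$name, x$mods$pos),
                               collapse = ", ") else "none"
  cat(sprintf("<peptide> %s [%s %d-%d] mc=%d label=%d mods: %s\n",
              x$sequence, x$protein_id, x$start, x$end,
              x$missed_cleavages, x$label, m))
  invisible(x)
}

.residue_vector <- function(sequence) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- .residue_masses[aa]
  if (anyNA(m)) {
    i <- which(is.na(m))[1L]
    stop(sprintf("unknown residue letter '%s' at position %d", aa[i], i))
  }
  unname(m)
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus water, modification deltas, and the 18O label
#' shift at the C-terminus.
#'
#' @param p A [peptide] or a plain sequence string.
#' @param mods,label Used only when `p` is a string; see [peptide()].
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass("G")  # 75.032029
peptide_mass <- function(p, mods = NULL, label = 0L) {
  if (is.character(p)) p <- peptide(p, mods = mods, label = label)
  sum(.residue_vector(p$sequence)) + .WATER + sum(p$mods$delta) +
    p$label * .O18_MINUS_O16
}

#' Convert neutral mass to m/z and back
#'
#' @param mass Neutral mass in Da.
#' @param z Positive integer charge.
#' @return `mz_from_mass`: m/z; `mass_from_mz`: neutral mass in Da.
#' @export
mz_from_mass <- function(mass, z) {
  if (any(z < 1L)) stop("charge must be >= 1")
  (mass + z * .PROTON) / z
}

#' @rdname mz_from_mass
#' @param mz Observed m/z.
#' @export
mass_from_mz <- function(mz, z) {
  if (any(z < 1L)) stop("charge must be >= 1")
  mz * z - z * .PROTON
}

#' Parts-per-million mass error
#'
#' @param observed,theoretical Masses in Da (or m/z on the same scale).
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  1e6 * (observed - theoretical) / theoretical
}

#' Construct a cross-linked peptide pair
#'
#' Two peptides joined through one Tyr or Trp residue each, with loss of two
#' hydrogen atoms (-2.01565 Da) relative to the sum of the parents.
#'
#' @param alpha,beta [peptide] objects. By convention `alpha` is the longer
#'   chain; the constructor does not reorder.
#' @param link_alpha_pos,link_beta_pos 1-based positions of the linked
#'   residues within each peptide.
#' @return An object of class `crosslink_pair` with fields `alpha`, `beta`,
#'   `link_alpha_pos`, `link_beta_pos`, `link_type` (`"YY"`, `"WW"` or
#'   `"YW"`) and `link_delta`.
#' @export
crosslink_pair <- function(alpha, beta, link_alpha_pos, link_beta_pos) {
  stopifnot(inherits(alpha, "peptide"), inherits(beta, "peptide"))
  ra <- substr(alpha$sequence, link_alpha_pos, link_alpha_pos)
  rb <- substr(beta$sequence, link_beta_pos, link_beta_pos)
  if (!ra %in% c("Y", "W"))
    stop(sprintf("link residue '%s' at alpha position %d is not Y or W",
                 ra, link_alpha_pos))
  if (!rb %in% c("Y", "W"))
    stop(sprintf("link residue '%s' at beta position %d is not Y or W",
                 rb, link_beta_pos))
  type <- if (ra == "Y" && rb == "Y") "YY"
          else if (ra == "W" && rb == "W") "WW"
          else "YW"
  structure(list(alpha = alpha, beta = beta,
                 link_alpha_pos = as.integer(link_alpha_pos),
                 link_beta_pos = as.integer(link_beta_pos),
                 link_type = type, link_delta = .LINK_DELTA),
            class = "crosslink_pair")
}

#' @export
print.crosslink_pair <- function(x, ...) {
  cat(sprintf("<crosslink_pair> %s(%s%d) x %s(%s%d) [%s]\n",
              x$alpha$sequence,
              substr(x$alpha$sequence, x$link_alpha_pos, x$link_alpha_pos),
              x$link_alpha_pos,
              x$beta$sequence,
              substr(x$beta$sequence, x$link_beta_pos, x$link_beta_pos),
              x$link_beta_pos, x$link_type))
  invisible(x)
}

#' Neutral monoisotopic mass of a cross-linked pair
#'
#' `peptide_mass(alpha) + peptide_mass(beta) - 2.01565`.
#'
#' @param pair A [crosslink_pair].
#' @return Neutral monoisotopic mass in Da.
#' @export
crosslink_mass <- function(pair) {
  stopifnot(inherits(pair, "crosslink_pair"))
  peptide_mass(pair$alpha) + peptide_mass(pair$beta) + pair$link_delta
}

#' 18O proteolytic label mass shift
#'
#' Digestion in heavy-oxygen water incorporates up to two 18O atoms at each
#' newly formed peptide C-terminus, so a linear peptide fully labeled at its
#' one new terminus shifts by +4.008 Da and a cross-linked pair (two new
#' termini) by +8.017 Da.
#'
#' @param n_new_c_termini Number of proteolytic C-termini (1 for a linear
#'   peptide, 2 for a cross-linked pair).
#' @param o18_per_terminus 18O atoms incorporated per terminus (0, 1 or 2).
#' @return Mass shift in Da.
#' @export
#' @examples
#' label_shift(1, 2)  # +4.008 Da, linear peptide
#' label_shift(2, 2)  # +8.017 Da, cross-linked pair
label_shift <- function(n_new_c_termini, o18_per_terminus) {
  if (!all(n_new_c_termini %in% 1:2))
    stop("n_new_c_termini must be 1 or 2")
  if (!all(o18_per_terminus %in% 0:2))
    stop("o18_per_terminus must be 0, 1 or 2")
  n_new_c_termini * o18_per_terminus * .O18_MINUS_O16
}

#' Count residues of interest in a chain
#'
#' Tabulates the oxidant-target residues (Tyr, Trp, Met by default) of a
#' protein sequence.
#'
#' @param sequence Protein sequence string.
#' @param residues Residue letters to count.
#' @return Named integer vector of counts.
#' @export
residue_census <- function(sequence, residues = c("Y", "W", "M")) {
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  vapply(residues, function(r) sum(aa == r), integer(1))
}

# mods encoded as "pos:name:delta;pos:name:delta" in flat tables
encode_mods <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0L) return("")
  paste(sprintf("%d:%s:%.6f", mods$pos, mods$name, mods$delta), collapse = ";")
}

decode_mods <- function(s) {
  if (is.na(s) || !nzchar(s)) return(.empty_mods())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(pos = as.integer(vapply(parts, `[`, "", 1L)),
             name = vapply(parts, `[`, "", 2L),
             delta = as.numeric(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}
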