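# Atomic and residue mass bookkeeping. Heavy labels (13C, 15N) are carried
# as distinct elements so that isotope envelopes stay correct.

# monoisotopic atomic masses (Da); C13/N15 are pure-isotope entries
.MONO_MASS <- c(
  C   = 12.0,
  C13 = 13.0033548378,
  H   = 1.00782503207,
  N   = 14.0030740048,
  N15 = 15.0001088982,
  O   = 15.9949146196,
  S   = 31.9720710015
)

# standard atomic weights; pure isotopes keep their exact mass
.AVG_MASS <- c(
  C   = 12.0107,
  C13 = 13.0033548378,
  H   = 1.00794,
  N   = 14.0067,
  N15 = 15.0001088982,
  O   = 15.9994,
  S   = 32.065
)

.ELECTRON_MASS <- 0.00054857990907
.PROTON_MASS <- .MONO_MASS[["H"]] - .ELECTRON_MASS
.WATER_MONO <- 2 * .MONO_MASS[["H"]] + .MONO_MASS[["O"]]
# nominal isotopologue spacing used for envelopes and de-isotoping
.ISO_SPACING <- 1.0033548378

.ELEMENTS <- names(.MONO_MASS)

# zero composition vector in canonical element order
.comp0 <- function() setNames(numeric(length(.ELEMENTS)), .ELEMENTS)

# build a composition from element counts, e.g. .comp(C = 2, H = 3, N = 1, O = 1)
.comp <- function(...) {
  x <- c(...)
  out <- .comp0()
  bad <- setdiff(names(x), .ELEMENTS)
  if (length(bad) > 0L)
    stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out[names(x)] <- out[names(x)] + x
  out
}

# residue (peptide-bond) elemental compositions of the 20 standard amino acids
.RESIDUE_COMP <- list(
  G = .comp(C = 2,  H = 3,  N = 1, O = 1),
  A = .comp(C = 3,  H = 5,  N = 1, O = 1),
  S = .comp(C = 3,  H = 5,  N = 1, O = 2),
  P = .comp(C = 5,  H = 7,  N = 1, O = 1),
  V = .comp(C = 5,  H = 9,  N = 1, O = 1),
  T = .comp(C = 4,  H = 7,  N = 1, O = 2),
  C = .comp(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = .comp(C = 6,  H = 11, N = 1, O = 1),
  I = .comp(C = 6,  H = 11, N = 1, O = 1),
  N = .comp(C = 4,  H = 6,  N = 2, O = 2),
  D = .comp(C = 4,  H = 5,  N = 1, O = 3),
  Q = .comp(C = 5,  H = 8,  N = 2, O = 2),
  K = .comp(C = 6,  H = 12, N = 2, O = 1),
  E = .comp(C = 5,  H = 7,  N = 1, O = 3),
  M = .comp(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = .comp(C = 6,  H = 7,  N = 3, O = 1),
  F = .comp(C = 9,  H = 9,  N = 1, O = 1),
  R = .comp(C = 6,  H = 12, N = 4, O = 1),
  Y = .comp(C = 9,  H = 9,  N = 1, O = 2),
  W = .comp(C = 11, H = 10, N = 2, O = 1)
)

.comp_mass <- function(comp, table) sum(comp * table[names(comp)])

#' Residue mass table
#'
#' Elemental compositions and monoisotopic/average residue masses of the 20
#' standard amino acids (peptide-bond residues, i.e. free amino acid minus
#' water). Masses are computed from the compositions, so the table is
#' internally consistent by construction.
#'
#' @return A data frame with one row per one-letter residue code and columns
#'   `C`, `H`, `N`, `O`, `S`, `monoisotopic`, `average` (Da).
#' @export
#' @examples
#' residue_table()["G", ]
residue_table <- function() {
  codes <- names(.RESIDUE_COMP)
  m <- do.call(rbind, .RESIDUE_COMP)
  out <- data.frame(m[, c("C", "H", "N", "O", "S")], row.names = codes)
  out$monoisotopic <- vapply(.RESIDUE_COMP, .comp_mass, 0, table = .MONO_MASS)
  out$average <- vapply(.RESIDUE_COMP, .comp_mass, 0, table = .AVG_MASS)
  out
}

#' Define a terminal or residue modification
#'
#' A modification is a signed elemental delta applied to a peptide
#' composition. The mass delta is computed from the delta composition, so
#' the two can never disagree.
#'
#' @param name Modification name.
#' @param target One of `"N-terminus"`, `"C-terminus"`, `"residue"`.
#' @param delta Named numeric vector of signed atom counts, names among
#'   `C, C13, H, N, N15, O, S`.
#' @param position Residue index (1-based), required when `target =
#'   "residue"`.
#' @return An object of class `peptide_modification`.
#' @export
#' @examples
#' modification("amide", "C-terminus", c(H = 1, N = 1, O = -1))
modification <- function(name, target = c("N-terminus", "C-terminus", "residue"),
                         delta, position = NA_integer_) {
  target <- match.arg(target)
  d <- .comp0()
  bad <- setdiff(names(delta), .ELEMENTS)
  if (length(bad) > 0L)
    stop("unknown element(s) in modification delta: ",
         paste(bad, collapse = ", "), call. = FALSE)
  d[names(delta)] <- delta
  if (target == "residue" && is.na(position))
    stop("residue modifications need a position", call. = FALSE)
  structure(
    list(name = name, target = target, delta = d,
         mass_delta = .comp_mass(d, .MONO_MASS),
         position = as.integer(position)),
    class = "peptide_modification"
  )
}

#' Common modifications
#'
#' Convenience constructors for the modifications carried by AKH-family
#' species: N-terminal pyroglutamate (cyclized Gln, loss of NH3),
#' C-terminal amidation (OH replaced by NH2), and the heavy-leucine label
#' (all six carbons as 13C plus the backbone nitrogen as 15N).
#'
#' @param position Residue index carrying the heavy label.
#' @return A `peptide_modification`.
#' @name builtin_modifications
NULL

#' @rdname builtin_modifications
#' @export
mod_pyroglutamate <- function() {
  modification("pyroglutamate", "N-terminus", c(H = -3, N = -1))
}

#' @rdname builtin_modifications
#' @export
mod_amide <- function() {
  modification("amide", "C-terminus", c(H = 1, N = 1, O = -1))
}

#' @rdname builtin_modifications
#' @export
mod_label_13C6_15N <- function(position) {
  modification("13C6,15N label", "residue",
               c(C = -6, C13 = 6, N = -1, N15 = 1), position = position)
}

#' Define a peptide species
#'
#' @param name Species name (e.g. `"AKH"`, `"AKH*"`).
#' @param sequence One-letter amino-acid string, N- to C-terminus.
#' @param modifications List of [modification()] objects; at most one
#'   N-terminal and one C-terminal modification; residue modification
#'   positions must lie within the sequence.
#' @return An object of class `peptide_species`.
#' @export
#' @examples
#' peptide_species("AKH", "QLTFSPDW",
#'                 list(mod_pyroglutamate(), mod_amide()))
peptide_species <- function(name, sequence, modifications = list()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("sequence must be non-empty", call. = FALSE)
  targets <- vapply(modifications, function(m) m$target, "")
  if (sum(targets == "N-terminus") > 1L || sum(targets == "C-terminus") > 1L)
    stop("at most one N-terminal and one C-terminal modification",
         call. = FALSE)
  for (m in modifications) {
    if (m$target == "residue" &&
        (m$position < 1L || m$position > nchar(sequence)))
      stop("label position ", m$position, " outside sequence", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence,
                 modifications = modifications),
            class = "peptide_species")
}

#' @export
print.peptide_species <- function(x, ...) {
  mods <- if (length(x$modifications) == 0L) "none" else
    paste(vapply(x$modifications, function(m) m$name, ""), collapse = ", ")
  cat(sprintf("<peptide_species> %s: %s (mods: %s)\n  monoisotopic %.4f Da\n",
              x$name, x$sequence, mods, monoisotopic_mass(x)))
  invisible(x)
}

#' The three profiled AKH species
#'
#' Returns the mature hormone AKH (pGlu-LTFSPDW-amide), its free-acid
#' processing intermediate AKHGK (pGlu-LTFSPDWGK), and the heavy-labelled
#' internal standard AKH* (AKH with Leu2 as 13C6,15N).
#'
#' @return Named list of `peptide_species` (`AKH`, `AKHGK`, `AKH*`).
#' @export
#' @examples
#' vapply(akh_species(), monoisotopic_mass, 0)
akh_species <- function() {
  list(
    "AKH" = peptide_species("AKH", "QLTFSPDW",
                            list(mod_pyroglutamate(), mod_amide())),
    "AKHGK" = peptide_species("AKHGK", "QLTFSPDWGK",
                              list(mod_pyroglutamate())),
    "AKH*" = peptide_species("AKH*", "QLTFSPDW",
                             list(mod_pyroglutamate(), mod_amide(),
                                  mod_label_13C6_15N(2)))
  )
}

#' Elemental composition of a peptide species
#'
#' Sum of residue compositions plus one water, plus all modification deltas.
#' Heavy-isotope labels replace the corresponding light atoms one-for-one
#' and appear as distinct `C13`/`N15` entries.
#'
#' @param species A [peptide_species()].
#' @return Named numeric vector of atom counts over
#'   `C, C13, H, N, N15, O, S`.
#' @export
#' @examples
#' elemental_composition(peptide_species("G", "G"))  # free glycine C2H5NO2
elemental_composition <- function(species) {
  stopifnot(inherits(species, "peptide_species"))
  chars <- strsplit(species$sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(unique(chars), names(.RESIDUE_COMP))
  if (length(unknown) > 0L)
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  comp <- .comp(H = 2, O = 1)  # terminal water
  for (ch in chars) comp <- comp + .RESIDUE_COMP[[ch]]
  for (m in species$modifications) comp <- comp + m$delta
  if (any(comp < 0))
    stop("modification deltas drive element count below zero", call. = FALSE)
  comp
}

#' Neutral monoisotopic and average masses
#'
#' @param species A [peptide_species()].
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(akh_species()[["AKH"]])  # 974.4498
monoisotopic_mass <- function(species) {
  .comp_mass(elemental_composition(species), .MONO_MASS)
}

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(species) {
  .comp_mass(elemental_composition(species), .AVG_MASS)
}

#' Singly charged cation adducts
#'
#' Mass shifts are cation masses minus one electron mass.
#'
#' @return Data frame with adduct `name` (`[M+H]+`, `[M+Na]+`, `[M+K]+`),
#'   `charge`, and `shift` (Da).
#' @export
adduct_table <- function() {
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+"),
    charge = 1L,
    shift = c(.PROTON_MASS,
              22.98976928 - .ELECTRON_MASS,
              38.9637064864 - .ELECTRON_MASS),
    row.names = c("H", "Na", "K")
  )
}

#' Adduct m/z of a neutral mass
#'
#' @param neutral_mass Neutral monoisotopic mass (Da), positive.
#' @param adduct Adduct name: `"[M+H]+"`, `"[M+Na]+"`, `"[M+K]+"` (short
#'   forms `"H"`, `"Na"`, `"K"` also accepted).
#' @return m/z of the singly charged adduct ion.
#' @export
#' @examples
#' adduct_mz(974.4498, "[M+Na]+")  # 997.439
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(neutral_mass > 0)
  tab <- adduct_table()
  i <- match(adduct, tab$name)
  if (is.na(i)) i <- match(adduct, rownames(tab))
  if (is.na(i)) stop("unknown adduct: ", adduct, call. = FALSE)
  neutral_mass + tab$shift[i]
}

# aggregated isotope distributions per element, indexed by nominal mass
# offset 0,1,2,... (IUPAC abundances); pure heavy labels have no spread
.ISO_DIST <- list(
  C   = c(0.9893, 0.0107),
  C13 = 1,
  H   = c(0.999885, 0.000115),
  N   = c(0.99636, 0.00364),
  N15 = 1,
  O   = c(0.99757, 0.00038, 0.00205),
  S   = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

# truncated polynomial product: out[k] = sum_j a[j] b[k-j], length n
.conv_trunc <- function(a, b, n) {
  out <- numeric(n)
  for (j in seq_along(a)) {
    k <- j + seq_along(b) - 1L
    keep <- k <= n
    if (!any(keep)) break
    out[k[keep]] <- out[k[keep]] + a[j] * b[keep]
  }
  out
}

#' Isotopologue envelope of a composition
#'
#' Aggregated (unit-mass-spaced) isotope envelope obtained by convolving
#' the per-element isotope distributions. The first entry is the
#' monoisotopic peak; abundances are absolute probabilities and sum to at
#' most 1 (the remainder lies beyond `n_peaks`). Pure heavy-label atoms
#' (13C, 15N) contribute no spread.
#'
#' @param composition Named atom-count vector as returned by
#'   [elemental_composition()].
#' @param n_peaks Number of isotopologues to return (>= 2).
#' @return Data frame with `offset` (Da, multiples of 1.00335) and
#'   `abundance`.
#' @export
#' @examples
#' isotope_envelope(c(C = 1), n_peaks = 2)  # 0.9893, 0.0107
isotope_envelope <- function(composition, n_peaks = 5L) {
  if (n_peaks < 2L) stop("n_peaks must be >= 2", call. = FALSE)
  comp <- .comp0()
  comp[names(composition)] <- composition
  env <- c(1, numeric(n_peaks - 1L))
  for (el in .ELEMENTS) {
    cnt <- comp[[el]]
    if (cnt <= 0) next
    dist <- .ISO_DIST[[el]]
    if (length(dist) == 1L) next
    # per-element envelope for cnt atoms by binary exponentiation
    base <- c(dist, numeric(max(0L, n_peaks - length(dist))))[seq_len(n_peaks)]
    acc <- c(1, numeric(n_peaks - 1L))
    p <- base
    k <- cnt
    while (k > 0) {
      if (k %% 2 == 1) acc <- .conv_trunc(acc, p, n_peaks)
      k <- k %/% 2
      if (k > 0) p <- .conv_trunc(p, p, n_peaks)
    }
    env <- .conv_trunc(env, acc, n_peaks)
  }
  data.frame(offset = (seq_len(n_peaks) - 1) * .ISO_SPACING,
             abundance = env)
}
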