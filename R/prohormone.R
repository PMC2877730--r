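# Prohormone maturation model: signal peptidase, prohormone convertase
# (PC2-type cleavage C-terminal to a dibasic site), carboxypeptidase
# trimming of the exposed basic residues, and glycine-donor amidation with
# N-terminal pyroglutamate formation.

#' Annotate a prohormone precursor
#'
#' Describes how a preprohormone tiles into signal peptide, bioactive
#' peptide, dibasic linker, and C-terminal peptide. Spans are 1-based,
#' inclusive, must be contiguous, ordered, and tile the precursor.
#'
#' @param precursor Full precursor sequence (one-letter codes).
#' @param signal_end Last residue index of the signal peptide.
#' @param peptide Integer pair `c(start, end)` of the peptide span.
#' @param linker Integer pair of the linker span (e.g. the GKR positions).
#' @param cterm Integer pair of the C-terminal peptide span.
#' @return Object of class `prohormone_annotation`.
#' @export
#' @examples
#' prohormone_annotation("MKLQLTFSPDWGKRAPE", 3, c(4, 11), c(12, 14), c(15, 17))
prohormone_annotation <- function(precursor, signal_end, peptide, linker,
                                  cterm) {
  n <- nchar(precursor)
  spans <- rbind(c(1, signal_end), peptide, linker, cterm)
  if (any(spans[, 1] > spans[, 2]))
    stop("empty or reversed span", call. = FALSE)
  starts <- spans[-1, 1]
  ends <- spans[-nrow(spans), 2]
  if (!all(starts == ends + 1L) || spans[nrow(spans), 2] != n)
    stop("spans must be contiguous, ordered, and tile the precursor",
         call. = FALSE)
  structure(list(precursor = precursor, signal_end = as.integer(signal_end),
                 peptide = as.integer(peptide), linker = as.integer(linker),
                 cterm = as.integer(cterm)),
            class = "prohormone_annotation")
}

#' Enumerate prohormone processing intermediates
#'
#' Applies the maturation chain to an annotated precursor: (1) signal
#' peptidase removes the signal peptide, leaving the pro-peptide; (2) the
#' prohormone convertase cleaves C-terminal to the dibasic pair at the
#' linker end, releasing peptide+linker; (3) a carboxypeptidase removes the
#' exposed basic residues (K/R) one at a time; (4) when the trimmed peptide
#' ends in glycine, the glycine is consumed as amide donor and the mature
#' peptide is C-terminally amidated.
#'
#' An N-terminal glutamine cyclizes to pyroglutamate as soon as the
#' convertase exposes it, so every post-convertase intermediate (including
#' the Gly-Lys-extended form observed in tissue profiles) carries the
#' pyroglutamate modification.
#'
#' @param annotation A [prohormone_annotation()].
#' @return Ordered list of [peptide_species()]: pro-peptide, peptide+linker,
#'   one entry per carboxypeptidase trim, and the mature amidated peptide.
#' @export
#' @examples
#' ann <- prohormone_annotation("MKLQLTFSPDWGKRAPE", 3, c(4, 11), c(12, 14),
#'                              c(15, 17))
#' vapply(process_prohormone(ann), function(s) s$sequence, "")
process_prohormone <- function(annotation) {
  stopifnot(inherits(annotation, "prohormone_annotation"))
  a <- annotation
  linker_seq <- substr(a$precursor, a$linker[1], a$linker[2])
  last2 <- substring(linker_seq, nchar(linker_seq) - 1:0,
                     nchar(linker_seq) - 1:0)
  if (nchar(linker_seq) < 2L || !all(last2 %in% c("K", "R")))
    stop("no PC site: linker does not end in a dibasic pair", call. = FALSE)

  out <- list()
  propep <- substr(a$precursor, a$signal_end + 1L, nchar(a$precursor))
  out[[1]] <- peptide_species(paste0("pro-", propep), propep)

  has_q <- substr(a$precursor, a$peptide[1], a$peptide[1]) == "Q"
  pglu_mods <- if (has_q) list(mod_pyroglutamate()) else list()
  pre <- if (has_q) "pGlu-" else ""

  # PC cleavage C-terminal to the dibasic pair releases peptide+linker
  cur <- substr(a$precursor, a$peptide[1], a$linker[2])
  out[[length(out) + 1L]] <- peptide_species(paste0(pre, cur), cur,
                                             pglu_mods)

  # carboxypeptidase trims basic residues one at a time
  while (substr(cur, nchar(cur), nchar(cur)) %in% c("K", "R")) {
    cur <- substr(cur, 1L, nchar(cur) - 1L)
    out[[length(out) + 1L]] <- peptide_species(paste0(pre, cur), cur,
                                               pglu_mods)
  }

  # amidation consumes a C-terminal glycine as amide donor
  if (substr(cur, nchar(cur), nchar(cur)) == "G" && nchar(cur) > 1L) {
    mature <- substr(cur, 1L, nchar(cur) - 1L)
    out[[length(out) + 1L]] <-
      peptide_species(paste0(pre, mature, "-amide"), mature,
                      c(list(mod_amide()), pglu_mods))
  }
  out
}
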