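# Monoisotopic residue masses (Da), standard IUPAC values; water and the
# PTM deltas follow the PEAKS sign convention (amide -0.98, pyroGlu -17.03).
AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764, V = 99.068414,
  T = 101.047679, C = 103.009185, L = 113.084064, I = 113.084064,
  N = 114.042927, D = 115.026943, Q = 128.058578, K = 128.094963,
  E = 129.042593, M = 131.040485, H = 137.058912, F = 147.068414,
  R = 156.101111, Y = 163.063329, W = 186.079313)
WATER_MONO    <- 18.010565
AMIDE_DELTA   <- -0.984016
PYROGLU_DELTA <- -17.026549

#' Theoretical monoisotopic peptide mass
#'
#' Neutral monoisotopic mass: sum of residue masses plus water, plus
#' -0.984016 Da for C-terminal amidation and -17.026549 Da for N-terminal
#' pyroglutamate (cyclized Gln). Vectorised over sequences.
#'
#' @param sequence Peptide string(s), 20 standard residues.
#' @param amidated,pyroglu Logical flag(s), recycled.
#' @return Numeric mass(es) in Da.
#' @examples
#' mono_mass("EGDFTPRL", amidated = TRUE)            # 932.4716
#' mono_mass("QQPFVPRL", amidated = TRUE, pyroglu = TRUE)  # 965.5447
#' @export
mono_mass <- function(sequence, amidated = FALSE, pyroglu = FALSE) {
  n <- length(sequence)
  amidated <- rep_len(amidated, n)
  pyroglu <- rep_len(pyroglu, n)
  vapply(seq_len(n), function(i) {
    aa <- strsplit(sequence[i], "")[[1]]
    bad <- which(!aa %in% names(AA_MONO))
    if (length(bad))
      stop("unknown residue '", aa[bad[1]], "' in peptide '", sequence[i], "'")
    if (pyroglu[i] && aa[1] != "Q")
      stop("pyroglutamate requires an N-terminal Q: '", sequence[i], "'")
    sum(AA_MONO[aa]) + WATER_MONO +
      (if (amidated[i]) AMIDE_DELTA else 0) +
      (if (pyroglu[i]) PYROGLU_DELTA else 0)
  }, numeric(1))
}

#' Expand a peptide library with pyroglutamate variants
#'
#' For each peptide flagged as a potential pyroglutamate (N-terminal Q), add
#' a second row with `pyroglu = TRUE` so both forms take part in mass
#' matching.
#'
#' @param library `data.frame` with at least `sequence`, `amidated`,
#'   `pyroglu` columns (as produced by [annotate_precursor()]).
#' @return The expanded `data.frame`; the original rows get
#'   `pyroglu = FALSE`.
#' @export
expand_pyroglu <- function(library) {
  cand <- library[library$pyroglu, , drop = FALSE]
  library$pyroglu <- FALSE
  if (nrow(cand)) {
    cand$pyroglu <- TRUE
    library <- rbind(library, cand)
  }
  rownames(library) <- NULL
  library
}

#' Match observed masses against a theoretical peptide library
#'
#' Reports every (observed, peptide) pair whose relative mass error is
#' within `tol_ppm` parts per million; matches for each observed mass are
#' sorted by absolute ppm error. Unmatched observed masses are kept in the
#' `"unmatched"` attribute.
#'
#' @param observed Numeric vector of observed monoisotopic masses (Da), or a
#'   `data.frame` with columns `id` and `mass`.
#' @param library `data.frame` with columns `sequence`, `amidated`,
#'   `pyroglu` and optionally `peptide_id` (defaults to the sequence with
#'   modification suffixes).
#' @param tol_ppm Tolerance in ppm (default 15, a typical Orbitrap parent-ion
#'   window).
#' @return `data.frame` with `observed_id`, `observed`, `peptide_id`,
#'   `theoretical`, `error_ppm`.
#' @export
match_masses <- function(observed, library, tol_ppm = 15.0) {
  stopifnot(tol_ppm > 0)
  if (is.data.frame(observed)) {
    obs_id <- as.character(observed$id); obs <- observed$mass
  } else {
    obs <- as.numeric(observed)
    obs_id <- as.character(seq_along(obs))
  }
  if (is.null(library$peptide_id))
    library$peptide_id <- paste0(library$sequence,
                                 ifelse(library$pyroglu, " pyroQ", ""),
                                 ifelse(library$amidated, " amide", ""))
  theo <- mono_mass(library$sequence, library$amidated, library$pyroglu)
  rows <- list()
  unmatched <- character(0)
  for (i in seq_along(obs)) {
    ppm <- 1e6 * (obs[i] - theo) / theo
    hit <- which(abs(ppm) <= tol_ppm)
    if (!length(hit)) { unmatched <- c(unmatched, obs_id[i]); next }
    hit <- hit[order(abs(ppm[hit]))]
    rows[[length(rows) + 1L]] <- data.frame(
      observed_id = obs_id[i], observed = obs[i],
      peptide_id = library$peptide_id[hit], theoretical = theo[hit],
      error_ppm = ppm[hit], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(observed_id = character(0), observed = numeric(0),
               peptide_id = character(0), theoretical = numeric(0),
               error_ppm = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}

#' The published locust pyrokinin-family peptide table
#'
#' The LC-MS/MS-identified peptide set shipped with the package
#' (`inst/extdata/lom_peptides.tsv`): name, processed sequence, modification
#' flags, the published monoisotopic mass and, where given, the DH type.
#' Used by the golden mass tests and the worked examples.
#'
#' @return `data.frame` with columns `name`, `sequence`, `amidated`,
#'   `pyroglu`, `published_mass`, `type`.
#' @export
lom_peptides <- function() {
  path <- system.file("extdata", "lom_peptides.tsv", package = "dhmine",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
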