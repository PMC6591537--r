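#' Endoproteolytic cleavage rule set
#'
#' The rule set used to excise mature neuropeptides from a prohormone.
#' Defaults follow the sites observed in locust CAPA/PBAN/DH precursors:
#' cleavage at GR, GRR and KR, with AR explicitly excluded (a G-to-A mutation
#' at a GR site silences the peptide). A glycine immediately preceding a
#' cleavage site (or the G that begins a GR/GRR motif) is the amide donor for
#' C-terminal amidation.
#'
#' @param motifs Cleavage motifs, matched longest-first.
#' @param excluded Dibasic-like contexts that are never cleaved.
#' @param amide_donor Residue donating the C-terminal amide (removed from the
#'   mature peptide when it is the segment's final residue).
#' @param min_peptide_len Segments shorter than this (after amide-donor
#'   removal) are discarded as linker fragments.
#' @return Object of class `"cleavage_rules"`.
#' @export
cleavage_rules <- function(motifs = c("GRR", "GR", "KR"),
                           excluded = "AR",
                           amide_donor = "G",
                           min_peptide_len = 4L) {
  stopifnot(length(motifs) >= 1L, nchar(amide_donor) == 1L,
            min_peptide_len >= 1L)
  if (!all(substring(motifs, nchar(motifs)) %in% c("K", "R")))
    stop("every cleavage motif must end in a basic residue (K or R)")
  motifs <- motifs[order(-nchar(motifs), motifs)]  # longest-first
  structure(list(motifs = motifs, excluded = excluded,
                 amide_donor = amide_donor,
                 min_peptide_len = as.integer(min_peptide_len)),
            class = "cleavage_rules")
}

# Kyte-Doolittle hydropathy values
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)

#' Trim the signal peptide from a precursor
#'
#' Three modes are offered. `"heuristic"`: locate the maximal-scoring
#' Kyte-Doolittle window (width 9, mean hydropathy >= 1.6) within the first
#' 40 residues and cleave after the first A/G/S/C at or downstream of the
#' window end (small-residue signal-peptidase context). `"fixed"`: remove the
#' first `fixed_len` residues. `"none"`: no trimming. Externally computed
#' signal spans can be applied with `mode = "fixed"`.
#'
#' @param precursor Protein string.
#' @param mode One of `"heuristic"`, `"fixed"`, `"none"`.
#' @param fixed_len Signal length for `mode = "fixed"`.
#' @return List with `signal_span` (0-based half-open `c(start, end)` or
#'   `NULL`) and `mature` (the untrimmed remainder).
#' @export
trim_signal <- function(precursor, mode = c("heuristic", "fixed", "none"),
                        fixed_len = NULL) {
  mode <- match.arg(mode)
  n <- nchar(precursor)
  if (mode == "none")
    return(list(signal_span = NULL, mature = precursor))
  if (mode == "fixed") {
    stopifnot(!is.null(fixed_len), n > fixed_len)
    return(list(signal_span = c(0L, as.integer(fixed_len)),
                mature = substr(precursor, fixed_len + 1L, n)))
  }
  aa <- strsplit(precursor, "")[[1]]
  kd <- .KD[aa]
  kd[is.na(kd)] <- 0
  w <- 9L
  lim <- min(40L, n)
  if (lim < w) {
    warning("precursor too short for signal-peptide heuristic")
    return(list(signal_span = NULL, mature = precursor))
  }
  starts <- seq_len(lim - w + 1L)
  means <- vapply(starts, function(i) mean(kd[i:(i + w - 1L)]), numeric(1))
  best <- which.max(means)
  if (means[best] < 1.6) {
    warning("no hydrophobic window found; signal peptide not trimmed")
    return(list(signal_span = NULL, mature = precursor))
  }
  win_end <- best + w - 1L                 # last residue of window (1-based)
  search <- seq(win_end + 1L, min(n - 1L, 45L))
  hit <- search[aa[search] %in% c("A", "G", "S", "C")]
  if (!length(hit)) {
    warning("no small-residue cleavage context found; signal not trimmed")
    return(list(signal_span = NULL, mature = precursor))
  }
  cut <- hit[1]                            # cleave after this residue
  list(signal_span = c(0L, cut),
       mature = substr(precursor, cut + 1L, n))
}

#' Cleave a mature region into modified peptides
#'
#' Scans N-to-C, matching cleavage motifs longest-first and non-overlapping;
#' excluded contexts (default AR) are never cleaved. The segment between
#' consecutive sites becomes a peptide. A peptide is amidated when its final
#' residue is the amide donor (that G is removed from the sequence) or when
#' the following motif begins with G (GR/GRR donate their own G). A peptide
#' whose processed sequence starts with Q is flagged as a potential
#' N-terminal pyroglutamate (both forms are retained downstream for mass
#' matching). Segments shorter than `min_peptide_len` are discarded but
#' recorded.
#'
#' @param mature Protein string (signal peptide already removed).
#' @param rules A [cleavage_rules()] object.
#' @param offset 0-based offset of `mature` within the full precursor
#'   (i.e. the signal length), used for reported coordinates.
#' @param precursor_id Id recorded in the output.
#' @return `data.frame` of peptides with columns `precursor_id`, `index`,
#'   `start`, `end` (0-based half-open, covering the processed sequence),
#'   `sequence`, `amidated`, `pyroglu`. Attributes: `"cleavage_sites"`
#'   (`data.frame` of 0-based `position`, `motif`) and `"discarded"`
#'   (sub-threshold segments).
#' @export
cleave <- function(mature, rules = cleavage_rules(), offset = 0L,
                   precursor_id = "precursor") {
  stopifnot(inherits(rules, "cleavage_rules"))
  n <- nchar(mature)
  aa <- mature
  sites <- list(); segs <- list()
  i <- 1L; seg_start <- 1L
  while (i <= n) {
    matched <- FALSE
    for (m in rules$motifs) {
      len <- nchar(m)
      if (i + len - 1L > n) next
      if (substr(aa, i, i + len - 1L) != m) next
      excl <- FALSE
      for (x in rules$excluded) {
        xs <- i + len - nchar(x)
        if (xs >= 1L && substr(aa, xs, i + len - 1L) == x) excl <- TRUE
      }
      if (excl) next
      sites[[length(sites) + 1L]] <- list(position = i - 1L, motif = m)
      segs[[length(segs) + 1L]] <- list(start = seg_start, end = i - 1L,
                                        next_motif = m)
      seg_start <- i + len
      i <- i + len
      matched <- TRUE
      break
    }
    if (!matched) i <- i + 1L
  }
  segs[[length(segs) + 1L]] <- list(start = seg_start, end = n, next_motif = NA)

  peps <- list(); disc <- list()
  for (s in segs) {
    if (s$end < s$start) next
    raw <- substr(aa, s$start, s$end)
    amid <- FALSE
    seq <- raw
    if (!is.na(s$next_motif) && startsWith(s$next_motif, rules$amide_donor)) {
      amid <- TRUE
    } else if (nchar(raw) > 0 &&
               substring(raw, nchar(raw)) == rules$amide_donor) {
      amid <- TRUE
      seq <- substr(raw, 1L, nchar(raw) - 1L)
    }
    span <- c(offset + s$start - 1L, offset + s$start - 1L + nchar(seq))
    if (nchar(seq) < rules$min_peptide_len) {
      if (nchar(raw) > 0)
        disc[[length(disc) + 1L]] <- data.frame(
          sequence = raw, start = offset + s$start - 1L,
          end = offset + s$end, stringsAsFactors = FALSE)
      next
    }
    peps[[length(peps) + 1L]] <- data.frame(
      precursor_id = precursor_id, index = NA_integer_,
      start = span[1], end = span[2], sequence = seq,
      amidated = amid, pyroglu = startsWith(seq, "Q"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(peps)) do.call(rbind, peps) else
    data.frame(precursor_id = character(0), index = integer(0),
               start = integer(0), end = integer(0), sequence = character(0),
               amidated = logical(0), pyroglu = logical(0),
               stringsAsFactors = FALSE)
  if (nrow(out)) out$index <- seq_len(nrow(out))
  sites_df <- if (length(sites))
    data.frame(position = vapply(sites, `[[`, integer(1), "position") + offset,
               motif = vapply(sites, `[[`, character(1), "motif"),
               stringsAsFactors = FALSE)
  else data.frame(position = integer(0), motif = character(0))
  attr(out, "cleavage_sites") <- sites_df
  attr(out, "discarded") <- if (length(disc)) do.call(rbind, disc) else
    data.frame(sequence = character(0), start = integer(0), end = integer(0))
  rownames(out) <- NULL
  out
}

#' Annotate a precursor: signal trimming, cleavage, classification, mass
#'
#' Composition of [trim_signal()] and [cleave()], followed by C-terminal
#' classification ([classify_peptide()]) and theoretical monoisotopic mass
#' ([mono_mass()]) for every mature peptide.
#'
#' @param precursor Protein string.
#' @param precursor_id Id recorded in the output.
#' @param rules A [cleavage_rules()] object.
#' @param signal Signal-trimming mode, see [trim_signal()].
#' @param fixed_len Signal length when `signal = "fixed"`.
#' @param class_rules Classification rules, see [class_rules()].
#' @return Object of class `"precursor_annotation"`: list with
#'   `precursor_id`, `sequence`, `signal_span`, `cleavage_sites`, `peptides`
#'   (data.frame incl. `label` and `mono_mass`), `discarded`.
#' @export
annotate_precursor <- function(precursor, precursor_id = "precursor",
                               rules = cleavage_rules(),
                               signal = c("heuristic", "fixed", "none"),
                               fixed_len = NULL,
                               class_rules = dhmine::class_rules()) {
  signal <- match.arg(signal)
  tr <- trim_signal(precursor, mode = signal, fixed_len = fixed_len)
  offset <- if (is.null(tr$signal_span)) 0L else tr$signal_span[2]
  peps <- cleave(tr$mature, rules = rules, offset = offset,
                 precursor_id = precursor_id)
  if (nrow(peps)) {
    peps$label <- vapply(seq_len(nrow(peps)), function(i)
      classify_peptide(peps$sequence[i], amidated = peps$amidated[i],
                       rules = class_rules)$label, character(1))
    peps$mono_mass <- mono_mass(peps$sequence, amidated = peps$amidated)
  } else {
    peps$label <- character(0); peps$mono_mass <- numeric(0)
  }
  structure(list(precursor_id = precursor_id, sequence = precursor,
                 signal_span = tr$signal_span,
                 cleavage_sites = attr(peps, "cleavage_sites"),
                 peptides = peps,
                 discarded = attr(peps, "discarded")),
            class = "precursor_annotation")
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat("Precursor", x$precursor_id, "(", nchar(x$sequence), "aa )\n")
  if (!is.null(x$signal_span))
    cat("  signal peptide: [", x$signal_span[1], ",", x$signal_span[2], ")\n")
  cat("  cleavage sites:", nrow(x$cleavage_sites), "   peptides:",
      nrow(x$peptides), "\n")
  if (nrow(x$peptides)) {
    p <- x$peptides
    cat(sprintf("  %2d. %-35s %-8s %9.4f Da%s%s\n", p$index,
                p$sequence, p$label, p$mono_mass,
                ifelse(p$amidated, " amide", ""),
                ifelse(p$pyroglu, " pyroQ?", "")), sep = "")
  }
  invisible(x)
}
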