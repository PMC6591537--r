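#' Optimal local protein alignment
#'
#' Smith-Waterman local alignment with affine gaps, scored with a standard
#' substitution matrix (BLOSUM62 by default, gap open 11 / extend 1, the
#' common protein-BLAST defaults). A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param query,subject Protein strings (may contain `*` from six-frame
#'   translation; `*` is scored by the matrix).
#' @param matrix Substitution matrix name (any matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`).
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return `NULL` when the optimal score is not positive, otherwise a one-row
#'   `data.frame` with `score`, `aligned_aa` (alignment columns),
#'   `identity_fraction`, `query_start`, `query_end`, `subject_start`,
#'   `subject_end` (1-based inclusive residue coordinates).
#' @export
local_align <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(query), nzchar(subject))
  mat <- .get_submat(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0) return(NULL)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  cols <- nchar(as.character(pat))
  data.frame(
    score = sc,
    aligned_aa = cols,
    identity_fraction = Biostrings::nmatch(aln) / cols,
    query_start = BiocGenerics::start(pat),
    query_end = BiocGenerics::end(pat),
    subject_start = BiocGenerics::start(sub),
    subject_end = BiocGenerics::end(sub),
    stringsAsFactors = FALSE)
}

# substitution-matrix cache (data() lookup is slow inside screening loops)
.submat_cache <- new.env(parent = emptyenv())
.get_submat <- function(name) {
  if (!exists(name, envir = .submat_cache, inherits = FALSE)) {
    ok <- tryCatch({
      e <- new.env()
      utils::data(list = name, package = "Biostrings", envir = e)
      assign(name, get(name, envir = e), envir = .submat_cache)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok) stop("unknown substitution matrix: ", name)
  }
  get(name, envir = .submat_cache, inherits = FALSE)
}

#' Screen contigs for neuropeptide-precursor candidates and motif targets
#'
#' Reproduces the two-tier genome-mining funnel: each contig is translated in
#' all six frames and locally aligned against every query precursor. A contig
#' is a *candidate* when its best alignment covers at least `min_aligned_nt`
#' nucleotides (3 x aligned amino-acid columns); it is additionally a
#' *target* when the conserved C-terminal motif (default `FGPR[VIY]`, the
#' CAPA/PBAN FGPRV/I/Y core) occurs in any frame.
#'
#' @param queries Named character vector of query precursor proteins.
#' @param contigs Named character vector of nucleotide contigs.
#' @param min_aligned_nt Candidate threshold in aligned nucleotides
#'   (default 100, i.e. >= 34 aligned residues).
#' @param min_score Raw-score reporting floor (default 50). Length alone
#'   does not separate homology from chance at desk scale: spurious local
#'   alignments of >= 34 columns against random translations score below
#'   ~35 with BLOSUM62 while genuine precursor homology scores in the
#'   hundreds, so the floor only suppresses chance hits.
#' @param motif Regular expression for the conserved motif.
#' @param matrix,gap_open,gap_extend Passed to [local_align()].
#' @return `data.frame` with one row per candidate contig: `contig_id`,
#'   `tier` (`"candidate"` or `"target"`), `best_score`, `best_query`,
#'   `aligned_aa`, `n_motif`, `motif_positions`
#'   (`"frame:aa_position:text"`, `;`-separated). Contigs with no qualifying
#'   alignment are absent.
#' @export
screen_contigs <- function(queries, contigs, min_aligned_nt = 100,
                           min_score = 50, motif = "FGPR[VIY]",
                           matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  stopifnot(length(queries) > 0)
  min_aa <- ceiling(min_aligned_nt / 3)
  rows <- list()
  for (cid in names(contigs)) {
    frames <- six_frame(contigs[[cid]])
    best <- NULL
    for (qid in names(queries)) {
      for (f in names(frames)) {
        if (!nzchar(frames[[f]])) next
        hit <- local_align(queries[[qid]], frames[[f]], matrix = matrix,
                           gap_open = gap_open, gap_extend = gap_extend)
        if (is.null(hit)) next
        if (hit$aligned_aa < min_aa || hit$score < min_score) next
        if (is.null(best) || hit$score > best$score) {
          best <- hit; best$query <- qid
        }
      }
    }
    if (is.null(best)) next
    mm <- character(0)
    for (f in names(frames)) {
      m <- gregexpr(motif, frames[[f]], perl = TRUE)[[1]]
      if (m[1] != -1) {
        txt <- regmatches(frames[[f]], gregexpr(motif, frames[[f]], perl = TRUE))[[1]]
        mm <- c(mm, sprintf("%s:%d:%s", f, as.integer(m), txt))
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = cid,
      tier = if (length(mm)) "target" else "candidate",
      best_score = best$score, best_query = best$query,
      aligned_aa = best$aligned_aa,
      n_motif = length(mm),
      motif_positions = paste(mm, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(contig_id = character(0), tier = character(0),
                      best_score = numeric(0), best_query = character(0),
                      aligned_aa = integer(0), n_motif = integer(0),
                      motif_positions = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
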