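#' @importFrom Biostrings readBStringSet BStringSet writeXStringSet
#' @importFrom stats rnorm runif rbinom setNames sd aov
#' @importFrom utils read.delim write.table read.csv
NULL

# residue alphabets; "*" is a translation artifact only
NUC_ALPHABET  <- c("A", "C", "G", "T", "N")
PROT_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*")
AA20 <- setdiff(PROT_ALPHABET, c("X", "*"))

#' Read a FASTA file
#'
#' Reads nucleotide or protein FASTA into a named character vector, enforcing
#' the residue alphabet. `N` is tolerated in nucleotide records (with a
#' warning); `X` and `*` are tolerated in protein records.
#'
#' @param path Path to a FASTA file.
#' @param type `"nuc"`, `"prot"`, or `"auto"` (guess from residue content).
#' @return Named character vector of upper-case residues, one element per
#'   record, in file order. Full header lines are kept in the
#'   `"descriptions"` attribute.
#' @export
read_fasta <- function(path, type = c("auto", "nuc", "prot")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  descs <- names(set)
  ids <- sub("\\s.*$", "", descs)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (type == "auto") {
    pooled <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    type <- if (all(pooled %in% NUC_ALPHABET)) "nuc" else "prot"
  }
  alpha <- if (type == "nuc") NUC_ALPHABET else PROT_ALPHABET
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) stop("empty sequence in record '", ids[i], "'")
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!chars %in% alpha)
    if (length(bad))
      stop("illegal residue '", chars[bad[1]], "' at position ", bad[1],
           " in record '", ids[i], "'")
    if (type == "nuc" && any(chars == "N"))
      warning("record '", ids[i], "' contains N")
  }
  attr(seqs, "descriptions") <- descs
  attr(seqs, "type") <- type
  seqs
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in residues.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' @param nuc Nucleotide string over A/C/G/T/N.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(nuc) {
  vapply(nuc, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# codon -> amino acid lookup from the standard genetic code (table 1)
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

#' Translate one reading frame
#'
#' Standard genetic code (table 1). Frames are numbered +1/+2/+3 on the given
#' strand and -1/-2/-3 on its reverse complement. A trailing partial codon is
#' dropped; stop codons become `*`; codons containing `N` become `X`.
#'
#' @param nuc Nucleotide string.
#' @param frame Integer in `c(1, 2, 3, -1, -2, -3)`.
#' @return Protein string (possibly empty).
#' @export
translate_frame <- function(nuc, frame = 1L) {
  stopifnot(length(frame) == 1L, abs(frame) %in% 1:3)
  s <- if (frame < 0) reverse_complement(nuc) else nuc
  off <- abs(frame) - 1L
  n <- nchar(s) - off
  n_codons <- n %/% 3L
  if (n_codons <= 0L) return("")
  starts <- off + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"  # codon contains N or other ambiguity
  paste(aa, collapse = "")
}

#' Six-frame translation
#'
#' @param nuc Nucleotide string.
#' @return Character vector of 6 proteins named `"+1","+2","+3","-1","-2","-3"`.
#' @export
six_frame <- function(nuc) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  out <- vapply(frames, function(f) translate_frame(nuc, f), character(1))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Find open reading frames
#'
#' An ORF is an ATG...stop span in any of the six frames with a protein of at
#' least `min_aa` residues (initiator Met included, stop excluded). For each
#' stop codon only the longest ORF (left-most in-frame ATG) is reported.
#' Coordinates are 0-based half-open on the forward strand and include the
#' stop codon; minus-strand ORFs are mapped back to forward coordinates with
#' `frame < 0`.
#'
#' @param nuc Nucleotide string (one contig).
#' @param min_aa Minimum protein length in residues (>= 1).
#' @param contig_id Id recorded in the output.
#' @return `data.frame` with columns `contig_id`, `frame`, `start`, `end`,
#'   `length_aa`, `protein`, sorted by `length_aa` descending.
#' @export
find_orfs <- function(nuc, min_aa = 30L, contig_id = "contig") {
  stopifnot(min_aa >= 1L)
  L <- nchar(nuc)
  rows <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    prot <- translate_frame(nuc, frame)
    if (!nzchar(prot)) next
    aa <- strsplit(prot, "")[[1]]
    stops <- which(aa == "*")
    starts <- which(aa == "M")
    if (!length(stops) || !length(starts)) next
    used_stop <- integer(0)
    for (st in starts) {
      nx <- stops[stops > st]
      if (!length(nx)) next
      stp <- nx[1]
      if (stp %in% used_stop) next  # keep longest ORF per stop only
      used_stop <- c(used_stop, stp)
      len_aa <- stp - st
      if (len_aa < min_aa) next
      # aa positions st..stp (1-based) -> nucleotide span on translated strand
      off <- abs(frame) - 1L
      nt_start <- off + 3L * (st - 1L)       # 0-based
      nt_end <- off + 3L * stp               # includes stop codon
      if (frame > 0) {
        fs <- nt_start; fe <- nt_end
      } else {
        fs <- L - nt_end; fe <- L - nt_start
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = contig_id, frame = frame, start = fs, end = fe,
        length_aa = len_aa,
        protein = substr(prot, st, stp - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(contig_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      length_aa = integer(0), protein = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$length_aa, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write ORFs as a BED6-like TSV
#'
#' Columns: contig, start, end, id, length_aa, strand.
#'
#' @param orfs Output of [find_orfs()].
#' @param path Output path.
#' @export
write_orf_bed <- function(orfs, path) {
  bed <- data.frame(
    contig = orfs$contig_id, start = orfs$start, end = orfs$end,
    id = sprintf("orf%03d", seq_len(nrow(orfs))),
    length_aa = orfs$length_aa,
    strand = ifelse(orfs$frame > 0, "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
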