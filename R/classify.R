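#' C-terminal classification rules
#'
#' Ordered, C-terminally anchored patterns assigning a mature (amidated)
#' peptide to a pyrokinin-family class. The five DH types are the locust
#' consensus classes (I: LWFGPRXa with X in V/I/Y/P/F; II: MWFGPRVa;
#' III: TWFGPRIa; IV: TWFGARIa; V: VWFGARIa). Generic pyrokinin (FXPRLa),
#' periviscerokinin (F(X)PRVa) and a PRXamide-like fallback follow, most
#' specific first; the amidated sequence is matched *without* a trailing "a"
#' marker (the amidation flag carries that information).
#'
#' @param labels,patterns,priorities Optional replacement rule set; patterns
#'   must be anchored (`$`) and priorities unique.
#' @return `data.frame` with columns `label`, `pattern`, `priority`,
#'   ordered by priority.
#' @export
class_rules <- function(labels = NULL, patterns = NULL, priorities = NULL) {
  if (is.null(labels)) {
    df <- data.frame(
      label = c("DH-I", "DH-II", "DH-III", "DH-IV", "DH-V",
                "PK", "PVK", "PK-like"),
      pattern = c("LWFGPR[VIYPF]$", "MWFGPRV$", "TWFGPRI$", "TWFGARI$",
                  "VWFGARI$", "F.?PRL$", "F.?PR[VI]$", "[AP]R[LVI]$"),
      priority = 1:8,
      stringsAsFactors = FALSE)
  } else {
    stopifnot(length(labels) == length(patterns),
              length(labels) == length(priorities),
              !anyDuplicated(priorities))
    if (!all(endsWith(patterns, "$")))
      stop("classification patterns must be anchored at the C-terminus ('$')")
    df <- data.frame(label = labels, pattern = patterns,
                     priority = priorities, stringsAsFactors = FALSE)
  }
  df[order(df$priority), , drop = FALSE]
}

#' Classify one mature peptide by its C-terminus
#'
#' The first matching rule (lowest priority number) wins; classification is
#' deterministic and total, with `"unclassified"` when nothing matches.
#'
#' @param sequence Processed peptide sequence (amide-donor G removed).
#' @param amidated Logical; non-amidated peptides are classified on sequence
#'   alone with a warning.
#' @param rules A [class_rules()] data.frame.
#' @return List with `label` and `matched_pattern` (`NA` if unclassified).
#' @export
classify_peptide <- function(sequence, amidated = TRUE, rules = class_rules()) {
  if (!isTRUE(amidated))
    warning("classifying non-amidated peptide '", sequence,
            "' on sequence alone")
  for (i in seq_len(nrow(rules))) {
    if (grepl(rules$pattern[i], sequence, perl = TRUE))
      return(list(label = rules$label[i], matched_pattern = rules$pattern[i]))
  }
  list(label = "unclassified", matched_pattern = NA_character_)
}

#' Count DH-like peptides by type
#'
#' Tabulates DH type labels (I-V) among classified peptides; non-DH labels
#' are ignored.
#'
#' @param labels Character vector of class labels (e.g. from
#'   [annotate_precursor()] output).
#' @return Named integer vector over the DH types present (names
#'   `"I".."V"`); empty input gives an empty vector.
#' @export
count_types <- function(labels) {
  dh <- labels[grepl("^DH-", labels)]
  if (!length(dh)) return(stats::setNames(integer(0), character(0)))
  roman <- sub("^DH-", "", dh)
  tab <- table(factor(roman, levels = c("I", "II", "III", "IV", "V")))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0]
}

#' Find maximal tandem repeats in a label sequence
#'
#' Exhaustive scan over block lengths 1..floor(n/2). A call is reported when
#' a primitive block (one that is not itself a tandem repeat) occurs in >= 2
#' immediately adjacent copies, the run is not extendable by a further full
#' copy on either side, and the copy count is maximal.
#'
#' @param labels Character vector of ordered cassette labels.
#' @return `data.frame` with columns `start`, `end` (1-based inclusive
#'   positions of the whole run), `block` (comma-collapsed), `block_len`,
#'   `copies`.
#' @export
find_tandem_repeats <- function(labels) {
  n <- length(labels)
  out <- list()
  if (n >= 2L) {
    for (L in seq_len(n %/% 2L)) {
      i <- 1L
      while (i + 2L * L - 1L <= n) {
        block <- labels[i:(i + L - 1L)]
        if (.primitive_block(block)) {
          k <- 1L
          while (i + (k + 1L) * L - 1L <= n &&
                 identical(labels[(i + k * L):(i + (k + 1L) * L - 1L)], block))
            k <- k + 1L
          left_ext <- i - L >= 1L &&
            identical(labels[(i - L):(i - 1L)], block)
          if (k >= 2L && !left_ext) {
            out[[length(out) + 1L]] <- data.frame(
              start = i, end = i + k * L - 1L,
              block = paste(block, collapse = ","),
              block_len = L, copies = k, stringsAsFactors = FALSE)
          }
        }
        i <- i + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      block = character(0), block_len = integer(0),
                      copies = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$block_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# a block is primitive when it is not k>=2 copies of a shorter block
.primitive_block <- function(block) {
  L <- length(block)
  if (L == 1L) return(TRUE)
  for (d in seq_len(L %/% 2L)) {
    if (L %% d != 0L) next
    if (all(vapply(seq_len(L / d - 1L), function(k)
      identical(block[(k * d + 1L):((k + 1L) * d)], block[1:d]), logical(1))))
      return(FALSE)
  }
  TRUE
}

#' C-terminal sequence logo statistics
#'
#' Per-column residue frequencies, information content and consensus over the
#' `k` C-terminal residues of a peptide set. Peptides shorter than `k` are
#' left-padded with gaps; gaps are excluded from the frequencies.
#' Information content is `log2(20) - H` where `H` is the Shannon entropy of
#' the column (bits).
#'
#' @param peptides Character vector of peptide sequences.
#' @param k Number of C-terminal positions (default 13).
#' @return Object of class `"cterm_logo"`: list with `freq` (20 x k matrix,
#'   columns named `-k..-1` from the C-terminus), `ic` (length-k vector of
#'   bits), `consensus` (string of modal residues, `"-"` for all-gap
#'   columns).
#' @export
cterm_logo <- function(peptides, k = 13L) {
  stopifnot(length(peptides) >= 1L)
  tails <- vapply(peptides, function(s) {
    n <- nchar(s)
    if (n >= k) substr(s, n - k + 1L, n) else
      paste0(strrep("-", k - n), s)
  }, character(1), USE.NAMES = FALSE)
  mat <- do.call(rbind, strsplit(tails, ""))
  freq <- matrix(0, nrow = 20L, ncol = k,
                 dimnames = list(AA20, as.character(seq(-k, -1L))))
  ic <- numeric(k); cons <- character(k)
  for (j in seq_len(k)) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (!length(col)) { ic[j] <- 0; cons[j] <- "-"; next }
    tab <- table(factor(col, levels = AA20))
    p <- as.numeric(tab) / sum(tab)
    freq[, j] <- p
    h <- -sum(p[p > 0] * log2(p[p > 0]))
    ic[j] <- log2(20) - h
    cons[j] <- AA20[which.max(p)]
  }
  structure(list(freq = freq, ic = ic,
                 consensus = paste(cons, collapse = "")),
            class = "cterm_logo")
}

#' @export
print.cterm_logo <- function(x, ...) {
  cat("C-terminal logo over", ncol(x$freq), "positions\n")
  cat("  consensus:", x$consensus, "\n")
  cat("  IC (bits):", paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' Write logo statistics as TSV
#'
#' Columns: position, the 20 residue frequencies, IC, consensus residue.
#'
#' @param logo A [cterm_logo()] object.
#' @param path Output path.
#' @export
write_logo_tsv <- function(logo, path) {
  df <- data.frame(position = colnames(logo$freq), t(logo$freq),
                   IC = logo$ic,
                   consensus = strsplit(logo$consensus, "")[[1]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
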