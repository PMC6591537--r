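# synonymous codon families from the standard genetic code
.codon_info <- local({
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- as.character(gc)
  fam_size <- table(aa)
  list(codons = codons, aa = stats::setNames(aa, codons),
       stops = codons[aa == "*"],
       # degenerate, index-informative codons: exclude Met, Trp and stops
       informative = codons[!aa %in% c("*", "M", "W")])
})

# count codons of one CDS; errors name the gene
.count_codons <- function(cds, gene_id = "cds") {
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length of '", gene_id, "' is not divisible by 3")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  if (any(codons[-length(codons)] %in% .codon_info$stops))
    stop("internal stop codon in '", gene_id, "'")
  # a terminal stop is tolerated and dropped
  if (codons[length(codons)] %in% .codon_info$stops)
    codons <- codons[-length(codons)]
  table(factor(codons, levels = .codon_info$codons))
}

#' Build a codon-usage reference set
#'
#' Pools codon counts across a reference gene set (e.g. highly expressed
#' housekeeping genes such as actin/gapdh/ef) and derives, per synonymous
#' family, the relative adaptiveness `w = f_codon / max f among synonyms`
#' and the optimal codon(s) (maximal frequency). Codons never observed are
#' given a 0.5 pseudo-count before `w` is computed (the CodonW convention,
#' avoiding `log 0` in CAI).
#'
#' @param cds_set Named character vector of CDS nucleotide sequences
#'   (length divisible by 3, no internal stops; a terminal stop is allowed).
#' @return Object of class `"codon_ref"`: list with `counts` (64 codons),
#'   `w` (relative adaptiveness, informative codons), `optimal`
#'   (character vector of optimal codons).
#' @export
build_reference <- function(cds_set) {
  stopifnot(length(cds_set) >= 1L)
  ids <- if (is.null(names(cds_set))) as.character(seq_along(cds_set)) else
    names(cds_set)
  counts <- Reduce(`+`, lapply(seq_along(cds_set), function(i)
    .count_codons(cds_set[[i]], ids[i])))
  counts <- as.numeric(counts)
  names(counts) <- .codon_info$codons
  adj <- counts
  adj[.codon_info$informative][adj[.codon_info$informative] == 0] <- 0.5
  w <- numeric(0); optimal <- character(0)
  for (a in setdiff(unique(.codon_info$aa), c("*", "M", "W"))) {
    fam <- names(.codon_info$aa)[.codon_info$aa == a]
    fw <- adj[fam] / max(adj[fam])
    w <- c(w, fw)
    optimal <- c(optimal, fam[counts[fam] == max(counts[fam])])
  }
  structure(list(counts = counts, w = w, optimal = optimal),
            class = "codon_ref")
}

#' Codon Adaptation Index (CAI)
#'
#' Geometric mean of the relative adaptiveness `w` over the synonymously
#' informative codons of a gene (Met, Trp and stops excluded).
#'
#' @param cds CDS nucleotide string.
#' @param ref A [build_reference()] object.
#' @param gene_id Used in error messages.
#' @return CAI in (0, 1].
#' @export
cai <- function(cds, ref, gene_id = "cds") {
  stopifnot(inherits(ref, "codon_ref"))
  counts <- .count_codons(cds, gene_id)
  counts <- counts[.codon_info$informative]
  n <- sum(counts)
  if (n == 0) { warning("no informative codons in '", gene_id, "'"); return(NA_real_) }
  exp(sum(counts * log(ref$w[names(counts)])) / n)
}

#' Frequency of optimal codons (FOP) and Codon Bias Index (CBI)
#'
#' `FOP = N_opt / N_syn` over degenerate amino acids;
#' `CBI = (N_opt - N_exp) / (N_syn - N_exp)` where `N_exp` is the expected
#' optimal count under uniform synonym usage (`sum n_aa / k_aa`).
#'
#' @inheritParams cai
#' @return A single numeric value.
#' @export
fop <- function(cds, ref, gene_id = "cds") {
  st <- .opt_stats(cds, ref, gene_id)
  if (st$n_syn == 0) return(NA_real_)
  st$n_opt / st$n_syn
}

#' @rdname fop
#' @export
cbi <- function(cds, ref, gene_id = "cds") {
  st <- .opt_stats(cds, ref, gene_id)
  if (st$n_syn == 0 || st$n_syn == st$n_exp) return(NA_real_)
  (st$n_opt - st$n_exp) / (st$n_syn - st$n_exp)
}

.opt_stats <- function(cds, ref, gene_id) {
  stopifnot(inherits(ref, "codon_ref"))
  counts <- .count_codons(cds, gene_id)
  counts <- counts[.codon_info$informative]
  n_syn <- sum(counts)
  n_opt <- sum(counts[names(counts) %in% ref$optimal])
  n_exp <- 0
  for (a in setdiff(unique(.codon_info$aa), c("*", "M", "W"))) {
    fam <- names(.codon_info$aa)[.codon_info$aa == a]
    n_aa <- sum(counts[fam])
    k_opt <- sum(fam %in% ref$optimal)
    n_exp <- n_exp + n_aa * k_opt / length(fam)
  }
  list(n_syn = n_syn, n_opt = n_opt, n_exp = n_exp)
}

#' GC content at synonymous third positions (GC3s)
#'
#' Fraction of G or C at the third codon position among codons of
#' synonymously degenerate amino acids (Met, Trp and stops excluded).
#'
#' @inheritParams cai
#' @return GC3s in `[0, 1]`, or `NA` with a warning when the gene has no
#'   synonymous sites.
#' @export
gc3s <- function(cds, gene_id = "cds") {
  counts <- .count_codons(cds, gene_id)
  counts <- counts[.codon_info$informative]
  n <- sum(counts)
  if (n == 0) {
    warning("no synonymous third positions in '", gene_id, "'")
    return(NA_real_)
  }
  third <- substring(names(counts), 3L, 3L)
  sum(counts[third %in% c("G", "C")]) / n
}

#' Codon-bias indices for a gene set
#'
#' Computes CAI, CBI, FOP and GC3s for each gene against a reference
#' codon-usage set, the index panel used to discriminate gene families by
#' synonymous-codon preference.
#'
#' @param cds_set Named character vector of CDS sequences.
#' @param ref A [build_reference()] object.
#' @return `data.frame` with columns `gene_id`, `CAI`, `CBI`, `FOP`,
#'   `GC3s`, `n_codons` (informative codons used).
#' @export
codon_bias <- function(cds_set, ref) {
  ids <- if (is.null(names(cds_set))) as.character(seq_along(cds_set)) else
    names(cds_set)
  rows <- lapply(seq_along(cds_set), function(i) {
    counts <- .count_codons(cds_set[[i]], ids[i])
    data.frame(gene_id = ids[i],
               CAI = cai(cds_set[[i]], ref, ids[i]),
               CBI = cbi(cds_set[[i]], ref, ids[i]),
               FOP = fop(cds_set[[i]], ref, ids[i]),
               GC3s = gc3s(cds_set[[i]], ids[i]),
               n_codons = sum(counts[.codon_info$informative]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
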