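# Generators emulating the inputs of a CAPA/PBAN/DH precursor study: every
# generator is a pure function of its arguments and seed, and returns the
# data together with machine-readable ground truth.

# residues allowed in random cassette prefixes / linkers: R is excluded so
# no spurious GR/KR/GRR cleavage context can arise by chance
.PREFIX_AA <- c("A", "D", "E", "F", "H", "I", "L", "M", "N", "P", "Q",
                "S", "T", "V", "W", "Y", "G")

# C-terminal class motifs planted by the generator
.TYPE_MOTIFS <- list(
  "DH-I"   = function() paste0("LWFGPR", sample(c("V", "I", "Y", "P", "F"), 1)),
  "DH-II"  = function() "MWFGPRV",
  "DH-III" = function() "TWFGPRI",
  "DH-IV"  = function() "TWFGARI",
  "DH-V"   = function() "VWFGARI",
  "PK"     = function() paste0("F", sample(setdiff(.PREFIX_AA, "G"), 1), "PRL"))

#' Generate synthetic neuropeptide precursors with ground truth
#'
#' Each precursor is `signal + [cassette + cleavage motif] x n`: an
#' N-terminal signal peptide (Met + hydrophobic core + small-residue
#' cleavage context), followed by peptide cassettes, each a random prefix
#' ending in a planted C-terminal class motif, delimited by endoproteolytic
#' sites. Sites are drawn from GKR-style (amide-donor G + KR), GRR and GR,
#' all of which amidate the upstream peptide. Cassette counts up to the
#' largest observed in real DH precursors (14) are supported.
#'
#' @param n Number of precursors.
#' @param n_cassettes Cassettes per precursor (recycled).
#' @param type_mix Named probability vector over
#'   `names(.TYPE_MOTIFS)`-style labels (default: the five DH types,
#'   type-I-heavy as in real DH genes).
#' @param motif_mix Named probability vector over `c("GKR", "GRR", "GR")`.
#' @param signal_len Range (length-2) of signal-peptide lengths.
#' @param prefix_len Range of cassette-prefix lengths.
#' @param cassette_labels Optional list (length `n`) of explicit per-
#'   precursor label vectors, overriding `n_cassettes`/`type_mix` (used to
#'   plant tandem-repeat blocks).
#' @param seed Mandatory integer seed.
#' @return List with `fasta` (named character vector of precursor proteins)
#'   and `truth` (list per precursor: `signal_span`, `peptides` data.frame
#'   with `start`, `end`, `sequence`, `amidated`, `pyroglu`, `label`).
#' @export
gen_precursors <- function(n, n_cassettes = 5L,
                           type_mix = c("DH-I" = 0.6, "DH-II" = 0.16,
                                        "DH-III" = 0.07, "DH-IV" = 0.1,
                                        "DH-V" = 0.07),
                           motif_mix = c(GKR = 1 / 3, GRR = 1 / 3, GR = 1 / 3),
                           signal_len = c(13L, 22L), prefix_len = c(2L, 8L),
                           cassette_labels = NULL, seed) {
  stopifnot(!missing(seed), abs(sum(type_mix) - 1) < 1e-8,
            abs(sum(motif_mix) - 1) < 1e-8)
  set.seed(seed)
  n_cassettes <- rep_len(n_cassettes, n)
  fasta <- character(n)
  truth <- vector("list", n)
  ids <- sprintf("prec%03d", seq_len(n))
  for (i in seq_len(n)) {
    s_len <- sample(signal_len[1]:signal_len[2], 1)
    signal <- paste0("M",
                     paste(sample(c("L", "V", "I", "F"), s_len - 2L,
                                  replace = TRUE), collapse = ""),
                     "A")
    labels <- if (!is.null(cassette_labels)) cassette_labels[[i]] else
      sample(names(type_mix), n_cassettes[i], replace = TRUE, prob = type_mix)
    pos <- s_len                       # 0-based end of what is built so far
    parts <- signal
    peps <- list()
    for (lab in labels) {
      pre_len <- sample(prefix_len[1]:prefix_len[2], 1)
      prefix <- paste(sample(.PREFIX_AA, pre_len, replace = TRUE),
                      collapse = "")
      cassette <- paste0(prefix, .TYPE_MOTIFS[[lab]]())
      site <- sample(names(motif_mix), 1, prob = motif_mix)
      emitted <- switch(site, GKR = paste0(cassette, "G", "KR"),
                        GRR = paste0(cassette, "GRR"),
                        GR = paste0(cassette, "GR"))
      peps[[length(peps) + 1L]] <- data.frame(
        start = pos, end = pos + nchar(cassette), sequence = cassette,
        amidated = TRUE, pyroglu = startsWith(cassette, "Q"),
        label = lab, stringsAsFactors = FALSE)
      parts <- c(parts, emitted)
      pos <- pos + nchar(emitted)
    }
    fasta[i] <- paste(parts, collapse = "")
    truth[[i]] <- list(precursor_id = ids[i],
                       signal_span = c(0L, s_len),
                       peptides = do.call(rbind, peps))
  }
  names(fasta) <- ids
  list(fasta = fasta, truth = stats::setNames(truth, ids))
}

#' Synthetic stand-in for the five locust DH precursor genes
#'
#' A deterministic, clearly synthetic surrogate for the five deposited
#' DH-precursor sequences (which this package does not download): five
#' generated precursors carrying the published per-gene cassette counts
#' (5, 8, 11, 6 and 14) and the published type totals over all 44 DH-like
#' peptides (27 type I, 7 type II, 3 type III, 4 type IV, 3 type V). The
#' sequences themselves are simulated; only the architecture matches the
#' published genes.
#'
#' @param seed Integer seed (the architecture is seed-independent; the seed
#'   fixes prefixes and site choices).
#' @return As [gen_precursors()], with precursors named `sdh1..sdh5`.
#' @export
synthetic_lomdh_bundle <- function(seed = 101L) {
  layouts <- list(
    sdh1 = rep("DH-I", 5),
    sdh2 = c(rep("DH-I", 4), rep("DH-II", 2), "DH-IV", "DH-V"),
    sdh3 = c(rep("DH-I", 7), rep("DH-II", 2), "DH-III", "DH-IV"),
    sdh4 = c(rep("DH-I", 4), "DH-III", "DH-IV"),
    sdh5 = c(rep("DH-I", 7), rep("DH-II", 3), "DH-III", "DH-IV",
             rep("DH-V", 2)))
  out <- gen_precursors(n = 5L, cassette_labels = unname(layouts), seed = seed)
  names(out$fasta) <- names(layouts)
  names(out$truth) <- names(layouts)
  for (i in seq_along(out$truth)) out$truth[[i]]$precursor_id <- names(layouts)[i]
  out
}

# uniform synonymous back-translation of one protein
.back_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  aa2codons <- split(names(gc), as.character(gc))
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- aa2codons[[a]]
    if (is.null(cods)) stop("cannot back-translate residue '", a, "'")
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

#' Generate a synthetic genome with embedded precursor genes
#'
#' Back-translates each precursor protein (uniform synonymous codon choice),
#' embeds it at a random position and strand inside a random-nucleotide
#' contig, and optionally adds decoy contigs in which every conserved
#' FGPR[VIY] core has been knocked out (terminal residue mutated to Q), so
#' that decoys remain alignable candidates but are no longer motif targets.
#'
#' @param precursors Named character vector of precursor proteins.
#' @param contig_len Total length of each contig (>= 3 x protein length + 60).
#' @param n_decoys Number of decoy contigs (cycled over the precursors).
#' @param seed Mandatory integer seed.
#' @return List with `contigs` (named character vector) and `truth`
#'   (`data.frame`: `contig_id`, `precursor_id`, `start`, `end`, `strand`,
#'   `is_decoy`; 0-based half-open coordinates of the embedded CDS on the
#'   forward strand).
#' @export
gen_genome <- function(precursors, contig_len = 2000L, n_decoys = 0L, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  specs <- data.frame(precursor_id = names(precursors),
                      protein = unname(precursors),
                      is_decoy = FALSE, stringsAsFactors = FALSE)
  if (n_decoys > 0L) {
    idx <- rep_len(seq_along(precursors), n_decoys)
    dec <- data.frame(
      precursor_id = paste0(names(precursors)[idx], "_decoy",
                            seq_len(n_decoys)),
      protein = gsub("(FGPR)[VIY]", "\\1Q", unname(precursors)[idx]),
      is_decoy = TRUE, stringsAsFactors = FALSE)
    specs <- rbind(specs, dec)
  }
  contigs <- character(nrow(specs))
  rows <- list()
  for (i in seq_len(nrow(specs))) {
    cds <- .back_translate(specs$protein[i])
    L <- nchar(cds)
    stopifnot(contig_len >= L + 60L)
    ins <- sample.int(contig_len - L, 1)   # 0-based insert position
    bg <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                            collapse = "")
    strand <- sample(c("+", "-"), 1)
    emb <- if (strand == "+") cds else reverse_complement(cds)
    contigs[i] <- paste0(bg(ins), emb, bg(contig_len - ins - L))
    rows[[i]] <- data.frame(
      contig_id = sprintf("contig%03d", i),
      precursor_id = specs$precursor_id[i],
      start = ins, end = ins + L, strand = strand,
      is_decoy = specs$is_decoy[i], stringsAsFactors = FALSE)
  }
  names(contigs) <- sprintf("contig%03d", seq_len(nrow(specs)))
  list(contigs = contigs, truth = do.call(rbind, rows))
}

#' Generate CDS sequences with controlled synonymous-codon skew
#'
#' Random proteins are back-translated with one of two dials: when
#' `opt_fraction` is given, each degenerate codon is the family's designated
#' optimal codon with that probability (uniform among the non-optimal
#' synonyms otherwise); when `gc3_skew` is given instead, the third position
#' is G/C with probability `gc3_skew` (uniform within the chosen side).
#' Exactly one of the two dials must be non-`NULL`.
#'
#' @param n_genes Number of genes.
#' @param n_codons Codons per gene.
#' @param gc3_skew Target GC3s in `[0, 1]`, or `NULL`.
#' @param opt_fraction Probability of the optimal codon, or `NULL`.
#' @param seed Mandatory integer seed.
#' @return List with `fasta` (named character vector of CDS) and `truth`
#'   (list: the dial used, its value, and the optimal-codon set when
#'   `opt_fraction` drove the generation).
#' @export
gen_cds <- function(n_genes, n_codons = 300L, gc3_skew = NULL,
                    opt_fraction = NULL, seed) {
  stopifnot(!missing(seed), xor(is.null(gc3_skew), is.null(opt_fraction)))
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  aa_all <- setdiff(unique(as.character(gc)), c("*", "M", "W"))
  fams <- lapply(stats::setNames(aa_all, aa_all),
                 function(a) names(gc)[gc == a])
  # designated optimal codon: alphabetically first in each family (arbitrary
  # but fixed; the reference built from an all-optimal gene recovers it)
  optimal <- vapply(fams, function(f) sort(f)[1], character(1))
  genes <- character(n_genes)
  for (g in seq_len(n_genes)) {
    aas <- sample(aa_all, n_codons, replace = TRUE)
    codons <- vapply(aas, function(a) {
      fam <- fams[[a]]
      if (!is.null(opt_fraction)) {
        if (stats::runif(1) < opt_fraction || length(fam) == 1L)
          optimal[[a]]
        else sample(rep(setdiff(fam, optimal[[a]]), 2L), 1)
      } else {
        third <- substring(fam, 3L, 3L)
        side <- if (stats::runif(1) < gc3_skew) fam[third %in% c("G", "C")]
                else fam[third %in% c("A", "T")]
        if (!length(side)) side <- fam
        sample(rep(side, 2L), 1)
      }
    }, character(1))
    genes[g] <- paste(codons, collapse = "")
  }
  names(genes) <- sprintf("gene%03d", seq_len(n_genes))
  list(fasta = genes,
       truth = list(gc3_skew = gc3_skew, opt_fraction = opt_fraction,
                    optimal = optimal))
}

#' Generate observed-mass lists with ppm jitter and decoys
#'
#' True theoretical masses are jittered by `N(0, ppm_sigma)` in ppm space;
#' decoy masses are drawn uniformly over the library's mass range.
#'
#' @param masses Named numeric vector of theoretical monoisotopic masses.
#' @param ppm_sigma Jitter standard deviation in ppm.
#' @param n_decoys Number of uniform decoy masses.
#' @param seed Mandatory integer seed.
#' @return `data.frame` with `id`, `mass`, `is_decoy`, `true_id`.
#' @export
gen_masses <- function(masses, ppm_sigma = 3, n_decoys = 0L, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  obs <- masses * (1 + stats::rnorm(length(masses), 0, ppm_sigma) * 1e-6)
  out <- data.frame(id = paste0("obs_", names(masses)), mass = unname(obs),
                    is_decoy = FALSE, true_id = names(masses),
                    stringsAsFactors = FALSE)
  if (n_decoys > 0L) {
    rng <- range(masses)
    dec <- stats::runif(n_decoys, rng[1], rng[2])
    out <- rbind(out, data.frame(
      id = sprintf("decoy%04d", seq_len(n_decoys)), mass = dec,
      is_decoy = TRUE, true_id = NA_character_, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Generate bioassay hatch-count tables
#'
#' Per replicate, `H2 ~ Binomial(n_eggs, p_group)` (diapausing, hatch only
#' after chilling) and `H1 = n_eggs - H2`.
#'
#' @param p_by_group Named vector of true diapause probabilities.
#' @param n_eggs Eggs per replicate.
#' @param n_reps Replicates per group.
#' @param seed Mandatory integer seed.
#' @return `data.frame` with `treatment`, `rep`, `H1`, `H2`.
#' @export
gen_bioassay <- function(p_by_group, n_eggs = 100L, n_reps = 3L, seed) {
  stopifnot(!missing(seed), all(p_by_group >= 0), all(p_by_group <= 1))
  set.seed(seed)
  rows <- list()
  for (g in names(p_by_group)) {
    h2 <- stats::rbinom(n_reps, n_eggs, p_by_group[[g]])
    rows[[g]] <- data.frame(treatment = g, rep = seq_len(n_reps),
                            H1 = n_eggs - h2, H2 = h2,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize generator ground truth as JSON
#'
#' @param truth Ground-truth object from a generator.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
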