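#' Run the full mining-to-statistics pipeline
#'
#' Orchestrates the stages on file inputs: contig mining (when `queries` and
#' `contigs` are given), precursor annotation + classification (when
#' `precursors` is given), mass matching (when `observed_masses` is given),
#' codon-bias indices (when `cds` and `reference_cds` are given), NJ
#' phylogeny (when `msa` is given) and bioassay statistics (when `bioassay`
#' is given). Each stage writes a TSV/Newick file into `out_dir` and
#' contributes to the returned summary. Deterministic given the inputs and
#' `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param queries,contigs,precursors,cds,reference_cds,msa FASTA paths
#'   (or `NULL` to skip the stage).
#' @param observed_masses TSV path with columns `id`, `mass`, or `NULL`.
#' @param bioassay CSV path (see [read_bioassay()]), or `NULL`.
#' @param min_aligned_nt,motif Passed to [screen_contigs()].
#' @param rules,signal Passed to [annotate_precursor()].
#' @param tol_ppm Passed to [match_masses()].
#' @param n_boot Bootstrap replicates for the phylogeny stage.
#' @param alpha Significance level for the statistics stage.
#' @param seed Integer seed (bootstrap resampling).
#' @return Invisible list of per-stage summaries (`mining`, `annotation`,
#'   `type_counts`, `repeats`, `mass_matches`, `codon_bias`, `tree`,
#'   `bioassay`).
#' @export
run_pipeline <- function(out_dir,
                         queries = NULL, contigs = NULL, precursors = NULL,
                         observed_masses = NULL, cds = NULL,
                         reference_cds = NULL, msa = NULL, bioassay = NULL,
                         min_aligned_nt = 100, motif = "FGPR[VIY]",
                         rules = cleavage_rules(),
                         signal = "heuristic", tol_ppm = 15.0,
                         n_boot = 100L, alpha = 0.05, seed = 1L) {
  stopifnot(min_aligned_nt > 0, tol_ppm > 0, alpha > 0, n_boot >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list()

  if (!is.null(queries) && !is.null(contigs)) {
    calls <- screen_contigs(read_fasta(queries, "prot"),
                            read_fasta(contigs, "nuc"),
                            min_aligned_nt = min_aligned_nt, motif = motif)
    utils::write.table(calls, file.path(out_dir, "mining.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$mining <- list(n_candidates = nrow(calls),
                           n_targets = sum(calls$tier == "target"))
  }

  peptide_lib <- NULL
  if (!is.null(precursors)) {
    prots <- read_fasta(precursors, "prot")
    anns <- lapply(names(prots), function(id)
      annotate_precursor(prots[[id]], precursor_id = id, rules = rules,
                         signal = signal))
    peps <- do.call(rbind, lapply(anns, `[[`, "peptides"))
    utils::write.table(peps, file.path(out_dir, "peptides.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    peptide_lib <- peps
    reps <- do.call(rbind, lapply(anns, function(a) {
      r <- find_tandem_repeats(a$peptides$label)
      if (nrow(r)) r$precursor_id <- a$precursor_id
      r
    }))
    summary$annotation <- list(n_precursors = length(anns),
                               n_peptides = nrow(peps),
                               peptides_per_precursor = vapply(
                                 anns, function(a) nrow(a$peptides),
                                 numeric(1)))
    summary$type_counts <- count_types(peps$label)
    summary$repeats <- reps
  }

  if (!is.null(observed_masses) && !is.null(peptide_lib)) {
    obs <- utils::read.delim(observed_masses, stringsAsFactors = FALSE)
    lib <- expand_pyroglu(peptide_lib)
    matches <- match_masses(obs, lib, tol_ppm = tol_ppm)
    utils::write.table(matches, file.path(out_dir, "mass_matches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$mass_matches <- list(n_observed = nrow(obs),
                                 n_matched = length(unique(matches$observed_id)),
                                 n_unmatched = length(attr(matches, "unmatched")))
  }

  if (!is.null(cds) && !is.null(reference_cds)) {
    ref <- build_reference(read_fasta(reference_cds, "nuc"))
    bias <- codon_bias(read_fasta(cds, "nuc"), ref)
    utils::write.table(bias, file.path(out_dir, "codon_bias.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$codon_bias <- bias
  }

  if (!is.null(msa)) {
    aln <- read_fasta(msa, "prot")
    tree <- nj_bootstrap(aln, n_reps = n_boot, seed = seed)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    summary$tree <- list(n_taxa = length(aln),
                         sum_branch_lengths = sum(tree$edge.length))
  }

  if (!is.null(bioassay)) {
    ba <- read_bioassay(bioassay)
    an <- one_way_anova(ba$incidence, ba$treatment)
    letters <- posthoc_letters(ba$incidence, ba$treatment, alpha = alpha)
    utils::write.table(letters, file.path(out_dir, "bioassay_letters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$bioassay <- list(F = an$F, p = an$p, letters = letters)
  }

  jsonlite::write_json(
    summary[!vapply(summary, is.data.frame, logical(1))],
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", force = TRUE)
  invisible(summary)
}
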