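#' Poisson-corrected protein distance matrix
#'
#' From a pre-aligned protein MSA, columns containing gaps (`-`) or ambiguous
#' residues (`X`, `?`, `*`) are removed across all taxa (complete deletion;
#' pairwise deletion is available behind a flag). For each pair the
#' p-distance `p = mismatches / valid columns` is corrected to
#' `d = -ln(1 - p)`, in units of amino-acid substitutions per site.
#'
#' @param msa Named character vector of aligned protein rows (equal length).
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return Symmetric numeric matrix of distances with taxa as dimnames; the
#'   underlying p-distances are kept in the `"p"` attribute, and the number
#'   of columns used in `"n_sites"` (complete deletion only).
#' @export
poisson_distance <- function(msa, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(length(msa) >= 2L)
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) stop("MSA rows differ in length")
  taxa <- names(msa)
  mat <- do.call(rbind, strsplit(unname(msa), ""))
  amb <- mat %in% c("-", "X", "?", "*", ".")
  dim(amb) <- dim(mat)
  if (deletion == "complete") {
    keep <- !apply(amb, 2L, any)
    if (!any(keep)) stop("no unambiguous columns remain after complete deletion")
    mat <- mat[, keep, drop = FALSE]
    amb <- amb[, keep, drop = FALSE]
  }
  n <- length(msa)
  p <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !(amb[i, ] | amb[j, ])
      nv <- sum(ok)
      if (nv == 0L) stop("no comparable columns for pair ", taxa[i], "/", taxa[j])
      pij <- sum(mat[i, ok] != mat[j, ok]) / nv
      if (pij >= 1) stop("p-distance of 1 between ", taxa[i], " and ",
                         taxa[j], ": Poisson correction is infinite")
      p[i, j] <- p[j, i] <- pij
    }
  }
  d <- -log(1 - p)
  attr(d, "p") <- p
  if (deletion == "complete") attr(d, "n_sites") <- ncol(mat)
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix: at each step the pair
#' minimising `Q_ij = (n-2) d_ij - r_i - r_j` is joined (ties broken by the
#' lowest index pair in the current matrix order, which is deterministic in
#' the input taxon order); pendant branch lengths follow the standard NJ
#' formulas, with negative lengths clamped to zero (a message is emitted).
#' The final three lineages are resolved onto an unrooted trifurcating root.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor-joining needs at least 3 taxa")
  labs <- rownames(dm)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  # subtrees carried as newick fragments
  nodes <- labs
  D <- dm
  clamp <- function(x) {
    if (x < 0) { message("negative NJ branch length clamped to 0"); 0 } else x
  }
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- clamp(li); lj <- clamp(lj)
    newick <- sprintf("(%s:%.15g,%s:%.15g)", nodes[i], li, nodes[j], lj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], newick)
    D <- D2
  }
  l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 nodes[1], l1, nodes[2], l2, nodes[3], l3)
  ape::read.tree(text = nwk)
}

#' Bootstrap support for the NJ tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' Poisson-corrected NJ tree for each replicate, and reports for every
#' internal edge of the full-data tree the percentage of replicates
#' containing the same bipartition.
#'
#' @param msa Named character vector of aligned protein rows.
#' @param n_reps Number of bootstrap replicates (the classical choice is
#'   1000; smaller values are adequate at desk scale).
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param deletion Passed to [poisson_distance()].
#' @return The full-data `ape::phylo` tree with `node.label` holding the
#'   support percentages (root label empty).
#' @export
nj_bootstrap <- function(msa, n_reps = 1000L, seed = 1L,
                         deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(n_reps >= 1L)
  ref <- nj_tree(poisson_distance(msa, deletion))
  mat <- do.call(rbind, strsplit(unname(msa), ""))
  rownames(mat) <- names(msa)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    rs <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    reps[[b]] <- nj_tree(poisson_distance(rs, deletion))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps, 1)
  ref$node.label <- as.character(support)
  ref$node.label[1] <- ""  # root trifurcation carries no bipartition
  ref
}

#' Write a tree in Newick format
#'
#' Support values (node labels) are written as internal-node labels.
#'
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
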