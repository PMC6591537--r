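test_that("signal trimming modes behave as documented", {
  g <- gen_precursors(10, n_cassettes = 3, seed = 91)
  for (id in names(g$fasta)) {
    tr <- trim_signal(g$fasta[[id]], "heuristic")
    expect_false(is.null(tr$signal_span))
    expect_lte(abs(tr$signal_span[2] - g$truth[[id]]$signal_span[2]), 2)
  }
  p <- g$fasta[[1]]
  none <- trim_signal(p, "none")
  expect_null(none$signal_span)
  expect_identical(none$mature, p)
  fx <- trim_signal(p, "fixed", fixed_len = 10)
  expect_equal(fx$signal_span, c(0L, 10L))
  expect_identical(paste0(substr(p, 1, 10), fx$mature), p)
  expect_warning(res <- trim_signal(strrep("D", 50), "heuristic"),
                 "hydrophobic")
  expect_null(res$signal_span)
})

test_that("cleavage reproduces the published processing examples", {
  # G before KR is the amide donor and is removed
  p <- cleave("AQPPGLWFGPRVGKRSHPEPGMWFGPRVGKK")
  expect_identical(p$sequence[1], "AQPPGLWFGPRV")
  expect_true(p$amidated[1])
  # GRR donates its own motif G
  p <- cleave("EGDFTPRLGRRDDDD")
  expect_identical(p$sequence[1], "EGDFTPRL")
  expect_true(p$amidated[1])
  # AR is never cleaved: the PK-3-like segment stays fused
  p <- cleave("DPPVDGPLVWLPLQVSPRLARDDDDKRAAAA")
  expect_false(any(grepl("^DPPVDGPLVWLPLQVSPRL$", p$sequence)))
  expect_identical(p$sequence[1], "DPPVDGPLVWLPLQVSPRLARDDDD")
  # N-terminal Q flags a pyroglutamate variant
  p <- cleave("QQPFVPRLGR")
  expect_identical(p$sequence, "QQPFVPRL")
  expect_true(p$amidated && p$pyroglu)
})

test_that("cleavage is idempotent on its own output peptides", {
  g <- gen_precursors(20, n_cassettes = 5, seed = 101)
  for (id in names(g$fasta)[1:5]) {
    peps <- cleave(trim_signal(g$fasta[[id]])$mature)
    for (s in peps$sequence) {
      again <- cleave(s)
      expect_identical(again$sequence, s)
    }
  }
})

test_that("processing conserves every precursor residue", {
  g <- gen_precursors(30, n_cassettes = 6, seed = 111)
  for (id in names(g$fasta)) {
    prec <- g$fasta[[id]]
    ann <- annotate_precursor(prec, id)
    # rebuild: signal + segments (+ removed donor G) + motifs, in coordinate order
    sig <- if (is.null(ann$signal_span)) "" else
      substr(prec, 1, ann$signal_span[2])
    pieces <- data.frame(start = integer(0), text = character(0))
    for (k in seq_len(nrow(ann$peptides))) {
      pep <- ann$peptides[k, ]
      raw <- substr(prec, pep$start + 1, pep$end)
      expect_identical(raw, pep$sequence)
      # if amidated via a removed donor, the next residue is G
      nxt <- substr(prec, pep$end + 1, pep$end + 1)
      follows_site <- any(ann$cleavage_sites$position == pep$end) ||
        any(ann$cleavage_sites$position == pep$end + 1)
      if (pep$amidated) expect_true(nxt == "G" || follows_site)
    }
    # coverage: signal + peptides + donor Gs + motifs + discarded == precursor
    covered <- logical(nchar(prec))
    if (nzchar(sig)) covered[seq_len(nchar(sig))] <- TRUE
    for (k in seq_len(nrow(ann$peptides)))
      covered[(ann$peptides$start[k] + 1):ann$peptides$end[k]] <- TRUE
    for (k in seq_len(nrow(ann$cleavage_sites))) {
      pos <- ann$cleavage_sites$position[k]
      len <- nchar(ann$cleavage_sites$motif[k])
      covered[(pos + 1):(pos + len)] <- TRUE
      if (substr(prec, pos, pos) == "G" && !covered[pos]) covered[pos] <- TRUE
    }
    d <- ann$discarded
    for (k in seq_len(nrow(d))) covered[(d$start[k] + 1):d$end[k]] <- TRUE
    expect_true(all(covered))
  }
})

test_that("annotation recovers generator ground truth exactly", {
  g <- gen_precursors(50, n_cassettes = 8, seed = 121)
  n_ok <- 0; n_tot <- 0; amid_ok <- 0
  for (id in names(g$fasta)) {
    ann <- annotate_precursor(g$fasta[[id]], id)
    tp <- g$truth[[id]]$peptides
    n_tot <- n_tot + nrow(tp)
    key_t <- paste(tp$start, tp$end, tp$sequence)
    key_a <- paste(ann$peptides$start, ann$peptides$end, ann$peptides$sequence)
    hit <- key_t %in% key_a
    n_ok <- n_ok + sum(hit)
    m <- match(key_t, key_a)
    amid_ok <- amid_ok + sum(tp$amidated == ann$peptides$amidated[m],
                             na.rm = TRUE)
    expect_identical(ann$peptides$label, tp$label)
  }
  expect_equal(n_ok, n_tot)
  expect_equal(amid_ok, n_tot)
})

test_that("a motif-free mature region yields one whole-region peptide", {
  ann <- cleave("AQPPGLWFDDDEEEE")
  expect_equal(nrow(ann), 1L)
  expect_identical(ann$sequence, "AQPPGLWFDDDEEEE")
  expect_false(ann$amidated)
})
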