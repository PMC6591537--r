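test_that("published peptides classify to their printed types", {
  expect_identical(classify_peptide("LWFGPRV")$label, "DH-I")
  expect_identical(classify_peptide("SHPEPGMWFGPRV")$label, "DH-II")
  expect_identical(classify_peptide("SQAEPGVWFGARI")$label, "DH-V")
  expect_identical(classify_peptide("DSGDEWPQQPFVPRL")$label, "PK")
  expect_identical(classify_peptide("KGLVASARV")$label, "PK-like")
  expect_identical(classify_peptide("DDDDDDD")$label, "unclassified")
  expect_warning(classify_peptide("LWFGPRV", amidated = FALSE),
                 "non-amidated")
})

test_that("classification is total, deterministic and priority-driven", {
  set.seed(131)
  rules <- class_rules()
  seqs <- c(replicate(50, random_protein(10)),
            paste0(replicate(20, random_protein(4)), "LWFGPRV"))
  labs1 <- vapply(seqs, function(s) classify_peptide(s, rules = rules)$label,
                  character(1))
  labs2 <- vapply(seqs, function(s) classify_peptide(s, rules = rules)$label,
                  character(1))
  expect_identical(labs1, labs2)
  expect_true(all(nzchar(labs1)))
  # reversing priorities is the only way results change: a DH-I peptide
  # reclassifies to the now-higher-priority generic PVK rule
  rev_rules <- class_rules(labels = rules$label, patterns = rules$pattern,
                           priorities = rev(rules$priority))
  expect_identical(classify_peptide("AQPPGLWFGPRV", rules = rev_rules)$label,
                   "PK-like")
})

test_that("type counting partitions DH-classified peptides", {
  tab <- lom_peptides()
  dh <- tab[tab$type != "", ]
  labs <- vapply(dh$sequence, function(s) classify_peptide(s)$label,
                 character(1))
  ct <- count_types(labs)
  expect_equal(ct, c(I = 4L, II = 2L, IV = 1L, V = 1L))
  expect_equal(sum(ct), sum(grepl("^DH-", labs)))
  expect_length(count_types(character(0)), 0L)
  expect_length(count_types(c("PK", "PVK")), 0L)
})

test_that("tandem repeat finder matches an exhaustive oracle", {
  # exhaustive over all label sequences of length <= 7 on 3 labels
  alpha <- c("a", "b", "c")
  for (n in 2:7) {
    grids <- do.call(expand.grid, rep(list(alpha), n))
    for (r in seq_len(nrow(grids))) {
      labs <- as.character(unlist(grids[r, ]))
      got <- find_tandem_repeats(labs)
      want <- tandem_oracle(labs)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        expect_equal(got$start, as.integer(want[, 1]))
        expect_equal(got$end, as.integer(want[, 2]))
        expect_equal(got$copies, as.integer(want[, 4]))
      }
    }
  }
})

test_that("published precursor architectures yield the reported repeats", {
  capa <- find_tandem_repeats(c("CAPA-1", "CAPA-2", "DH-1", "CAPA-2",
                                "DH-1", "PK-1"))
  expect_equal(nrow(capa), 1L)
  expect_identical(capa$block, "CAPA-2,DH-1")
  expect_equal(capa$copies, 2L)
  pban <- find_tandem_repeats(c("PK-1", "PK-2", "PBAN", "PK-3", "PK-2",
                                "PK-2", "PBAN"))
  expect_equal(nrow(pban), 1L)
  expect_identical(pban$block, "PK-2")
  expect_equal(pban$start, 5L)
  expect_equal(pban$end, 6L)
  expect_equal(nrow(find_tandem_repeats(c("x", "y", "z"))), 0L)
})

test_that("logo information content follows the entropy formula", {
  ten <- rep("AQPPGLWFGPRVA", 10)
  logo <- cterm_logo(ten, k = 13)
  expect_true(all(abs(logo$ic - log2(20)) < 1e-12))
  expect_identical(logo$consensus, "AQPPGLWFGPRVA")
  # a 50/50 column loses exactly one bit
  two <- c(rep(strrep("A", 13), 5), rep(paste0(strrep("A", 12), "C"), 5))
  logo2 <- cterm_logo(two, k = 13)
  expect_equal(logo2$ic[13], log2(20) - 1, tolerance = 1e-12)
  # short peptides are gap-padded; gaps excluded from frequencies
  mixed <- c("LWFGPRV", rep(strrep("W", 13), 2))
  logo3 <- cterm_logo(mixed, k = 13)
  expect_equal(sum(logo3$freq[, 1]), 1)        # only the two W rows count
  expect_equal(unname(logo3$freq["W", 1]), 1)
  # planted 70% L at position -7 becomes the modal residue
  set.seed(141)
  peps <- vapply(1:200, function(i) {
    pos7 <- if (runif(1) < 0.7) "L" else sample(c("M","T","V"), 1)
    paste0(random_protein(6), pos7, random_protein(6))
  }, character(1))
  logo4 <- cterm_logo(peps, k = 13)
  expect_identical(substr(logo4$consensus, 7, 7), "L")
})
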