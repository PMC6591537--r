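test_that("Poisson distance matches hand counts and the closed form", {
  msa <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKV", c = "ACDEFGHIVV")
  d <- poisson_distance(msa)
  p <- attr(d, "p")
  expect_equal(p["a", "b"], 0.1)
  expect_equal(p["a", "c"], 0.2)
  expect_equal(p["b", "c"], 0.1)
  expect_equal(d["a", "b"], -log(0.9))
  expect_equal(diag(d), setNames(c(0, 0, 0), c("a", "b", "c")))
  expect_equal(d, t(d))
  # identical rows -> zero distance
  same <- c(x = "WWWW", y = "WWWW", z = "WWWW")
  expect_true(all(poisson_distance(same) == 0))
  # complete deletion removes gap/ambiguous columns across all taxa
  gappy <- c(a = "AC-EF", b = "ACDEF", c = "ACXEF")
  dg <- poisson_distance(gappy)
  expect_equal(attr(dg, "n_sites"), 4L)  # only the -/D/X column is dropped
  expect_true(all(dg == 0))
  # saturated pair errors
  expect_error(poisson_distance(c(a = "AAAA", b = "CCCC")), "Poisson")
})

test_that("distance is monotone in mismatch count", {
  base <- strrep("A", 50)
  d_prev <- 0
  for (k in c(5, 10, 20, 30)) {
    other <- paste0(strrep("C", k), strrep("A", 50 - k))
    d <- poisson_distance(c(a = base, b = other))["a", "b"]
    expect_gt(d, d_prev)
    d_prev <- d
  }
})

test_that("NJ recovers additive trees exactly", {
  set.seed(231)
  for (r in 1:25) {
    nt <- sample(5:10, 1)
    tr <- ape::rtree(nt, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(tr)
    mt <- nj_tree(D)
    expect_lt(max(abs(ape::cophenetic.phylo(mt)[rownames(D), colnames(D)] - D)),
              1e-8)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("NJ topology agrees with the ape::nj oracle on random matrices", {
  set.seed(241)
  for (r in 1:25) {
    D <- as.matrix(dist(matrix(runif(8 * 5), 8)))
    dimnames(D) <- list(paste0("t", 1:8), paste0("t", 1:8))
    expect_equal(ape::dist.topo(ape::unroot(nj_tree(D)),
                                ape::unroot(ape::nj(D))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("ultrametric 3-leaf star resolves with equal pendant lengths", {
  D <- matrix(2, 3, 3); diag(D) <- 0
  dimnames(D) <- list(c("a", "b", "c"), c("a", "b", "c"))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  expect_true(all(abs(tr$edge.length - 1) < 1e-12))
})

test_that("branch-length sum is invariant under taxon input order", {
  set.seed(251)
  tr <- ape::rtree(7, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  D <- ape::cophenetic.phylo(tr)
  s1 <- sum(nj_tree(D)$edge.length)
  perm <- sample(rownames(D))
  s2 <- sum(nj_tree(D[perm, perm])$edge.length)
  expect_lt(abs(s1 - s2), 1e-9)
})

test_that("bootstrap supports are deterministic and bounded", {
  msa <- sim_two_clades(n_sites = 150, seed = 261)
  t1 <- nj_bootstrap(msa, n_reps = 50, seed = 5)
  t2 <- nj_bootstrap(msa, n_reps = 50, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # single replicate: supports are 0 or 100
  t3 <- nj_bootstrap(msa, n_reps = 1, seed = 6)
  s3 <- suppressWarnings(as.numeric(t3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
})

test_that("well-separated clades earn high bootstrap support", {
  msa <- sim_two_clades(n_sites = 300, within = 0.01, between = 0.5,
                        seed = 271)
  tr <- nj_bootstrap(msa, n_reps = 200, seed = 7)
  # the two three-taxon clades must be present and strongly supported
  parts <- ape::prop.part(tr)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  labs <- tr$tip.label
  clade_support <- function(tips) {
    for (k in seq_along(parts)) {
      mem <- sort(labs[parts[[k]]])
      comp <- sort(setdiff(labs, mem))
      if (identical(mem, sort(tips)) || identical(comp, sort(tips)))
        return(sup[k])
    }
    NA_real_
  }
  expect_gte(clade_support(c("a1", "a2", "a3")), 95)
  expect_gte(clade_support(c("b1", "b2", "b3")), 95)
  # Newick writing keeps supports as internal labels
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_true(any(grepl("\\)[0-9]", readLines(f))))
})
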