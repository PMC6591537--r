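test_that("diapause incidence follows the hatch-count formula", {
  expect_equal(diapause_incidence(8, 2), 20.0)
  expect_equal(diapause_incidence(5, 0), 0.0)
  expect_equal(diapause_incidence(0, 5), 100.0)
  expect_warning(x <- diapause_incidence(0, 0), "undefined")
  expect_true(is.na(x))
  # scale invariance
  expect_equal(diapause_incidence(8, 2), diapause_incidence(80, 20))
  expect_true(all(diapause_incidence(0:10, 10:0) >= 0 &
                  diapause_incidence(0:10, 10:0) <= 100))
})

test_that("2^-ddCt fold changes behave as defined", {
  q <- data.frame(group = rep(c("ref", "same", "up"), each = 3),
                  ct_target = c(20, 20, 20, 20, 20, 20, 19, 19, 19),
                  ct_ref = rep(15, 9))
  r <- ddct(q, "ref")
  expect_equal(r$fold[r$group == "ref"], 1.0)
  expect_equal(r$fold[r$group == "same"], 1.0)
  expect_equal(r$fold[r$group == "up"], 2.0)  # ddCt = -1
  # fold is invariant under a constant Ct offset on both channels
  q2 <- q; q2$ct_target <- q2$ct_target + 3; q2$ct_ref <- q2$ct_ref + 3
  expect_equal(ddct(q2, "ref")$fold, r$fold)
})

test_that("ddCt recovers a true knockdown within sampling error", {
  true_fold <- 0.25
  hit <- 0; n_sim <- 500
  for (s in seq_len(n_sim)) {
    set.seed(s)
    q <- data.frame(
      group = rep(c("ref", "kd"), each = 3),
      ct_target = c(rnorm(3, 20, 0.2), rnorm(3, 20 - log2(true_fold), 0.2)),
      ct_ref = rnorm(6, 15, 0.2))
    f <- ddct(q, "ref")$fold[2]
    if (f >= 0.15 && f <= 0.40) hit <- hit + 1
  }
  expect_gte(hit / n_sim, 0.95)
})

test_that("one-way ANOVA matches the t-test identity and null behaviour", {
  a <- c(1, 2); b <- c(3, 4)
  an <- one_way_anova(c(a, b), rep(c("a", "b"), each = 2))
  tt <- t_test2(a, b)
  expect_equal(abs(tt$statistic), 2.8284, tolerance = 1e-4)
  expect_equal(an$F, tt$statistic^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p, tolerance = 1e-10)
  # all observations equal: F = 0, p = 1
  an0 <- one_way_anova(rep(5, 6), rep(c("x", "y", "z"), each = 2))
  expect_equal(an0$F, 0)
  expect_equal(an0$p, 1)
  # shift invariance
  set.seed(281)
  v <- rnorm(15); g <- rep(letters[1:3], each = 5)
  expect_equal(one_way_anova(v, g)$F, one_way_anova(v + 100, g)$F,
               tolerance = 1e-9)
  # degenerate inputs rejected
  expect_error(one_way_anova(1:3, c("a", "a", "b")))
})

test_that("t-test on identical samples gives t = 0, p = 1", {
  x <- c(1.2, 3.4, 5.6)
  tt <- t_test2(x, x)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)
  # Welch flag changes df on heteroscedastic unbalanced data
  set.seed(291)
  a <- rnorm(10, sd = 1); b <- rnorm(25, sd = 5)
  expect_false(isTRUE(all.equal(t_test2(a, b)$df,
                                t_test2(a, b, var_equal = FALSE)$df)))
})

test_that("letter groupings separate clear effects and merge identical ones", {
  set.seed(301)
  v <- c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 10))
  g <- rep(c("g1", "g2", "g3"), each = 10)
  for (meth in c("tukey", "duncan")) {
    lt <- posthoc_letters(v, g, method = meth)
    expect_identical(lt$letters[lt$group == "g3"], "a")  # highest mean first
    expect_identical(lt$letters[lt$group == "g1"], lt$letters[lt$group == "g2"])
    expect_false(lt$letters[lt$group == "g3"] %in%
                   lt$letters[lt$group == "g1"])
  }
  # identical groups share one letter
  set.seed(302)
  v2 <- rnorm(30); lt2 <- posthoc_letters(v2, g)
  expect_true(all(lt2$letters == "a"))
  # unbalanced design warns about harmonic-mean n
  expect_warning(posthoc_letters(c(v, rnorm(3, 5)),
                                 c(g, rep("g4", 3))), "harmonic")
})

test_that("Tukey is never more liberal than Duncan", {
  set.seed(311)
  for (r in 1:100) {
    v <- rnorm(20, mean = rep(runif(4, 0, 2), each = 5))
    g <- rep(paste0("g", 1:4), each = 5)
    st <- attr(posthoc_letters(v, g, "tukey"), "significant")
    sd_ <- attr(posthoc_letters(v, g, "duncan"), "significant")
    expect_lte(sum(st), sum(sd_))
  }
})

test_that("bioassay tables round-trip through the CSV reader", {
  ba <- gen_bioassay(c(control = 0.19, SDH1 = 0.68), n_eggs = 100,
                     n_reps = 3, seed = 321)
  f <- tempfile(fileext = ".csv")
  write.csv(ba, f, row.names = FALSE)
  got <- read_bioassay(f)
  expect_equal(got$incidence, diapause_incidence(ba$H1, ba$H2))
  expect_error(read_bioassay({
    f2 <- tempfile(); write.csv(data.frame(x = 1), f2, row.names = FALSE); f2
  }), "columns")
})
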