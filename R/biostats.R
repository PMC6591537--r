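#' Diapause incidence
#'
#' `100 * H2 / (H1 + H2)`, where `H1` counts individuals hatching within the
#' first incubation window (30 d at 28 C) and `H2` those hatching only after
#' a chilling rescue (60 d at 4 C followed by 30 d at 28 C). Vectorised.
#'
#' @param h1,h2 Non-negative hatch counts.
#' @return Percentage in `[0, 100]`; `NA` with a warning when `H1 + H2 = 0`.
#' @export
diapause_incidence <- function(h1, h2) {
  stopifnot(all(h1 >= 0), all(h2 >= 0))
  tot <- h1 + h2
  out <- ifelse(tot > 0, 100 * h2 / tot, NA_real_)
  if (anyNA(out)) warning("diapause incidence undefined where H1 + H2 = 0")
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_ref` (the reference gene, e.g.
#' beta-actin); per group, `ddCt = mean dCt(group) - mean dCt(reference
#' group)` and fold change `2^-ddCt`.
#'
#' @param records `data.frame` with columns `group`, `ct_target`, `ct_ref`.
#' @param reference_group Name of the calibrator group (fold change 1).
#' @return `data.frame` with `group`, `n`, `dct_mean`, `dct_se`, `ddct`,
#'   `fold`.
#' @export
ddct <- function(records, reference_group) {
  stopifnot(all(c("group", "ct_target", "ct_ref") %in% names(records)),
            reference_group %in% records$group)
  dct <- records$ct_target - records$ct_ref
  groups <- unique(records$group)
  agg <- data.frame(
    group = groups,
    n = vapply(groups, function(g) sum(records$group == g), integer(1)),
    dct_mean = vapply(groups, function(g) mean(dct[records$group == g]),
                      numeric(1)),
    dct_se = vapply(groups, function(g) {
      x <- dct[records$group == g]
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  agg$ddct <- agg$dct_mean - agg$dct_mean[agg$group == reference_group]
  agg$fold <- 2^(-agg$ddct)
  rownames(agg) <- NULL
  agg
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: F from between/within mean
#' squares, p from the F distribution, plus per-group means and standard
#' errors.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (>= 2 groups, each with >= 2 observations).
#' @return Object of class `"anova_result"`: list with `F`, `df_between`,
#'   `df_within`, `p`, `means` (`data.frame` of group, n, mean, se) and the
#'   residual mean square `ms_within`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2L, all(table(groups) >= 2L),
            length(values) == length(groups))
  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1]]
  f_stat <- sm[["F value"]][1]
  p_val <- sm[["Pr(>F)"]][1]
  # degenerate case: no between-group variation (incl. all-equal data,
  # where aov's sums of squares are pure floating-point noise)
  if (is.nan(f_stat) || isTRUE(all.equal(stats::var(values), 0))) {
    f_stat <- 0; p_val <- 1
  }
  means <- data.frame(
    group = levels(groups),
    n = as.integer(table(groups)),
    mean = as.numeric(tapply(values, groups, mean)),
    se = as.numeric(tapply(values, groups, function(x)
      stats::sd(x) / sqrt(length(x)))),
    stringsAsFactors = FALSE)
  structure(list(F = f_stat,
                 df_between = sm[["Df"]][1],
                 df_within = sm[["Df"]][2],
                 p = p_val,
                 ms_within = sm[["Mean Sq"]][2],
                 means = means),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Post-hoc letter groupings (Tukey HSD or Duncan's multiple range test)
#'
#' Pairwise comparisons via the studentized range distribution. Tukey uses
#' the range over all `k` groups at level `alpha`; Duncan uses, for means
#' separated by `p` ranks, the protection level `1 - (1 - alpha)^(p - 1)`
#' (the more liberal test). Unbalanced designs use the harmonic-mean group
#' size with a warning. Letters are assigned so that groups sharing a letter
#' are not significantly different (maximal homogeneous intervals over the
#' ordered means).
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector.
#' @param method `"tukey"` (default) or `"duncan"`.
#' @param alpha Significance level.
#' @return `data.frame` with `group`, `mean`, `letters`, ordered by
#'   decreasing mean; the logical matrix of significant pairs is in the
#'   `"significant"` attribute.
#' @export
posthoc_letters <- function(values, groups, method = c("tukey", "duncan"),
                            alpha = 0.05) {
  method <- match.arg(method)
  an <- one_way_anova(values, groups)
  k <- nrow(an$means)
  df <- an$df_within
  ns <- an$means$n
  if (length(unique(ns)) > 1L)
    warning("unbalanced groups: using harmonic-mean n")
  n_h <- k / sum(1 / ns)
  se <- sqrt(an$ms_within / n_h)
  ord <- order(-an$means$mean)
  m <- an$means$mean[ord]
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      span <- j - i + 1L
      crit <- if (method == "tukey") {
        stats::qtukey(1 - alpha, k, df)
      } else {
        stats::qtukey((1 - alpha)^(span - 1L), span, df)
      }
      sig[i, j] <- sig[j, i] <- abs(m[i] - m[j]) > crit * se
    }
  }
  # maximal homogeneous intervals over ordered means -> letters
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1L), i:(j + 1L)])) j <- j + 1L
    intervals[[length(intervals) + 1L]] <- c(i, j)
  }
  intervals <- unique(intervals)
  maximal <- Filter(function(iv) {
    !any(vapply(intervals, function(o)
      !identical(o, iv) && o[1] <= iv[1] && o[2] >= iv[2], logical(1)))
  }, intervals)
  letters_out <- rep("", k)
  for (li in seq_along(maximal)) {
    iv <- maximal[[li]]
    letters_out[iv[1]:iv[2]] <- paste0(letters_out[iv[1]:iv[2]], letters[li])
  }
  out <- data.frame(group = an$means$group[ord], mean = m,
                    letters = letters_out, stringsAsFactors = FALSE)
  dimnames(sig) <- list(out$group, out$group)
  attr(out, "significant") <- sig
  rownames(out) <- NULL
  out
}

#' Two-sample Student's t-test
#'
#' Two-sided; pooled-variance by default (matching the textbook pairing with
#' one-way ANOVA, `F = t^2` for two groups), Welch behind a flag.
#'
#' @param a,b Numeric samples.
#' @param paired Paired test.
#' @param var_equal Pooled variance (default `TRUE`); `FALSE` gives Welch.
#' @return List with `statistic`, `df`, `p`.
#' @export
t_test2 <- function(a, b, paired = FALSE, var_equal = TRUE) {
  tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Read a bioassay count table
#'
#' CSV with columns `treatment`, `dose_nmol`, `photoperiod`, `H1`, `H2`;
#' adds the computed `incidence` column.
#'
#' @param path CSV path.
#' @return `data.frame`.
#' @export
read_bioassay <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("treatment", "H1", "H2")
  if (!all(need %in% names(df)))
    stop("bioassay table must have columns: ", paste(need, collapse = ", "))
  df$incidence <- diapause_incidence(df$H1, df$H2)
  df
}
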