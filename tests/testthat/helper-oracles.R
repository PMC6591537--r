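# Independent oracles used by the property tests. These deliberately do not
# share code with the package implementation.

# Brute-force Smith-Waterman with affine gaps (Gotoh), score only.
# A gap of length L costs gap_open + L * gap_extend, matching the scoring
# convention of the package aligner.
sw_oracle <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                      Iy[i, j - 1] - gap_extend)
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
    }
  }
  best
}

# Brute-force maximal-tandem-repeat finder over label vectors, written as a
# direct check of the definition on collapsed strings.
tandem_oracle <- function(labels) {
  n <- length(labels)
  key <- function(v) paste(v, collapse = "\r")
  prim <- function(block) {
    L <- length(block)
    if (L == 1L) return(TRUE)
    divs <- which(L %% seq_len(L %/% 2L) == 0L)
    !any(vapply(divs, function(d)
      key(block) == key(rep(block[seq_len(d)], L / d)), logical(1)))
  }
  res <- list()
  for (i in seq_len(n)) for (L in seq_len(n %/% 2L)) {
    if (i + 2L * L - 1L > n) next
    block <- labels[i:(i + L - 1L)]
    if (!prim(block)) next
    k <- 1L
    while (i + (k + 1L) * L - 1L <= n &&
           key(labels[(i + k * L):(i + (k + 1L) * L - 1L)]) == key(block))
      k <- k + 1L
    if (k < 2L) next
    if (i - L >= 1L && key(labels[(i - L):(i - 1L)]) == key(block)) next
    res[[length(res) + 1L]] <- c(i, i + k * L - 1L, L, k)
  }
  if (!length(res)) return(matrix(numeric(0), ncol = 4))
  out <- unique(do.call(rbind, res))
  out[order(out[, 1], out[, 3]), , drop = FALSE]
}

random_protein <- function(n, alphabet = c("A","C","D","E","F","G","H","I",
                                           "K","L","M","N","P","Q","R","S",
                                           "T","V","W","Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

# simulate two well-separated clades of protein sequences
sim_two_clades <- function(n_sites = 300, within = 0.02, between = 0.4,
                           seed = 1) {
  set.seed(seed)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  mutate <- function(s, p) {
    v <- strsplit(s, "")[[1]]
    idx <- which(runif(length(v)) < p)
    v[idx] <- sample(aa, length(idx), replace = TRUE)
    paste(v, collapse = "")
  }
  anc <- random_protein(n_sites, aa)
  ancA <- mutate(anc, between / 2); ancB <- mutate(anc, between / 2)
  c(a1 = mutate(ancA, within), a2 = mutate(ancA, within),
    a3 = mutate(ancA, within),
    b1 = mutate(ancB, within), b2 = mutate(ancB, within),
    b3 = mutate(ancB, within))
}
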