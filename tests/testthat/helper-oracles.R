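# Independent brute-force oracles used to cross-check the implementation.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at_pos <- function(seq, pos, base = NULL) {
  chars <- strsplit(seq, "")[[1]]
  if (is.null(base)) base <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1)
  chars[pos] <- base
  paste(chars, collapse = "")
}

# Gotoh global alignment by exhaustive dynamic programming; gap of length L
# costs go + ge * L.
dp_global_score <- function(a, b, match = 5, mismatch = -4, go = 10, ge = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) Ix[i, 1] <- -(go + ge * (i - 1))
  for (j in seq_len(m) + 1) Iy[1, j] <- -(go + ge * (j - 1))
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - go - ge, Ix[i - 1, j] - ge, Iy[i - 1, j] - go - ge)
      Iy[i, j] <- max(M[i, j - 1] - go - ge, Iy[i, j - 1] - ge, Ix[i, j - 1] - go - ge)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Connected components of the Levenshtein distance <= d graph (single
# linkage) by breadth-first search on the full pairwise distance matrix.
single_linkage_components <- function(seqs, d = 1) {
  n <- length(seqs)
  D <- utils::adist(seqs)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      i <- queue[1]
      queue <- queue[-1]
      nb <- which(D[i, ] <= d & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Exhaustive windowed-mean quality scan.
qc_keep_bruteforce <- function(scores, window = 50, min_mean = 20) {
  n <- length(scores)
  if (n <= window) return(mean(scores) >= min_mean)
  for (s in seq_len(n - window + 1)) {
    if (mean(scores[s:(s + window - 1)]) < min_mean) return(FALSE)
  }
  TRUE
}

# Direct IndVal statistic (max over groups of A * B) for one labeling.
indval_stat_direct <- function(X, g) {
  g <- as.factor(g)
  ks <- levels(g)
  stats <- matrix(0, length(ks), ncol(X))
  for (ki in seq_along(ks)) {
    ing <- g == ks[ki]
    for (j in seq_len(ncol(X))) {
      means <- vapply(ks, function(k2) mean(X[g == k2, j]), numeric(1))
      A <- if (sum(means) == 0) 0 else means[ki] / sum(means)
      B <- mean(X[ing, j] > 0)
      stats[ki, j] <- A * B
    }
  }
  apply(stats, 2, max)
}

# Expand an IUPAC string into every concrete ACGT realization.
iupac_expand <- function(x) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", M = c("A", "C"),
               R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
               Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
               H = c("A", "C", "T"), D = c("A", "G", "T"),
               B = c("C", "G", "T"), N = c("A", "C", "G", "T"))
  opts <- sets[strsplit(x, "")[[1]]]
  apply(expand.grid(opts, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

# Kruskal-Wallis H with tie correction from the direct rank formula.
kw_h_direct <- function(values, groups) {
  g <- as.factor(groups)
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Build a read pair covering `fragment` with reads of length `rl` from both
# ends (r2 as sequenced, i.e. reverse-complemented), constant phred `q`.
pair_from_fragment <- function(fragment, rl, q = 38) {
  flen <- nchar(fragment)
  tibble::tibble(
    read_id = "p1",
    seq1 = substr(fragment, 1, rl),
    qual1 = phred_string(rep(q, rl)),
    seq2 = dna_revcomp(substr(fragment, flen - rl + 1, flen)),
    qual2 = phred_string(rep(q, rl))
  )
}
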