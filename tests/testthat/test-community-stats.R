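make_comm <- function(m, samples = paste0("s", seq_len(nrow(m)))) {
  if (is.null(colnames(m))) colnames(m) <- paste0("otu", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample = samples), tibble::as_tibble(m))
}

test_that("abundance thresholding is strict and does not renormalize", {
  m <- matrix(c(0.0009, 0.001, 0.5, 0.4982, 0.0009, 0.0), 2, 3, byrow = TRUE)
  comm <- make_comm(m)
  out <- threshold_relative_abundance(comm, 0.001)
  v <- unname(as.matrix(out[, -1]))
  expect_equal(v[1, 1], 0)          # < 0.001 zeroed
  expect_equal(v[1, 2], 0.001)      # boundary kept (strict inequality)
  expect_equal(v[1, 3], 0.5)        # untouched, no renormalization
  expect_equal(sum(v[2, ]), 0.4982)
})

test_that("all-zero OTU columns after thresholding match a brute-force scan", {
  set.seed(51)
  m <- matrix(runif(200, 0, 0.003), 10, 20,
              dimnames = list(NULL, paste0("otu", 1:20)))
  comm <- make_comm(m)
  out <- threshold_relative_abundance(comm, 0.001)
  m2 <- m
  m2[m2 < 0.001] <- 0
  expect_equal(attr(out, "empty_otus"),
               colnames(m2)[colSums(m2) == 0])
  expect_equal(as.matrix(out[, -1]), m2, ignore_attr = TRUE)
})

test_that("log normalization matches log_b(x) + 1 with pre-division", {
  counts <- make_comm(matrix(c(0, 8, 2, 1), 2, 2, byrow = TRUE))
  out <- log_normalize(counts, base = 2)
  v <- unname(as.matrix(out[, -1]))
  expect_equal(v[1, 1], 0)          # zeros stay zero
  expect_equal(v[1, 2], 4)          # log2(8) + 1
  expect_equal(v[2, 2], 1)          # log2(1) + 1

  rel <- make_comm(matrix(c(0.001, 0.5, 0.008, 0.2), 2, 2, byrow = TRUE))
  vout <- unname(as.matrix(log_normalize(rel, base = 2)[, -1]))
  expect_equal(vout[1, 1], 1)       # min positive maps to 1 after pre-division
  expect_true(all(vout >= 0))
})

test_that("log normalization agrees with the vegan reference transform", {
  skip_if_not_installed("vegan")
  set.seed(52)
  m <- matrix(rpois(60, 15), 6, 10)
  ours <- as.matrix(log_normalize(make_comm(m), base = 2)[, -1])
  ref <- as.matrix(vegan::decostand(m, method = "log", logbase = 2))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("partial RDA decomposes inertia exactly", {
  set.seed(53)
  n <- 16
  md <- tibble::tibble(
    sample = paste0("s", 1:n),
    treatment = rep(c("grazed", "exclosed"), each = n / 2),
    date = rep(c("summer", "spring"), times = n / 2),
    site = rep(rep(c("SV1", "SV2"), each = 2), times = n / 4),
    ch4_rate = runif(n, 5, 120)
  )
  comm <- make_comm(matrix(rlnorm(n * 12), n, 12), md$sample)
  fit <- partial_rda(comm, md, ~ treatment * date + ch4_rate, ~ site)
  inr <- fit$inertia
  expect_equal(inr$conditioned + inr$constrained + inr$unconstrained,
               inr$total, tolerance = 1e-9)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_true(all(fit$eigenvalues >= 0))
  expect_equal(sum(fit$terms$variance), inr$constrained, tolerance = 1e-9)
})

test_that("partial RDA matches the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(54)
  n <- 12
  md <- data.frame(
    sample = paste0("s", 1:n),
    treatment = rep(c("g", "e"), each = 6),
    site = rep(c("A", "B"), times = 6),
    ch4_rate = runif(n, 10, 90)
  )
  Y <- matrix(rpois(n * 6, 20), n, 6)
  colnames(Y) <- paste0("o", 1:6)
  fit <- partial_rda(make_comm(Y, md$sample), tibble::as_tibble(md),
                     ~ treatment + ch4_rate, ~ site)
  vfit <- vegan::rda(Y ~ treatment + ch4_rate + Condition(site), data = md)
  expect_equal(fit$inertia$constrained, vfit$CCA$tot.chi, tolerance = 1e-9)
  expect_equal(fit$inertia$conditioned, vfit$pCCA$tot.chi, tolerance = 1e-9)
  expect_equal(fit$inertia$unconstrained, vfit$CA$tot.chi, tolerance = 1e-9)
  expect_equal(unname(fit$eigenvalues), unname(vfit$CCA$eig), tolerance = 1e-9)
})

test_that("degenerate designs are handled as specified", {
  set.seed(55)
  n <- 10
  md <- tibble::tibble(sample = paste0("s", 1:n),
                       x = rep(1, n),
                       g = rep(c("a", "b"), each = n / 2))
  comm <- make_comm(matrix(rnorm(n * 4), n, 4), md$sample)
  constant <- partial_rda(comm, md, ~ x, condition = NULL)
  expect_equal(constant$inertia$constrained, 0)

  # noiseless group structure: Y equals its group means
  Y <- matrix(rep(c(1, 5), each = n / 2), n, 3) +
    matrix(rep(c(0, 2, 4), each = n), n, 3)
  fit <- partial_rda(make_comm(Y, md$sample), md, ~ g, condition = NULL)
  expect_equal(fit$inertia$unconstrained, 0, tolerance = 1e-12)
  expect_equal(unname(fit$eigenvalues[1]), fit$inertia$constrained,
               tolerance = 1e-12)

  md$alias <- ifelse(md$g == "a", 1, 0)   # perfectly collinear with g
  expect_error(
    partial_rda(make_comm(matrix(rnorm(n * 4), n, 4), md$sample),
                md, ~ g + alias, condition = NULL),
    "aliased"
  )
})

test_that("permutation tests bound p below and detect planted effects", {
  set.seed(56)
  n <- 16
  md <- tibble::tibble(
    sample = paste0("s", 1:n),
    treatment = rep(c("g", "e"), each = n / 2),
    site = rep(c("A", "B"), times = n / 2)
  )
  shift <- ifelse(md$treatment == "g", 0, 6)
  Y <- matrix(rnorm(n * 8, 0, 0.3), n, 8) + shift
  fit <- partial_rda(make_comm(Y, md$sample), md, ~ treatment, ~ site)
  res <- rda_permutation_test(fit, permutations = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)            # minimum attainable
  expect_error(rda_permutation_test(fit, permutations = 0), ">= 1")

  ax <- rda_permutation_test(fit, permutations = 99, scope = "axis", seed = 2)
  expect_true(all(ax$p_value >= 1 / 100))
  mod <- rda_permutation_test(fit, permutations = 99, scope = "model", seed = 3)
  expect_lte(mod$p_value, 0.05)
})

test_that("indval reproduces hand-computed specificity and fidelity", {
  comm <- make_comm(matrix(c(4, 4, 0, 0), 4, 1), paste0("s", 1:4))
  g <- c("G1", "G1", "G2", "G2")
  res <- indval(comm, g, permutations = 199, seed = 1)
  expect_equal(res$group, "G1")
  expect_equal(res$A, 1)
  expect_equal(res$B, 1)
  expect_equal(res$indval, 1)

  comm2 <- make_comm(matrix(c(4, 0, 4, 0), 4, 1), paste0("s", 1:4))
  res2 <- indval(comm2, g, permutations = 199, seed = 1)
  expect_equal(res2$A, 0.5)
  expect_equal(res2$B, 0.5)
  expect_equal(res2$indval, 0.25)
})

test_that("indval permutation p approximates exhaustive enumeration at n=4", {
  X <- matrix(c(5, 4, 0, 1, 2, 2, 2, 2), 4, 2)
  colnames(X) <- c("ind", "flat")
  g <- c("G1", "G1", "G2", "G2")
  obs <- indval_stat_direct(X, g)
  labelings <- combn(4, 2)
  enum <- apply(labelings, 2, function(ix) {
    gg <- rep("G2", 4); gg[ix] <- "G1"
    indval_stat_direct(X, gg)
  })
  # probability that a uniformly drawn relabeling strictly exceeds the
  # observed statistic, from the exhaustive arrangement distribution
  pi_enum <- colMeans(t(enum) > matrix(obs, ncol(labelings), 2, byrow = TRUE))
  m <- 9999
  p_expect <- (1 + m * pi_enum) / (1 + m)
  # a permutation-invariant statistic carries no evidence: p reported as 1
  degenerate <- apply(t(enum), 2, function(s) all(s == s[1])) & pi_enum == 0
  p_expect[degenerate & abs(enum[, 1] - obs) < 1e-12] <- 1
  res <- indval(make_comm(X, paste0("s", 1:4)), g, permutations = m, seed = 2)
  expect_lt(max(abs(res$p_value - p_expect)), 0.03)
})

test_that("indval is invariant to rescaling one sample's sequencing depth", {
  set.seed(57)
  counts <- matrix(rpois(8 * 6, 30), 8, 6)
  g <- rep(c("a", "b"), each = 4)
  comm1 <- relative_abundance(make_comm(counts))
  counts2 <- counts
  counts2[3, ] <- counts2[3, ] * 5        # deeper sequencing of one sample
  comm2 <- relative_abundance(make_comm(counts2))
  r1 <- indval(comm1, g, permutations = 99, seed = 9)
  r2 <- indval(comm2, g, permutations = 99, seed = 9)
  expect_equal(r1$indval, r2$indval)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("degenerate indval inputs do not produce spurious bioindicators", {
  comm <- make_comm(matrix(c(0, 0, 0, 0, 3, 3, 3, 3), 4, 2))
  res <- indval(comm, c("a", "a", "b", "b"), permutations = 499, seed = 3)
  expect_equal(res$p_value, c(1, 1))      # all-zero and constant columns
  expect_false(any(res$bioindicator))
  expect_error(indval(comm, c("a", "a", "a", "a"), permutations = 9), "two groups")
})

test_that("Kruskal-Wallis matches hand-ranked and direct-formula values", {
  sep <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(sep$statistic, 3.857, tolerance = 1e-3)
  expect_equal(sep$df, 1)

  const <- kruskal_wallis(rep(7, 6), rep(c("a", "b"), each = 3))
  expect_equal(const$statistic, 0)

  set.seed(58)
  for (i in 1:10) {
    v <- sample(1:8, 15, replace = TRUE)      # ties present
    g <- sample(c("a", "b", "c"), 15, replace = TRUE)
    if (length(unique(g)) < 2 || length(unique(v)) < 2) next
    expect_equal(kruskal_wallis(v, g)$statistic, kw_h_direct(v, g),
                 tolerance = 1e-10)
  }
})
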