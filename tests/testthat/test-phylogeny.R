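make_aln <- function(seqs, taxa = paste0("t", seq_along(seqs))) {
  tibble::tibble(taxon = taxa, seq = seqs)
}

test_that("window selection slices columns and validates bounds", {
  set.seed(61)
  aln <- make_aln(replicate(3, random_dna(500)))
  full <- select_window(aln, 1, 500)
  expect_equal(full, aln)
  win <- select_window(aln, 1, 440)
  expect_equal(unique(nchar(win$seq)), 440)
  expect_equal(win$taxon, aln$taxon)
  expect_error(select_window(aln, 100, 440), "past the alignment")
})

test_that("Jukes-Cantor distances follow the closed form", {
  set.seed(62)
  a <- random_dna(100)
  ident <- jc_distance(make_aln(c(a, a)))
  expect_equal(as.vector(ident), 0)

  # exactly 30 mismatches over 100 compared columns
  b <- a
  for (p in 1:30) b <- mutate_at_pos(b, p)
  d <- as.vector(jc_distance(make_aln(c(a, b))))
  expect_equal(d, -0.75 * log(0.6), tolerance = 1e-9)
  expect_equal(d, 0.38312, tolerance = 1e-4)
})

test_that("pairwise deletion and the p >= 0.75 guard work", {
  aln <- make_aln(c("ACGT-ACGTN", "ACGTTAC-TA"))
  # comparable columns: 1,2,3,4,6,7 (gap/N columns dropped); all match except 10th excluded
  d <- as.vector(jc_distance(aln))
  expect_equal(d, 0)

  set.seed(63)
  a <- random_dna(60)
  far <- vapply(strsplit(a, "")[[1]], function(x)
    setdiff(c("A", "C", "G", "T"), x)[1], character(1))
  expect_error(jc_distance(make_aln(c(a, paste(far, collapse = "")))),
               "undefined")
  expect_error(jc_distance(make_aln("ACGT")), "two taxa")
})

test_that("mismatch proportions equal a brute-force column scan and ape", {
  skip_if_not_installed("ape")
  set.seed(64)
  seqs <- replicate(5, random_dna(200))
  for (k in 2:5) seqs[k] <- local({
    s <- seqs[1]
    for (i in sample(200, 20)) s <- mutate_at_pos(s, i)
    s
  })
  aln <- make_aln(seqs)
  ours <- as.matrix(jc_distance(aln))
  # brute-force column scan for one pair
  x <- strsplit(seqs[1], "")[[1]]; y <- strsplit(seqs[2], "")[[1]]
  p <- mean(x != y)
  expect_equal(ours[1, 2], -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(seqs, "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-9)
})

test_that("JC distance is strictly increasing in p", {
  p <- seq(0.01, 0.74, by = 0.01)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(d) > 0))
})

test_that("three-taxon neighbor joining gives the three-point branch lengths", {
  D <- matrix(c(0, 0.2, 0.3, 0.2, 0, 0.4, 0.3, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(as.dist(D))
  tip_edge <- function(tree, tip) {
    tree$edge.length[tree$edge[, 2] == match(tip, tree$tip.label)]
  }
  expect_equal(tip_edge(tree, "A"), 0.05, tolerance = 1e-12)
  expect_equal(tip_edge(tree, "B"), 0.15, tolerance = 1e-12)
  expect_equal(tip_edge(tree, "C"), 0.25, tolerance = 1e-12)
  expect_error(nj_tree(dist(c(1, 2))), "three taxa")
})

test_that("neighbor joining recovers additive five-taxon distances exactly", {
  skip_if_not_installed("ape")
  ref <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.1,E:0.3);")
  D <- cophenetic(ref)
  tree <- nj_tree(as.dist(D))
  expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
  expect_equal(unname(cophenetic(tree)[rownames(D), colnames(D)]), unname(D),
               tolerance = 1e-10)
})

test_that("clean clade signal yields full bootstrap support", {
  set.seed(65)
  clade <- function(b) vapply(1:2, function(i) {
    s <- b
    for (p in sample(300, 2)) s <- mutate_at_pos(s, p)
    s
  }, character(1))
  ancestor <- random_dna(300)
  diverge <- function(b, k) {
    for (p in sample(300, k)) b <- mutate_at_pos(b, p)
    b
  }
  aln <- make_aln(c(clade(diverge(ancestor, 60)), clade(diverge(ancestor, 60)),
                    clade(diverge(ancestor, 60))))
  tree <- suppressWarnings(bootstrap_support(aln, replicates = 100, seed = 7))
  # three widely separated cherries: every real bipartition at full support
  expect_gte(sum(tree$node.label >= 95), 3)
  expect_true(all(tree$node.label >= 0 & tree$node.label <= 100))
})

test_that("bootstrap support is seed-deterministic and order-invariant", {
  set.seed(66)
  # well-resolved signal (nested divergence), so no near-tie star regions
  ancestor <- random_dna(200)
  diverge <- function(b, k) {
    for (p in sample(200, k)) b <- mutate_at_pos(b, p)
    b
  }
  a <- diverge(ancestor, 40)
  b <- diverge(ancestor, 40)
  seqs <- c(diverge(a, 6), diverge(a, 6), diverge(b, 6), diverge(b, 20),
            diverge(ancestor, 60))
  aln <- make_aln(seqs)
  t1 <- suppressWarnings(bootstrap_support(aln, replicates = 50, seed = 3))
  t2 <- suppressWarnings(bootstrap_support(aln, replicates = 50, seed = 3))
  expect_equal(t1$node.label, t2$node.label)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  perm <- sample(nrow(aln))
  t3 <- suppressWarnings(bootstrap_support(aln[perm, ], replicates = 50, seed = 3))
  support_by_clade <- function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    sets <- vapply(pp, function(ix) paste(sort(labs[ix]), collapse = ","),
                   character(1))
    setNames(tr$node.label, sets)
  }
  s1 <- support_by_clade(t1)
  s3 <- support_by_clade(t3)
  shared <- intersect(names(s1), names(s3))
  expect_gt(length(shared), 0)
  expect_equal(s1[shared], s3[shared])
})

test_that("negative branch lengths are clamped with a warning", {
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  D[1, 2] <- D[2, 1] <- 0.1   # force an ill-conditioned configuration
  tree <- suppressWarnings(nj_tree(as.dist(D)))
  expect_true(all(tree$edge.length >= 0))
})
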