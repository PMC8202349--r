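test_that("dereplication collapses identical reads with per-sample counts", {
  reads <- tibble::tibble(
    sample = c("s1", "s1", "s2"),
    seq = rep("ACGT", 3)
  )
  amp <- dereplicate(reads)
  expect_equal(nrow(amp), 2)                       # two (seq, sample) cells
  expect_equal(amplicon_totals(amp)$total, 3)
  distinct <- dereplicate(tibble::tibble(sample = "s1", seq = c("AA", "CC", "GG")))
  expect_equal(amplicon_totals(distinct)$total, rep(1, 3))
})

test_that("dereplication totals equal brute-force multiset counting", {
  set.seed(21)
  pool <- replicate(6, random_dna(12))
  reads <- tibble::tibble(
    sample = sample(c("s1", "s2", "s3"), 300, replace = TRUE),
    seq = sample(pool, 300, replace = TRUE)
  )
  tot <- amplicon_totals(dereplicate(reads))
  direct <- table(reads$seq)
  expect_equal(sum(tot$total), 300)
  expect_equal(tot$total[match(names(direct), tot$seq)], unname(as.integer(direct)))
  # ordering: decreasing total, ties lexicographic
  expect_true(all(diff(tot$total) <= 0))
})

test_that("a constructed two-parent crossover is flagged as chimeric", {
  set.seed(22)
  pa <- random_dna(400)
  pb <- random_dna(400)
  query <- paste0(substr(pa, 1, 200), substr(pb, 201, 400))
  amp <- tibble::tibble(
    sample = "s1",
    seq = c(rep(pa, 10), rep(pb, 10), rep(query, 2))
  ) |> dereplicate()
  res <- detect_chimeras(amp, mode = "denovo")
  expect_true(res$chimera[res$seq == query])
  expect_false(any(res$chimera[res$seq %in% c(pa, pb)]))
})

test_that("database members are never flagged in reference mode", {
  set.seed(23)
  db <- tibble::tibble(id = c("a", "b", "c"),
                       taxonomy = "x;y",
                       seq = replicate(3, random_dna(300)))
  amp <- tibble::tibble(sample = "s1", seq = rep(db$seq, c(5, 3, 1))) |>
    dereplicate()
  res <- detect_chimeras(amp, mode = "reference", db = db)
  expect_false(any(res$chimera))
  expect_error(detect_chimeras(amp, mode = "reference"), "requires")
})

test_that("abundance skew gates de novo chimera parents", {
  set.seed(24)
  pa <- random_dna(400)
  pb <- random_dna(400)
  query <- paste0(substr(pa, 1, 200), substr(pb, 201, 400))
  equal_ab <- tibble::tibble(
    sample = "s1", seq = c(rep(pa, 2), rep(pb, 2), rep(query, 2))
  ) |> dereplicate()
  res <- detect_chimeras(equal_ab, min_parent_skew = 2, mode = "denovo")
  expect_false(res$chimera[res$seq == query])   # parents not 2x more abundant
})

test_that("swarm clustering follows abundance-seeded single linkage", {
  set.seed(25)
  s1 <- random_dna(60)
  s2 <- mutate_at_pos(s1, 10)
  s3 <- mutate_at_pos(s2, 40)
  amp <- tibble::tibble(sample = "s1", seq = c(rep(s1, 9), rep(s2, 3), s3)) |>
    dereplicate()
  otus <- cluster_swarm(amp, d = 1)
  expect_equal(length(unique(otus$otu_id)), 1)
  expect_equal(unique(otus$representative), s1)
  expect_equal(sum(otus$total), 13)

  far <- mutate_at_pos(mutate_at_pos(s1, 5), 25)  # distance 2, no intermediate
  two <- dereplicate(tibble::tibble(sample = "s1", seq = c(s1, far)))
  expect_equal(length(unique(cluster_swarm(two, d = 1)$otu_id)), 2)
})

test_that("swarm partition equals brute-force single-linkage components", {
  set.seed(26)
  for (trial in 1:25) {
    base <- replicate(sample(2:5, 1), random_dna(25))
    seqs <- unique(unlist(lapply(base, function(b) {
      c(b, replicate(sample(1:6, 1),
                     mutate_at_pos(b, sample(nchar(b), 1))))
    })))
    amp <- dereplicate(tibble::tibble(
      sample = "s1", seq = sample(rep(seqs, sample(1:4, length(seqs), TRUE)))
    ))
    otus <- cluster_swarm(amp, d = 1)
    comp <- single_linkage_components(otus$seq, d = 1)
    # identical partitions: same equivalence classes
    expect_equal(length(unique(otus$otu_id)), length(unique(comp)))
    expect_true(all(tapply(comp, otus$otu_id, function(x) length(unique(x))) == 1))
    # partition property: every amplicon appears exactly once
    expect_setequal(otus$seq, amplicon_totals(amp)$seq)
    expect_equal(anyDuplicated(otus$seq), 0)
  }
})

test_that("reading-frame validation applies the rules in order", {
  spec <- frame_spec("mb661")
  good <- sim_reference_db(n_genera = 1, n_per_genus = 1, seed = 31)$seq[1]
  expect_true(validate_reading_frame(good, spec)$valid)

  plus_one <- paste0(good, "A")
  expect_equal(validate_reading_frame(plus_one, spec)$reason,
               "not divisible by three")

  stopmid <- paste0(substr(good, 1, 150), "TAA",
                    substr(good, 154, nchar(good)))
  expect_equal(validate_reading_frame(stopmid, spec)$reason, "stop codon")

  badstart <- paste0("AAA", substr(good, 4, nchar(good)))
  expect_equal(validate_reading_frame(badstart, spec)$reason,
               "wrong first codon")

  ambig <- paste0(substr(good, 1, 100), "N", substr(good, 102, nchar(good)))
  expect_equal(validate_reading_frame(ambig, spec)$reason, "ambiguous")

  expect_error(validate_reading_frame(good, frame_spec("V3V4")), "frame-checked")
})

test_that("OTU length and taxonomy filters follow the printed windows", {
  spec <- frame_spec("mb661")
  otus <- tibble::tibble(
    otu_id = c("a", "b", "c"),
    representative = c(random_dna(480), random_dna(468), random_dna(470)),
    taxonomy = c("Bacteria;Gammaproteobacteria;Methylococcales;Methylobacter",
                 "Bacteria;Gammaproteobacteria;Methylococcales;Methylobacter",
                 "Bacteria;Cyanobacteria;Chloroplast;x")
  )
  out <- filter_otus(otus, spec)
  expect_equal(out$retained, c(FALSE, TRUE, FALSE))
  expect_equal(out$reason[1], "length outside window")
  expect_equal(out$reason[3], "excluded taxonomy")

  v34 <- filter_otus(
    tibble::tibble(otu_id = "d", representative = random_dna(400),
                   taxonomy = "Archaea;Euryarchaeota"),
    frame_spec("V3V4")
  )
  expect_false(v34$retained)
})

test_that("the OTU table conserves counts and block structure", {
  one <- dereplicate(tibble::tibble(sample = rep("s1", 7), seq = "ACGTACG"))
  memb <- cluster_swarm(one)
  tab <- build_otu_table(memb, one)
  expect_equal(dim(tab), c(1, 2))
  expect_equal(tab[[2]], 7)

  set.seed(27)
  sa <- random_dna(40); sb <- random_dna(40)
  disjoint <- dereplicate(tibble::tibble(
    sample = rep(c("s1", "s2"), c(4, 6)), seq = rep(c(sa, sb), c(4, 6))
  ))
  tab2 <- build_otu_table(cluster_swarm(disjoint), disjoint)
  m <- as.matrix(tab2[, -1])
  expect_equal(sort(as.vector(m)), c(0, 0, 4, 6))
  expect_equal(sum(m), 10)
})
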