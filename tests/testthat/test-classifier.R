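test_that("PML computation reproduces the hand-worked fixture", {
  wx <- worked_example()
  res <- compute_pmls(wx$idx, "ACG", strategy = "true")
  expect_equal(res$pml, c(2L, 1L, 0L))
  # the two scoring positions both land in the A-run (run 3) after LF
  expect_equal(res$visited[1:2], c(3L, 3L))
  expect_equal(score_read(res, wx$idx), c(2L, 2L))
  expect_equal(average_pml(res), 1.0)
})

test_that("characters absent from the BWT give zero PML and no score", {
  wx <- worked_example()
  res <- compute_pmls(wx$idx, "TTTT")
  expect_equal(res$pml, rep(0L, 4))
  expect_true(all(is.na(res$visited)))
  expect_equal(score_read(res, wx$idx), c(0L, 0L))
  # non-ACGT characters behave the same way
  resn <- compute_pmls(wx$idx, "ANG")
  expect_equal(resn$pml[2], 0L)
})

test_that("PML never exceeds the matching statistic, under all strategies", {
  set.seed(202)
  strategies <- c("true", "mid-run", "always-up")
  for (rep in 1:170) {
    dc <- random_text_collection(n_docs = sample(1:3, 1),
                                 len_range = c(20, 120))
    tx <- build_concat(dc)
    idx <- build_index(dc)
    m <- sample(10:60, 1)
    read <- paste(sample(c("A", "C", "G", "T"), m, replace = TRUE),
                  collapse = "")
    ms <- brute_matching_statistics(tx$S, read)
    for (strategy in strategies) {
      pml <- compute_pmls(idx, read, strategy)$pml
      expect_true(all(pml <= ms))
      expect_true(all(pml >= 0L))
      # a length can grow by at most one per leftward step
      expect_true(all(pml[-m] <= pml[-1] + 1L))
    }
  }
})

test_that("per-position score mass equals the color size where PML > 0", {
  set.seed(303)
  for (rep in 1:10) {
    dc <- random_text_collection(n_docs = 3, len_range = c(30, 150))
    idx <- build_index(dc)
    read <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                  collapse = "")
    res <- compute_pmls(idx, read)
    scores <- score_read(res, idx)
    sel <- res$pml > 0 & !is.na(res$visited)
    expected_mass <- sum(lengths(
      idx$colors$colors[idx$colors$run_color_ids[res$visited[sel] + 1L] + 1L]))
    expect_equal(sum(scores), expected_mass)
  }
})

test_that("identical inputs give identical outputs for every strategy", {
  set.seed(404)
  dc <- random_text_collection(n_docs = 3)
  idx <- build_index(dc)
  read <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                collapse = "")
  for (strategy in c("true", "mid-run", "always-up")) {
    a <- compute_pmls(idx, read, strategy)
    b <- compute_pmls(idx, read, strategy)
    expect_identical(a$pml, b$pml)
    expect_identical(a$visited, b$visited)
  }
})

test_that("average PML is the PML sum over the read length", {
  expect_equal(average_pml(c(2L, 1L, 0L)), 1.0)
  expect_equal(average_pml(rep(0L, 10)), 0.0)
  expect_error(average_pml(integer(0)), "empty")
})

test_that("cutoff calibration uses the nearest-rank percentile", {
  calib <- calibrate_cutoff(seq(0.01, 1.00, by = 0.01), percentile = 95)
  expect_equal(calib$cutoff, 0.95)
  expect_equal(calib$n_null, 100L)
  expect_equal(calibrate_cutoff(rep(0.3, 20))$cutoff, 0.3)
  expect_error(calibrate_cutoff(rep(0.3, 19)), "at least 20")
})

test_that("classification applies the gate, 95% ratio and LCA rules", {
  tree <- tiny_taxonomy()
  doc_taxon <- c(4L, 5L, 6L)  # docs 0..2 -> species s1 (g1), s2 (g1), s3 (g2)

  # 96 >= 0.95 * 100: report both, assign the genus LCA
  cls <- classify_read(c(100L, 96L, 50L), avg_pml = 5, calibration = 1,
                       tree = tree, doc_taxon = doc_taxon)
  expect_equal(cls$status, "C")
  expect_equal(cls$reported_docs, c(0L, 1L))
  expect_equal(cls$assigned_taxon, 2L)  # lca(s1, s2) = g1
  expect_equal(cls$assigned_rank, "genus")

  # 94 < 95: only Dbest, assigned its own species
  cls2 <- classify_read(c(100L, 94L, 0L), avg_pml = 5, calibration = 1,
                        tree = tree, doc_taxon = doc_taxon)
  expect_equal(cls2$reported_docs, 0L)
  expect_equal(cls2$assigned_taxon, 4L)
  expect_equal(cls2$assigned_rank, "species")

  # gate: below-cutoff average PML is unclassified regardless of scores
  cls3 <- classify_read(c(100L, 0L, 0L), avg_pml = 0.4, calibration = 0.9,
                        tree = tree, doc_taxon = doc_taxon)
  expect_equal(cls3$status, "U")
  expect_equal(cls3$reported_docs, integer(0))

  # all-zero scores with the gate passed: degenerate, unclassified
  cls4 <- classify_read(c(0L, 0L, 0L), avg_pml = 5, calibration = 1)
  expect_equal(cls4$status, "U")

  # ties at the top: smallest doc id is Dbest, tied doc counts as secondary
  cls5 <- classify_read(c(80L, 80L, 10L), avg_pml = 5, calibration = NULL,
                        tree = tree, doc_taxon = doc_taxon)
  expect_equal(cls5$reported_docs, c(0L, 1L))

  # max_secondary limits co-reported documents
  cls6 <- classify_read(c(100L, 99L, 98L), avg_pml = 5, calibration = NULL,
                        max_secondary = 1L)
  expect_equal(length(cls6$reported_docs), 2L)
})

test_that("reads from an indexed genome far outscore random reads on average PML", {
  set.seed(505)
  pg <- simulate_pangenome(n_species = 3, genomes_per_species = 3,
                           genome_length = 4000, seed = 11)
  idx <- build_index(pg$collection, taxonomy = pg$taxonomy)
  src <- heldout_sources(pg)
  pos <- simulate_reads(src, n_reads = 20, length_mean = 1200,
                        length_sd = 100, seed = 12)
  rand <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
          collapse = ""), character(1))
  avg_pos <- average_pmls(idx, pos$reads)
  avg_rand <- average_pmls(idx, rand)
  expect_gt(mean(avg_pos), 2 * mean(avg_rand))
})

test_that("the true document is recovered for most reads on an easy pangenome", {
  pg <- simulate_pangenome(n_species = 5, genomes_per_species = 3,
                           genome_length = 8000,
                           inter_divergence = 0.10, intra_divergence = 0.01,
                           seed = 21)
  idx <- build_index(pg$collection, taxonomy = pg$taxonomy)
  sim <- simulate_reads(heldout_sources(pg), n_reads = 60,
                        length_mean = 1500, length_sd = 200,
                        sub_rate = 0.03, ins_rate = 0.02, del_rate = 0.02,
                        seed = 22)
  res <- classify_reads(idx, sim$reads)
  best <- as.integer(sub(",.*", "", res$reported_docs))
  expect_gte(mean(best == sim$truth$doc_id), 0.9)
})
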