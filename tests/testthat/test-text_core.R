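test_that("concatenation appends a single terminator and records boundaries", {
  wx <- worked_example()
  expect_equal(wx$tx$S, "ACAACG$")
  expect_equal(wx$tx$n, 7L)
  expect_equal(wx$tx$doc_starts, c(0L, 3L))
  expect_equal(wx$tx$doc_lens, c(3L, 3L))
  expect_equal(lengths(regmatches(wx$tx$S, gregexpr("\\$", wx$tx$S))),
               1L, ignore_attr = TRUE)

  single <- build_concat(document_collection(list(D1 = "A")))
  expect_equal(single$S, "A$")
  expect_equal(single$n, 2L)
})

test_that("non-ACGT stretches split a sequence into pieces of the same document", {
  dc <- document_collection(list(D1 = "ACNNGT"))
  expect_equal(dc$sequences$D1, c("AC", "GT"))
  dc2 <- document_collection(list(D1 = c("acgt", "NNN", "ttNaa")))
  expect_equal(dc2$sequences$D1, c("ACGT", "TT", "AA"))
  expect_error(document_collection(list(D1 = "NNNN")), "sanitization")
  expect_error(document_collection(list()), "nonempty")
})

test_that("suffix structures match the worked fixture and the rotation-sort oracle", {
  wx <- worked_example()
  expect_equal(wx$st$sa, c(6L, 2L, 0L, 3L, 1L, 4L, 5L))
  expect_equal(wx$st$bwt, "GC$AAAC")
  expect_equal(wx$st$lcp, c(0L, 0L, 1L, 2L, 0L, 1L, 0L))
  # terminator suffix attributed to the last document
  expect_equal(wx$st$da, c(1L, 0L, 0L, 1L, 0L, 1L, 1L))

  two <- build_suffix_structures(build_concat(document_collection(list(D1 = "A"))))
  expect_equal(two$bwt, "A$")

  set.seed(42)
  for (rep in 1:25) {
    dc <- random_text_collection(n_docs = sample(1:4, 1))
    tx <- build_concat(dc)
    st <- build_suffix_structures(tx)
    oracle <- brute_bwt(tx$S)
    expect_equal(st$sa, oracle$sa)
    expect_equal(st$bwt, oracle$bwt)
    expect_equal(st$lcp, brute_lcp(tx$S))
    # document array: per-position lookup over SA
    nD <- length(tx$doc_starts)
    da_oracle <- vapply(st$sa, function(p)
      min(sum(tx$doc_starts <= p), nD) - 1L, integer(1))
    expect_equal(st$da, da_oracle)
  }
})

test_that("inverse BWT reconstructs the text on random multi-document texts", {
  set.seed(7)
  for (rep in 1:50) {
    dc <- random_text_collection(n_docs = sample(1:4, 1),
                                 len_range = c(10, 400))
    tx <- build_concat(dc)
    st <- build_suffix_structures(tx)
    expect_identical(invert_bwt(st$bwt_codes), tx$S)
  }
})

test_that("runs are maximal equal-letter and cover the BWT", {
  wx <- worked_example()
  expect_equal(wx$rs$r, 5L)
  expect_equal(wx$rs$chars, c("G", "C", "$", "A", "C"))
  expect_equal(wx$rs$lengths, c(1L, 1L, 1L, 3L, 1L))

  expect_equal(find_runs("AAAA")$r, 1L)
  expect_equal(find_runs("AAAA")$lengths, 4L)
  expect_equal(find_runs("ACGT")$r, 4L)

  set.seed(11)
  for (rep in 1:20) {
    tx <- build_concat(random_text_collection())
    st <- build_suffix_structures(tx)
    rs <- find_runs(st$bwt_codes)
    expect_equal(sum(rs$lengths), tx$n)
    expect_true(all(rs$codes[-1] != rs$codes[-rs$r]))
    expect_lte(rs$r, tx$n)
  }
})

test_that("thresholds follow the min-LCP rule with absent-side clamps", {
  wx <- worked_example()
  th <- compute_thresholds(wx$rs, wx$st)
  # run of A at flat 3..5: prev C at 1, next C at 6, first min LCP at flat 4
  expect_equal(th[4, "C"], 1L, ignore_attr = TRUE)
  # G exists only above the A run -> always up (threshold = run length)
  expect_equal(th[4, "G"], 3L, ignore_attr = TRUE)
  # C exists only below the G run at flat 0 -> always down (threshold 0)
  expect_equal(th[1, "C"], 0L, ignore_attr = TRUE)
  # the run's own character has no threshold
  expect_true(is.na(th[4, "A"]))
})

test_that("threshold direction maximizes the preserved LCP on small texts", {
  # brute check: for each run, character and offset, the side chosen by the
  # threshold reaches an occurrence with LCP >= the other side's
  set.seed(23)
  for (rep in 1:15) {
    tx <- build_concat(random_text_collection(n_docs = 2,
                                              len_range = c(10, 60)))
    st <- build_suffix_structures(tx)
    rs <- find_runs(st$bwt_codes)
    th <- compute_thresholds(rs, st)
    n <- tx$n
    bwt <- strsplit(st$bwt, "", fixed = TRUE)[[1]]
    range_min <- function(a, b) # min LCP over flat lcp positions a..b (1-based)
      if (a > b) Inf else min(st$lcp[a:b])
    for (i in seq_len(rs$r)) {
      for (cc in c("A", "C", "G", "T")) {
        if (rs$chars[i] == cc) next
        occ <- which(bwt == cc) - 1L       # flat, 0-based
        lo <- rs$starts[i]; hi <- lo + rs$lengths[i] - 1L
        above <- occ[occ < lo]; below <- occ[occ > hi]
        if (length(above) == 0 || length(below) == 0) next
        pa <- max(above); pb <- min(below)
        for (j in 0:(rs$lengths[i] - 1L)) {
          p <- lo + j
          up_lcp <- range_min(pa + 2L, p + 1L)
          down_lcp <- range_min(p + 2L, pb + 1L)
          if (j < th[i, match(cc, c("A", "C", "G", "T"))])
            expect_gte(up_lcp, down_lcp)
          else
            expect_gte(down_lcp, up_lcp)
        }
      }
    }
  }
})

test_that("shared LCP of a run is the min interior LCP (suffix length for singletons)", {
  wx <- worked_example()
  # run of A at flat 3..5: min(LCP[4], LCP[5]) = 0
  expect_equal(shared_lcp(3, wx$rs, wx$st), 0L)
  # length-1 runs: suffix length, e.g. run 0 is the 'G' row of suffix "$"
  expect_equal(shared_lcp(0, wx$rs, wx$st), wx$st$n - wx$st$sa[1])
  # a 2-row run equals the pairwise LCP of its suffixes
  tx <- build_concat(document_collection(list(D1 = "ACC", D2 = "TCC")))
  st <- build_suffix_structures(tx)
  rs <- find_runs(st$bwt_codes)
  lcp_o <- brute_lcp(tx$S)
  for (i in which(rs$lengths == 2L)) {
    s <- rs$starts[i]
    expect_equal(shared_lcp(i - 1L, rs, st), lcp_o[s + 2L])
  }
})
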