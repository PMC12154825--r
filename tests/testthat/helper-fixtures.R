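# Shared small fixtures and independent mini-oracles used across test files.

# the worked two-document example: D1="ACA", D2="ACG" -> S="ACAACG$"
worked_example <- function() {
  dc <- document_collection(list(D1 = "ACA", D2 = "ACG"))
  tx <- build_concat(dc)
  st <- build_suffix_structures(tx)
  rs <- find_runs(st$bwt_codes)
  list(dc = dc, tx = tx, st = st, rs = rs,
       mt = build_move_table(rs, st),
       idx = build_index(dc, keep_structures = TRUE))
}

random_text_collection <- function(n_docs = 3, len_range = c(20, 200)) {
  docs <- lapply(seq_len(n_docs), function(d)
    paste(sample(c("A", "C", "G", "T"),
                 sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = ""))
  names(docs) <- paste0("D", seq_len(n_docs))
  document_collection(docs)
}

# rank-based LF oracle: LF[i] = C[bwt[i]] + rank of bwt[i] at i (0-based)
rank_lf <- function(bwt_codes) {
  n <- length(bwt_codes)
  counts <- tabulate(bwt_codes + 1L, nbins = 5L)
  Carr <- c(0L, cumsum(counts)[-5L])
  lf <- integer(n)
  seen <- integer(5)
  for (i in seq_len(n)) {
    cd <- bwt_codes[i] + 1L
    lf[i] <- Carr[cd] + seen[cd]
    seen[cd] <- seen[cd] + 1L
  }
  lf
}

# inverse BWT: reconstruct the text by repeated LF from the terminator row
invert_bwt <- function(bwt) {
  codes <- if (is.character(bwt)) {
    match(strsplit(bwt, "", fixed = TRUE)[[1]], c("$", "A", "C", "G", "T")) - 1L
  } else bwt
  n <- length(codes)
  lf <- rank_lf(codes)
  out <- character(n)
  out[n] <- "$"
  # row 0 is the '$'-first rotation; its BWT char is the text's last real
  # character, and LF walks one text position left at a time
  pos <- 1L
  for (k in (n - 1):1) {
    out[k] <- c("$", "A", "C", "G", "T")[codes[pos] + 1L]
    pos <- lf[pos] + 1L
  }
  paste(out, collapse = "")
}

# pairwise-LCP oracle from the sorted suffixes
brute_lcp <- function(S) {
  n <- nchar(S)
  sa <- brute_bwt(S)$sa
  sufs <- vapply(sa, function(i) substr(S, i + 1L, n), character(1))
  lcp <- integer(n)
  for (i in 2:n) {
    a <- sufs[i - 1]; b <- sufs[i]
    l <- 0L
    while (l < nchar(a) && l < nchar(b) &&
           substr(a, l + 1, l + 1) == substr(b, l + 1, l + 1)) l <- l + 1L
    lcp[i] <- l
  }
  lcp
}

# tiny three-rank taxonomy: root(1) -> genus 2,3 -> species 4..7
tiny_taxonomy <- function() {
  taxonomy_tree(id = c(1L, 2L, 3L, 4L, 5L, 6L, 7L),
                parent = c(1L, 1L, 1L, 2L, 2L, 3L, 3L),
                rank = c("domain", "genus", "genus",
                         "species", "species", "species", "species"),
                name = c("root", "g1", "g2", "s1", "s2", "s3", "s4"))
}
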