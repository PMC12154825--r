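# Brute-force reference implementations. These deliberately share no logic
# with the index code paths: the BWT comes from an explicit rotation sort,
# matching statistics from substring scans, and run colors from direct
# lookups. Quadratic-time by design; intended for small inputs in tests.

#' Brute-force BWT via rotation sort
#'
#' Forms all cyclic rotations of `S`, sorts them bytewise, and reads the
#' last column. With a unique terminator the rotation order equals the
#' suffix order, so the suffix array is returned too.
#'
#' @param S String ending in a unique `$`.
#' @return List with `sa` (0-based) and `bwt`.
#' @export
brute_bwt <- function(S) {
  n <- nchar(S)
  if (substr(S, n, n) != "$" || lengths(regmatches(S, gregexpr("\\$", S))) != 1)
    stop("S must end with a unique '$'")
  rots <- vapply(seq_len(n) - 1L, function(i)
    paste0(substr(S, i + 1L, n), substr(S, 1L, i)), character(1))
  o <- order(rots, method = "radix")
  list(sa = o - 1L, bwt = paste(substr(rots[o], n, n), collapse = ""))
}

#' Brute-force matching statistics
#'
#' `MS[k]` is the length of the longest prefix of `R[k..]` occurring
#' anywhere in `S`, found by direct substring search.
#'
#' @param S Reference string.
#' @param R Query string.
#' @return Integer vector of length `nchar(R)`.
#' @export
brute_matching_statistics <- function(S, R) {
  m <- nchar(R)
  ms <- integer(m)
  # MS[k] <= MS[k+1] + 1, so scan right-to-left shrinking from prev + 1
  prev <- 0L
  for (k in m:1) {
    len <- min(prev + 1L, m - k + 1L)
    while (len > 0L &&
           !grepl(substr(R, k, k + len - 1L), S, fixed = TRUE))
      len <- len - 1L
    ms[k] <- len
    prev <- len
  }
  ms
}

#' Brute-force backward-search interval
#'
#' The half-open interval of BWM rows (sorted rotations) whose suffixes are
#' prefixed by `pattern`; empty interval (`lo == hi`) when the pattern does
#' not occur.
#'
#' @param S String ending in a unique `$`.
#' @param pattern Query pattern.
#' @return List `lo`, `hi` (0-based, half-open).
#' @export
brute_backward_search <- function(S, pattern) {
  n <- nchar(S)
  sa <- brute_bwt(S)$sa
  sufs <- vapply(sa, function(i) substr(S, i + 1L, n), character(1))
  hits <- which(startsWith(sufs, pattern))
  if (length(hits) == 0) list(lo = 0L, hi = 0L)
  else list(lo = hits[1] - 1L, hi = hits[length(hits)])
}

#' Brute-force run colors
#'
#' Recomputes the document of every BWT row from the suffix array and the
#' document boundaries, and collects the per-run sets directly.
#'
#' @param S String ending in a unique `$`.
#' @param doc_starts 0-based start offset of each document.
#' @param runs A `run_set` over the BWT of `S`.
#' @return List of sorted doc-id vectors, one per run.
#' @export
brute_run_colors <- function(S, doc_starts, runs) {
  sa <- brute_bwt(S)$sa
  nD <- length(doc_starts)
  doc_of <- function(p) min(sum(doc_starts <= p), nD) - 1L
  lapply(seq_len(runs$r), function(i) {
    flats <- runs$starts[i] + seq_len(runs$lengths[i]) - 1L
    sort(unique(vapply(flats, function(f) doc_of(sa[f + 1L]), integer(1))))
  })
}
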