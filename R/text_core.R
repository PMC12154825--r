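# Alphabet codes used throughout: terminator '$' = 0, A = 1, C = 2, G = 3,
# T = 4. All positions (text offsets, SA values, run indices, within-run
# offsets) are 0-based with half-open intervals, and document ids are
# 0..|D|-1, matching the conventions of the underlying index structures.

RC_ALPHABET <- c("$", "A", "C", "G", "T")

chars_to_codes <- function(x) {
  codes <- match(strsplit(x, "", fixed = TRUE)[[1]], RC_ALPHABET) - 1L
  if (anyNA(codes)) stop("string contains characters outside {$,A,C,G,T}")
  codes
}

codes_to_chars <- function(codes) {
  paste(RC_ALPHABET[codes + 1L], collapse = "")
}

#' Create a document collection
#'
#' A document is the unit of classification: a named group of one or more
#' DNA sequences (e.g. all genomes of a species). Documents are numbered
#' `0..|D|-1` in the order given.
#'
#' @param documents Named list; each element is a character vector of
#'   sequences over A,C,G,T (case-insensitive). Stretches of other
#'   characters (e.g. N) split a sequence into separate pieces of the same
#'   document, so no artificial adjacencies are introduced.
#' @param doc_taxon Optional integer vector, one taxonomy node id per
#'   document (same order as `documents`).
#' @return An object of class `document_collection` with elements
#'   `doc_ids` (0-based), `names`, `sequences` (list of character vectors)
#'   and `doc_taxon`.
#' @examples
#' dc <- document_collection(list(D1 = "ACA", D2 = "ACG"))
#' @export
document_collection <- function(documents, doc_taxon = NULL) {
  if (!is.list(documents) || length(documents) == 0)
    stop("'documents' must be a nonempty list of character vectors")
  nms <- names(documents)
  if (is.null(nms) || any(nms == ""))
    nms <- paste0("D", seq_along(documents))
  seqs <- lapply(documents, function(s) {
    s <- toupper(as.character(s))
    pieces <- unlist(strsplit(s, "[^ACGT]+"))
    pieces <- pieces[nzchar(pieces)]
    if (length(pieces) == 0)
      stop("a document has no A/C/G/T content after sanitization")
    pieces
  })
  if (!is.null(doc_taxon) && length(doc_taxon) != length(documents))
    stop("'doc_taxon' must have one entry per document")
  structure(
    list(doc_ids = seq_along(documents) - 1L,
         names = nms,
         sequences = seqs,
         doc_taxon = if (is.null(doc_taxon)) NULL else as.integer(doc_taxon)),
    class = "document_collection")
}

#' @export
print.document_collection <- function(x, ...) {
  tot <- sum(vapply(x$sequences, function(s) sum(nchar(s)), numeric(1)))
  cat(sprintf("document_collection: %d documents, %d sequences, %.0f bp total\n",
              length(x$doc_ids),
              sum(lengths(x$sequences)), tot))
  invisible(x)
}

#' Concatenate a document collection into a single terminated text
#'
#' Documents are concatenated in doc-id order and a single terminator `$`
#' (lexicographically smallest) is appended. The terminator is attributed to
#' the last document, so every BWT run color is nonempty. Suffixes may cross
#' document boundaries; the document of a suffix is the document containing
#' its start position.
#'
#' @param collection A [document_collection()].
#' @return A list of class `concat_text`: `S` (the text, character scalar),
#'   `codes` (integer codes, terminator 0), `n` (length including `$`),
#'   `doc_starts` (0-based start offset of each document) and `doc_lens`.
#' @export
build_concat <- function(collection) {
  stopifnot(inherits(collection, "document_collection"))
  per_doc <- vapply(collection$sequences, paste, character(1), collapse = "")
  if (sum(nchar(per_doc)) < 1) stop("empty collection")
  S <- paste0(paste(per_doc, collapse = ""), "$")
  doc_lens <- nchar(per_doc)
  doc_starts <- c(0L, cumsum(doc_lens)[-length(doc_lens)])
  structure(
    list(S = S,
         codes = chars_to_codes(S),
         n = nchar(S),
         doc_starts = as.integer(doc_starts),
         doc_lens = as.integer(doc_lens)),
    class = "concat_text")
}

#' Build suffix array, BWT, LCP and document array
#'
#' The suffix array is built by prefix doubling, the LCP array by Kasai's
#' algorithm, both in compiled code. `DA[i]` is the document whose interval
#' contains `SA[i]` (the terminator belongs to the last document).
#'
#' @param text A `concat_text` from [build_concat()].
#' @return A list of class `suffix_structures`: `sa` (0-based), `bwt`
#'   (character scalar), `bwt_codes`, `lcp`, `da` (0-based doc ids), `n`.
#' @export
build_suffix_structures <- function(text) {
  stopifnot(inherits(text, "concat_text"))
  sa <- sa_prefix_doubling(text$codes)
  lcp <- lcp_kasai(text$codes, sa)
  prev <- ifelse(sa == 0L, text$n - 1L, sa - 1L)
  bwt_codes <- text$codes[prev + 1L]
  da <- findInterval(sa, text$doc_starts) - 1L
  da[da >= length(text$doc_starts)] <- length(text$doc_starts) - 1L
  structure(
    list(sa = sa, bwt = codes_to_chars(bwt_codes), bwt_codes = bwt_codes,
         lcp = lcp, da = as.integer(da), n = text$n),
    class = "suffix_structures")
}

#' Find maximal equal-letter runs of a BWT
#'
#' @param bwt Character scalar (a BWT string) or an integer code vector.
#' @return A list of class `run_set`: `r` (number of runs), `starts`
#'   (0-based flat offsets of run heads), `chars` (run characters),
#'   `codes` (integer codes) and `lengths`.
#' @export
find_runs <- function(bwt) {
  codes <- if (is.character(bwt)) chars_to_codes(bwt) else as.integer(bwt)
  if (length(codes) == 0) stop("empty BWT")
  head <- c(TRUE, codes[-1] != codes[-length(codes)])
  starts <- which(head) - 1L
  lengths <- diff(c(starts, length(codes)))
  structure(
    list(r = length(starts), starts = starts,
         codes = codes[starts + 1L],
         chars = RC_ALPHABET[codes[starts + 1L] + 1L],
         lengths = as.integer(lengths)),
    class = "run_set")
}

#' Repositioning thresholds for every run and query character
#'
#' For a run of character x and a query character c != x, offsets below the
#' threshold reposition up and the rest down. The threshold is derived from
#' the flat position of the first minimum of LCP strictly between the nearest
#' occurrence of c above the run and the nearest occurrence below, clamped to
#' `[0, run length]`; with no occurrence above it is 0 (always down), with
#' none below it is the run length (always up).
#'
#' @param runs A `run_set`.
#' @param structures A `suffix_structures`.
#' @return Integer matrix `r x 4` with columns A,C,G,T; `NA` for the run's
#'   own character.
#' @export
compute_thresholds <- function(runs, structures) {
  stopifnot(inherits(runs, "run_set"), inherits(structures, "suffix_structures"))
  th <- thresholds_from_lcp(runs$codes, runs$starts, runs$lengths,
                            structures$lcp)
  colnames(th) <- c("A", "C", "G", "T")
  th
}

#' Shared LCP of a run
#'
#' The length of the longest prefix common to all rows (suffixes) of a BWM
#' run: the minimum of LCP over the run's interior flat positions. For a
#' length-1 run the vacuous minimum is taken as the suffix length.
#'
#' @param run_index 0-based run index.
#' @param runs A `run_set`.
#' @param structures A `suffix_structures`.
#' @return Integer scalar.
#' @export
shared_lcp <- function(run_index, runs, structures) {
  stopifnot(run_index >= 0, run_index < runs$r)
  start <- runs$starts[run_index + 1L]
  len <- runs$lengths[run_index + 1L]
  if (len == 1L) return(structures$n - structures$sa[start + 1L])
  min(structures$lcp[(start + 2L):(start + len)])
}
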