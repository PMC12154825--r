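#' Per-run colors: the document set of each BWT run
#'
#' The color of run i is the set of documents contributing at least one row
#' (suffix) to the run — multiplicities are discarded.
#'
#' @param runs A `run_set`.
#' @param structures The matching `suffix_structures` (provides the document
#'   array).
#' @return List of length r; element i is a sorted integer vector of 0-based
#'   doc ids.
#' @export
compute_run_colors <- function(runs, structures) {
  stopifnot(inherits(runs, "run_set"), inherits(structures, "suffix_structures"))
  run_of <- rep.int(seq_len(runs$r), runs$lengths)  # 1-based run per flat pos
  da <- structures$da
  nD <- max(da) + 1L
  key <- as.numeric(run_of) * nD + da
  keep <- !duplicated(key)
  run2 <- run_of[keep]; da2 <- da[keep]
  o <- order(run2, da2)
  unname(split(da2[o], factor(run2[o], levels = seq_len(runs$r))))
}

#' Deduplicate run colors into a color table
#'
#' Distinct colors are numbered 0,1,2,... by first appearance in run order,
#' and each run stores only its color id.
#'
#' @param run_colors List of sorted doc-id vectors, one per run
#'   (from [compute_run_colors()]).
#' @return A list of class `color_table`: `colors` (list of distinct sorted
#'   doc-id vectors, indexed by color id + 1) and `run_color_ids` (integer
#'   vector length r, 0-based color ids).
#' @export
build_color_table <- function(run_colors) {
  if (length(run_colors) == 0) stop("no run colors")
  keys <- vapply(run_colors, paste, character(1), collapse = ",")
  first <- !duplicated(keys)
  ids <- match(keys, keys[first]) - 1L
  structure(
    list(colors = run_colors[first], run_color_ids = ids),
    class = "color_table")
}

#' Encode a color as dense bits or a sparse id list
#'
#' Dense: a logical presence vector of length `n_docs` (one bit per
#' document, `|C| x |D|` bits in total). Sparse: the sorted doc ids
#' themselves (`|C| x b` integers for mean set size b). The default picks
#' dense when `n_docs <= 64`.
#'
#' @param docs Sorted integer vector of 0-based doc ids.
#' @param n_docs Number of documents.
#' @param representation `"auto"`, `"dense"` or `"sparse"`.
#' @return For dense, a logical vector of length `n_docs`; for sparse, the
#'   integer vector. Attribute `representation` records which was used.
#' @export
encode_color <- function(docs, n_docs,
                         representation = c("auto", "dense", "sparse")) {
  representation <- match.arg(representation)
  if (representation == "auto")
    representation <- if (n_docs <= 64) "dense" else "sparse"
  out <- if (representation == "dense") {
    v <- logical(n_docs); v[docs + 1L] <- TRUE; v
  } else {
    as.integer(sort(docs))
  }
  attr(out, "representation") <- representation
  out
}

#' Decode an encoded color back to its doc-id set
#'
#' @param enc Output of [encode_color()].
#' @return Sorted integer vector of 0-based doc ids.
#' @export
decode_color <- function(enc) {
  if (is.logical(enc)) which(enc) - 1L else as.integer(sort(enc))
}

#' Color-table compression statistics
#'
#' @param table A `color_table`.
#' @param n_docs Number of documents (defaults to 1 + max doc id seen).
#' @param top_k How many most frequent colors the cumulative run-coverage
#'   curve reports.
#' @return A list of class `color_stats`: `r`, `num_colors`, `ratio`
#'   (r/|C|), `b` (mean set bits per color), `dense_bits` (|C| x |D|),
#'   `sparse_ints` (|C| x b), `frequency` (runs per color id, decreasing)
#'   and `top_k_coverage` (cumulative fraction of runs covered by the k most
#'   frequent colors, k = 1..top_k).
#' @export
color_stats <- function(table, n_docs = NULL, top_k = 10L) {
  stopifnot(inherits(table, "color_table"))
  r <- length(table$run_color_ids)
  nC <- length(table$colors)
  if (is.null(n_docs)) n_docs <- max(unlist(table$colors)) + 1L
  b <- mean(lengths(table$colors))
  freq <- sort(tabulate(table$run_color_ids + 1L, nbins = nC),
               decreasing = TRUE)
  k <- min(top_k, nC)
  structure(
    list(r = r, num_colors = nC, ratio = r / nC, b = b,
         n_docs = n_docs,
         dense_bits = nC * n_docs,
         sparse_ints = nC * b,
         frequency = freq,
         top_k_coverage = cumsum(freq[seq_len(k)]) / r),
    class = "color_stats")
}

#' @export
print.color_stats <- function(x, ...) {
  cat(sprintf("runs (r)        %d\n", x$r))
  cat(sprintf("colors (|C|)    %d\n", x$num_colors))
  cat(sprintf("r/|C|           %.3f\n", x$ratio))
  cat(sprintf("mean bits (b)   %.3f\n", x$b))
  cat(sprintf("dense           %d bits\n", x$dense_bits))
  cat(sprintf("sparse          %.1f integers\n", x$sparse_ints))
  invisible(x)
}
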