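RC_INDEX_VERSION <- 1L

#' Build a run-colored move-structure index
#'
#' End-to-end construction: concatenate the documents, build the suffix
#' array / BWT / LCP / document array, derive the BWT runs and move table
#' (optionally with repositioning thresholds), and attach the deduplicated
#' color table mapping each run to its set of source documents.
#'
#' @param collection A [document_collection()].
#' @param taxonomy Optional `taxonomy_tree`; document-to-taxon links come
#'   from the collection's `doc_taxon`.
#' @param thresholds Compute true repositioning thresholds (default `TRUE`).
#'   Without them only the `"mid-run"` and `"always-up"` query strategies
#'   are available.
#' @param keep_structures Keep the full suffix structures on the object
#'   (memory-heavy; useful for inspection and testing).
#' @return An object of class `rc_index` bundling the move table
#'   (`$move`), color table (`$colors`), document metadata (`$doc_names`,
#'   `$n_docs`, `$doc_taxon`, `$boundaries`), the taxonomy and header
#'   fields (`$n`, `$version`).
#' @examples
#' dc <- document_collection(list(D1 = "ACA", D2 = "ACG"))
#' idx <- build_index(dc)
#' classify_reads(idx, c(r1 = "ACG"))
#' @export
build_index <- function(collection, taxonomy = NULL, thresholds = TRUE,
                        keep_structures = FALSE) {
  stopifnot(inherits(collection, "document_collection"))
  text <- build_concat(collection)
  structures <- build_suffix_structures(text)
  runs <- find_runs(structures$bwt_codes)
  move <- build_move_table(runs, structures, thresholds = thresholds)
  ctab <- build_color_table(compute_run_colors(runs, structures))
  move$color_ids <- ctab$run_color_ids
  idx <- structure(
    list(version = RC_INDEX_VERSION,
         n = text$n,
         n_docs = length(collection$doc_ids),
         doc_names = collection$names,
         doc_taxon = collection$doc_taxon,
         boundaries = list(starts = text$doc_starts, lens = text$doc_lens),
         move = move,
         colors = ctab,
         taxonomy = taxonomy),
    class = "rc_index")
  if (keep_structures) idx$structures <- structures
  idx
}

#' @export
print.rc_index <- function(x, ...) {
  cat(sprintf("rc_index: n=%d, %d docs, r=%d runs, |C|=%d colors (r/|C|=%.2f)%s\n",
              x$n, x$n_docs, x$move$r, length(x$colors$colors),
              x$move$r / length(x$colors$colors),
              if (is.null(x$move$thresholds)) ", no thresholds" else ""))
  invisible(x)
}

#' Save / load an index
#'
#' The on-disk container is versioned; loading a file with a different
#' format version, or a corrupt/truncated file, raises an explicit error.
#' A saved-then-loaded index classifies identically to the original.
#'
#' @param index An `rc_index`.
#' @param path File path.
#' @return `load_index` returns the `rc_index`; `save_index` returns `path`
#'   invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "rc_index"))
  saveRDS(index, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  idx <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt or unreadable index file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (!inherits(idx, "rc_index"))
    stop("file does not contain a runcolor index: ", path)
  if (!identical(idx$version, RC_INDEX_VERSION))
    stop("index format version ", idx$version,
         " does not match this package (", RC_INDEX_VERSION, ")")
  idx
}

#' Read sequences from FASTA or FASTQ
#'
#' Plain or gzip-compressed. Sequences are folded to upper case. The format
#' is taken from the file extension (`.fq`/`.fastq` = FASTQ) or, failing
#' that, from the first record marker.
#'
#' @param path File path.
#' @return A data.frame with columns `id`, `seq`, and `qual` (NA for FASTA).
#' @export
read_sequences <- function(path) {
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  if (!grepl("\\.(fa|fasta|fna|fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
    con <- gzfile(path, "r"); first <- readLines(con, n = 1); close(con)
    if (length(first) == 0) stop("empty sequence file: ", path)
    fastq <- startsWith(first, "@")
  }
  if (fastq) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(x))
  }
  if (length(x) == 0) stop("empty sequence file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  data.frame(id = ids, seq = toupper(as.character(x)), qual = qual,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequences to FASTA / FASTQ
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path (`.gz` to compress).
#' @param qual Quality string recycled per base for FASTQ output.
#' @return `path` invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path, qual = "I") {
  x <- Biostrings::DNAStringSet(seqs)
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(m)
    paste(rep(qual, m), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Assemble a document collection from reference files
#'
#' @param ref_path Multi-FASTA of reference sequences.
#' @param docmap_path Headerless TSV `sequence_id<TAB>doc_id`; every
#'   sequence in the FASTA must be mapped (0-based contiguous doc ids).
#' @param doc2tax_path Optional headerless TSV `doc_id<TAB>taxon_id`.
#' @return A [document_collection()].
#' @export
collection_from_files <- function(ref_path, docmap_path, doc2tax_path = NULL) {
  refs <- read_sequences(ref_path)
  dm <- utils::read.delim(docmap_path, header = FALSE,
                          stringsAsFactors = FALSE)
  doc_of <- dm[[2]][match(refs$id, dm[[1]])]
  if (anyNA(doc_of))
    stop("unmapped sequences in doc map: ",
         paste(utils::head(refs$id[is.na(doc_of)], 5), collapse = ", "))
  doc_ids <- sort(unique(as.integer(doc_of)))
  if (!identical(doc_ids, seq_along(doc_ids) - 1L))
    stop("doc ids must be 0..|D|-1 and contiguous")
  docs <- lapply(doc_ids, function(d) refs$seq[doc_of == d])
  names(docs) <- paste0("D", doc_ids)
  doc_taxon <- NULL
  if (!is.null(doc2tax_path)) {
    dt <- utils::read.delim(doc2tax_path, header = FALSE,
                            stringsAsFactors = FALSE)
    doc_taxon <- as.integer(dt[[2]][match(doc_ids, dt[[1]])])
    if (anyNA(doc_taxon)) stop("doc ids missing from doc-to-taxon map")
  }
  document_collection(docs, doc_taxon)
}
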