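strategy_code <- function(strategy) {
  strategy <- match.arg(strategy, c("true", "true-thresholds",
                                    "mid-run", "always-up"))
  switch(strategy, "true" = 0L, "true-thresholds" = 0L,
         "mid-run" = 1L, "always-up" = 2L)
}

#' Compute pseudo-matching lengths for a read
#'
#' Tracks a single BWT position right-to-left through the read, starting at
#' the last BWT offset. A matching run character extends the current length;
#' a mismatch triggers a repositioning step (per `strategy`) and resets the
#' length to zero. After each recorded length the LF-mapping is applied and
#' the post-LF run index is recorded for color scoring. Read characters
#' outside A,C,G,T or absent from the BWT give length 0 and leave the
#' tracked position unchanged.
#'
#' @param table A `move_table` (or an index bundle from [build_index()]).
#' @param read Character scalar (the read sequence).
#' @param strategy Repositioning strategy: `"true"` (thresholds),
#'   `"mid-run"`, or `"always-up"`.
#' @return A list of class `pml_result`: `pml` (integer vector, one entry
#'   per read position), `visited` (0-based post-LF run index per position,
#'   `NA` where the position was skipped), `strategy`.
#' @export
compute_pmls <- function(table, read, strategy = "true") {
  if (inherits(table, "rc_index")) table <- table$move
  stopifnot(inherits(table, "move_table"))
  if (!nzchar(read)) stop("empty read")
  scode <- strategy_code(strategy)
  if (scode == 0L && is.null(table$thresholds))
    stop("move table has no thresholds; use strategy 'mid-run' or 'always-up'")
  codes <- match(strsplit(toupper(read), "", fixed = TRUE)[[1]],
                 RC_ALPHABET) - 1L
  codes[is.na(codes)] <- -1L
  res <- pml_query(table$codes, table$lengths, table$dest_run, table$dest_off,
                   table$thresholds, table$up_run, table$down_run,
                   codes, scode)
  structure(list(pml = res$pml, visited = res$visited, strategy = strategy),
            class = "pml_result")
}

#' Tally per-document scores from a PML result
#'
#' For every read position with a positive pseudo-matching length, each
#' document in the color of the post-LF run gets +1.
#'
#' @param result A `pml_result`.
#' @param table A `color_table` (or an index bundle from [build_index()]).
#' @param n_docs Number of documents (inferred from the color table when
#'   omitted).
#' @return Integer vector of scores, one per document (position d+1 holds
#'   the score of doc id d).
#' @export
score_read <- function(result, table, n_docs = NULL) {
  if (inherits(table, "rc_index")) {
    if (is.null(n_docs)) n_docs <- table$n_docs
    table <- table$colors
  }
  stopifnot(inherits(result, "pml_result"), inherits(table, "color_table"))
  if (is.null(n_docs)) n_docs <- max(unlist(table$colors)) + 1L
  sel <- result$pml > 0L & !is.na(result$visited)
  if (!any(sel)) return(integer(n_docs))
  cids <- table$run_color_ids[result$visited[sel] + 1L]
  tabulate(unlist(table$colors[cids + 1L]) + 1L, nbins = n_docs)
}

#' Average pseudo-matching length of a read
#'
#' @param result A `pml_result` (or a bare numeric vector of PMLs).
#' @return Sum of PMLs divided by the read length.
#' @export
average_pml <- function(result) {
  pml <- if (inherits(result, "pml_result")) result$pml else result
  if (length(pml) == 0) stop("empty PML vector")
  sum(pml) / length(pml)
}

#' Calibrate the binary in-index cutoff from null reads
#'
#' The cutoff is the nearest-rank percentile (the `ceiling(p/100 * n)`-th
#' smallest value) of the average PMLs of reads known to be absent from the
#' index. With the default 95th percentile the gate is a level-0.05 test:
#' about 5% of fresh null reads are expected to pass it.
#'
#' @param null_avg_pmls Numeric vector of average PMLs of null reads
#'   (at least 20).
#' @param percentile Percentile in (0, 100]; default 95.
#' @return A list of class `binary_calibration`: `cutoff`, `percentile`,
#'   `n_null`.
#' @export
calibrate_cutoff <- function(null_avg_pmls, percentile = 95) {
  n <- length(null_avg_pmls)
  if (n < 20) stop("need at least 20 null reads to calibrate")
  stopifnot(percentile > 0, percentile <= 100)
  idx <- ceiling(percentile / 100 * n)
  structure(
    list(cutoff = sort(null_avg_pmls)[idx],
         percentile = percentile, n_null = n),
    class = "binary_calibration")
}

#' Classify one read from its scores and average PML
#'
#' The binary gate runs first: a read whose average PML does not exceed the
#' cutoff is left unclassified. Otherwise the best-scoring document Dbest is
#' reported (ties broken towards the smallest doc id), together with up to
#' `max_secondary` further documents scoring at least `ratio` times Dbest's
#' score. A single reported document is assigned its own taxon; several are
#' assigned their lowest common ancestor.
#'
#' @param scores Integer score vector (position d+1 = doc id d), from
#'   [score_read()].
#' @param avg_pml Average PML of the read.
#' @param calibration A `binary_calibration`, a bare numeric cutoff, or
#'   `NULL` to disable the gate.
#' @param tree Optional `taxonomy_tree`.
#' @param doc_taxon Optional integer vector mapping doc id d to the taxon at
#'   position d+1.
#' @param ratio Secondary documents must score at least this fraction of
#'   Dbest's score (default 0.95).
#' @param max_secondary Maximum number of documents reported besides Dbest.
#' @return A list of class `read_classification`: `status` ("C" or "U"),
#'   `avg_pml`, `reported_docs` (0-based ids, decreasing score),
#'   `reported_scores`, `assigned_taxon` (`NA` without a taxonomy),
#'   `assigned_rank`.
#' @export
classify_read <- function(scores, avg_pml, calibration = NULL,
                          tree = NULL, doc_taxon = NULL,
                          ratio = 0.95, max_secondary = 1L) {
  cutoff <- if (inherits(calibration, "binary_calibration"))
    calibration$cutoff else calibration
  unclassified <- function() {
    structure(list(status = "U", avg_pml = avg_pml,
                   reported_docs = integer(0), reported_scores = integer(0),
                   assigned_taxon = NA_integer_,
                   assigned_rank = NA_character_),
              class = "read_classification")
  }
  if (!is.null(cutoff) && avg_pml <= cutoff) return(unclassified())
  if (all(scores == 0)) return(unclassified())
  best <- which.max(scores) - 1L              # first max = smallest doc id
  best_score <- scores[best + 1L]
  others <- setdiff(which(scores >= ratio * best_score) - 1L, best)
  if (length(others) > 0) {
    o <- order(-scores[others + 1L], others)
    others <- others[o][seq_len(min(max_secondary, length(others)))]
  }
  reported <- c(best, others)
  taxon <- NA_integer_; rank <- NA_character_
  if (!is.null(tree) && !is.null(doc_taxon)) {
    taxa <- doc_taxon[reported + 1L]
    taxon <- if (length(taxa) == 1L) taxa else lca(tree, taxa)
    rank <- tree$rank[match(taxon, tree$id)]
  }
  structure(
    list(status = "C", avg_pml = avg_pml,
         reported_docs = as.integer(reported),
         reported_scores = scores[reported + 1L],
         assigned_taxon = taxon, assigned_rank = rank),
    class = "read_classification")
}

#' Classify a set of reads against an index
#'
#' Each read is queried in both orientations (the index stores only the
#' forward strand of the references) and the orientation with the higher
#' average PML is kept. The binary average-PML gate is applied before
#' multi-class scoring when a cutoff is supplied.
#'
#' @param index An `rc_index` from [build_index()].
#' @param reads Named character vector of read sequences.
#' @param cutoff A `binary_calibration`, a bare numeric cutoff, or `NULL`
#'   (gate disabled).
#' @param strategy Repositioning strategy; `NULL` picks `"true"` when the
#'   index has thresholds and `"mid-run"` otherwise.
#' @param ratio,max_secondary Passed to [classify_read()].
#' @return A data.frame with one row per read: `read_id`, `status` ("C" or
#'   "U"), `assigned_taxon`, `assigned_rank`, `reported_docs` and
#'   `reported_scores` (comma-separated), `avg_pml`, `read_length`,
#'   `orientation` ("+"/"-").
#' @export
classify_reads <- function(index, reads, cutoff = NULL, strategy = NULL,
                           ratio = 0.95, max_secondary = 1L) {
  stopifnot(inherits(index, "rc_index"))
  if (is.null(strategy))
    strategy <- if (!is.null(index$move$thresholds)) "true" else "mid-run"
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  rows <- vector("list", length(reads))
  for (k in seq_along(reads)) {
    pick <- best_orientation(index, reads[[k]], strategy)
    cls <- classify_read(score_read(pick$result, index), pick$avg,
                         cutoff, index$taxonomy, index$doc_taxon,
                         ratio = ratio, max_secondary = max_secondary)
    rows[[k]] <- data.frame(
      read_id = ids[k], status = cls$status,
      assigned_taxon = cls$assigned_taxon,
      assigned_rank = cls$assigned_rank,
      reported_docs = paste(cls$reported_docs, collapse = ","),
      reported_scores = paste(cls$reported_scores, collapse = ","),
      avg_pml = pick$avg, read_length = nchar(reads[[k]]),
      orientation = pick$orientation,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Query both orientations, keep the higher average PML (tie: forward).
best_orientation <- function(index, read, strategy) {
  fwd <- compute_pmls(index, read, strategy)
  rev <- compute_pmls(index, reverse_complement(read), strategy)
  afwd <- average_pml(fwd); arev <- average_pml(rev)
  if (arev > afwd)
    list(result = rev, avg = arev, orientation = "-")
  else
    list(result = fwd, avg = afwd, orientation = "+")
}

#' Average PMLs for a set of reads (best orientation)
#'
#' Convenience used for gate calibration and evaluation: for each read,
#' the larger of the two orientations' average PML.
#'
#' @inheritParams classify_reads
#' @return Numeric vector, one average PML per read.
#' @export
average_pmls <- function(index, reads, strategy = NULL) {
  stopifnot(inherits(index, "rc_index"))
  if (is.null(strategy))
    strategy <- if (!is.null(index$move$thresholds)) "true" else "mid-run"
  vapply(reads, function(rd) best_orientation(index, rd, strategy)$avg,
         numeric(1), USE.NAMES = FALSE)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
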