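#' Tally TP/VP/FP/FN at a taxonomic rank
#'
#' Kraken-style per-rank scoring. Reads whose truth label has no ancestor at
#' `rank` are excluded from the evaluation at that rank. For an included
#' positive read: unclassified is a false negative; a prediction whose
#' ancestor at `rank` equals the truth's is a true positive (so a correct
#' call at or below the rank counts); a prediction strictly above the rank
#' but on the truth lineage is a vague positive; anything else is a false
#' positive. Negative reads (truth `-`, absent from the index) are excluded
#' when unclassified (true negatives) and count as false positives when
#' classified.
#'
#' @param predictions Data frame from [classify_reads()] (needs `read_id`,
#'   `status`, `assigned_taxon`).
#' @param truth Data frame with `read_id` and `taxon_id` (`"-"` marks a
#'   negative read).
#' @param tree A `taxonomy_tree`.
#' @param rank Rank to evaluate at (e.g. `"species"`, `"genus"`).
#' @return A list of class `rank_counts`: `rank`, `TP`, `VP`, `FP`, `FN`,
#'   `n_evaluated` (= TP+VP+FP+FN), `n_excluded`.
#' @export
tally_rank_counts <- function(predictions, truth, tree, rank) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  m <- match(predictions$read_id, truth$read_id)
  if (anyNA(m)) stop("predictions contain read ids absent from truth")
  tlab <- truth$taxon_id[m]
  TP <- VP <- FP <- FN <- 0L
  excluded <- 0L
  for (k in seq_len(nrow(predictions))) {
    classified <- predictions$status[k] == "C"
    if (tlab[k] %in% c("-", NA)) {            # negative read
      if (classified) FP <- FP + 1L else excluded <- excluded + 1L
      next
    }
    tr <- as.integer(tlab[k])
    tr_at <- ancestor_at_rank(tree, tr, rank)
    if (is.na(tr_at)) { excluded <- excluded + 1L; next }
    if (!classified) { FN <- FN + 1L; next }
    pred <- predictions$assigned_taxon[k]
    if (is.na(pred) || !(pred %in% tree$id))
      stop("prediction taxon not in tree: ", pred)
    pred_at <- ancestor_at_rank(tree, pred, rank)
    if (!is.na(pred_at) && pred_at == tr_at) {
      TP <- TP + 1L
    } else if (is.na(pred_at) && pred %in% ancestors(tree, tr)) {
      VP <- VP + 1L
    } else {
      FP <- FP + 1L
    }
  }
  structure(
    list(rank = rank, TP = TP, VP = VP, FP = FP, FN = FN,
         n_evaluated = TP + VP + FP + FN, n_excluded = excluded),
    class = "rank_counts")
}

#' Precision, recall and F1 from rank counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + VP + FN + FP)`,
#' `F1 = 2PR / (P + R)`. A zero denominator yields `NA` rather than an
#' error.
#'
#' @param counts A `rank_counts`.
#' @return A list `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  stopifnot(inherits(counts, "rank_counts"))
  P <- with(counts, if (TP + FP > 0) TP / (TP + FP) else NA_real_)
  R <- with(counts, if (TP + VP + FN + FP > 0)
    TP / (TP + VP + FN + FP) else NA_real_)
  f1 <- if (!is.na(P) && !is.na(R) && P + R > 0) 2 * P * R / (P + R)
        else NA_real_
  list(precision = P, recall = R, f1 = f1)
}
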