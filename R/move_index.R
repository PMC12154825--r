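#' Build the move table from BWT runs
#'
#' One row per BWT run, holding the run character, its length, and the
#' LF-mapping destination of the run head as a (run, offset) pair. The
#' destination of an arbitrary within-run offset j is obtained by adding j to
#' the head's destination offset and fast-forwarding across run boundaries
#' ([lf_step()]). Repositioning thresholds and nearest-run lookups for every
#' character are attached for query-time use.
#'
#' @param runs A `run_set` from [find_runs()].
#' @param structures The matching `suffix_structures`.
#' @param thresholds Logical; compute and attach true repositioning
#'   thresholds (requires the LCP array). When `FALSE` only the mid-run and
#'   always-up strategies are available at query time.
#' @return A list of class `move_table`: `r`, `n`, `codes`, `chars`,
#'   `lengths`, `starts`, `dest_run`, `dest_off` (all 0-based),
#'   `thresholds` (matrix or `NULL`), `up_run`, `down_run`, and `color_ids`
#'   (filled by [build_color_table()], initially `NULL`).
#' @export
build_move_table <- function(runs, structures, thresholds = TRUE) {
  stopifnot(inherits(runs, "run_set"), inherits(structures, "suffix_structures"))
  n <- structures$n
  counts <- tabulate(structures$bwt_codes + 1L, nbins = 5L)
  Carr <- c(0L, cumsum(counts)[-5L])  # first-column start per character code
  # occurrences of each run's character strictly before its head =
  # exclusive cumulative sum of lengths of earlier runs with that character
  occ_before <- integer(runs$r)
  for (cd in unique(runs$codes)) {
    sel <- runs$codes == cd
    occ_before[sel] <- cumsum(c(0L, runs$lengths[sel]))[seq_len(sum(sel))]
  }
  lf_head <- Carr[runs$codes + 1L] + occ_before
  dest_run <- findInterval(lf_head, runs$starts) - 1L
  dest_off <- lf_head - runs$starts[dest_run + 1L]
  nn <- nearest_char_runs(runs$codes)
  tab <- structure(
    list(r = runs$r, n = n,
         codes = runs$codes, chars = runs$chars,
         lengths = runs$lengths, starts = runs$starts,
         dest_run = as.integer(dest_run), dest_off = as.integer(dest_off),
         thresholds = NULL,
         up_run = nn$up, down_run = nn$down,
         color_ids = NULL),
    class = "move_table")
  if (thresholds)
    tab$thresholds <- compute_thresholds(runs, structures)
  tab
}

#' One LF step through the move table
#'
#' Maps a position one step backwards through the text: destination run and
#' offset are read from the table row, then fast-forwarded while the offset
#' exceeds the current run length.
#'
#' @param table A `move_table`.
#' @param pos Integer vector `c(run, offset)`, 0-based.
#' @return Integer vector `c(run, offset)`.
#' @export
lf_step <- function(table, pos) {
  i <- pos[1]; j <- pos[2]
  stopifnot(i >= 0, i < table$r, j >= 0, j < table$lengths[i + 1L])
  ii <- table$dest_run[i + 1L]
  jj <- table$dest_off[i + 1L] + j
  while (jj >= table$lengths[ii + 1L]) {
    jj <- jj - table$lengths[ii + 1L]
    ii <- ii + 1L
  }
  c(ii, jj)
}

#' Reposition to a nearby run with a given character
#'
#' Used when the tracked position's run character differs from the next read
#' character c. The direction is up iff the within-run offset is below the
#' effective threshold: the stored threshold (`"true"`), the run length
#' (`"always-up"`), or ceiling(run length / 2) (`"mid-run"`). Repositioning
#' up lands on the last offset of the nearest preceding run with character c;
#' down on the first offset of the nearest following such run. If no run
#' exists in the chosen direction the other direction is used; if c is absent
#' from the BWT entirely, `NULL` is returned.
#'
#' @param table A `move_table`.
#' @param pos Integer vector `c(run, offset)`, 0-based.
#' @param c Single character, one of A,C,G,T.
#' @param strategy `"true"`, `"mid-run"` or `"always-up"`.
#' @return Integer vector `c(run, offset)`, or `NULL` when c is absent.
#' @export
reposition <- function(table, pos, c,
                       strategy = c("true", "mid-run", "always-up")) {
  strategy <- match.arg(strategy)
  i <- pos[1]; j <- pos[2]
  cd <- match(toupper(c), RC_ALPHABET) - 1L
  stopifnot(!is.na(cd), cd >= 1L)
  if (table$codes[i + 1L] == cd)
    stop("reposition called with the run's own character")
  n_run <- table$lengths[i + 1L]
  thr <- switch(strategy,
    "true" = {
      if (is.null(table$thresholds))
        stop("this move table has no thresholds; use 'mid-run' or 'always-up'")
      table$thresholds[i + 1L, cd]
    },
    "mid-run" = (n_run + 1L) %/% 2L,
    "always-up" = n_run)
  ui <- table$up_run[i + 1L, cd]
  di <- table$down_run[i + 1L, cd]
  if (ui < 0 && di < 0) return(NULL)
  go_up <- j < thr
  if (go_up && ui < 0) go_up <- FALSE
  if (!go_up && di < 0) go_up <- TRUE
  if (go_up) c(ui, table$lengths[ui + 1L] - 1L) else c(di, 0L)
}

#' Flat BWT offset of a (run, offset) position
#'
#' @param table A `move_table`.
#' @param pos Integer vector `c(run, offset)`, 0-based.
#' @return 0-based flat BWT offset.
#' @export
to_flat_offset <- function(table, pos) {
  table$starts[pos[1] + 1L] + pos[2]
}

#' Flat BWT offset to (run, offset)
#'
#' @param table A `move_table`.
#' @param flat 0-based flat BWT offset.
#' @return Integer vector `c(run, offset)`.
#' @export
from_flat_offset <- function(table, flat) {
  i <- findInterval(flat, table$starts) - 1L
  c(i, flat - table$starts[i + 1L])
}
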