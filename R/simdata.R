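# Synthetic pangenome and long-read simulator.
#
# The generator emulates a small multi-species pangenome: a random root
# genome, one ancestor per species obtained by point substitution at the
# inter-species rate, and several genomes per species at the intra-species
# rate. Divergence between genomes is substitution-only; sequencing errors
# include substitutions, insertions and deletions (ONT-like defaults:
# 3% / 2% / 2%, about 7% total).

DNA_BASES <- c("A", "C", "G", "T")

random_genome <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# substitute each base independently with probability `rate` (to one of the
# three other bases)
mutate_genome <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(stats::runif(length(v)) < rate)
  if (length(idx) > 0) {
    shift <- sample.int(3L, length(idx), replace = TRUE)
    cur <- match(v[idx], DNA_BASES)
    v[idx] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

#' Simulate a multi-species pangenome with a taxonomy
#'
#' A root genome is drawn i.i.d. uniform over A,C,G,T; each species ancestor
#' substitutes the root at `inter_divergence`; each genome of a species
#' substitutes its ancestor at `intra_divergence`. One randomly chosen
#' genome per species is held out (for read simulation) and the rest become
#' the species' document. Species are grouped into genera of
#' `genus_size` under a single root to give the taxonomy some depth.
#'
#' @param n_species Number of species (= documents).
#' @param genomes_per_species Genomes drawn per species (one is held out).
#' @param genome_length Genome length in bp (>= 100).
#' @param inter_divergence Substitution fraction root -> species ancestor.
#' @param intra_divergence Substitution fraction ancestor -> genome.
#' @param genus_size Species per genus in the generated taxonomy.
#' @param seed Optional RNG seed; fixed seed gives byte-identical output.
#' @return A list: `collection` (a [document_collection()], doc d = species
#'   d), `taxonomy` (a `taxonomy_tree`), `heldout` (named character vector,
#'   one held-out genome per species), `species_taxa` (taxon id per doc),
#'   `root` (the root genome).
#' @export
simulate_pangenome <- function(n_species = 5, genomes_per_species = 3,
                               genome_length = 100000,
                               inter_divergence = 0.10,
                               intra_divergence = 0.01,
                               genus_size = 2, seed = NULL) {
  stopifnot(genome_length >= 100,
            inter_divergence >= 0, inter_divergence < 1,
            intra_divergence >= 0, intra_divergence < 1,
            genomes_per_species >= 2)
  if (!is.null(seed)) set.seed(seed)
  root <- random_genome(genome_length)
  n_genera <- ceiling(n_species / genus_size)
  genus_ids <- 1L + seq_len(n_genera)
  species_ids <- 1L + n_genera + seq_len(n_species)
  genus_of <- genus_ids[ceiling(seq_len(n_species) / genus_size)]
  tax <- taxonomy_tree(
    id = c(1L, genus_ids, species_ids),
    parent = c(1L, rep(1L, n_genera), genus_of),
    rank = c("domain", rep("genus", n_genera), rep("species", n_species)),
    name = c("root", paste0("genus", seq_len(n_genera)),
             paste0("species", seq_len(n_species))))
  docs <- vector("list", n_species)
  heldout <- character(n_species)
  for (s in seq_len(n_species)) {
    anc <- mutate_genome(root, inter_divergence)
    genomes <- vapply(seq_len(genomes_per_species),
                      function(g) mutate_genome(anc, intra_divergence),
                      character(1))
    out <- sample.int(genomes_per_species, 1L)
    heldout[s] <- genomes[out]
    docs[[s]] <- genomes[-out]
  }
  names(docs) <- paste0("species", seq_len(n_species))
  names(heldout) <- names(docs)
  list(collection = document_collection(docs, doc_taxon = species_ids),
       taxonomy = tax,
       heldout = heldout,
       species_taxa = species_ids,
       root = root)
}

# apply the read error model to one template substring: per base, delete
# with prob del, substitute with prob sub, and insert a random base after it
# with prob ins
apply_read_errors <- function(template, sub_rate, ins_rate, del_rate) {
  v <- strsplit(template, "", fixed = TRUE)[[1]]
  m <- length(v)
  u <- stats::runif(m)
  del <- u < del_rate
  subst <- !del & u < del_rate + sub_rate
  if (any(subst)) {
    shift <- sample.int(3L, sum(subst), replace = TRUE)
    cur <- match(v[subst], DNA_BASES)
    v[subst] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  ins <- stats::runif(m) < ins_rate
  copies <- ifelse(del, 0L, 1L) + ins
  out <- rep.int(v, copies)
  # positions where an insertion follows: replace the duplicate with a
  # random base
  if (any(ins)) {
    ins_pos <- cumsum(copies)[ins]
    out[ins_pos] <- sample(DNA_BASES, sum(ins), replace = TRUE)
  }
  paste(out, collapse = "")
}

#' Simulate noisy long reads with ground truth
#'
#' Read start positions are uniform over each source genome; lengths come
#' from a normal distribution truncated below at `min_length` (reads longer
#' than the genome are resampled). Errors are applied per base
#' (substitution / insertion / deletion); half the reads are
#' reverse-complemented. The truth table records the source document and
#' taxon of every read.
#'
#' @param genomes Data frame with columns `genome_id`, `seq`, `doc_id`,
#'   `taxon_id` — the pool of source genomes (use the held-out genomes to
#'   emulate querying novel strains of indexed species).
#' @param n_reads Number of reads.
#' @param length_mean,length_sd Read-length distribution (bp).
#' @param min_length Lower truncation for read length.
#' @param sub_rate,ins_rate,del_rate Per-base error rates (sum < 0.5).
#' @param rc_prob Probability a read is reverse-complemented.
#' @param seed Optional RNG seed.
#' @param prefix Read-id prefix.
#' @return A list: `reads` (named character vector) and `truth` (data.frame
#'   `read_id`, `taxon_id`, `doc_id`).
#' @export
simulate_reads <- function(genomes, n_reads = 1000,
                           length_mean = 9000, length_sd = NULL,
                           min_length = 100,
                           sub_rate = 0.03, ins_rate = 0.02, del_rate = 0.02,
                           rc_prob = 0.5, seed = NULL, prefix = "read") {
  stopifnot(is.data.frame(genomes), nrow(genomes) >= 1,
            all(c("genome_id", "seq", "doc_id", "taxon_id") %in%
                  names(genomes)),
            sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate + ins_rate + del_rate < 0.5)
  if (is.null(length_sd)) length_sd <- round(0.2 * length_mean)
  if (!is.null(seed)) set.seed(seed)
  glens <- nchar(genomes$seq)
  src <- sample.int(nrow(genomes), n_reads, replace = TRUE)
  reads <- character(n_reads)
  for (k in seq_len(n_reads)) {
    g <- src[k]
    repeat {
      len <- round(stats::rnorm(1, length_mean, length_sd))
      if (len >= min_length && len <= glens[g]) break
    }
    start <- sample.int(glens[g] - len + 1L, 1L)
    tmpl <- substr(genomes$seq[g], start, start + len - 1L)
    rd <- apply_read_errors(tmpl, sub_rate, ins_rate, del_rate)
    if (stats::runif(1) < rc_prob) rd <- reverse_complement(rd)
    reads[k] <- rd
  }
  ids <- sprintf("%s%05d", prefix, seq_len(n_reads))
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read_id = ids,
                          taxon_id = genomes$taxon_id[src],
                          doc_id = genomes$doc_id[src],
                          stringsAsFactors = FALSE))
}

#' Simulate null reads from a clade absent from the index
#'
#' A null root is derived from the indexed root at `null_divergence`
#' (comfortably past the point where long exact matches to the index are
#' homology rather than chance), several null species descend from it at
#' `inter_divergence`, and reads are drawn with the same error model as
#' positive reads. Null reads carry truth label `-` (absent from index).
#'
#' @param root The indexed pangenome's root genome (character scalar).
#' @param n_reads Number of null reads.
#' @param n_species Null species count.
#' @param null_divergence Substitution fraction indexed root -> null root
#'   (>= 0.25).
#' @param inter_divergence Divergence null root -> null species.
#' @param genomes Optional precomputed null genome data.frame (as returned
#'   in `$genomes`); reuse it to draw several read batches from one clade.
#' @param seed Optional RNG seed.
#' @param prefix Read-id prefix.
#' @inheritParams simulate_reads
#' @return A list: `reads`, `truth` (taxon_id = `"-"`), `genomes` (the null
#'   genome data.frame, for drawing further batches).
#' @export
simulate_null_reads <- function(root, n_reads = 1000, n_species = 5,
                                null_divergence = 0.3,
                                inter_divergence = 0.10,
                                genomes = NULL,
                                length_mean = 9000, length_sd = NULL,
                                min_length = 100,
                                sub_rate = 0.03, ins_rate = 0.02,
                                del_rate = 0.02,
                                rc_prob = 0.5, seed = NULL,
                                prefix = "null") {
  stopifnot(null_divergence >= 0.25)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genomes)) {
    null_root <- mutate_genome(root, null_divergence)
    seqs <- vapply(seq_len(n_species),
                   function(s) mutate_genome(null_root, inter_divergence),
                   character(1))
    genomes <- data.frame(genome_id = paste0("nullsp", seq_len(n_species)),
                          seq = seqs, doc_id = NA_integer_,
                          taxon_id = NA_integer_, stringsAsFactors = FALSE)
  }
  sim <- simulate_reads(genomes, n_reads = n_reads,
                        length_mean = length_mean, length_sd = length_sd,
                        min_length = min_length,
                        sub_rate = sub_rate, ins_rate = ins_rate,
                        del_rate = del_rate, rc_prob = rc_prob,
                        seed = NULL, prefix = prefix)
  sim$truth$taxon_id <- "-"
  sim$truth$doc_id <- NA_integer_
  sim$genomes <- genomes
  list(reads = sim$reads, truth = sim$truth, genomes = genomes)
}

#' Held-out genomes as a read-source table
#'
#' @param pg Output of [simulate_pangenome()].
#' @return Data frame suitable for [simulate_reads()]: one row per held-out
#'   genome with its species' doc and taxon ids.
#' @export
heldout_sources <- function(pg) {
  data.frame(genome_id = names(pg$heldout),
             seq = unname(pg$heldout),
             doc_id = seq_along(pg$heldout) - 1L,
             taxon_id = pg$species_taxa,
             stringsAsFactors = FALSE)
}
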