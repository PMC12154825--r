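---
title: "Run-colored move-structure classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Run-colored move-structure classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runcolor)
```

## The problem

Taxonomic classification of long reads asks, for each sequencing read, which
reference genome(s) — or which node of a taxonomy — it most plausibly came
from. k-mer classifiers fix a single match length ahead of time;
full-text-index classifiers instead find matches of any length, at the cost
of heavier machinery. This package implements a run-length compressed
full-text approach: a move-structure (BWT) index whose runs are annotated
with *colors*, the sets of documents (classification units, e.g. species)
that contribute suffixes to each run.

## The index

The references are grouped into documents $D_0,\dots,D_{|D|-1}$,
concatenated in document order, and terminated with a single `$` that sorts
before every base. From the concatenated text $S$ (length $n$) we build the
suffix array (prefix doubling), the BWT ($\mathrm{BWT}[i] = S[SA[i]-1]$),
the LCP array (Kasai), and the document array $DA[i]$ = document containing
position $SA[i]$. The document of a suffix is the document containing its
*start*; suffixes may run across document boundaries, and the terminator
suffix is attributed to the last document so every run color is nonempty.

The BWT of a redundant collection has few maximal equal-letter runs
($r \ll n$). The move table stores one row per run: the run character, its
length, and the LF-mapping destination of the run head as a (run, offset)
pair. An LF step for any position is a table hop plus a "fast-forward" loop
across run boundaries. We do not split long runs to bound the fast-forward
(the constant-time refinement used by production move structures); at the
scales this package targets the loop is short and correctness is unaffected.

Each run's color is $C_i = \{DA[p] : p \in \text{run } i\}$, a set (row
multiplicities are discarded). Distinct colors are deduplicated into a color
table and numbered by first appearance in run order, which makes builds
deterministic; each move row keeps only its color id. The table can be held
densely (one presence bit per document, $|C|\times|D|$ bits) or sparsely
(the sorted doc ids, $|C| \times b$ integers for mean set size $b$);
`encode_color()` picks dense automatically up to 64 documents. The
compression payoff is summarized by $r/|C|$, the mean number of runs sharing
a color.

## Queries: pseudo-matching lengths

A read $R$ is processed right-to-left while tracking a *single* BWT
position, initialized at the last BWT offset. If the tracked run's character
equals the next read character (case 1) the current match length $\ell$
grows by one; otherwise (case 2) the position is *repositioned* to a nearby
run of the required character and $\ell$ resets to zero. After recording
$\mathrm{PML}[k] = \ell$ the LF-mapping is applied. The resulting
pseudo-matching lengths are a lower bound on the matching statistics
($\mathrm{PML}[k] \le \mathrm{MS}[k]$), which the test suite verifies
against a brute-force substring-scan oracle.

Repositioning direction is decided by a per-run, per-character threshold:
within-run offsets below the threshold go up (to the last offset of the
nearest preceding run of that character), the rest go down (to the first
offset of the nearest following run). The *true* threshold is derived from
the flat position of the minimum LCP value strictly between the nearest
occurrence of the character above the run and the nearest below — the side
containing the minimum is the side to avoid, because crossing it truncates
the preserved match. Ties take the first (topmost) minimum. When the
character is absent above, the threshold is 0 (always down); absent below,
the run length (always up); absent from the BWT entirely, the position is
left unchanged and the PML is 0 (the same rule handles non-ACGT read
characters such as N).

Two threshold-free strategies are provided for indexes built without LCP
information: **always-up** (threshold = run length) and **mid-run**
(threshold = $\lceil n_{\mathrm{run}}/2 \rceil$; the ceiling is our fixed
choice where "midway" leaves rounding open). If the chosen direction has no
occurrence, the other direction is used, which keeps the query total.

## Classification

**Scoring.** At each read position with $\mathrm{PML}[k] > 0$, every
document in the color of the *post-LF* run receives +1. We follow the
pseudocode ordering (score update after LF) rather than the looser prose
"runs the process moves through": after LF the tracked row's suffix begins
with the just-matched string, so its run's color describes the documents
containing that match context. Repositioned (case-2) positions contribute
nothing, because their length is zero.

**Binary gate.** Before multi-class classification, a read must look like it
belongs to the index at all: its average PML (PML sum / read length) must
exceed a cutoff calibrated as the nearest-rank 95th percentile
($\lceil 0.95\,n\rceil$-th smallest; deterministic and well defined for
small $n$) of the average PMLs of *null* reads known to be absent from the
index. This is a level-0.05 test; about 5% of fresh null reads pass. The
gate can be disabled when no null set exists.

**Reporting.** Among the scored documents, the best one $D_{best}$ is
reported (ties broken toward the smallest doc id), plus up to
`max_secondary` (default 1) further documents whose *raw* score is at least
`ratio` (default 0.95) of $D_{best}$'s — we apply the ratio to raw counts,
not normalized scores. A single reported document is assigned its own
taxon; several are assigned their lowest common ancestor, which moves the
call up the taxonomy exactly when the evidence is ambiguous.

**Strand.** The index stores only the forward strand. Each read is queried
as-is and reverse-complemented, and the orientation with the higher average
PML is kept (ties favor forward). Both the gate and scoring use that
orientation.

## Evaluation scheme

At a rank (say species): reads whose truth label has no ancestor at that
rank are excluded; an unclassified positive read is a false negative; a
prediction whose ancestor at the rank equals the truth's is a true positive
(calls *below* the rank project up); a prediction strictly above the rank
but on the truth lineage is a vague positive; everything else is a false
positive. Negative reads are excluded when unclassified and are false
positives when classified — the convention of the k-mer classifier
literature; the published formulas do not say how true negatives enter, so
we exclude them and state it here. Then
$\mathrm{precision} = TP/(TP+FP)$ and
$\mathrm{recall} = TP/(TP+VP+FN+FP)$; counts always satisfy
$TP+VP+FP+FN = n_{\mathrm{evaluated}}$.

## The synthetic pangenome generator

The generator is first-class, tested code; every stage of the pipeline is
testable without downloads.

* **Pangenome**: a root genome i.i.d. uniform over ACGT; one ancestor per
  species by point substitution at `inter_divergence` (default 0.10); each
  genome of a species from its ancestor at `intra_divergence` (default
  0.01); one genome per species held out for read simulation, the rest form
  the species' document. Species are grouped pairwise into genera under a
  single root so rank projection and LCA have something to do.
* **Reads**: uniform start, normal length truncated at 100 bp (default mean
  9,000 bp, emulating current nanopore long-read averages; sd defaults to
  20% of the mean), per-base substitution/insertion/deletion errors
  (defaults 3%/2%/2%, ONT-like ~7% total), half the reads
  reverse-complemented.
* **Null reads**: a null root at `null_divergence` = 0.30 from the indexed
  root (comfortably past the 25% floor below which residual homology could
  leak into the null distribution), five null species under it, same error
  model — emulating a clade absent from the index.

Everything is deterministic given a seed. What the generator does *not*
emulate: structural variation and rearrangement between genomes (divergence
is substitution-only), chemistry-specific error profiles and homopolymer
artifacts, composition bias, and contamination. Passing tests therefore
demonstrate the machinery and its operating characteristics under a clean
substitution model, not performance on real metagenomes.

## Problem sizes used in the shipped experiments

The gate experiments use the generator's default study conditions: 5
species × 3 genomes × 100 kb (index over the 2 retained genomes per
species, $n \approx 1$ Mb), 2,000 calibration nulls, 2,000 evaluation
nulls, 2,000 positive reads of mean 9,000 bp at 7% error. The
strategy-robustness experiment uses 50 kb genomes with 2,000 positive and
1,000 + 1,000 null reads of mean 3,000 bp — enough reads that the binomial
noise of the ~5% of nulls passing each strategy's own calibrated gate does
not dominate the sub-percentage-point differences being compared.

## Numerical and degenerate-input choices

* 0-based positions and doc ids, half-open intervals, everywhere.
* Sequences are sanitized by splitting on non-ACGT stretches (pieces stay
  in the same document; no artificial adjacencies).
* A length-1 run's shared LCP is its suffix length (vacuous minimum).
* `classify_read` with all-zero scores returns unclassified even when the
  gate passes.
* `calibrate_cutoff` refuses fewer than 20 null values.
* Index files are versioned; corrupt or mismatched files are refused with
  explicit errors.

## Known limitations

* The suffix array is built in memory by prefix doubling
  ($O(n\log^2 n)$); practical to a few tens of Mb, not to real reference
  databases, whose external-memory BWT construction is out of scope here.
* No run splitting, so a single LF step is not worst-case constant time.
* Colors are stored as plain sets; meta-color or spanning-tree compression
  of the color table is not attempted.
* Abundance estimation from the per-document scores (e.g. via EM) is not
  implemented.
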