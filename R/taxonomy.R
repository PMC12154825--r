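RANK_ORDER <- c("species", "genus", "family", "order", "class",
                "phylum", "kingdom", "domain")

#' Construct a taxonomy tree
#'
#' @param id Integer node ids.
#' @param parent Integer parent ids; the root is its own parent.
#' @param rank Character ranks (e.g. "species", "genus"); unranked
#'   intermediate nodes are allowed (any label outside the canonical order).
#' @param name Character node names.
#' @return An object of class `taxonomy_tree` with fields `id`, `parent`,
#'   `rank`, `name`, `root`.
#' @export
taxonomy_tree <- function(id, parent, rank, name = as.character(id)) {
  id <- as.integer(id); parent <- as.integer(parent)
  if (anyDuplicated(id)) stop("duplicate node ids")
  if (!all(parent %in% id)) stop("orphan node: parent id not in tree")
  root <- id[parent == id]
  if (length(root) != 1) stop("taxonomy must have exactly one root (parent == id)")
  tree <- structure(
    list(id = id, parent = parent, rank = as.character(rank),
         name = as.character(name), root = root),
    class = "taxonomy_tree")
  # cycle check: every node must reach the root
  pidx <- match(parent, id)
  for (k in seq_along(id)) {
    cur <- k; steps <- 0L
    while (id[cur] != root) {
      cur <- pidx[cur]; steps <- steps + 1L
      if (steps > length(id)) stop("cycle detected in taxonomy")
    }
  }
  tree
}

#' Load a taxonomy from file
#'
#' The native format is a headerless 4-column TSV: `id<TAB>parent<TAB>rank
#' <TAB>name`. NCBI-style `nodes.dmp` (fields separated by `\t|\t`) is
#' accepted with `dialect = "ncbi"`; names then default to the ids.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"ncbi"`.
#' @return A `taxonomy_tree`.
#' @export
load_taxonomy <- function(path, dialect = c("tsv", "ncbi")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            quote = "", comment.char = "",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 3) stop("taxonomy TSV needs id, parent, rank[, name]")
    if (ncol(df) < 4) df[[4]] <- as.character(df[[1]])
    taxonomy_tree(df[[1]], df[[2]], df[[3]], df[[4]])
  } else {
    lines <- readLines(path)
    # nodes.dmp fields are separated by "\t|\t" and lines end with "\t|"
    lines <- sub("\t\\|$", "", lines)
    parts <- strsplit(lines, "\t|\t", fixed = TRUE)
    id <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    parent <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    rank <- vapply(parts, function(p) trimws(p[3]), character(1))
    taxonomy_tree(id, parent, rank)
  }
}

#' Ancestors of a node, self first, root last
#'
#' @param tree A `taxonomy_tree`.
#' @param node Node id.
#' @return Integer vector of node ids.
#' @export
ancestors <- function(tree, node) {
  idx <- match(node, tree$id)
  if (is.na(idx)) stop("node not in tree: ", node)
  path <- integer(0)
  repeat {
    path <- c(path, tree$id[idx])
    if (tree$id[idx] == tree$root) break
    idx <- match(tree$parent[idx], tree$id)
  }
  path
}

#' Lowest common ancestor of a set of nodes
#'
#' @param tree A `taxonomy_tree`.
#' @param node_ids Nonempty integer vector of node ids.
#' @return The deepest node ancestral to (or equal to) every input.
#' @export
lca <- function(tree, node_ids) {
  node_ids <- unique(as.integer(node_ids))
  if (length(node_ids) == 0) stop("lca of an empty set")
  common <- ancestors(tree, node_ids[1])
  for (nd in node_ids[-1]) {
    anc <- ancestors(tree, nd)
    common <- common[common %in% anc]
  }
  common[1]
}

#' Ancestor of a node at a given rank
#'
#' Walks from the node towards the root and returns the first node whose
#' rank equals `rank` (the node itself qualifies). Returns `NA` when the
#' lineage has no node at that rank — including when the query node is
#' already above it.
#'
#' @param tree A `taxonomy_tree`.
#' @param node Node id.
#' @param rank One of species, genus, family, order, class, phylum,
#'   kingdom, domain.
#' @return Node id or `NA_integer_`.
#' @export
ancestor_at_rank <- function(tree, node, rank) {
  if (!rank %in% RANK_ORDER) stop("unknown rank: ", rank)
  path <- ancestors(tree, node)
  hit <- path[tree$rank[match(path, tree$id)] == rank]
  if (length(hit) == 0) NA_integer_ else hit[1]
}
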