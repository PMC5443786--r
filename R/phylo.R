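# Distance-based neighbor-joining phylogeny of cluster representatives
# with annotated Newick output.

#' Pairwise identity distance matrix
#'
#' `d = 1 - pairwise_identity`, using the clustering module's
#' global-alignment identity. Symmetric with a zero diagonal. Users who run
#' their own multiple alignment can skip this and hand
#' [neighbor_joining()] any distance matrix.
#'
#' @param representatives Tibble with `id`, `sequence`.
#' @return A symmetric numeric matrix with the ids as dimnames.
#' @export
distance_matrix <- function(representatives) {
  seqs <- as_sequence_tbl(representatives)
  n <- nrow(seqs)
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1)) {
    ids <- identity_to_set(seqs$sequence[i], seqs$sequence[(i + 1):n])
    d[i, (i + 1):n] <- 1 - ids
    d[(i + 1):n, i] <- 1 - ids
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Saitou-Nei, as implemented in \pkg{ape});
#' negative branch-length estimates are clamped to zero with a log note.
#' Additive matrices are inverted exactly.
#'
#' @param D Symmetric distance matrix with labels; `n >= 3` (for `n < 3` a
#'   trivial star is returned).
#' @return An [ape::as.phylo] tree (unrooted, binary for n >= 3).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    abort("neighbor_joining(): distance matrix must be symmetric")
  }
  n <- nrow(D)
  if (n < 2) abort("neighbor_joining(): need at least two taxa")
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", rownames(D)[1],
                                        D[1, 2] / 2, rownames(D)[2], D[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(as.dist(D))
  if (any(tr$edge.length < 0)) {
    smdiv_log("neighbor_joining: %d negative branch length(s) clamped to 0",
              sum(tr$edge.length < 0))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Write an annotated Newick tree
#'
#' Leaf labels are rewritten as `id|site|stage|origin` from the annotation
#' table; characters with structural meaning in Newick are replaced by
#' `_`. The output round-trips through [read_newick()].
#'
#' @param tree An `ape` phylo object.
#' @param annotations Optional tibble with `id` and any of `site`, `stage`,
#'   `origin`.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, annotations = NULL, path = NULL) {
  if (!is.null(annotations)) {
    ann <- as_tibble(annotations)
    stopifnot("id" %in% names(ann))
    idx <- match(tree$tip.label, ann$id)
    parts <- cbind(tree$tip.label,
                   if ("site" %in% names(ann)) ann$site[idx] else NULL,
                   if ("stage" %in% names(ann)) ann$stage[idx] else NULL,
                   if ("origin" %in% names(ann)) ann$origin[idx] else NULL)
    lab <- apply(parts, 1, function(r) paste(r[!is.na(r)], collapse = "|"))
    tree$tip.label <- lab
  }
  tree$tip.label <- gsub("[\\s,;:()\\[\\]']", "_", tree$tip.label, perl = TRUE)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick tree
#' @param path File path or a Newick string.
#' @return An `ape` phylo object.
#' @export
read_newick <- function(path) {
  if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
}
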