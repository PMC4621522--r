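# Chemotaxonomic clustering of species by cyclotide presence/absence.

#' Pairwise distance between species' cyclotide profiles
#'
#' Jaccard distance (default) is 1 - |A intersect B| / |A union B|, so
#' joint absence of a cyclotide carries no signal; simple matching is the
#' fraction of discordant records. A species with an empty profile gets
#' Jaccard distance 1 to every other species (logged via a message).
#'
#' @param x An `occurrence_matrix` (records x species) or a plain
#'   logical/0-1 matrix with species as columns.
#' @param metric `"jaccard"` (default) or `"simple_matching"`.
#' @return A `stats::dist` object labelled by species.
#' @export
profile_distance <- function(x, metric = c("jaccard", "simple_matching")) {
  metric <- match.arg(metric)
  m <- unclass(x) * 1
  if (ncol(m) < 2L) {
    abort("need at least two species columns", class = "cycloscreen_input_error")
  }
  m <- (m[, order(colnames(m)), drop = FALSE] > 0) * 1
  empty <- colSums(m) == 0
  if (metric == "jaccard" && any(empty)) {
    message(sprintf("%d species with empty profiles assigned distance 1 to all",
                    sum(empty)))
  }
  inter <- crossprod(m)
  s <- colSums(m)
  both <- outer(s, s, "+")
  d <- if (metric == "jaccard") {
    un <- both - inter
    j <- ifelse(un == 0, 1, 1 - inter / un)
    diag(j) <- 0
    j
  } else {
    (both - 2 * inter) / nrow(m)
  }
  as.dist(d)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering yielding an ultrametric rooted
#' tree (leaf-to-root path length is half the merge distance). Labels are
#' sorted lexicographically before clustering so equal-distance ties are
#' broken deterministically on the smallest label pair.
#'
#' @param d A `dist` object or symmetric matrix.
#' @return An [ape::ape-package] `phylo` tree (rooted, ultrametric).
#' @export
upgma_tree <- function(d) {
  d <- stats::as.dist(as.matrix(d))
  labs <- attr(d, "Labels")
  dm <- as.matrix(d)[order(labs), order(labs)]
  hc <- hclust(as.dist(dm), method = "average")
  # as.phylo() places each leaf at half the merge distance from the root,
  # the standard UPGMA ultrametric convention.
  ape::as.phylo(hc)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (unrooted); additive distance matrices are
#' recovered exactly. Negative branch lengths are clamped to zero and the
#' total clamped deficit is attached as attribute `clamped_deficit`.
#'
#' @param d A `dist` object or symmetric matrix over at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) < 3L) {
    abort("neighbor joining needs at least 3 taxa",
          class = "cycloscreen_input_error")
  }
  ord <- order(rownames(dm))
  phy <- ape::nj(as.dist(dm[ord, ord]))
  deficit <- -sum(pmin(phy$edge.length, 0))
  if (deficit > 0) {
    message(sprintf("clamped negative NJ branch lengths (total deficit %.4g)",
                    deficit))
    phy$edge.length <- pmax(phy$edge.length, 0)
  }
  attr(phy, "clamped_deficit") <- deficit
  phy
}

#' Serialize a tree to newick
#'
#' @param tree A `phylo` tree.
#' @param path Optional output file; when `NULL` the newick string is
#'   returned.
#' @return The newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  if (anyDuplicated(tree$tip.label)) {
    abort("duplicate leaf labels cannot be serialized",
          class = "cycloscreen_serialization_error")
  }
  if (is.null(path)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = path)
    invisible(ape::write.tree(tree))
  }
}
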