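#' Group-average distance matrix
#'
#' Collapses a per-protein distance matrix to a per-group matrix: the
#' entry for groups G != H is the arithmetic mean of d(x, y) over all
#' cross pairs x in G, y in H; the diagonal is 0. This is the matrix the
#' subgroup-level neighbour-joining trees are built from.
#'
#' @param D labeled symmetric distance matrix.
#' @param groups named character vector (or factor) mapping every id in
#'   `D` to its group.
#' @return labeled symmetric matrix over the groups.
#' @export
group_average_matrix <- function(D, groups) {
  D <- check_square_matrix(D)
  ids <- rownames(D)
  if (is.null(names(groups))) {
    if (length(groups) != nrow(D)) stop("group map size mismatch")
    names(groups) <- ids
  }
  missing_ids <- setdiff(ids, names(groups))
  if (length(missing_ids) > 0) {
    stop("ids without a group: ", paste(missing_ids, collapse = ", "))
  }
  g <- as.character(groups[ids])
  glev <- unique(g)
  if (length(glev) < 2) stop("need at least 2 groups")
  if (any(table(factor(g, glev)) == 0)) stop("empty group")
  G <- matrix(0, length(glev), length(glev), dimnames = list(glev, glev))
  for (i in seq_along(glev)) {
    for (j in seq_along(glev)) {
      if (i >= j) next
      block <- D[g == glev[i], g == glev[j], drop = FALSE]
      G[i, j] <- G[j, i] <- mean(block)
    }
  }
  G
}

#' Neighbour-joining tree
#'
#' Classical Saitou-Nei agglomeration (via ape) on a labeled distance
#' matrix. Negative branch lengths, which NJ can produce on non-additive
#' input, are clamped to 0; the pre-clamp lengths are kept in the
#' `pre_clamp_edge_lengths` attribute.
#'
#' @param D labeled symmetric distance matrix with >= 3 taxa.
#' @return an `ape::phylo` tree (unrooted).
#' @export
neighbor_joining <- function(D) {
  D <- check_square_matrix(D)
  if (nrow(D) < 3) stop("neighbour joining needs at least 3 taxa")
  tree <- ape::nj(stats::as.dist(D))
  if (any(tree$edge.length < 0)) {
    attr(tree, "pre_clamp_edge_lengths") <- tree$edge.length
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  tree
}

#' UPGMA tree
#'
#' Average-linkage agglomerative clustering of the distance matrix, with
#' node heights equal to half the merge distance (so leaf-to-leaf path
#' lengths reproduce an ultrametric input exactly). The underlying hclust
#' merge structure is retained so the dendrogram can be cut into k
#' clusters.
#'
#' @param D labeled symmetric distance matrix with >= 2 taxa.
#' @return an `ape::phylo` tree (rooted, ultrametric) with the `hclust`
#'   object stored in the `"hclust"` attribute.
#' @export
upgma <- function(D) {
  D <- check_square_matrix(D)
  if (nrow(D) < 2) stop("UPGMA needs at least 2 taxa")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  tree <- ape::as.phylo(hc)
  attr(tree, "hclust") <- hc
  tree
}

#' Cut a UPGMA dendrogram into k clusters
#'
#' Removes the k-1 highest merges of the average-linkage dendrogram,
#' yielding k clusters.
#'
#' @param tree a tree returned by [upgma()] (or an `hclust` object).
#' @param k number of clusters, `1 <= k <=` leaf count.
#' @return named integer vector of cluster memberships.
#' @export
cut_tree <- function(tree, k) {
  hc <- if (inherits(tree, "hclust")) tree else attr(tree, "hclust")
  if (is.null(hc)) stop("cut_tree needs a UPGMA tree (no hclust attribute)")
  n <- length(hc$labels)
  if (k < 1 || k > n) stop("k must be in 1..", n)
  stats::cutree(hc, k = k)
}

#' Bootstrap supports for a profile-based tree
#'
#' Resamples the 210 profile coordinates with replacement (the analogue of
#' site resampling in sequence phylogenetics), recomputes the distance
#' matrix and the tree for each replicate, and reports for every internal
#' bipartition of the reference tree the fraction of replicates containing
#' it. Fully deterministic given `seed`.
#'
#' @param profiles named list of `energy_profile`s or a profile matrix
#'   (rows = proteins).
#' @param method `"nj"` or `"upgma"`.
#' @param n_reps number of bootstrap replicates (the analyses this package
#'   mirrors use 100).
#' @param seed integer seed.
#' @param metric distance metric for [distance_matrix()].
#' @return the reference tree with `node.label` set to supports in
#'   \[0, 1\] (root label empty) and the replicate trees in the
#'   `"replicates"` attribute.
#' @export
bootstrap_support <- function(profiles, method = c("nj", "upgma"),
                              n_reps = 100L, seed = 1L,
                              metric = "manhattan") {
  method <- match.arg(method)
  stopifnot(n_reps >= 1)
  X <- profiles_as_matrix(profiles)
  build <- function(M) {
    D <- distance_matrix(M, metric = metric)
    if (method == "nj") neighbor_joining(D) else upgma(D)
  }
  ref <- build(X)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(X), replace = TRUE)
      build(X[, cols, drop = FALSE])
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(ref, reps, rooted = (method == "upgma"))
  counts[is.na(counts)] <- 0
  support <- counts / n_reps
  ref$node.label <- formatC(support, format = "f", digits = 3)
  ref$node.label[1] <- ""  # root bipartition is not informative
  attr(ref, "support") <- support
  attr(ref, "replicates") <- reps
  ref
}

#' Branching order of leaves relative to an anchor
#'
#' Operationalizes "which lineage splits off first" for comparing a tree
#' against a reference arrangement: the tree is rooted on the edge leading
#' to `anchor`, and the remaining leaves are ordered by the topological
#' depth (edge count from the root) at which their subtree diverges --
#' concretely, by the depth of the leaf's parent node, with ties broken
#' alphabetically by label. The order is invariant to rotation of children
#' at internal nodes.
#'
#' @param tree an `ape::phylo` tree.
#' @param anchor a leaf label present in the tree.
#' @return character vector: the non-anchor leaves in branching order.
#' @export
branching_order <- function(tree, anchor) {
  stopifnot(inherits(tree, "phylo"))
  if (!(anchor %in% tree$tip.label)) {
    stop("anchor '", anchor, "' is not a leaf of the tree")
  }
  rooted <- if (length(tree$tip.label) > 2) {
    ape::root(tree, outgroup = anchor, resolve.root = TRUE)
  } else {
    tree
  }
  n_tip <- length(rooted$tip.label)
  root_node <- n_tip + 1L
  # topological depth of every node
  depth <- integer(n_tip + rooted$Nnode)
  depth[root_node] <- 0L
  children <- split(rooted$edge[, 2], rooted$edge[, 1])
  queue <- root_node
  while (length(queue) > 0) {
    nd <- queue[1]
    queue <- queue[-1]
    kids <- children[[as.character(nd)]]
    if (is.null(kids)) next
    depth[kids] <- depth[nd] + 1L
    queue <- c(queue, kids[kids > n_tip])
  }
  leaves <- setdiff(seq_len(n_tip), match(anchor, rooted$tip.label))
  labs <- rooted$tip.label[leaves]
  parent_depth <- depth[leaves] - 1L
  labs[order(parent_depth, labs)]
}

#' Write / read trees in Newick format
#'
#' Thin wrappers over ape's Newick I/O; branch lengths are serialized with
#' 6 decimals and internal node labels (bootstrap supports) are preserved.
#'
#' @param tree an `ape::phylo`.
#' @param path output (input) file path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()`
#'   returns an `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ape::read.tree(path)
}
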