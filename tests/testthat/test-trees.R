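test_that("group-average matrix takes arithmetic means of cross blocks", {
  ids <- c("a1", "a2", "b1", "b2")
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["a1", "b1"] <- D["b1", "a1"] <- 1
  D["a1", "b2"] <- D["b2", "a1"] <- 5
  D["a2", "b1"] <- D["b1", "a2"] <- 3
  D["a2", "b2"] <- D["b2", "a2"] <- 7
  D["a1", "a2"] <- D["a2", "a1"] <- 2
  D["b1", "b2"] <- D["b2", "b1"] <- 4
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  G <- group_average_matrix(D, groups)
  expect_equal(G["A", "B"], 4.0)  # mean(1, 5, 3, 7)
  expect_equal(G["A", "A"], 0)
  # permuting ids leaves the group matrix unchanged
  perm <- c("b2", "a1", "b1", "a2")
  G2 <- group_average_matrix(D[perm, perm], groups)
  expect_equal(G2[rownames(G), colnames(G)], G)
  # two singleton groups give the single cross distance
  Gs <- group_average_matrix(D[c("a1", "b1"), c("a1", "b1")],
                             c(a1 = "A", b1 = "B"))
  expect_equal(Gs["A", "B"], 1)
  expect_error(group_average_matrix(D, c(a1 = "A", a2 = "A", b1 = "A",
                                         b2 = "A")), "2 groups")
})

test_that("neighbour joining solves the three-leaf case in closed form", {
  ids <- c("A", "B", "C")
  D <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, dimnames = list(ids, ids))
  tree <- neighbor_joining(D)
  # three-point formulas: l_A = (d_AB + d_AC - d_BC)/2 = 0, l_B = 2, l_C = 4
  tip_edge <- function(tr, lab) {
    tr$edge.length[tr$edge[, 2] == match(lab, tr$tip.label)]
  }
  expect_equal(tip_edge(tree, "A"), 0)
  expect_equal(tip_edge(tree, "B"), 2)
  expect_equal(tip_edge(tree, "C"), 4)
})

test_that("neighbour joining reconstructs additive metrics exactly", {
  for (seed in c(1, 2, 3)) {
    gen <- additive_tree_distances(n_leaves = 8, seed = seed)
    tree <- neighbor_joining(gen$D)
    expect_null(attr(tree, "pre_clamp_edge_lengths"))
    Dhat <- ape::cophenetic.phylo(tree)
    Dhat <- Dhat[rownames(gen$D), colnames(gen$D)]
    expect_lt(max(abs(Dhat - gen$D)), 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(gen$tree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("the generated additive matrices satisfy the four-point condition", {
  gen <- additive_tree_distances(n_leaves = 8, seed = 5)
  D <- gen$D
  ids <- rownames(D)
  set.seed(1)
  for (t in 1:30) {
    q <- sample(ids, 4)
    s1 <- D[q[1], q[2]] + D[q[3], q[4]]
    s2 <- D[q[1], q[3]] + D[q[2], q[4]]
    s3 <- D[q[1], q[4]] + D[q[2], q[3]]
    sums <- sort(c(s1, s2, s3))
    expect_lt(sums[3] - sums[2], 1e-9)  # two largest sums are equal
  }
})

test_that("UPGMA reconstructs ultrametrics and matches average-linkage cuts", {
  ids <- c("A", "B")
  D2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(ids, ids))
  tr2 <- upgma(D2)
  expect_equal(sort(tr2$edge.length), c(1, 1))
  # an ultrametric built from a seeded UPGMA-style hierarchy round-trips
  set.seed(9)
  X <- matrix(rnorm(7 * 4), 7, 4)
  rownames(X) <- paste0("t", 1:7)
  hc <- hclust(dist(X), method = "average")
  DU <- as.matrix(cophenetic(hc))
  tru <- upgma(DU)
  DT <- ape::cophenetic.phylo(tru)[rownames(DU), colnames(DU)]
  expect_lt(max(abs(DT - DU)), 1e-9)
  # cutting the dendrogram reproduces average-linkage clustering
  same_partition <- function(a, b) {
    identical(as.integer(factor(a, unique(a))),
              as.integer(factor(b, unique(b))))
  }
  for (k in c(1, 2, 3, 7)) {
    expect_true(same_partition(cut_tree(tru, k), cutree(hc, k)))
  }
  expect_equal(adjusted_rand_index(cut_tree(tru, 3), cutree(hc, 3)), 1)
  expect_error(cut_tree(tru, 0), "k must be")
  expect_error(cut_tree(tru, 8), "k must be")
})

test_that("UPGMA cut recovers planted cluster structure", {
  gp <- gaussian_profile_clusters(k = 4, n_per = 5, separation = 80,
                                  noise_sd = 0.02, seed = 13)
  D <- distance_matrix(gp$profiles)
  tree <- upgma(D)
  cl <- cut_tree(tree, 4)
  expect_equal(adjusted_rand_index(cl, gp$labels), 1)
  # k = 1 and k = n edge cases
  expect_equal(length(unique(cut_tree(tree, 1))), 1L)
  expect_equal(length(unique(cut_tree(tree, nrow(D)))), nrow(D))
})

test_that("NJ and UPGMA agree on ultrametric input topologies", {
  set.seed(11)
  X <- matrix(rnorm(6 * 3), 6, 3)
  rownames(X) <- paste0("u", 1:6)
  hc <- hclust(dist(X), method = "average")
  DU <- as.matrix(cophenetic(hc))
  t_nj <- neighbor_joining(DU)
  t_up <- upgma(DU)
  expect_equal(ape::dist.topo(ape::unroot(t_nj), ape::unroot(t_up)), 0,
               ignore_attr = TRUE)
})

test_that("bootstrap supports are deterministic and saturate on separated clusters", {
  gp <- gaussian_profile_clusters(k = 2, n_per = 4, separation = 100,
                                  noise_sd = 0.01, seed = 7)
  t1 <- bootstrap_support(gp$profiles, method = "nj", n_reps = 25, seed = 5)
  t2 <- bootstrap_support(gp$profiles, method = "nj", n_reps = 25, seed = 5)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  expect_equal(length(attr(t1, "replicates")), 25L)
  # the bipartition separating the two planted clusters has support 1
  part <- ape::prop.part(attr(t1, "replicates"))
  labs <- attr(part, "labels")
  target <- sort(names(gp$labels)[gp$labels == "C1"])
  # a bipartition can be stored as either side of the split
  hits <- 0
  for (i in seq_along(part)) {
    grp <- sort(labs[part[[i]]])
    comp <- sort(setdiff(labs, grp))
    if (identical(grp, target) || identical(comp, target)) {
      hits <- hits + attr(part, "number")[i]
    }
  }
  expect_equal(hits, 25)
  # single replicate: supports are 0 or 1
  t3 <- bootstrap_support(gp$profiles, method = "upgma", n_reps = 1, seed = 2)
  expect_true(all(attr(t3, "support") %in% c(0, 1)))
})

test_that("branching order reads the ladder of a caterpillar tree", {
  cat_tree <- ape::read.tree(text = "((((A:1,B:1):1,C:1):1,D:1):1,E:1);")
  expect_equal(branching_order(cat_tree, "E"), c("D", "C", "A", "B"))
  # 3-leaf tree anchored at A: B and C split at the same node
  tri <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(branching_order(tri, "A"), c("B", "C"))
  # invariance to child rotation
  rot <- ape::read.tree(text = "(E:1,(D:1,(C:1,(B:1,A:1):1):1):1);")
  expect_equal(branching_order(rot, "E"), branching_order(cat_tree, "E"))
  expect_error(branching_order(cat_tree, "Z"), "not a leaf")
})

test_that("Newick round trip preserves topology, lengths and supports", {
  gen <- additive_tree_distances(n_leaves = 8, seed = 8)
  tree <- neighbor_joining(gen$D)
  path <- tempfile(fileext = ".nwk")
  on.exit(unlink(path))
  write_newick(tree, path)
  back <- read_newick(path)
  expect_equal(sort(back$tip.label), sort(tree$tip.label))
  expect_equal(ape::dist.topo(back, tree), 0, ignore_attr = TRUE)
  D1 <- ape::cophenetic.phylo(tree)
  D2 <- ape::cophenetic.phylo(back)[rownames(D1), colnames(D1)]
  expect_lt(max(abs(D1 - D2)), 1e-5)  # 6-decimal serialization
  # supports survive as internal node labels
  gp <- gaussian_profile_clusters(k = 2, n_per = 3, separation = 60,
                                  noise_sd = 0.01, seed = 4)
  bt <- bootstrap_support(gp$profiles, method = "nj", n_reps = 10, seed = 3)
  write_newick(bt, path)
  back2 <- read_newick(path)
  expect_true(!is.null(back2$node.label))
})
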