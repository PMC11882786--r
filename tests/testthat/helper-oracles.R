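# Independent oracle implementations used by the tests. These deliberately
# take the naive route (double loops, direct formula evaluation) and stay
# independent of the package's vectorized code paths.

# Direct evaluation of the potential formula on a raw count array.
oracle_potential <- function(count_array, RT, sigma) {
  nt <- dim(count_array)[1]
  ns <- dim(count_array)[3]
  grand <- sum(count_array)
  out <- array(0, dim = dim(count_array))
  for (i in seq_len(nt)) {
    for (j in i:nt) {
      Mij <- sum(count_array[i, j, ])
      if (Mij == 0) next
      for (d in seq_len(ns)) {
        fxx <- sum(count_array[, , d]) / grand
        if (fxx == 0) next
        fij <- count_array[i, j, d] / Mij
        out[i, j, d] <- RT * (log(1 + Mij * sigma) -
                              log(1 + Mij * sigma * fij / fxx))
      }
    }
  }
  out
}

# Brute-force 1-NN LOOCV on a distance matrix, smallest-index tie-break.
oracle_knn_loocv_accuracy <- function(D, labels) {
  n <- nrow(D)
  correct <- 0
  for (k in seq_len(n)) {
    best <- Inf
    pick <- NA
    for (m in seq_len(n)) {
      if (m == k) next
      if (D[k, m] < best) {
        best <- D[k, m]
        pick <- m
      }
    }
    if (labels[pick] == labels[k]) correct <- correct + 1
  }
  correct / n
}

# Pair-counting adjusted Rand index from the contingency table.
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  n <- length(x)
  choose2 <- function(v) v * (v - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  expected <- sum_i * sum_j / choose2(n)
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(0)
  (sum_ij - expected) / (maxidx - expected)
}

# Rank-then-Pearson Spearman with average ties.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Closest-set distance straight off the displayed formula.
oracle_closest_set <- function(A, B, D, within = FALSE) {
  tot <- 0
  for (a in A) {
    cand <- if (within) setdiff(B, a) else B
    tot <- tot + min(D[a, cand])
  }
  for (b in B) {
    cand <- if (within) setdiff(A, b) else A
    tot <- tot + min(D[b, cand])
  }
  tot / (length(A) + length(B))
}

# A tiny hand-built two-residue structure (ALA + GLY) with controlled
# geometry: 9 heavy atoms, all inter-atom distances within the shell range.
two_residue_structure <- function() {
  atoms <- data.frame(
    chain = "A",
    resno = c(rep(1L, 5), rep(2L, 4)),
    insert = "",
    resid = c(rep("ALA", 5), rep("GLY", 4)),
    elety = c("N", "CA", "C", "O", "CB", "N", "CA", "C", "O"),
    x = c(0.0, 1.5, 2.2, 2.0, 1.8, 3.6, 4.9, 5.9, 6.1),
    y = c(0.0, 0.2, 1.4, 2.5, -1.1, 1.3, 1.6, 0.6, -0.5),
    z = c(0.0, 1.1, 1.3, 0.9, 1.9, 1.8, 1.1, 1.7, 1.2),
    res_index = c(rep(1L, 5), rep(2L, 4)),
    stringsAsFactors = FALSE
  )
  structure(list(id = "toyAG", atoms = atoms, sequence = "AG", length = 2L),
            class = "protein_structure")
}

# Random well-separated profile matrix for comparison tests.
random_profiles <- function(n, seed, scale = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 210, sd = scale), n, 210)
  rownames(X) <- sprintf("p%02d", seq_len(n))
  X
}
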