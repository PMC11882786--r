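# Deterministic synthetic-data generators. These are geometric toys, not
# physically realistic proteins: their purpose is to exercise every code
# path (atom typing, tessellation, shell binning, the potential formula,
# profile construction, predictor fitting, comparison and trees) with
# fully seeded, self-validating inputs.

#' Generate a synthetic protein structure
#'
#' Residue types are drawn uniformly from the 20-letter alphabet; residue
#' centers follow a seeded self-avoiding random walk with 3.8 Angstrom
#' steps (the C-alpha virtual bond length) and a 3.0 Angstrom minimum
#' center separation; each residue's full heavy-atom complement is placed
#' at small seeded offsets (0.3-1.5 Angstrom) around its center using
#' correct PDB atom names, so every atom resolves in the 167-type scheme.
#'
#' @param n_res residue count (>= 2).
#' @param seed integer seed; the same seed yields a byte-identical
#'   structure.
#' @param id structure id.
#' @return a `protein_structure`.
#' @export
synth_structure <- function(n_res = 30L, seed = 1L, id = NULL) {
  stopifnot(n_res >= 2)
  if (is.null(id)) id <- sprintf("synth%03d_s%d", n_res, seed)
  topo <- residue_topology()
  res_names <- names(topo)
  with_seed(seed, {
    restypes <- sample(res_names, n_res, replace = TRUE)
    # self-avoiding walk of residue centers
    centers <- matrix(NA_real_, n_res, 3)
    centers[1, ] <- c(0, 0, 0)
    for (k in 2:n_res) {
      placed <- FALSE
      for (try in 1:200) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- centers[k - 1, ] + 3.8 * u
        prev <- centers[seq_len(k - 1), , drop = FALSE]
        if (min(sqrt(rowSums((prev - matrix(cand, k - 1, 3,
                                            byrow = TRUE))^2))) >= 3.0) {
          centers[k, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        # restart the walk from the stuck position with a fresh direction;
        # with 3.8 steps and a 3.0 exclusion this is essentially unreachable
        stop("self-avoiding walk failed to place residue ", k)
      }
    }
    rows <- list()
    for (k in seq_len(n_res)) {
      atoms <- topo[[restypes[k]]]
      off <- matrix(stats::rnorm(3 * length(atoms)), ncol = 3)
      off <- off / sqrt(rowSums(off^2)) *
        stats::runif(length(atoms), 0.3, 1.5)
      rows[[k]] <- data.frame(
        chain = "A", resno = k, insert = "", resid = restypes[k],
        elety = atoms,
        x = round(centers[k, 1] + off[, 1], 3),
        y = round(centers[k, 2] + off[, 2], 3),
        z = round(centers[k, 3] + off[, 3], 3),
        res_index = k, stringsAsFactors = FALSE
      )
    }
    at <- do.call(rbind, rows)
    cmin <- min(stats::dist(centers))
    stopifnot(nrow(at) >= 4, cmin >= 3.0)
    s <- structure(
      list(id = id, atoms = at,
           sequence = paste(aa_three_to_one(restypes), collapse = ""),
           length = n_res),
      class = "protein_structure"
    )
    s
  })
}

#' Generate a synthetic training set
#'
#' `n` structures with lengths drawn from `len_range`. The generator
#' checks its own construction guarantee that every distance shell of the
#' pooled reference state is populated (f_xx(d) > 0 for all shells) and
#' re-seeds once if necessary.
#'
#' @param n number of structures.
#' @param len_range integer range of residue counts.
#' @param seed integer seed.
#' @return named list of `protein_structure`s.
#' @export
synth_training_set <- function(n = 12L, len_range = c(25L, 60L), seed = 1L) {
  stopifnot(n >= 1)
  base_seed <- as.integer(seed)
  for (round in 0:4) {
    sd <- base_seed + round * 1000003L
    lens <- with_seed(sd, {
      sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    })
    structures <- lapply(seq_len(n), function(k) {
      synth_structure(lens[k], seed = sd + k,
                      id = sprintf("train%02d", k))
    })
    names(structures) <- vapply(structures, function(s) s$id, character(1))
    counts <- accumulate_counts(structures, seed = sd)
    if (all(counts$shell_totals > 0)) {
      attr(structures, "counts") <- counts
      return(structures)
    }
  }
  stop("could not populate every distance shell; enlarge the training set")
}

#' Planted predictor-recovery case
#'
#' Generates a well-conditioned random 20x20 matrix P* (entries in
#' \[-2, 2\]), `n_cases` random compositions, and per-type energy targets
#' computed *exactly* from the composition model
#' e_i = N_i sum_j P*_ij n_j. Fitting the predictor on these cases must
#' recover P* to numerical precision, which is the module's
#' parameter-recovery oracle.
#'
#' @param n_cases number of training cases (>= 40 recommended).
#' @param seed integer seed.
#' @param max_condition resample bound on the design condition number.
#' @return list with `P_star` (20x20), `compositions` (list of
#'   `composition`), `type_energies` (list of length-20 vectors).
#' @export
planted_predictor_case <- function(n_cases = 60L, seed = 1L,
                                   max_condition = 1e6) {
  stopifnot(n_cases >= 21)
  aa <- aa_alphabet()
  with_seed(seed, {
    P_star <- matrix(stats::runif(400, -2, 2), 20, 20,
                     dimnames = list(aa, aa))
    repeat {
      comps <- lapply(seq_len(n_cases), function(k) {
        L <- sample(50:200, 1)
        w <- stats::runif(20, 0.2, 1)
        counts <- stats::rmultinom(1, L, w)[, 1]
        counts <- stats::setNames(as.integer(counts), aa)
        structure(list(counts = counts, fractions = counts / L, L = L),
                  class = "composition")
      })
      Fr <- do.call(rbind, lapply(comps,
                                  function(cc) as.numeric(cc$fractions)))
      if (kappa(crossprod(Fr), exact = TRUE) < max_condition) break
    }
    te <- lapply(comps, function(cc) {
      n <- as.numeric(cc$fractions)
      N <- as.numeric(cc$counts)
      stats::setNames(N * as.numeric(P_star %*% n), aa)
    })
    list(P_star = P_star, compositions = comps, type_energies = te)
  })
}

#' Labeled Gaussian profile clusters
#'
#' `k` cluster centers in 210-space with pairwise Manhattan separation at
#' least `separation`; each point is its center plus seeded Gaussian noise
#' whose expected Manhattan magnitude is far below the separation. Used to
#' exercise classification, clustering and tree cutting on a planted
#' truth.
#'
#' @param k number of clusters.
#' @param n_per number of points per cluster.
#' @param separation minimal pairwise L1 separation between centers.
#' @param noise_sd per-coordinate Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return list with `profiles` (matrix, rows = points), `labels` (named
#'   character), `centers`.
#' @export
gaussian_profile_clusters <- function(k = 3L, n_per = 8L, separation = 50,
                                      noise_sd = 0.01, seed = 1L) {
  stopifnot(k >= 2, n_per >= 1)
  with_seed(seed, {
    repeat {
      centers <- matrix(stats::rnorm(k * 210), k, 210)
      l1 <- as.matrix(stats::dist(centers, method = "manhattan"))
      m <- min(l1[upper.tri(l1)])
      if (m > 0) break
    }
    centers <- centers * (separation / m)  # enforce the minimal separation
    X <- matrix(NA_real_, k * n_per, 210)
    labels <- character(k * n_per)
    r <- 1L
    for (cl in seq_len(k)) {
      for (p in seq_len(n_per)) {
        X[r, ] <- centers[cl, ] + stats::rnorm(210, sd = noise_sd)
        labels[r] <- paste0("C", cl)
        r <- r + 1L
      }
    }
    rownames(X) <- sprintf("%s_p%02d", labels, rep(seq_len(n_per), k))
    colnames(X) <- aa_pair_codes()
    names(labels) <- rownames(X)
    list(profiles = X, labels = labels, centers = centers)
  })
}

#' Random additive tree metric
#'
#' Draws a random topology with positive branch lengths and returns the
#' leaf-to-leaf path-length distance matrix, which is additive by
#' construction. Neighbour joining must reconstruct the generating tree
#' exactly from it.
#'
#' @param n_leaves number of leaves (>= 4).
#' @param seed integer seed.
#' @return list with `tree` (ape::phylo, unrooted) and `D` (labeled
#'   distance matrix of path lengths).
#' @export
additive_tree_distances <- function(n_leaves = 8L, seed = 1L) {
  stopifnot(n_leaves >= 4)
  with_seed(seed, {
    tree <- ape::rtree(n_leaves, rooted = FALSE,
                       br = function(n) stats::runif(n, 0.5, 2))
    D <- ape::cophenetic.phylo(tree)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    list(tree = tree, D = D)
  })
}

#' Write a full fixture bundle to a directory
#'
#' Materializes a training set (PDB files + manifest), a query structure,
#' a FASTA file of all sequences, and a label table, so the command-line
#' pipeline can run end-to-end from files alone.
#'
#' @param dir output directory (created if needed).
#' @param n_train training-set size.
#' @param seed integer seed.
#' @return invisibly, a list of the written paths.
#' @export
write_fixture_bundle <- function(dir, n_train = 12L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  train <- synth_training_set(n = n_train, seed = seed)
  pdb_paths <- character(0)
  for (s in train) {
    p <- file.path(dir, paste0(s$id, ".pdb"))
    write_structure(s, p)
    pdb_paths <- c(pdb_paths, p)
  }
  manifest <- file.path(dir, "train_manifest.txt")
  writeLines(basename(pdb_paths), manifest)
  query <- synth_structure(40L, seed = as.integer(seed) + 500L,
                           id = "query")
  query_path <- file.path(dir, "query.pdb")
  write_structure(query, query_path)
  seqs <- vapply(train, function(s) s$sequence, character(1))
  seqs <- c(seqs, query = query$sequence)
  fasta <- file.path(dir, "sequences.fasta")
  write_fasta(seqs, fasta)
  labels <- file.path(dir, "labels.tsv")
  utils::write.table(
    data.frame(id = names(seqs),
               class = ifelse(grepl("^train0[0-6]", names(seqs)),
                              "G1", "G2")),
    labels, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, pdbs = pdb_paths, query = query_path,
                 fasta = fasta, labels = labels, dir = dir))
}
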