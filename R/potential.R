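#' Parameters of the knowledge-based potential
#'
#' @param RT energy scale in kcal/mol (default 0.582).
#' @param sigma weight given to each observation in the sparse-data
#'   correction (default 0.02).
#' @param grid a `shell_grid`.
#' @return object of class `potential_params`.
#' @export
potential_params <- function(RT = 0.582, sigma = 0.02, grid = shell_grid()) {
  stopifnot(RT > 0, sigma > 0, inherits(grid, "shell_grid"))
  structure(list(RT = RT, sigma = sigma, grid = grid),
            class = "potential_params")
}

#' Accumulate contact counts over a training set
#'
#' Pools Delaunay contact observations from a set of structures into the
#' count tensor M_ij(d): for every retained contact between atom types
#' (i, j) at shell d, the count of the unordered pair (min(i,j), max(i,j))
#' in shell d is incremented. Counts are pooled over the whole set because
#' the potential's frequencies are database frequencies, not per-structure
#' averages.
#'
#' @param structures list of `protein_structure` objects (or a single one).
#' @param scheme an `atom_type_scheme`.
#' @param grid a `shell_grid`.
#' @param exclude_intra passed to [delaunay_contacts()].
#' @param seed jitter seed passed to [delaunay_contacts()].
#' @return object of class `count_tensor`: list with `counts` (array
#'   `n_types x n_types x n_shells`, populated on `i <= j` only),
#'   `pair_totals` (`n_types x n_types`, upper triangle), `shell_totals`
#'   (length `n_shells`), `grand_total`, `scheme_version`, `grid`.
#' @export
accumulate_counts <- function(structures, scheme = build_atom_type_scheme(),
                              grid = shell_grid(), exclude_intra = TRUE,
                              seed = 1L) {
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  if (length(structures) == 0) stop("empty structure list")
  nt <- scheme$n_types
  ns <- grid$count
  counts <- array(0, dim = c(nt, nt, ns))
  total <- 0
  for (s in structures) {
    cs <- delaunay_contacts(s, scheme, grid,
                            exclude_intra = exclude_intra, seed = seed)
    e <- cs$edges
    if (nrow(e) == 0) next
    i <- pmin(e$type_a, e$type_b)
    j <- pmax(e$type_a, e$type_b)
    idx <- cbind(i, j, e$shell)
    # aggregate duplicate (i, j, shell) triplets before incrementing
    key <- paste(i, j, e$shell)
    tab <- table(key)
    first <- !duplicated(key)
    counts[idx[first, , drop = FALSE]] <-
      counts[idx[first, , drop = FALSE]] + as.numeric(tab[key[first]])
    total <- total + nrow(e)
  }
  if (total == 0) stop("no retained contacts in any training structure")
  structure(
    list(counts = counts,
         pair_totals = apply(counts, c(1, 2), sum),
         shell_totals = apply(counts, 3, sum),
         grand_total = total,
         scheme_version = scheme$version,
         grid = grid),
    class = "count_tensor"
  )
}

#' Convert contact counts into the distance-dependent potential
#'
#' For each atom-type pair (i, j) and distance shell d, the energy is
#'
#'   dE_ij(d) = RT \[ ln(1 + M_ij sigma) - ln(1 + M_ij sigma f_ij(d) / f_xx(d)) \]
#'
#' where M_ij is the total number of observations for the pair,
#' f_ij(d) = M_ij(d) / M_ij is the pair's relative frequency in shell d and
#' f_xx(d) is the relative frequency of *all* pairs in shell d (the
#' reference state). Shells observed more often than the background are
#' favourable (negative energy). Conventions where the formula is
#' undefined: pairs never observed (M_ij = 0) and shells with no
#' observations at all (f_xx(d) = 0) get energy exactly 0, the
#' information-free value.
#'
#' @param counts a `count_tensor`.
#' @param params a `potential_params`.
#' @return object of class `potential_table`: list with `energies` (array
#'   like `counts$counts`, symmetric in its first two indices), `counts`,
#'   `params`, `scheme_version`, `provenance` (optional manifest digest).
#' @export
compute_potential <- function(counts, params = potential_params()) {
  stopifnot(inherits(counts, "count_tensor"),
            inherits(params, "potential_params"))
  stopifnot(identical(params$grid$count, counts$grid$count))
  M <- counts$pair_totals            # nt x nt, i <= j
  Md <- counts$counts                # nt x nt x ns
  fxx <- counts$shell_totals / counts$grand_total
  nt <- dim(Md)[1]
  ns <- dim(Md)[3]
  energies <- array(0, dim = dim(Md))
  sig <- params$sigma
  for (d in seq_len(ns)) {
    if (fxx[d] <= 0) next
    fij <- Md[, , d] / ifelse(M > 0, M, 1)
    e <- params$RT * (log1p(M * sig) - log1p(M * sig * fij / fxx[d]))
    e[M == 0] <- 0
    energies[, , d] <- e
  }
  # mirror the upper triangle so lookups need not order the pair
  for (d in seq_len(ns)) {
    ed <- energies[, , d]
    ed[lower.tri(ed)] <- t(ed)[lower.tri(ed)]
    energies[, , d] <- ed
  }
  structure(
    list(energies = energies, counts = counts, params = params,
         scheme_version = counts$scheme_version, provenance = NULL),
    class = "potential_table"
  )
}

#' Train a potential from a manifest of PDB files
#'
#' Convenience wrapper: reads every structure listed in a plain-text
#' manifest (one path per line, relative paths resolved against the
#' manifest's directory), re-checks only the length bound of the training
#' filter (40-1000 residues, warning outside it), accumulates contacts and
#' computes the potential. The manifest digest is recorded as provenance.
#'
#' @param manifest path to the manifest file.
#' @param params a `potential_params`.
#' @param scheme an `atom_type_scheme`.
#' @param seed jitter seed.
#' @return a `potential_table`.
#' @export
train_potential <- function(manifest, params = potential_params(),
                            scheme = build_atom_type_scheme(), seed = 1L) {
  paths <- trimws(readLines(manifest))
  paths <- paths[nzchar(paths)]
  if (length(paths) == 0) stop("empty manifest: ", manifest)
  base <- dirname(manifest)
  paths <- ifelse(file.exists(paths), paths, file.path(base, paths))
  structures <- lapply(paths, read_structure)
  lens <- vapply(structures, function(s) s$length, integer(1))
  if (any(lens < 40 | lens > 1000)) {
    warning(sum(lens < 40 | lens > 1000),
            " structure(s) outside the 40-1000 residue training length bound")
  }
  counts <- accumulate_counts(structures, scheme, params$grid, seed = seed)
  tab <- compute_potential(counts, params)
  tab$provenance <- unname(tools::md5sum(manifest))
  tab
}

#' Look up potential energies for contact edges
#'
#' @param table a `potential_table`.
#' @param type_a,type_b atom type indices (vectorized).
#' @param shell shell indices (vectorized).
#' @return numeric energies in kcal/mol.
#' @keywords internal
potential_lookup <- function(table, type_a, type_b, shell) {
  table$energies[cbind(type_a, type_b, shell)]
}
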