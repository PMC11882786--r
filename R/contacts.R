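#' Delaunay contacts of a protein structure
#'
#' Runs a 3-D Delaunay tessellation over the structure's typed heavy atoms
#' and returns the unique tessellation edges as atomic contacts, binned into
#' the distance shells of `grid`. An edge in the tessellation means the two
#' atoms are spatial neighbours not shielded from each other by any other
#' atom.
#'
#' Filtering, in order: atoms whose (residue, atom name) is not part of the
#' 167-type scheme are excluded from the point set; edges between two atoms
#' of the same residue are removed when `exclude_intra = TRUE` (default);
#' edges with distances below the first shell edge or at/beyond the last
#' are removed (they cannot be binned). To keep degenerate inputs (collinear
#' or cospherical points) tractable, coordinates are perturbed by a
#' deterministic uniform jitter of magnitude `jitter` Angstrom drawn from a
#' generator seeded with `seed`; if the tessellation still fails, one retry
#' with a derived seed is attempted. Distances are computed from the
#' *unjittered* coordinates.
#'
#' @param s a `protein_structure`.
#' @param scheme an `atom_type_scheme` (default [build_atom_type_scheme()]).
#' @param grid a `shell_grid` (default [shell_grid()]).
#' @param exclude_intra drop edges within a residue? Default `TRUE`.
#' @param jitter jitter magnitude in Angstrom.
#' @param seed integer seed for the jitter.
#' @return object of class `contact_set`: list with `id`, `edges` (data
#'   frame with columns `a`, `b` (atom row indices into `s$atoms`, `a < b`),
#'   `type_a`, `type_b` (atom type indices), `res_a`, `res_b` (residue
#'   indices), `d` (Angstrom), `shell`), and `n_dropped_range` (edges
#'   discarded for unbinnable distances).
#' @export
delaunay_contacts <- function(s, scheme = build_atom_type_scheme(),
                              grid = shell_grid(), exclude_intra = TRUE,
                              jitter = 1e-6, seed = 1L) {
  stopifnot(inherits(s, "protein_structure"),
            inherits(scheme, "atom_type_scheme"),
            inherits(grid, "shell_grid"))
  at <- s$atoms
  type <- atom_type_lookup(scheme, at$resid, at$elety)
  typed <- which(!is.na(type))
  if (length(typed) < 4) {
    stop("fewer than 4 typed heavy atoms in structure '", s$id, "'")
  }
  pts <- cbind(at$x[typed], at$y[typed], at$z[typed])

  edges_raw <- NULL
  for (attempt in 1:2) {
    jit <- with_seed(as.integer(seed) + (attempt - 1L) * 7919L, {
      matrix(stats::runif(length(pts), -jitter, jitter), ncol = 3)
    })
    edges_raw <- tryCatch(.delaunay_edges_cpp(pts + jit),
                          error = function(e) e)
    if (!inherits(edges_raw, "error")) break
  }
  if (inherits(edges_raw, "error")) {
    stop("Delaunay tessellation failed for '", s$id, "' after jitter retry: ",
         conditionMessage(edges_raw))
  }

  a <- typed[edges_raw[, 1]]
  b <- typed[edges_raw[, 2]]
  if (exclude_intra) {
    keep <- at$res_index[a] != at$res_index[b]
    a <- a[keep]; b <- b[keep]
  }
  d <- sqrt((at$x[a] - at$x[b])^2 + (at$y[a] - at$y[b])^2 +
            (at$z[a] - at$z[b])^2)
  pos <- d > 0  # coincident points can only arise from pathological input
  a <- a[pos]; b <- b[pos]; d <- d[pos]
  shell <- if (length(d)) assign_shell(d, grid) else integer(0)
  in_range <- !is.na(shell)
  n_dropped <- sum(!in_range)
  edges <- data.frame(
    a = a[in_range], b = b[in_range],
    type_a = type[a][in_range], type_b = type[b][in_range],
    res_a = at$res_index[a][in_range], res_b = at$res_index[b][in_range],
    d = d[in_range], shell = shell[in_range]
  )
  ord <- order(edges$a, edges$b)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(id = s$id, edges = edges, n_dropped_range = n_dropped),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat("contact_set '", x$id, "': ", nrow(x$edges), " edges (",
      x$n_dropped_range, " outside shell range)\n", sep = "")
  invisible(x)
}
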