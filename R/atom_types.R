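#' Heavy-atom topology of the 20 standard residues
#'
#' PDB atom names of the heavy (non-hydrogen) atoms of each standard
#' residue: the four backbone atoms N, CA, C, O plus the side chain.
#' Terminal variants (OXT) and any name outside this table are deliberately
#' not part of the scheme.
#'
#' @return named list, one character vector of atom names per residue.
#' @keywords internal
residue_topology <- function() {
  bb <- c("N", "CA", "C", "O")
  list(
    ALA = c(bb, "CB"),
    ARG = c(bb, "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    ASN = c(bb, "CB", "CG", "OD1", "ND2"),
    ASP = c(bb, "CB", "CG", "OD1", "OD2"),
    CYS = c(bb, "CB", "SG"),
    GLN = c(bb, "CB", "CG", "CD", "OE1", "NE2"),
    GLU = c(bb, "CB", "CG", "CD", "OE1", "OE2"),
    GLY = bb,
    HIS = c(bb, "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    ILE = c(bb, "CB", "CG1", "CG2", "CD1"),
    LEU = c(bb, "CB", "CG", "CD1", "CD2"),
    LYS = c(bb, "CB", "CG", "CD", "CE", "NZ"),
    MET = c(bb, "CB", "CG", "SD", "CE"),
    PHE = c(bb, "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    PRO = c(bb, "CB", "CG", "CD"),
    SER = c(bb, "CB", "OG"),
    THR = c(bb, "CB", "OG1", "CG2"),
    TRP = c(bb, "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
            "CZ2", "CZ3", "CH2"),
    TYR = c(bb, "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
    VAL = c(bb, "CB", "CG1", "CG2")
  )
}

#' Residue-specific heavy-atom type scheme
#'
#' Enumerates the heavy atoms of the 20 standard residues, treating the same
#' chemical element in different residues (and different positions) as
#' distinct types. This yields exactly 167 (residue, atom-name) types — GLY
#' contributes its 4 backbone atoms, TRP the most with 14 heavy atoms. All
#' contact counting and the trained potential are indexed by these types.
#'
#' @return an object of class `atom_type_scheme` with components
#'   `index` (named integer vector, names `"RES|ATOM"`, values `1:167`),
#'   `residue` and `atom` (character vectors parallel to `index`), and
#'   `version` (scheme version tag).
#' @examples
#' sch <- build_atom_type_scheme()
#' sch$n_types                       # 167
#' atom_type_lookup(sch, "ALA", "CB")  # an index
#' atom_type_lookup(sch, "ALA", "OXT") # NA: not part of the scheme
#' @export
build_atom_type_scheme <- function() {
  topo <- residue_topology()
  residues <- sort(names(topo))
  res <- rep(residues, vapply(topo[residues], length, integer(1)))
  atm <- unlist(topo[residues], use.names = FALSE)
  key <- paste(res, atm, sep = "|")
  stopifnot(!anyDuplicated(key))
  idx <- seq_along(key)
  names(idx) <- key
  structure(
    list(index = idx, residue = res, atom = atm,
         n_types = length(idx), version = "heavy167-v1"),
    class = "atom_type_scheme"
  )
}

#' @rdname build_atom_type_scheme
#' @param scheme an `atom_type_scheme`.
#' @param resid,atom character vectors of residue 3-letter names and PDB
#'   atom names (vectorized; recycled to common length).
#' @return `atom_type_lookup()` returns integer indices in `1:167`, `NA`
#'   where the (residue, atom) combination is not part of the scheme.
#' @export
atom_type_lookup <- function(scheme, resid, atom) {
  stopifnot(inherits(scheme, "atom_type_scheme"))
  unname(scheme$index[paste(toupper(resid), toupper(atom), sep = "|")])
}

#' Distance shell grid
#'
#' Contact distances are binned into `count` half-open shells
#' `[start + k*width, start + (k+1)*width)`, `k = 0, ..., count-1`. The
#' defaults (30 shells of 0.5 Angstrom starting at 0.75 Angstrom, last edge
#' 15.75 Angstrom) are the grid the potential is defined on.
#'
#' @param start lower edge of the first shell, Angstrom.
#' @param width shell width, Angstrom.
#' @param count number of shells.
#' @return object of class `shell_grid`.
#' @examples
#' g <- shell_grid()
#' assign_shell(c(0.75, 1.25, 15.7), g)  # 1, 2, 30
#' assign_shell(15.75, g)                # NA: beyond the last shell
#' @export
shell_grid <- function(start = 0.75, width = 0.5, count = 30L) {
  stopifnot(is.finite(start), start >= 0, width > 0, count >= 1)
  structure(list(start = start, width = width, count = as.integer(count)),
            class = "shell_grid")
}

#' @rdname shell_grid
#' @param d numeric vector of distances in Angstrom; must be positive and
#'   finite.
#' @param grid a `shell_grid`.
#' @return `assign_shell()` returns 1-based shell indices, `NA` for
#'   distances below the first edge or at/beyond the last.
#' @export
assign_shell <- function(d, grid = shell_grid()) {
  stopifnot(inherits(grid, "shell_grid"))
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("distances must be positive and finite")
  }
  k <- floor((d - grid$start) / grid$width)
  k <- as.integer(k) + 1L
  k[d < grid$start | k > grid$count] <- NA_integer_
  k
}
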