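#' Read a protein structure from a PDB file
#'
#' Parses a PDB coordinate file (via bio3d) into the package's structure
#' representation: heavy atoms of the 20 standard residues, one conformer
#' per atom, first model only. The retained atom table drives contact
#' identification, so the filtering policy is explicit:
#'
#' * hydrogens (and deuterium) are dropped;
#' * alternate locations: atoms with altloc `' '` or `'A'` are kept; if a
#'   residue uses other altloc letters exclusively, the highest-occupancy
#'   conformer is kept;
#' * `HETATM` records are excluded, except selenomethionine (`MSE`), which
#'   is mapped to `MET` (with `SE` renamed to `SD`) when
#'   `mse_to_met = TRUE` (default);
#' * residues whose name cannot be mapped to a standard residue are dropped
#'   with a warning;
#' * for multi-model files only the first model is used (bio3d behaviour),
#'   with a warning.
#'
#' @param path path to a PDB-format file.
#' @param id label for the structure; defaults to the file name without
#'   extension.
#' @param mse_to_met map selenomethionine to methionine? Default `TRUE`.
#' @return an object of class `protein_structure`: a list with `id`,
#'   `atoms` (data frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `x`, `y`, `z`), `sequence` (1-letter string in chain order)
#'   and `length` (residue count).
#' @export
read_structure <- function(path, id = NULL, mse_to_met = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (mse_to_met) {
    is_mse <- at$resid == "MSE"
    at$resid[is_mse] <- "MET"
    at$elety[is_mse & at$elety == "SE"] <- "SD"
    at$type[is_mse] <- "ATOM"
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  structure_from_atoms(at, id)
}

# Shared normalization: heavy atoms, altloc policy, residue mapping.
structure_from_atoms <- function(at, id) {
  if (nrow(at) > 0) {
    elem <- at$elesy
    if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
      elem <- substr(gsub("[^A-Za-z].*$", "", at$elety), 1, 1)
    }
    at <- at[!(toupper(elem) %in% c("H", "D")), , drop = FALSE]
  }
  if (nrow(at) > 0) {
    one <- aa_three_to_one(at$resid)
    if (anyNA(one)) {
      bad <- unique(at$resid[is.na(one)])
      warning("dropping residues with non-standard names: ",
              paste(bad, collapse = ", "))
      at <- at[!is.na(one), , drop = FALSE]
    }
  }
  if (nrow(at) > 0) {
    ins <- at$insert
    ins[is.na(ins)] <- ""
    alt <- at$alt
    alt[is.na(alt)] <- ""
    reskey <- paste(at$chain, at$resno, ins, sep = "|")
    keep <- alt %in% c("", "A")
    if (!all(keep)) {
      # residues served only by other altloc letters: keep the
      # highest-occupancy conformer letter per residue
      occ <- at$o
      occ[is.na(occ)] <- 1
      for (rk in unique(reskey[!keep])) {
        rows <- which(reskey == rk)
        if (any(keep[rows])) next
        byalt <- tapply(occ[rows], alt[rows], mean)
        best <- names(byalt)[which.max(byalt)]
        keep[rows[alt[rows] == best]] <- TRUE
      }
    }
    at <- at[keep, , drop = FALSE]
    # one atom per (residue, atom name): first occurrence wins
    ins <- at$insert
    ins[is.na(ins)] <- ""
    atomkey <- paste(at$chain, at$resno, ins, at$elety, sep = "|")
    at <- at[!duplicated(atomkey), , drop = FALSE]
  }
  if (nrow(at) == 0) stop("zero mappable residues in structure '", id, "'")
  if (any(!is.finite(at$x)) || any(!is.finite(at$y)) || any(!is.finite(at$z))) {
    stop("non-finite coordinates in structure '", id, "'")
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  reskey <- paste(at$chain, at$resno, ins, sep = "|")
  resfac <- factor(reskey, levels = unique(reskey))  # file order
  res_one <- aa_three_to_one(at$resid[!duplicated(reskey)])
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ins,
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    res_index = as.integer(resfac),
    stringsAsFactors = FALSE
  )
  structure(
    list(id = id, atoms = atoms,
         sequence = paste(res_one, collapse = ""),
         length = nlevels(resfac)),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure '", x$id, "': ", x$length, " residues, ",
      nrow(x$atoms), " heavy atoms\n", sep = "")
  invisible(x)
}

#' Write a structure as a minimal PDB file
#'
#' Writes fixed-width `ATOM` records (plus `END`) sufficient for the
#' package's own fixtures and round-trip tests. Not a general-purpose PDB
#' writer.
#'
#' @param s a `protein_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "protein_structure"))
  a <- s$atoms
  elem <- substr(a$elety, 1, 1)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
    a$resid, a$chain, a$resno, ifelse(a$insert == "", " ", a$insert),
    a$x, a$y, a$z, 1, 0, elem
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Record ids are the header tokens up to the first whitespace; sequences
#' are uppercased and concatenated across wrapped lines. Letters outside
#' the 20-letter alphabet are kept verbatim here and handled by the
#' composition policy downstream.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names = record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("unreadable FASTA file '", path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
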