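# Tool-owned tabular text formats. Each writer/reader pair is a value
# round-trip on its own dialect: floating point is serialized with 17
# significant digits (enough to reproduce any double bit-exactly).

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a potential table
#'
#' Self-describing tabular text: `#`-prefixed header lines carry the
#' format version, atom-type scheme version, RT, sigma, the shell grid and
#' the grand total; the body holds one row per observed
#' `(type_i <= type_j, shell)` cell with its count and energy. Cells with
#' zero count and zero energy are omitted (they reconstruct to 0).
#'
#' @param table a `potential_table`.
#' @param path file path.
#' @return `read_potential()` returns a `potential_table` value-identical
#'   to the one written.
#' @export
write_potential <- function(table, path) {
  stopifnot(inherits(table, "potential_table"))
  if (any(!is.finite(table$energies))) stop("non-finite energies")
  p <- table$params
  hdr <- c(
    "# enerprof potential v1",
    paste0("# scheme ", table$scheme_version),
    paste0("# RT ", fmt17(p$RT)),
    paste0("# sigma ", fmt17(p$sigma)),
    paste0("# shell_start ", fmt17(p$grid$start)),
    paste0("# shell_width ", fmt17(p$grid$width)),
    paste0("# shell_count ", p$grid$count),
    paste0("# n_types ", dim(table$energies)[1]),
    paste0("# grand_total ", fmt17(table$counts$grand_total)),
    if (!is.null(table$provenance)) paste0("# provenance ", table$provenance),
    "type_i\ttype_j\tshell\tcount\tenergy"
  )
  cnt <- table$counts$counts
  en <- table$energies
  nt <- dim(en)[1]
  rows <- character(0)
  for (d in seq_len(dim(en)[3])) {
    cd <- cnt[, , d]
    ed <- en[, , d]
    nz <- which((cd != 0 | ed != 0) & upper.tri(ed, diag = TRUE),
                arr.ind = TRUE)
    # restrict to i <= j canonical rows
    if (nrow(nz) > 0) {
      rows <- c(rows, sprintf("%d\t%d\t%d\t%s\t%s",
                              nz[, 1], nz[, 2], d,
                              fmt17(cd[nz]), fmt17(ed[nz])))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  if (length(hdr) == 0 || hdr[1] != "# enerprof potential v1") {
    stop("not an enerprof potential file (missing/unknown version header)")
  }
  get_hdr <- function(key, required = TRUE) {
    m <- hdr[startsWith(hdr, paste0("# ", key, " "))]
    if (length(m) == 0) {
      if (required) stop("potential file missing '", key, "' header")
      return(NULL)
    }
    sub(paste0("^# ", key, " "), "", m[1])
  }
  scheme_version <- get_hdr("scheme")
  RT <- as.numeric(get_hdr("RT"))
  sigma <- as.numeric(get_hdr("sigma"))
  grid <- shell_grid(as.numeric(get_hdr("shell_start")),
                     as.numeric(get_hdr("shell_width")),
                     as.integer(get_hdr("shell_count")))
  nt <- as.integer(get_hdr("n_types"))
  grand_total <- as.numeric(get_hdr("grand_total"))
  provenance <- get_hdr("provenance", required = FALSE)

  body_start <- which(lines == "type_i\ttype_j\tshell\tcount\tenergy")
  if (length(body_start) != 1) stop("malformed potential file body header")
  body <- lines[-seq_len(body_start)]
  body <- body[nzchar(body)]
  counts <- array(0, dim = c(nt, nt, grid$count))
  energies <- array(0, dim = c(nt, nt, grid$count))
  if (length(body) > 0) {
    tab <- utils::read.table(text = body, sep = "\t",
                             col.names = c("i", "j", "shell", "count",
                                           "energy"))
    if (any(tab$i > tab$j)) {
      stop("malformed potential body: rows must satisfy type_i <= type_j")
    }
    if (any(tab$shell < 1 | tab$shell > grid$count) ||
        any(tab$i < 1 | tab$j > nt)) {
      stop("malformed potential body: index out of range")
    }
    counts[cbind(tab$i, tab$j, tab$shell)] <- tab$count
    energies[cbind(tab$i, tab$j, tab$shell)] <- tab$energy
    energies[cbind(tab$j, tab$i, tab$shell)] <- tab$energy
  }
  ct <- structure(
    list(counts = counts,
         pair_totals = apply(counts, c(1, 2), sum),
         shell_totals = apply(counts, 3, sum),
         grand_total = grand_total,
         scheme_version = scheme_version,
         grid = grid),
    class = "count_tensor"
  )
  structure(
    list(energies = energies, counts = ct,
         params = potential_params(RT, sigma, grid),
         scheme_version = scheme_version, provenance = provenance),
    class = "potential_table"
  )
}

#' Write / read energy profiles
#'
#' Tab-separated table: first column `id`, then 210 columns labeled by the
#' canonical pair codes; a `# kind` header records SPE/CPE and the
#' normalization flag.
#'
#' @param profiles named list of `energy_profile`s (or a profile matrix).
#' @param path file path.
#' @return `read_profiles()` returns a numeric matrix (rows = ids,
#'   columns = 210 pair codes) with attributes `kind` and `normalized`.
#' @export
write_profiles <- function(profiles, path) {
  X <- profiles_as_matrix(profiles)
  if (ncol(X) != 210L) stop("profiles must have 210 columns")
  kind <- if (is.list(profiles)) attr(profiles[[1]], "kind") else
    attr(profiles, "kind")
  normalized <- if (is.list(profiles)) attr(profiles[[1]], "normalized") else
    attr(profiles, "normalized")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# enerprof profiles v1 kind=",
                    if (is.null(kind)) "NA" else kind,
                    " normalized=",
                    if (is.null(normalized)) "NA" else normalized), con)
  writeLines(paste(c("id", aa_pair_codes()), collapse = "\t"), con)
  for (r in seq_len(nrow(X))) {
    writeLines(paste(c(rownames(X)[r], fmt17(X[r, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- lines[1]
  if (!startsWith(meta, "# enerprof profiles v1")) {
    stop("not an enerprof profiles file")
  }
  tab <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) != 211L) {
    stop("profiles file must have 211 columns (id + 210 pairs), found ",
         ncol(tab))
  }
  if (!identical(colnames(tab)[-1], aa_pair_codes())) {
    stop("profiles file column labels do not match the canonical pair order")
  }
  X <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- tab$id
  kind <- sub(".*kind=(\\S+).*", "\\1", meta)
  normalized <- sub(".*normalized=(\\S+).*", "\\1", meta)
  attr(X, "kind") <- if (kind == "NA") NULL else kind
  attr(X, "normalized") <- if (normalized == "NA") NULL else
    as.logical(normalized)
  X
}

#' Write / read the predictor matrix
#'
#' 20x20 labeled matrix in canonical alphabet order, tab-separated.
#'
#' @param predictor a `predictor_matrix` (or bare 20x20 matrix).
#' @param path file path.
#' @return `read_predictor()` returns a `predictor_matrix`.
#' @export
write_predictor <- function(predictor, path) {
  P <- if (inherits(predictor, "predictor_matrix")) predictor$P else predictor
  stopifnot(is.matrix(P), all(dim(P) == c(20, 20)))
  lam <- if (inherits(predictor, "predictor_matrix")) predictor$lambda else 0
  ncase <- if (inherits(predictor, "predictor_matrix"))
    predictor$n_cases else NA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# enerprof predictor v1 lambda=", fmt17(lam),
                    " n_cases=", ncase), con)
  writeLines(paste(c("aa", aa_alphabet()), collapse = "\t"), con)
  for (r in 1:20) {
    writeLines(paste(c(aa_alphabet()[r], fmt17(P[r, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!startsWith(lines[1], "# enerprof predictor v1")) {
    stop("not an enerprof predictor file")
  }
  tab <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                           check.names = FALSE)
  if (!identical(as.character(tab$aa), aa_alphabet()) ||
      !identical(colnames(tab)[-1], aa_alphabet())) {
    stop("predictor file labels do not match the canonical alphabet order")
  }
  P <- as.matrix(tab[, -1, drop = FALSE])
  rownames(P) <- aa_alphabet()
  lam <- as.numeric(sub(".*lambda=(\\S+).*", "\\1", lines[1]))
  ncase <- suppressWarnings(
    as.integer(sub(".*n_cases=(\\S+).*", "\\1", lines[1])))
  structure(list(P = P, row_rss = NULL, n_cases = ncase, lambda = lam),
            class = "predictor_matrix")
}

#' Write / read a labeled distance matrix
#'
#' Tab-separated square table with row and column labels; the matrix must
#' be symmetric (within 1e-9), non-negative, with zero diagonal.
#'
#' @param D labeled symmetric matrix.
#' @param path file path.
#' @return `read_distmat()` returns the labeled matrix.
#' @export
write_distmat <- function(D, path) {
  D <- check_square_matrix(D)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# enerprof distmat v1", con)
  writeLines(paste(c("id", rownames(D)), collapse = "\t"), con)
  for (r in seq_len(nrow(D))) {
    writeLines(paste(c(rownames(D)[r], fmt17(D[r, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_distmat
#' @export
read_distmat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!startsWith(lines[1], "# enerprof distmat v1")) {
    stop("not an enerprof distance-matrix file")
  }
  tab <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                           check.names = FALSE)
  D <- as.matrix(tab[, -1, drop = FALSE])
  rownames(D) <- as.character(tab$id)
  check_square_matrix(D)
}
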