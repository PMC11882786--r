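#' Construct an energy-profile object
#'
#' @param values numeric vector of length 210 in canonical pair order.
#' @param kind `"SPE"` or `"CPE"`.
#' @param id source identifier.
#' @param normalized was the profile divided by protein length (SPE) /
#'   built from length-invariant fractions (CPE)?
#' @return object of class `energy_profile` (a named numeric vector with
#'   attributes `kind`, `id`, `normalized`).
#' @keywords internal
energy_profile <- function(values, kind, id, normalized) {
  stopifnot(length(values) == 210L, all(is.finite(values)),
            kind %in% c("SPE", "CPE"))
  values <- as.numeric(values)
  names(values) <- aa_pair_codes()
  structure(values, kind = kind, id = id, normalized = normalized,
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(attr(x, "kind"), " profile '", attr(x, "id"), "' (normalized: ",
      attr(x, "normalized"), "), total energy ",
      format(sum(x), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Structural profile of energy (SPE)
#'
#' Sums the trained pairwise potential over all retained inter-residue
#' atomic contacts of a structure, aggregated by the unordered amino-acid
#' type pair of the two parent residues. The interaction energy of residues
#' A and B is the sum of the atomic potential over their contacting atom
#' pairs; the profile entry for the type pair \{A, B\} accumulates those
#' sums over all residue pairs of that type combination. With
#' `normalize = TRUE` (default) every entry is divided by the residue count
#' L, putting structures of different sizes on a comparable scale.
#'
#' @param s a `protein_structure`.
#' @param table a `potential_table`.
#' @param normalize divide entries by L? Default `TRUE`.
#' @param scheme an `atom_type_scheme`; must match the table's scheme
#'   version.
#' @param exclude_intra,seed passed to [delaunay_contacts()].
#' @return an `energy_profile` of kind `"SPE"`. A structure with no
#'   retained contacts yields the zero profile with a warning.
#' @export
compute_spe <- function(s, table, normalize = TRUE,
                        scheme = build_atom_type_scheme(),
                        exclude_intra = TRUE, seed = 1L) {
  stopifnot(inherits(s, "protein_structure"),
            inherits(table, "potential_table"))
  if (!identical(scheme$version, table$scheme_version)) {
    stop("atom-type scheme version mismatch: structure typing uses '",
         scheme$version, "' but the potential was trained with '",
         table$scheme_version, "'")
  }
  cs <- delaunay_contacts(s, scheme, table$params$grid,
                          exclude_intra = exclude_intra, seed = seed)
  e <- cs$edges
  vals <- numeric(210L)
  if (nrow(e) == 0) {
    warning("structure '", s$id, "' has no retained contacts; zero profile")
  } else {
    seq1 <- strsplit(s$sequence, "")[[1]]
    energies <- potential_lookup(table, e$type_a, e$type_b, e$shell)
    bin <- aa_pair_index(seq1[e$res_a], seq1[e$res_b])
    acc <- tapply(energies, bin, sum)
    vals[as.integer(names(acc))] <- as.numeric(acc)
  }
  if (normalize) vals <- vals / s$length
  energy_profile(vals, "SPE", s$id, normalize)
}

#' Per-type interaction energies of a structure
#'
#' e_i is the energy of interactions between all residues of type i and
#' all residues in the structure, obtained from the un-normalized SPE: the
#' sum of every profile entry whose pair contains type i, with the
#' same-type entry \{i, i\} counted twice by default (each i-i interaction
#' involves two residues of type i). These vectors are the regression
#' targets for the predictor-matrix fit.
#'
#' @inheritParams compute_spe
#' @param count_self_twice count the \{i,i\} entry twice? Default `TRUE`.
#' @return numeric vector of length 20 in canonical alphabet order, with
#'   attribute `id`.
#' @export
compute_type_energy <- function(s, table, count_self_twice = TRUE,
                                scheme = build_atom_type_scheme(),
                                seed = 1L) {
  spe <- compute_spe(s, table, normalize = FALSE, scheme = scheme,
                     seed = seed)
  type_energy_from_profile(spe, count_self_twice = count_self_twice)
}

#' @rdname compute_type_energy
#' @param profile an un-normalized `energy_profile`.
#' @export
type_energy_from_profile <- function(profile, count_self_twice = TRUE) {
  aa <- aa_alphabet()
  e <- numeric(20L)
  names(e) <- aa
  codes <- aa_pair_codes()
  first <- substr(codes, 1, 1)
  second <- substr(codes, 2, 2)
  for (k in seq_along(codes)) {
    v <- profile[[k]]
    if (first[k] == second[k]) {
      e[first[k]] <- e[first[k]] + (if (count_self_twice) 2 else 1) * v
    } else {
      e[first[k]] <- e[first[k]] + v
      e[second[k]] <- e[second[k]] + v
    }
  }
  attr(e, "id") <- attr(profile, "id")
  e
}

#' Amino-acid composition of a sequence
#'
#' Counts the 20 standard letters; anything else (X, B, Z, U, gaps, ...)
#' is dropped with a warning, and L is the retained count, so the
#' fractions always sum to 1.
#'
#' @param seq a character scalar (1-letter amino-acid sequence).
#' @return object of class `composition`: list with `counts` (named
#'   integer, length 20), `fractions` (counts / L) and `L`.
#' @export
composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  letters1 <- strsplit(toupper(seq), "")[[1]]
  aa <- aa_alphabet()
  ok <- letters1 %in% aa
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " letter(s) outside the 20-letter ",
            "alphabet: ", paste(unique(letters1[!ok]), collapse = ""))
  }
  letters1 <- letters1[ok]
  if (length(letters1) == 0) {
    stop("sequence empty after removing non-standard letters")
  }
  counts <- table(factor(letters1, levels = aa))
  counts <- stats::setNames(as.integer(counts), aa)
  structure(list(counts = counts, fractions = counts / sum(counts),
                 L = sum(counts)),
            class = "composition")
}

#' Fit the composition-to-energy predictor matrix
#'
#' Each row i of the 20x20 predictor matrix P is fitted independently by
#' least squares: over training structures S, the model predicts the
#' per-type energy as
#'
#'   e_i(S) ~ N_i(S) * sum_j P_ij n_j(S)
#'
#' where N_i(S) is the count of type i in S and n_j(S) the composition
#' fractions. Row i's objective Z_i = sum_S (e_i(S) - prediction)^2 is
#' minimized by solving the normal equations in the 20 unknowns P_i1..P_i20
#' (an optional ridge term `lambda` is added to the normal-equation
#' diagonal).
#'
#' @param type_energies list of length-20 numeric vectors (one per
#'   structure, canonical order), or a matrix with 20 columns.
#' @param compositions list of `composition` objects (same length/order).
#' @param lambda ridge penalty; default 0 (plain normal equations).
#' @return object of class `predictor_matrix`: list with `P` (20x20,
#'   dimnames = alphabet), `row_rss` (residual sum of squares per row),
#'   `n_cases`, `lambda`.
#' @export
fit_predictor <- function(type_energies, compositions, lambda = 0) {
  if (is.matrix(type_energies)) {
    type_energies <- lapply(seq_len(nrow(type_energies)),
                            function(r) type_energies[r, ])
  }
  stopifnot(length(type_energies) == length(compositions),
            length(type_energies) >= 1, lambda >= 0)
  m <- length(type_energies)
  if (m < 20 && lambda == 0) {
    stop("need at least 20 training cases for the unregularized fit ",
         "(have ", m, "); consider ridge lambda > 0")
  }
  aa <- aa_alphabet()
  E <- do.call(rbind, lapply(type_energies, as.numeric))  # m x 20
  Nc <- do.call(rbind, lapply(compositions, function(cc) {
    stopifnot(inherits(cc, "composition"))
    as.numeric(cc$counts)
  }))
  Fr <- do.call(rbind, lapply(compositions,
                              function(cc) as.numeric(cc$fractions)))
  P <- matrix(0, 20, 20, dimnames = list(aa, aa))
  row_rss <- stats::setNames(numeric(20L), aa)
  for (i in 1:20) {
    X <- Nc[, i] * Fr             # m x 20 design for row i
    y <- E[, i]
    XtX <- crossprod(X) + diag(lambda, 20)
    if (lambda == 0) {
      qrx <- qr(XtX)
      if (qrx$rank < 20) {
        stop("rank-deficient design for predictor row '", aa[i],
             "' (rank ", qrx$rank, " < 20); supply more varied ",
             "compositions or set ridge lambda > 0")
      }
    }
    beta <- solve(XtX, crossprod(X, y))
    P[i, ] <- beta
    row_rss[i] <- sum((y - X %*% beta)^2)
  }
  structure(list(P = P, row_rss = row_rss, n_cases = m, lambda = lambda),
            class = "predictor_matrix")
}

#' Compositional profile of energy (CPE)
#'
#' Estimates the 210-entry energy profile of a protein from its amino-acid
#' composition alone. The entry for the unordered pair \{i, j\}, i != j, is
#' the symmetrized composition product n_i P_ij n_j + n_j P_ji n_i (so the
#' profile is well defined on unordered pairs even for a non-symmetric P);
#' the diagonal entry \{i, i\} is n_i P_ii n_i. Because the fractions n are
#' already length-invariant, no further division by L is applied.
#'
#' @param seq a 1-letter amino-acid sequence (character scalar), or a
#'   `composition` object.
#' @param predictor a `predictor_matrix` (or bare 20x20 matrix).
#' @param id profile identifier.
#' @param symmetrize_P use (P + t(P))/2 in place of P? Default `FALSE`
#'   (the symmetrized pair formula above is used either way).
#' @return an `energy_profile` of kind `"CPE"`.
#' @export
compute_cpe <- function(seq, predictor, id = "seq", symmetrize_P = FALSE) {
  cc <- if (inherits(seq, "composition")) seq else composition(seq)
  P <- if (inherits(predictor, "predictor_matrix")) predictor$P else predictor
  stopifnot(is.matrix(P), all(dim(P) == c(20, 20)))
  if (symmetrize_P) P <- (P + t(P)) / 2
  n <- as.numeric(cc$fractions)
  codes <- aa_pair_codes()
  aa <- aa_alphabet()
  i <- match(substr(codes, 1, 1), aa)
  j <- match(substr(codes, 2, 2), aa)
  vals <- ifelse(i == j,
                 n[i] * P[cbind(i, i)] * n[i],
                 n[i] * P[cbind(i, j)] * n[j] + n[j] * P[cbind(j, i)] * n[i])
  energy_profile(vals, "CPE", id, normalized = TRUE)
}
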