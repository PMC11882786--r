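#' Dissimilarity between two energy profiles
#'
#' The package's dissimilarity between proteins is the Manhattan (L1)
#' distance between their 210-dimensional energy profiles; no alignment of
#' any kind is involved. The metric argument is pluggable for
#' experimentation, but Manhattan is the method's metric.
#'
#' @param p,q `energy_profile` objects (or bare length-210 numeric
#'   vectors).
#' @param metric `"manhattan"` (default) or `"euclidean"`.
#' @return a non-negative number.
#' @export
profile_distance <- function(p, q, metric = c("manhattan", "euclidean")) {
  metric <- match.arg(metric)
  if (length(p) != length(q)) stop("profile dimension mismatch")
  np <- attr(p, "normalized"); nq <- attr(q, "normalized")
  if (!is.null(np) && !is.null(nq) && !identical(np, nq)) {
    stop("profiles have different normalization flags")
  }
  dv <- as.numeric(p) - as.numeric(q)
  switch(metric,
         manhattan = sum(abs(dv)),
         euclidean = sqrt(sum(dv^2)))
}

#' All pairwise profile distances
#'
#' @param profiles a named list of `energy_profile` objects, or a numeric
#'   matrix with one profile per row (rownames = ids).
#' @param metric passed to [profile_distance()].
#' @return a labeled symmetric `matrix` with zero diagonal.
#' @export
distance_matrix <- function(profiles, metric = "manhattan") {
  X <- profiles_as_matrix(profiles)
  if (nrow(X) < 2) stop("need at least 2 profiles")
  if (anyDuplicated(rownames(X))) {
    stop("duplicate profile ids: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))
  }
  D <- as.matrix(stats::dist(X, method = metric))
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

# Coerce a list of profiles (or a matrix) to an id-by-dimension matrix.
profiles_as_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    if (is.null(rownames(profiles))) {
      rownames(profiles) <- paste0("p", seq_len(nrow(profiles)))
    }
    return(profiles)
  }
  ids <- names(profiles)
  if (is.null(ids)) {
    ids <- vapply(profiles, function(p) {
      id <- attr(p, "id")
      if (is.null(id)) NA_character_ else id
    }, character(1))
  }
  if (anyNA(ids)) stop("profiles must be named or carry ids")
  X <- do.call(rbind, lapply(profiles, as.numeric))
  rownames(X) <- ids
  X
}

check_square_matrix <- function(D, tol = 1e-9) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(rownames(D))) {
    dimnames(D) <- list(paste0("s", seq_len(nrow(D))),
                        paste0("s", seq_len(nrow(D))))
  }
  if (max(abs(D - t(D))) > tol) stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("distance matrix has negative entries")
  D
}

#' 1-nearest-neighbour classification with leave-one-out cross-validation
#'
#' Each sample is predicted as the class of its nearest *other* sample
#' under the distance matrix (k = 1). Ties at the minimal distance are
#' broken by the smallest sample index, which makes the report fully
#' deterministic. Classes with a single member are kept (with a warning):
#' such samples can never be predicted correctly.
#'
#' @param D labeled symmetric distance matrix.
#' @param labels class labels, one per row of `D` (character or factor).
#' @return object of class `classification_report`: list with `accuracy`,
#'   `per_class_f1` (named), `macro_f1`, `confusion` (true x predicted
#'   table) and `predicted`.
#' @export
knn_loocv <- function(D, labels) {
  D <- check_square_matrix(D)
  n <- nrow(D)
  if (length(labels) != n) stop("label/matrix size mismatch")
  labels <- as.character(labels)
  singletons <- names(which(table(labels) < 2))
  if (length(singletons) > 0) {
    warning("class(es) with a single member can never be matched: ",
            paste(singletons, collapse = ", "))
  }
  pred <- character(n)
  for (k in seq_len(n)) {
    dk <- D[k, ]
    dk[k] <- Inf
    nn <- which(dk == min(dk))[1]  # smallest index among ties
    pred[k] <- labels[nn]
  }
  classes <- sort(unique(labels))
  confusion <- table(factor(labels, classes), factor(pred, classes),
                     dnn = c("true", "predicted"))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(labels == cl & pred == cl)
    fp <- sum(labels != cl & pred == cl)
    fn <- sum(labels == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  structure(
    list(accuracy = mean(pred == labels),
         per_class_f1 = f1,
         macro_f1 = mean(f1),
         confusion = confusion,
         predicted = stats::setNames(pred, rownames(D))),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("1-NN LOOCV: accuracy ", format(x$accuracy, digits = 4),
      ", macro-F1 ", format(x$macro_f1, digits = 4), "\n", sep = "")
  cat("per-class F1:\n")
  print(round(x$per_class_f1, 4))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to renaming), about 0 for random
#' agreement. Computed with the standard pair-counting contingency formula
#' (via mclust).
#'
#' @param x,y labelings of equal length.
#' @return a number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop("labelings have different lengths")
  mclust::adjustedRandIndex(x, y)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-tie ranks. A constant input has no
#' defined rank correlation; `NA` is returned with a warning.
#'
#' @param x,y numeric (or ordered) vectors of equal length >= 2.
#' @return a number in \[-1, 1\], or `NA` if undefined.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("inputs have different lengths")
  if (length(x) < 2) stop("need at least 2 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(as.numeric(x), as.numeric(y), method = "spearman")
}

#' Closest-distance between two sets of profiles
#'
#' The mean, over members of both sets, of each member's distance to its
#' closest counterpart in the other set:
#'
#'   <d_AB> = ( sum_\{a in A\} min_\{b in B\} d(a,b)
#'            + sum_\{b in B\} min_\{a in A\} d(a,b) ) / (|A| + |B|)
#'
#' For the within-set case `A == B` the minimum excludes the member itself
#' (otherwise the value would trivially be 0); the within-set value of a
#' singleton set is 0 by convention.
#'
#' @param A,B character vectors of ids present in `D`.
#' @param D labeled distance matrix.
#' @param within treat this as a within-set computation (self-exclusion)?
#'   Defaults to `TRUE` when `A` and `B` contain the same ids.
#' @return a non-negative number.
#' @export
closest_set_distance <- function(A, B, D, within = setequal(A, B)) {
  D <- check_square_matrix(D)
  ids <- rownames(D)
  unknown <- setdiff(c(A, B), ids)
  if (length(unknown) > 0) {
    stop("unknown ids: ", paste(unknown, collapse = ", "))
  }
  if (length(A) == 0 || length(B) == 0) stop("empty set")
  if (within && length(A) == 1) return(0)
  mins_to <- function(from, to, exclude_self) {
    vapply(from, function(a) {
      cand <- to
      if (exclude_self) cand <- setdiff(cand, a)
      min(D[a, cand])
    }, numeric(1))
  }
  tot <- sum(mins_to(A, B, within)) + sum(mins_to(B, A, within))
  tot / (length(A) + length(B))
}

#' Energy-profile separation measure between two protein sets
#'
#' Compares the cross-set closest distance with the within-set closest
#' distances of two sets of energy profiles:
#'
#'   E_AB = <d_AB> - ( <d_AA> + <d_BB> ) / 2
#'
#' A negative value means the two sets live in overlapping profile
#' neighbourhoods; a positive value means they are separated. The measure
#' is symmetric in A and B.
#'
#' @inheritParams closest_set_distance
#' @return object of class `separation_result`: list with `E_AB`, `d_AB`,
#'   `d_AA`, `d_BB`, `n_A`, `n_B`.
#' @export
separation <- function(A, B, D) {
  d_AB <- closest_set_distance(A, B, D, within = FALSE)
  d_AA <- closest_set_distance(A, A, D, within = TRUE)
  d_BB <- closest_set_distance(B, B, D, within = TRUE)
  structure(
    list(E_AB = d_AB - (d_AA + d_BB) / 2,
         d_AB = d_AB, d_AA = d_AA, d_BB = d_BB,
         n_A = length(A), n_B = length(B)),
    class = "separation_result"
  )
}

#' @export
print.separation_result <- function(x, ...) {
  cat("separation E_AB = ", format(x$E_AB, digits = 6),
      "  (<d_AB> = ", format(x$d_AB, digits = 6),
      ", <d_AA> = ", format(x$d_AA, digits = 6),
      ", <d_BB> = ", format(x$d_BB, digits = 6),
      "; |A| = ", x$n_A, ", |B| = ", x$n_B, ")\n", sep = "")
  invisible(x)
}
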