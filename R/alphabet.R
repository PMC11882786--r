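#' Canonical amino-acid alphabet and pair ordering
#'
#' All profile, composition and predictor objects in this package index the
#' 20 standard amino acids in the fixed one-letter order
#' `ACDEFGHIKLMNPQRSTVWY`, and the 210 unordered amino-acid pairs (including
#' self-pairs) in lexicographic order over that alphabet: `"AA", "AC", ...,
#' "YY"`. Fixing the order once makes every serialized table and every
#' profile vector deterministic and comparable across runs.
#'
#' @return `aa_alphabet()` returns the 20 one-letter codes in canonical
#'   order; `aa_pair_codes()` returns the 210 two-letter pair codes.
#' @examples
#' aa_alphabet()
#' head(aa_pair_codes())
#' length(aa_pair_codes())  # 210
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
aa_pair_codes <- function() {
  aa <- aa_alphabet()
  codes <- character(0L)
  for (i in seq_along(aa)) {
    for (j in i:length(aa)) {
      codes <- c(codes, paste0(aa[i], aa[j]))
    }
  }
  codes
}

#' Index of an unordered amino-acid pair in the canonical 210-vector
#'
#' @param a,b one-letter amino-acid codes (vectorized).
#' @return integer index in `1:210` into [aa_pair_codes()].
#' @keywords internal
aa_pair_index <- function(a, b) {
  aa <- aa_alphabet()
  ia <- match(a, aa)
  ib <- match(b, aa)
  if (anyNA(ia) || anyNA(ib)) {
    stop("unknown amino-acid letter(s): ",
         paste(unique(c(a[is.na(ia)], b[is.na(ib)])), collapse = ", "))
  }
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  # pairs (lo, hi) with lo <= hi, row-major over the upper triangle:
  # rows 1..lo-1 contribute (21 - k) entries each
  (lo - 1L) * 21L - ((lo - 1L) * lo) %/% 2L + (hi - lo + 1L)
}

#' Three-letter to one-letter residue name mapping
#'
#' @param resid character vector of 3-letter residue names (upper case).
#' @return one-letter codes; `NA` for names outside the 20 standard residues.
#' @keywords internal
aa_three_to_one <- function(resid) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  unname(map[toupper(resid)])
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic entry points funnel through this
# so a single integer seed fully determines their output.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
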