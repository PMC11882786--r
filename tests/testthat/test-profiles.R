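make_toy_potential <- function(seed = 1) {
  train <- synth_training_set(n = 8, len_range = c(20L, 40L), seed = seed)
  compute_potential(attr(train, "counts"))
}

test_that("pair bookkeeping: 210 codes in canonical order, correct indexing", {
  codes <- aa_pair_codes()
  expect_equal(length(codes), 210L)
  expect_equal(codes[1], "AA")
  expect_equal(codes[210], "YY")
  expect_false(anyDuplicated(codes) > 0)
  # index function agrees with a direct match and is symmetric
  for (k in sample(210, 25)) {
    a <- substr(codes[k], 1, 1)
    b <- substr(codes[k], 2, 2)
    expect_equal(enerprof:::aa_pair_index(a, b), k)
    expect_equal(enerprof:::aa_pair_index(b, a), k)
  }
})

test_that("SPE conserves the directly-accumulated total contact energy", {
  pot <- make_toy_potential(seed = 4)
  for (seed in c(21, 22)) {
    s <- synth_structure(30, seed = seed)
    spe <- compute_spe(s, pot, normalize = FALSE)
    cs <- delaunay_contacts(s, grid = pot$params$grid)
    direct <- sum(enerprof:::potential_lookup(pot, cs$edges$type_a,
                                              cs$edges$type_b,
                                              cs$edges$shell))
    expect_lt(abs(sum(spe) - direct), 1e-9)
    # normalization divides every entry by L
    spen <- compute_spe(s, pot, normalize = TRUE)
    expect_equal(as.numeric(spen), as.numeric(spe) / s$length)
  }
})

test_that("SPE puts a single retained contact in the right pair bin", {
  pot <- make_toy_potential(seed = 4)
  s <- two_residue_structure()
  spe <- compute_spe(s, pot, normalize = FALSE)
  cs <- delaunay_contacts(s, grid = pot$params$grid)
  expect_true(all(cs$edges$res_a != cs$edges$res_b))
  v <- sum(enerprof:::potential_lookup(pot, cs$edges$type_a,
                                       cs$edges$type_b, cs$edges$shell))
  expect_equal(spe[["AG"]], v)
  expect_equal(sum(spe[names(spe) != "AG"]), 0)
})

test_that("per-type energies follow the double-counting identity", {
  # synthetic profile: entry {A,G} = 3, {A,A} = 2, {C,Y} = -1
  vals <- numeric(210)
  names(vals) <- aa_pair_codes()
  vals["AG"] <- 3; vals["AA"] <- 2; vals["CY"] <- -1
  prof <- enerprof:::energy_profile(vals, "SPE", "toy", FALSE)
  e <- type_energy_from_profile(prof)
  expect_equal(e[["A"]], 3 + 2 * 2)   # {A,A} counted twice
  expect_equal(e[["G"]], 3)
  expect_equal(e[["C"]], -1)
  expect_equal(e[["Y"]], -1)
  # every interaction involves two residues, so summing the per-type
  # energies counts the whole profile exactly twice
  expect_equal(sum(e), 2 * sum(vals))
  e1 <- type_energy_from_profile(prof, count_self_twice = FALSE)
  expect_equal(e1[["A"]], 3 + 2)
  # on a real structure the identity holds exactly
  pot <- make_toy_potential(seed = 4)
  s <- synth_structure(25, seed = 31)
  spe <- compute_spe(s, pot, normalize = FALSE)
  te <- type_energy_from_profile(spe)
  expect_equal(sum(te), 2 * sum(spe))
})

test_that("composition counts the 20-letter alphabet and drops the rest", {
  cc <- composition("AC")
  expect_equal(cc$counts[["A"]], 1L)
  expect_equal(cc$counts[["C"]], 1L)
  expect_equal(cc$L, 2L)
  expect_equal(cc$fractions[["A"]], 0.5)
  expect_warning(cx <- composition("AXA"), "outside")
  expect_equal(cx$counts[["A"]], 2L)
  expect_equal(cx$L, 2L)
  expect_equal(sum(cx$fractions), 1)
  expect_error(suppressWarnings(composition("BBB")), "empty")
})

test_that("fit_predictor recovers a planted predictor matrix", {
  pc <- planted_predictor_case(n_cases = 60, seed = 9)
  fit <- fit_predictor(pc$type_energies, pc$compositions)
  expect_lt(max(abs(fit$P - pc$P_star)), 1e-8)
  expect_true(all(fit$row_rss < 1e-12))
  # residuals orthogonal to the design columns (normal-equation identity)
  Fr <- do.call(rbind, lapply(pc$compositions,
                              function(cc) as.numeric(cc$fractions)))
  Nc <- do.call(rbind, lapply(pc$compositions,
                              function(cc) as.numeric(cc$counts)))
  for (i in c(1, 7, 20)) {
    X <- Nc[, i] * Fr
    y <- vapply(pc$type_energies, function(e) e[[i]], numeric(1))
    resid <- y - X %*% fit$P[i, ]
    expect_lt(max(abs(crossprod(X, resid))), 1e-6)
  }
})

test_that("underdetermined fits fail loudly unless ridged", {
  pc <- planted_predictor_case(n_cases = 25, seed = 12)
  few <- 1:5
  expect_error(fit_predictor(pc$type_energies[few], pc$compositions[few]),
               "at least 20")
  # ridge makes the 5-case problem solvable (biased, but defined)
  fit <- fit_predictor(pc$type_energies[few], pc$compositions[few],
                       lambda = 1e-3)
  expect_true(all(is.finite(fit$P)))
})

test_that("CPE evaluates the composition formula on unordered pairs", {
  P <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  P["A", "A"] <- -1
  cpe <- compute_cpe("AAAA", P)
  expect_equal(cpe[["AA"]], -1)  # n_A = 1
  expect_equal(sum(cpe[names(cpe) != "AA"]), 0)

  set.seed(5)
  P2 <- matrix(rnorm(400), 20, 20,
               dimnames = list(aa_alphabet(), aa_alphabet()))
  cpe2 <- compute_cpe("AC", P2)
  expect_equal(cpe2[["AC"]], 0.25 * (P2["A", "C"] + P2["C", "A"]))
  expect_equal(cpe2[["AA"]], 0.25 * P2["A", "A"])
  # composition-only dependence: any permutation gives the same profile
  cpe3 <- compute_cpe("CA", P2)
  expect_equal(as.numeric(cpe2), as.numeric(cpe3))
  seqperm <- paste(sample(strsplit("ACDDGYKLMA", "")[[1]]), collapse = "")
  expect_equal(as.numeric(compute_cpe("ACDDGYKLMA", P2)),
               as.numeric(compute_cpe(seqperm, P2)))
})

test_that("SPE is invariant under rigid-body motion of the structure", {
  pot <- make_toy_potential(seed = 4)
  s <- synth_structure(25, seed = 41)
  spe1 <- compute_spe(s, pot)
  set.seed(8)
  M <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(M) < 0) M[, 1] <- -M[, 1]
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(M)
  s2 <- s
  s2$atoms$x <- xyz[, 1] + 5; s2$atoms$y <- xyz[, 2] - 3
  s2$atoms$z <- xyz[, 3] + 1
  spe2 <- compute_spe(s2, pot)
  expect_equal(as.numeric(spe1), as.numeric(spe2), tolerance = 1e-9)
})
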