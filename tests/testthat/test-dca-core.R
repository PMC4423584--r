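test_that("sequence weights collapse redundancy and spare diversity", {
  five <- matrix("K", 5, 8)
  w <- compute_sequence_weights(five, theta = 0.2)
  expect_equal(w$w, rep(1 / 5, 5))
  expect_equal(w$M_eff, 1)

  # three mutually dissimilar rows: pairwise identity far below 0.8
  dis <- rbind(rep("A", 10), rep("C", 10), rep("D", 10))
  w2 <- compute_sequence_weights(dis, theta = 0.2)
  expect_equal(w2$w, rep(1, 3))
  expect_equal(w2$M_eff, 3)

  expect_error(compute_sequence_weights(five, theta = 1), "theta")
  expect_error(compute_sequence_weights(five, theta = -0.1), "theta")
})

test_that("weights equal the O(M^2 L) brute-force definition", {
  chars <- random_alignment(100, 30, gap_rate = 0.15, n_letters = 3, seed = 11)
  for (theta in c(0.2, 0.5)) {
    w <- compute_sequence_weights(alignment_matrix(chars), theta = theta)
    expect_identical(w$w, brute_force_weights(chars, theta))
  }
})

test_that("frequency estimates match counting and respect the pseudocount limits", {
  one <- matrix("K", 10, 1)
  f <- estimate_frequencies(one, rep(1, 10), lambda = 0)
  expect_equal(f$fi[, 1], as.numeric(AA_idx <- (seq_len(21) == 9)))  # K is state 9

  # pseudocount-dominated limit: all frequencies -> 1/q
  fbig <- estimate_frequencies(one, rep(1, 10), lambda = 1e9)
  expect_equal(fbig$fi[, 1], rep(1 / 21, 21), tolerance = 1e-6)

  # unweighted empirical frequencies at lambda = 0
  chars <- random_alignment(50, 6, gap_rate = 0.1, seed = 5)
  f0 <- estimate_frequencies(chars, rep(1, 50), lambda = 0)
  for (i in 1:6) {
    emp <- tabulate(match(chars[, i], ALPHA21), 21) / 50
    expect_equal(f0$fi[, i], emp, tolerance = 1e-12)
  }
  expect_equal(pairdca:::pair_block(f0$fij, 2, 5),
               unname(brute_force_joint(chars, 2, 5)), tolerance = 1e-12)
})

test_that("frequency model invariants hold on random weighted inputs", {
  for (seed in 1:5) {
    chars <- random_alignment(40, 7, gap_rate = 0.2, seed = seed)
    w <- compute_sequence_weights(alignment_matrix(chars), theta = 0.3)
    lam <- if (seed %% 2) w$M_eff else 0
    f <- estimate_frequencies(chars, w, lambda = lam)
    expect_equal(colSums(f$fi), rep(1, 7), tolerance = 1e-12)
    for (i in 1:6) for (j in (i + 1):7) {
      blk <- pairdca:::pair_block(f$fij, i, j)
      expect_equal(sum(blk), 1, tolerance = 1e-12)
      expect_equal(rowSums(blk), f$fi[, i], tolerance = 1e-12)
      expect_equal(colSums(blk), f$fi[, j], tolerance = 1e-12)
    }
    if (lam > 0) expect_true(all(f$fij[1:42, 43:147] > 0))
  }
})

test_that("mutual information has its closed forms and brute-force values", {
  # exact product frequencies: two independent 50/50 columns
  indep <- alignment_matrix(rbind(c("A", "A"), c("A", "C"),
                                  c("C", "A"), c("C", "C")))
  f <- estimate_frequencies(indep, rep(1, 4), lambda = 0)
  expect_equal(mutual_information(f)$mi, 0, tolerance = 1e-14)

  # perfectly correlated 50/50 columns: MI = ln 2
  corr <- alignment_matrix(rbind(c("A", "A"), c("C", "C")))
  f2 <- estimate_frequencies(corr, rep(1, 2), lambda = 0)
  expect_equal(mutual_information(f2)$mi, log(2), tolerance = 1e-14)

  # random 8-column alignment vs explicit double sum
  chars <- random_alignment(60, 8, gap_rate = 0.1, seed = 21)
  f3 <- estimate_frequencies(chars, rep(1, 60), lambda = 0)
  mi <- mutual_information(f3)
  for (k in seq_len(nrow(mi)))
    expect_equal(mi$mi[k], brute_force_mi(chars, mi$i[k], mi$j[k]),
                 tolerance = 1e-12)
})

test_that("mean-field couplings are symmetric and vanish for independent data", {
  chars <- random_alignment(400, 6, gap_rate = 0.1, seed = 31)
  w <- compute_sequence_weights(alignment_matrix(chars), theta = 0.2)
  f <- estimate_frequencies(chars, w, lambda = w$M_eff)
  cpl <- infer_mean_field_couplings(f)
  for (pair in list(c(1, 2), c(2, 5), c(3, 6))) {
    e_ij <- get_couplings(cpl, pair[1], pair[2])
    e_ji <- get_couplings(cpl, pair[2], pair[1])
    expect_equal(e_ij, t(e_ji), tolerance = 1e-10)
    expect_equal(e_ij[21, ], rep(0, 21))  # gap is the zero-coupling gauge
  }

  # independent columns: max coupling magnitude shrinks with M
  small <- random_alignment(100, 6, gap_rate = 0, n_letters = 4, seed = 32)
  big <- random_alignment(4000, 6, gap_rate = 0, n_letters = 4, seed = 32)
  max_e <- function(chars) {
    w <- compute_sequence_weights(alignment_matrix(chars), theta = 0.2)
    f <- estimate_frequencies(chars, w, lambda = w$M_eff)
    cpl <- infer_mean_field_couplings(f)
    max(abs(get_couplings(cpl, 1, 2)))
  }
  expect_lt(max_e(big), max_e(small))
})

test_that("direct information is zero without coupling and symmetric under column swap", {
  # hand-built model with all inter-column couplings zero
  chars <- random_alignment(50, 3, gap_rate = 0.1, seed = 41)
  w <- compute_sequence_weights(alignment_matrix(chars), theta = 0.2)
  f <- estimate_frequencies(chars, w, lambda = w$M_eff)
  cpl <- infer_mean_field_couplings(f)
  cpl$invC[] <- 0  # e_ij = 0 everywhere -> P_ij = f_i f_j -> DI = 0
  di <- direct_information(cpl, f)
  expect_equal(di$di, rep(0, 3), tolerance = 1e-6)
  expect_true(all(di$di > -1e-9))

  # swapping two columns of the alignment swaps (not changes) DI
  chars2 <- random_alignment(80, 4, gap_rate = 0.1, seed = 42)
  run_di <- function(ch) {
    w <- compute_sequence_weights(alignment_matrix(ch), theta = 0.2)
    f <- estimate_frequencies(ch, w, lambda = w$M_eff)
    direct_information(infer_mean_field_couplings(f), f)
  }
  d1 <- run_di(chars2)
  d2 <- run_di(chars2[, c(2, 1, 3, 4)])
  # agreement is limited by the fixed point's marginal tolerance (1e-4)
  expect_equal(d1$di[d1$i == 1 & d1$j == 2], d2$di[d2$i == 1 & d2$j == 2],
               tolerance = 1e-3)
  expect_equal(d1$di[d1$i == 1 & d1$j == 3], d2$di[d2$i == 2 & d2$j == 3],
               tolerance = 1e-3)
})

test_that("an isolated planted coupling yields DI near the generating joint's MI", {
  spec <- synthetic_spec(len_a = 6, len_b = 6, M = 4000, n_planted = 1,
                         gap_rate = 0, seed = 51)
  sa <- synthetic_alignment(spec, spacer_len = 6)
  fit <- dca(sa$aln, position_map = sa$map)
  tr <- true_pair_statistics(spec)
  ci <- tr$col_a[1]; cj <- spec$len_a + 6 + tr$col_b[1]
  di_hat <- fit$pairs$di[fit$pairs$i == ci & fit$pairs$j == cj]
  expect_equal(di_hat, tr$true_mi[1], tolerance = 0.15)
  # and that pair dominates the DI ranking
  expect_equal(which.max(fit$pairs$di),
               which(fit$pairs$i == ci & fit$pairs$j == cj))
})

test_that("run_dca emits every pair exactly once, sorted", {
  chars <- random_alignment(30, 10, gap_rate = 0.1, seed = 61)
  tab <- run_dca(alignment_matrix(chars))
  expect_equal(nrow(tab), 45L)
  expect_named(tab, c("i", "j", "mi", "di"))
  expect_true(all(tab$i < tab$j))
  expect_equal(anyDuplicated(tab[, c("i", "j")]), 0L)
  expect_true(!is.unsorted(tab$i))
  o <- order(tab$i, tab$j)
  expect_equal(o, seq_len(nrow(tab)))
  expect_true(all(tab$mi >= 0))
  expect_true(all(tab$di >= -1e-9))
})

test_that("null alignments lose DI signal as M grows", {
  max_di <- function(M, seed) {
    chars <- random_alignment(M, 12, gap_rate = 0.05, n_letters = 6,
                              seed = seed)
    max(run_dca(alignment_matrix(chars))$di)
  }
  expect_lt(max_di(2000, 71), max_di(200, 71))
})
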