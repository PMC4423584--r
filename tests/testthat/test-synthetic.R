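test_that("synthetic specs are reproducible and validated", {
  s1 <- synthetic_spec(len_a = 10, len_b = 12, M = 50, n_planted = 3, seed = 2)
  s2 <- synthetic_spec(len_a = 10, len_b = 12, M = 50, n_planted = 3, seed = 2)
  expect_identical(s1$planted, s2$planted)
  expect_identical(s1$background, s2$background)
  # planted pairs form a matching: no column reused on either side
  expect_equal(anyDuplicated(vapply(s1$planted, `[[`, 1L, "col_a")), 0L)
  expect_equal(anyDuplicated(vapply(s1$planted, `[[`, 1L, "col_b")), 0L)
  # joint tables and background profiles are distributions
  for (p in s1$planted) expect_equal(sum(p$joint), 1, tolerance = 1e-12)
  expect_equal(colSums(s1$background), rep(1, 22), tolerance = 1e-12)

  expect_error(synthetic_spec(gap_rate = 1), "gap_rate")
  expect_error(synthetic_spec(len_a = 3, len_b = 3, n_planted = 5), "planted")
})

test_that("sampling is seed-deterministic and matches the planted joints", {
  spec <- synthetic_spec(len_a = 6, len_b = 6, M = 2000, n_planted = 1,
                         gap_rate = 0, seed = 13)
  r1 <- sample_paired_msa(spec)
  r2 <- sample_paired_msa(spec)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2000L)
  expect_equal(unique(nchar(r1$seq_a)), 6L)

  # empirical joint of the planted pair within multinomial error
  p <- spec$planted[[1]]
  a <- substr(r1$seq_a, p$col_a, p$col_a)
  b <- substr(r1$seq_b, p$col_b, p$col_b)
  for (cell in which(p$joint > 0.05)) {
    ra <- rownames(p$joint)[(cell - 1) %% 20 + 1]
    cb <- colnames(p$joint)[(cell - 1) %/% 20 + 1]
    emp <- mean(a == ra & b == cb)
    expect_lt(abs(emp - p$joint[cell]), 4 * sqrt(p$joint[cell] / 2000) + 0.01)
  }
})

test_that("a spec without planted pairs produces near-independent columns", {
  spec <- synthetic_spec(len_a = 5, len_b = 5, M = 3000, n_planted = 0,
                         gap_rate = 0, seed = 14)
  sa <- synthetic_alignment(spec, spacer_len = 5)
  f <- estimate_frequencies(sa$aln, rep(1, spec$M), lambda = 0,
                            columns = sa$map$column[sa$map$segment != "SPACER"])
  mi <- mutual_information(f)
  # finite-sample MI bias is O(states^2 / M); everything should be tiny
  expect_lt(max(mi$mi), 0.15)
  expect_gt(min(mi$mi), 0)
})

test_that("gap_rate plants gaps everywhere except the reference row", {
  spec <- synthetic_spec(len_a = 20, len_b = 20, M = 400, n_planted = 2,
                         gap_rate = 0.1, seed = 15)
  rec <- sample_paired_msa(spec)
  all_chars <- strsplit(paste0(rec$seq_a, rec$seq_b), "")
  gap_frac <- vapply(all_chars, function(ch) mean(ch == "-"), numeric(1))
  expect_equal(gap_frac[1], 0)
  expect_equal(mean(gap_frac[-1]), 0.1, tolerance = 0.05)
})

test_that("redundancy injection clones and mutates as specified", {
  spec <- synthetic_spec(len_a = 15, len_b = 15, M = 40, n_planted = 1,
                         gap_rate = 0.05, seed = 16)
  rec <- sample_paired_msa(spec)

  expect_identical(inject_redundancy(rec, 0, 0.1), rec)

  # mutation_rate = 0: clones identical to parents, M_eff preserved
  cl0 <- inject_redundancy(rec, 4, 0, seed = 1)
  expect_equal(nrow(cl0), 200L)
  expect_identical(cl0$seq_a[41:80], rec$seq_a)
  cc <- concatenate_with_spacer(cl0, spacer_len = 10)
  seqs <- cc$sequence; names(seqs) <- make.unique(cc$species_id)
  w <- compute_sequence_weights(alignment_matrix(seqs), theta = 0.2)
  w0 <- compute_sequence_weights(
    alignment_matrix(stats::setNames(concatenate_with_spacer(rec, spacer_len = 10)$sequence,
                                     rec$species_id)), theta = 0.2)
  expect_equal(w$M_eff, w0$M_eff, tolerance = 1e-9)

  # mean clone-parent identity over amino-acid sites is 1 - mutation_rate
  cl <- inject_redundancy(rec, 4, 0.05, seed = 2)
  parent <- strsplit(paste0(rec$seq_a, rec$seq_b), "")
  idents <- numeric(0)
  for (k in 1:4) {
    clone <- strsplit(paste0(cl$seq_a, cl$seq_b)[40 * k + 1:40], "")
    idents <- c(idents, mapply(function(p, c) {
      aa <- p != "-"
      mean(p[aa] == c[aa])
    }, parent, clone))
  }
  expect_equal(mean(idents), 0.95, tolerance = 0.01)

  expect_error(inject_redundancy(rec, -1, 0.1), "n_clones")
  expect_error(inject_redundancy(rec, 1, 1.5), "mutation_rate")
})

test_that("oracle MI has its closed forms", {
  # permutation over 4 equiprobable states: MI = ln 4
  set.seed(17)
  spec <- synthetic_spec(len_a = 5, len_b = 5, M = 10, n_planted = 1,
                         joint_states = 4, joint_purity = 1, seed = 17)
  tr <- true_pair_statistics(spec)
  expect_equal(tr$true_mi, log(4), tolerance = 1e-12)

  # pure product: MI = 0
  spec0 <- synthetic_spec(len_a = 5, len_b = 5, M = 10, n_planted = 1,
                          joint_purity = 0, seed = 18)
  expect_equal(true_pair_statistics(spec0)$true_mi, 0, tolerance = 1e-12)

  # mixture joints agree with an independent direct summation
  spec2 <- synthetic_spec(len_a = 8, len_b = 8, M = 10, n_planted = 3,
                          joint_states = 6, joint_purity = 0.85, seed = 19)
  tr2 <- true_pair_statistics(spec2)
  for (k in 1:3)
    expect_equal(tr2$true_mi[k], joint_mi(spec2$planted[[k]]$joint),
                 tolerance = 1e-12)
  expect_true(all(tr2$true_mi >= 1.0))
})

test_that("recovery metrics count planted hits in the top k", {
  spec <- synthetic_spec(len_a = 10, len_b = 10, M = 10, n_planted = 5, seed = 20)
  truth <- planted_keys(spec)
  mk <- function(res_a, res_b, di) {
    data.frame(protein_i = "A", res_i = res_a, protein_j = "B", res_j = res_b,
               mi = di, di = di, distance = NA_real_)
  }
  ra <- as.integer(sub(" .*", "", truth)); rb <- as.integer(sub(".* ", "", truth))
  perfect <- rbind(mk(ra, rb, 5:1), mk(1:5 + 5L, 2:6, runif(5, 0, 0.1)))
  ev <- evaluate_recovery(perfect, spec, k = 5)
  expect_equal(ev$precision, 1.0)
  expect_equal(ev$recall, 1.0)

  none <- mk(c(9, 9, 9, 10, 10), c(1, 2, 3, 1, 2), runif(5))
  none <- none[!paste(none$res_i, none$res_j) %in% truth, ]
  ev0 <- evaluate_recovery(none, spec, k = nrow(none))
  expect_equal(ev0$precision, 0.0)

  expect_error(evaluate_recovery(perfect, spec, k = 0), "positive")

  # random rankings recover planted pairs at about the base rate
  set.seed(21)
  grid <- expand.grid(res_i = 1:10, res_j = 1:10)
  hits <- replicate(300, {
    di <- runif(100)
    tab <- data.frame(protein_i = "A", res_i = grid$res_i, protein_j = "B",
                      res_j = grid$res_j, mi = di, di = di,
                      distance = NA_real_)
    evaluate_recovery(tab, spec, k = 10)$precision
  })
  expect_equal(mean(hits), 5 / 100, tolerance = 0.25)
})
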