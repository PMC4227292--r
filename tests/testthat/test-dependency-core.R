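test_that("marginal profiles are exact proportions at zero pseudocount", {
  aln <- make_aln(c("AA", "AT", "AT", "TA"))
  m <- compute_marginals(aln)
  expect_equal(unname(m$freq["A", 1]), 0.75)
  expect_equal(unname(m$freq["T", 1]), 0.25)
  expect_true(all(abs(colSums(m$freq) - 1) < 1e-12))
  expect_identical(colSums(m$counts), rep(4, 2))
  expect_error(compute_marginals(aln, -1), "non-negative")
})

test_that("smoothed and degenerate marginals behave as expected", {
  one <- make_aln("ACG")
  m1 <- compute_marginals(one)
  expect_equal(unname(m1$freq["A", 1]), 1)
  expect_equal(unname(m1$freq["G", 3]), 1)

  # a uniform column stays uniform under any smoothing (the alphabet
  # must hold exactly the observed categories for this to be exact)
  unif <- make_aln(c("AA", "CC", "GG", "TT"),
                   make_alphabet("custom", symbols = c("A", "C", "G", "T"),
                                 gap = NA))
  for (a in c(0, 0.5, 3)) {
    mu <- compute_marginals(unif, a)
    expect_equal(unname(mu$freq[, 1]), rep(0.25, 4))
  }
})

test_that("joint tables count co-occurrences and reconcile with marginals", {
  J <- compute_joint(aa_tt_family(), 1, 2)
  expect_identical(J$counts["A", "A"], 4L)
  expect_identical(J$counts["T", "T"], 4L)
  expect_identical(J$counts["A", "T"], 0L)
  expect_identical(sum(J$counts), J$n)

  J2 <- compute_joint(indep_family(), 1, 2)
  expect_true(all(J2$counts[c("A", "T"), c("A", "T")] == 1L))

  marg <- compute_marginals(aa_tt_family())
  expect_equal(rowSums(J$counts), marg$counts[, 1])
  expect_equal(colSums(J$counts), marg$counts[, 2])
  expect_error(compute_joint(aa_tt_family(), 2, 1), "j < k")
  expect_error(compute_joint(aa_tt_family(), 1, 5), "j < k")
})

test_that("residuals equal observed minus expected with the stated sign", {
  aln <- aa_tt_family()
  r <- compute_residuals(compute_joint(aln, 1, 2), compute_marginals(aln))
  expect_equal(r$r["A", "A"], 0.25)
  expect_equal(r$r["A", "T"], -0.25)
  r0 <- compute_residuals(compute_joint(indep_family(), 1, 2),
                          compute_marginals(indep_family()))
  expect_true(all(abs(r0$r[c("A", "T"), c("A", "T")]) < 1e-12))
})

test_that("residual matrices conserve mass globally, per row and per column", {
  for (seed in 1:5) {
    fam <- generate_independent_family(n = 40, L = 6, seed = seed)$alignment
    marg <- compute_marginals(fam)
    for (jk in list(c(1, 2), c(2, 5), c(1, 6))) {
      r <- compute_residuals(compute_joint(fam, jk[1], jk[2]), marg)
      expect_lt(abs(sum(r$r)), 1e-12)
      expect_true(all(abs(rowSums(r$r)) < 1e-12))
      expect_true(all(abs(colSums(r$r)) < 1e-12))
    }
  }
})

test_that("residual unit and type variants scale consistently", {
  aln <- aa_tt_family()
  marg <- compute_marginals(aln)
  J <- compute_joint(aln, 1, 2)
  rc <- compute_residuals(J, marg, units = "count")
  expect_equal(rc$r["A", "A"], 0.25 * 8)
  rp <- compute_residuals(J, marg, type = "pearson")
  expect_equal(rp$r["A", "A"], 0.25 / sqrt(0.25))
  expect_error(compute_residuals(J, compute_marginals(indep_family())),
               "disagree")
})

test_that("fisher p-values match the frozen exact values", {
  # margins (4,4)/(4,4): tables a=0..4 have point probabilities
  # (1,16,36,16,1)/70; observed a=4 has 1/70, so the two-sided sum is 2/70
  expect_equal(fisher_pvalue(4, 0, 0, 4), 2 / 70, tolerance = 1e-12)
  expect_equal(fisher_pvalue(1, 1, 1, 1), 1)
  expect_equal(fisher_pvalue(0, 0, 0, 0), 1)
  expect_equal(fisher_pvalue(0, 0, 3, 5), 1)
  expect_error(fisher_pvalue(-1, 0, 0, 1), "non-negative")
})

test_that("fisher p-values agree with enumeration and stats::fisher.test", {
  set.seed(42)
  for (i in 1:300) {
    cells <- as.integer(rmultinom(1, sample(1:40, 1), rep(0.25, 4)))
    p <- fisher_pvalue(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
    # symmetry under row and column swaps
    expect_equal(p, fisher_pvalue(cells[2], cells[1], cells[4], cells[3]),
                 tolerance = 1e-12)
    expect_equal(p, fisher_pvalue(cells[3], cells[4], cells[1], cells[2]),
                 tolerance = 1e-12)
  }
  set.seed(7)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(5:60, 1), c(0.4, 0.2, 0.2, 0.2)))
    tab <- matrix(cells, 2)
    expect_equal(fisher_pvalue(cells[1], cells[3], cells[2], cells[4]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-6)
  }
})

test_that("subnode pair tests collapse the joint to the right 2x2", {
  J <- compute_joint(aa_tt_family(), 1, 2)
  res <- subnode_pair_test(J, "A", "A")
  expect_identical(unname(res$two_by_two), c(4L, 0L, 0L, 4L))
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)

  Ji <- compute_joint(indep_family(), 1, 2)
  expect_equal(subnode_pair_test(Ji, "A", "A")$p_value, 1)
  # category absent at position 1: empty margin gives p = 1
  expect_equal(subnode_pair_test(J, "G", "A")$p_value, 1)
  expect_error(subnode_pair_test(J, "Z", "A"), "alphabet")
})

test_that("position pair counts follow L(L-1)/2", {
  expect_identical(count_position_pairs(9), 36L)
  expect_identical(count_position_pairs(300), 44850L)
  expect_identical(count_position_pairs(1), 0L)
  expect_identical(count_position_pairs(2), 1L)
  expect_error(count_position_pairs(0), "positive")
})

test_that("the all-pairs scan visits each pair once in canonical order", {
  toy <- toy_nine_column_family()$alignment
  scan <- scan_all_pairs(toy)
  pairs <- unique(scan[, c("j", "k")])
  expect_identical(nrow(pairs), 36L)
  expect_true(all(pairs$j < pairs$k))
  expect_identical(pairs, pairs[order(pairs$j, pairs$k), ])

  two <- scan_all_pairs(indep_family())
  expect_identical(nrow(unique(two[, c("j", "k")])), 1L)
  # scan rows reproduce the single-pair operations
  i <- which(scan$j == 6 & scan$k == 9 & scan$M == "G" & scan$N == "C")
  J <- compute_joint(toy, 6, 9)
  r <- compute_residuals(J, compute_marginals(toy))
  expect_identical(scan$count[i], J$counts["G", "C"])
  expect_equal(scan$residual[i], r$r["G", "C"])
  expect_equal(scan$p[i], subnode_pair_test(J, "G", "C")$p_value)
})
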