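test_that("an edge-free model reduces to a smoothed PSSM", {
  aln <- aa_tt_family()
  g <- filter_edges(build_metagraph(aln), filter_spec(0.9, 1e-12, 100))
  m <- build_crf(g, aln, alpha = 1e-8)
  expect_length(m$edge_potentials, 0)
  s <- score_sequence(m, "AA")
  expect_equal(s$edge_term, 0)
  expect_equal(s$log_score, log(0.25), tolerance = 1e-6)
  # per-position potentials exponentiate to a distribution
  expect_true(all(abs(colSums(exp(m$node_potentials)) - 1) < 1e-9))
})

test_that("edge potentials carry the sign of the residual", {
  aln <- aa_tt_family()
  g <- filter_edges(build_metagraph(aln), filter_spec(0, 1, 0))
  m <- build_crf(g, aln, alpha = 0.5)
  pot <- m$edge_potentials[["1:2"]]
  expect_gt(pot["A", "A"], 0)
  expect_gt(pot["T", "T"], 0)
  expect_lt(pot["A", "T"], 0)
  expect_gt(score_sequence(m, "AA")$log_score,
            score_sequence(m, "AT")$log_score)
  expect_error(build_crf(g, aln, alpha = 0), "positive")
  expect_error(build_crf(g, indep_family()), "not built from")
})

test_that("scoring is deterministic and additive in node and edge terms", {
  fam <- generate_stemloop_family(n = 120, seed = 9)
  g <- filter_edges(build_metagraph(fam$alignment), filter_spec(0.05, 0.01, 3))
  m <- build_crf(g, fam$alignment)
  seqv <- fam$alignment$matrix[1, ]
  s1 <- score_sequence(m, seqv)
  s2 <- score_sequence(m, seqv)
  expect_identical(s1, s2)
  expect_equal(s1$log_score, s1$node_term + s1$edge_term)
  m2 <- build_crf(g, fam$alignment)
  expect_identical(m, m2)
  expect_error(score_sequence(m, "ACGT"), "length")
  expect_error(score_sequence(m, paste(rep("Z", 30), collapse = "")),
               "alphabet")
})

test_that("relative scores use the reference-equals-one convention", {
  fam <- generate_stemloop_family(n = 120, seed = 9)
  g <- filter_edges(build_metagraph(fam$alignment), filter_spec(0.05, 0.01, 3))
  m <- build_crf(g, fam$alignment)
  ref <- fam$alignment$matrix[1, ]
  other <- fam$alignment$matrix[2, ]
  expect_identical(relative_score(m, ref, ref), 1)
  expect_equal(relative_score(m, other, ref) * relative_score(m, ref, other),
               1, tolerance = 1e-9)
  # a dependency-violating mutant scores below the intact sequence
  mt <- build_crf(filter_edges(build_metagraph(aa_tt_family()),
                               filter_spec(0, 1, 0)), aa_tt_family())
  expect_lt(relative_score(mt, "AT", "AA"), 1)
})

test_that("alignment scoring returns one finite row per sequence", {
  fam <- generate_stemloop_family(n = 80, seed = 2)
  g <- filter_edges(build_metagraph(fam$alignment), filter_spec(0.05, 0.01, 3))
  m <- build_crf(g, fam$alignment)
  sc <- score_alignment(m, fam$alignment, fam$alignment$ids[3])
  expect_identical(nrow(sc), 80L)
  expect_identical(sc$id, fam$alignment$ids)
  expect_true(all(is.finite(sc$log_score)))
  expect_equal(sc$relative[3], 1)
  expect_error(score_alignment(m, fam$alignment, "nope"), "not found")
})

test_that("edge-free ranking equals smoothed PSSM likelihood ranking", {
  fam <- generate_stemloop_family(n = 150, seed = 5)
  aln <- fam$alignment
  g0 <- filter_edges(build_metagraph(aln), filter_spec(0.9, 1e-12, 1e6))
  m0 <- build_crf(g0, aln, alpha = 0.5)
  marg <- compute_marginals(aln, 0)
  S <- length(aln$alphabet$symbols)
  pssm_ll <- function(seqv)
    sum(log((marg$counts[cbind(match(seqv, aln$alphabet$symbols),
                               seq_along(seqv))] + 0.5) /
              (marg$n + 0.5 * S)))
  cand <- lapply(1:20, function(i) aln$matrix[i, ])
  a <- vapply(cand, function(s) score_sequence(m0, s)$log_score, numeric(1))
  b <- vapply(cand, pssm_ll, numeric(1))
  expect_identical(order(a), order(b))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("the full-edge CRF separates mutants the PSSM cannot", {
  fam <- generate_stemloop_family(seed = 7)
  g <- build_metagraph(fam$alignment)
  crf <- build_crf(filter_edges(g, filter_spec(0.05, 0.001, 3)),
                   fam$alignment)
  pssm <- build_crf(filter_edges(g, filter_spec(1.1, 1, 1e6)),
                    fam$alignment)
  base <- stem_base_sequence(fam)
  muts <- stem_pair_mutants(fam, base)
  cc <- log_scores(crf, muts$consistent)
  cv <- log_scores(crf, muts$violating)
  expect_gt(min(cc), max(cv))
  # monotone degradation: two broken pairs score below one broken pair
  worst <- base
  worst[fam$truth$pairs[[1]][1]] <- WC[base[fam$truth$pairs[[1]][1]]]
  worst[fam$truth$pairs[[2]][1]] <- WC[base[fam$truth$pairs[[2]][1]]]
  one_broken <- base
  one_broken[fam$truth$pairs[[1]][1]] <- WC[base[fam$truth$pairs[[1]][1]]]
  expect_lt(log_scores(crf, list(worst)), log_scores(crf, list(one_broken)))
  expect_lt(log_scores(crf, list(one_broken)), log_scores(crf, list(base)))
  # the PSSM misorders at least one consistent/violating pair
  pc <- log_scores(pssm, muts$consistent)
  pv <- log_scores(pssm, muts$violating)
  expect_true(any(outer(pc, pv, "<=")))
})

test_that("CRF models persist through JSON round trips", {
  fam <- generate_stemloop_family(n = 100, seed = 3)
  g <- filter_edges(build_metagraph(fam$alignment), filter_spec(0.05, 0.01, 3))
  m <- build_crf(g, fam$alignment)
  path <- withr::local_tempfile(fileext = ".json")
  export_crf(m, path)
  back <- import_crf(path)
  seqv <- fam$alignment$matrix[5, ]
  expect_equal(score_sequence(back, seqv)$log_score,
               score_sequence(m, seqv)$log_score, tolerance = 1e-12)
  expect_equal(back$node_potentials, m$node_potentials, tolerance = 1e-12)
})
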