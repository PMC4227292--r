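test_that("raw metagraphs hold one subnode per observed category and no zero-count edges", {
  g <- build_metagraph(aa_tt_family())
  expect_identical(nrow(g$subnodes), 4L)
  expect_identical(nrow(g$edges), 2L)
  expect_setequal(paste(g$edges$M, g$edges$N), c("A A", "T T"))

  gi <- build_metagraph(indep_family())
  expect_identical(nrow(gi$subnodes), 4L)
  expect_identical(nrow(gi$edges), 4L)
  expect_true(all(abs(gi$edges$residual) < 1e-12))

  toy <- toy_nine_column_family()$alignment
  gt <- build_metagraph(toy)
  expect_true(all(gt$edges$j < gt$edges$k))
  expect_true(all(gt$edges$count > 0))
  # scan from a different alignment is rejected
  expect_error(build_metagraph(toy, scan_all_pairs(indep_family())),
               "not computed from this alignment")
})

test_that("subnode weights sum to one within each position node", {
  g <- build_metagraph(toy_nine_column_family()$alignment)
  w <- tapply(g$subnodes$weight, g$subnodes$j, sum)
  expect_true(all(abs(w - 1) < 1e-12))
})

test_that("filtering retains exactly the edges passing every threshold", {
  g <- build_metagraph(aa_tt_family())
  expect_identical(sum(filter_edges(g, filter_spec(0, 1, 0))$edges$retained), 2L)
  expect_identical(sum(filter_edges(g, filter_spec(0.3, 1, 0))$edges$retained), 0L)
  expect_identical(sum(filter_edges(g, filter_spec(0.2, 1, 5))$edges$retained), 0L)
  expect_identical(sum(filter_edges(g, filter_spec(0.2, 1, 4))$edges$retained), 2L)
  expect_error(filter_spec(-1, 0.5, 0), "non-negative")
  expect_error(filter_spec(0, 0, 0), "max_p")
})

test_that("filtering is idempotent, monotone, and leaves subnodes untouched", {
  g <- build_metagraph(toy_nine_column_family()$alignment)
  sub0 <- g$subnodes
  f1 <- filter_spec(0.05, 0.01, 2)
  g1 <- filter_edges(g, f1)
  g11 <- filter_edges(g1, f1)
  expect_identical(g1$edges$retained, g11$edges$retained)
  # tightening any threshold keeps a subset
  tighter <- list(filter_spec(0.10, 0.01, 2), filter_spec(0.05, 0.001, 2),
                  filter_spec(0.05, 0.01, 10))
  for (f2 in tighter) {
    g2 <- filter_edges(g, f2)
    expect_true(all(!g2$edges$retained | g1$edges$retained))
  }
  expect_identical(g1$subnodes, sub0)
  expect_identical(g11$subnodes, sub0)
})

test_that("pinned edges survive impossible thresholds; removed edges stay out", {
  g <- build_metagraph(aa_tt_family())
  g <- pin_edge(g, 1, "A", 2, "A")
  g <- filter_edges(g, filter_spec(0.9, 1e-12, 1000))
  expect_identical(sum(g$edges$retained), 1L)
  expect_true(g$edges$retained[g$edges$M == "A"])

  g2 <- build_metagraph(aa_tt_family())
  g2 <- remove_edge(g2, 1, "T", 2, "T")
  g2 <- filter_edges(g2, filter_spec(0, 1, 0))
  expect_false(g2$edges$retained[g2$edges$M == "T"])
  # pin and remove are mutually exclusive states
  expect_error(remove_edge(g, 1, "A", 2, "A"), "pinned")
  expect_error(pin_edge(g2, 1, "T", 2, "T"), "removed")
  expect_error(pin_edge(g, 1, "A", 2, "G"), "no edge")
})

test_that("replaying the history on a fresh build reproduces the edge set", {
  aln <- toy_nine_column_family()$alignment
  g <- build_metagraph(aln)
  g <- filter_edges(g, filter_spec(0.05, 0.01, 2))
  g <- pin_edge(g, 2, "G", 4, "T")
  g <- remove_edge(g, 6, "G", 9, "C")
  g <- filter_edges(g, filter_spec(0.1, 0.001, 3))
  replayed <- replay_history(build_metagraph(aln), g$history)
  expect_identical(replayed$edges$retained, g$edges$retained)
  expect_identical(replayed$edges$pinned, g$edges$pinned)
  expect_identical(replayed$edges$removed, g$edges$removed)
})

test_that("cycle detection distinguishes chains, triangles, and X-patterns", {
  chain <- manual_metagraph(
    data.frame(j = c(1, 2), k = c(2, 3), M = c("A", "A"), N = c("A", "A")),
    L = 3)
  expect_length(detect_cycles(chain, "subnode")$cycles, 0)
  expect_false(any(detect_cycles(chain, "node")$metagraph$edges$in_cycle))

  tri <- manual_metagraph(
    data.frame(j = c(1, 2, 1), k = c(2, 3, 3), M = "A", N = "A"), L = 3)
  res <- detect_cycles(tri, "subnode")
  expect_length(res$cycles, 1)
  expect_length(res$cycles[[1]], 3)
  expect_true(all(res$metagraph$edges$in_cycle))

  # stem-loop X-pattern: two parallel subnode edges project to a single
  # position-level (multi-)edge, which is no cycle
  x <- manual_metagraph(
    data.frame(j = c(6, 6), k = c(9, 9), M = c("G", "C"), N = c("C", "G")),
    L = 9)
  resx <- detect_cycles(x, "node")
  expect_length(resx$cycles, 0)
  expect_false(any(resx$metagraph$edges$in_cycle))
})

test_that("component labels are deterministic and match a union-find oracle", {
  two <- manual_metagraph(
    data.frame(j = c(1, 5), k = c(2, 9), M = c("A", "G"), N = c("A", "C")),
    L = 9)
  lab <- label_components(two)
  expect_identical(sort(unique(lab$edges$component_id)), c(1L, 2L))
  expect_identical(lab$edges$component_id[1], 1L)  # smallest position first

  g <- filter_edges(build_metagraph(toy_nine_column_family()$alignment),
                    filter_spec(0.1, 0.001, 3))
  lab2 <- label_components(g)
  ret <- lab2$edges[lab2$edges$retained, ]
  expect_identical(length(unique(ret$component_id)), oracle_components(ret))

  empty <- filter_edges(build_metagraph(aa_tt_family()),
                        filter_spec(0.9, 1e-9, 100))
  expect_true(all(is.na(label_components(empty)$edges$component_id)))
})

test_that("JSON round-trip preserves subnodes, edges, flags, and history", {
  aln <- toy_nine_column_family()$alignment
  g <- filter_edges(build_metagraph(aln), filter_spec(0.05, 0.01, 2))
  g <- pin_edge(g, 2, "G", 4, "T")
  g <- label_components(g)
  path <- withr::local_tempfile(fileext = ".json")
  export_metagraph(g, path, "json")
  back <- import_metagraph(path, "json")
  expect_equal(back$edges, g$edges, tolerance = 1e-12)
  expect_equal(back$subnodes, g$subnodes, tolerance = 1e-12)
  expect_identical(length(back$history), length(g$history))
  expect_identical(replay_history(build_metagraph(aln), back$history)$edges$retained,
                   g$edges$retained)
})

test_that("GraphML and TSV exports round-trip the edge set", {
  g <- filter_edges(build_metagraph(toy_nine_column_family()$alignment),
                    filter_spec(0.05, 0.01, 2))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_metagraph(g, gml, "graphml")
  back <- import_metagraph(gml, "graphml")
  expect_identical(nrow(back$subnodes), nrow(g$subnodes))
  expect_identical(nrow(back$edges), nrow(g$edges))
  key <- function(e) sort(paste(e$j, e$M, e$k, e$N, e$count, e$retained))
  expect_identical(key(back$edges), key(g$edges))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_metagraph(g, tsv, "tsv")
  back2 <- import_metagraph(tsv, "tsv")
  expect_identical(key(back2$edges), key(g$edges))
})

test_that("imports with intra-position edges are rejected", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("j", "k", "M", "N", "count", "residual", "p", sep = "\t"),
               paste(3, 3, "A", "C", 5, 0.1, 0.001, sep = "\t")), tsv)
  expect_error(import_metagraph(tsv, "tsv"), "invariant violation")
})
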