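#' Build the raw dependency metagraph
#'
#' The metagraph models each alignment position as a node containing
#' one weighted subnode per observed category (weight = marginal
#' frequency), and connects subnodes at *different* positions with
#' dependency edges carrying the joint count, the signed residual,
#' and the Fisher exact p-value.  Category pairs never observed
#' together produce no edge (the complete bipartite edge set is
#' implicit); subnodes within one position are never connected.
#'
#' @param aln a `cn_alignment`.
#' @param scan optional result of [scan_all_pairs()] on `aln`; computed
#'   if missing.  Must derive from the same alignment.
#' @return an object of class `cn_metagraph` with `subnodes`
#'   (`j`, `M`, `weight`, `count`), `edges` (`j`, `k`, `M`, `N`,
#'   `count`, `expected`, `residual`, `p`, `pinned`, `removed`,
#'   `retained`, `component_id`, `in_cycle`), an append-only,
#'   replayable `history`, and provenance.
#' @examples
#' aln <- toy_nine_column_family()$alignment
#' g <- build_metagraph(aln)
#' nrow(g$edges)
#' @export
build_metagraph <- function(aln, scan = NULL) {
  stopifnot(inherits(aln, "cn_alignment"))
  if (is.null(scan)) scan <- scan_all_pairs(aln)
  if (!inherits(scan, "cn_scan")) stop("scan must come from scan_all_pairs()")
  dig <- .alignment_digest(aln)
  if (!identical(attr(scan, "digest"), dig))
    stop("scan was not computed from this alignment")
  marg <- compute_marginals(aln, 0)
  syms <- aln$alphabet$symbols
  nz <- which(marg$counts > 0, arr.ind = TRUE)
  ord <- order(nz[, 2L], nz[, 1L])
  subnodes <- data.frame(
    j = as.integer(nz[ord, 2L]), M = syms[nz[ord, 1L]],
    weight = marg$freq[nz[ord, , drop = FALSE]],
    count = marg$counts[nz[ord, , drop = FALSE]],
    stringsAsFactors = FALSE)
  rownames(subnodes) <- NULL
  edges <- as.data.frame(scan)[scan$count > 0, , drop = FALSE]
  rownames(edges) <- NULL
  for (at in setdiff(names(attributes(edges)),
                     c("names", "row.names", "class")))
    attr(edges, at) <- NULL
  class(edges) <- "data.frame"
  edges$pinned <- FALSE
  edges$removed <- FALSE
  edges$retained <- TRUE
  edges$component_id <- NA_integer_
  edges$in_cycle <- FALSE
  structure(list(L = attr(scan, "L"), alphabet = aln$alphabet,
                 subnodes = subnodes, edges = edges, history = list(),
                 provenance = list(digest = dig, n = attr(scan, "n"))),
            class = "cn_metagraph")
}

#' Edge retention thresholds
#'
#' @param min_abs_residual minimum absolute residual.
#' @param max_p maximum Fisher exact p-value, in (0, 1].
#' @param min_joint_count minimum joint co-occurrence count.
#' @return a `cn_filter_spec`.
#' @export
filter_spec <- function(min_abs_residual = 0, max_p = 1, min_joint_count = 0) {
  if (min_abs_residual < 0 || min_joint_count < 0)
    stop("thresholds must be non-negative")
  if (!(max_p > 0 && max_p <= 1)) stop("max_p must be in (0, 1]")
  structure(list(min_abs_residual = min_abs_residual, max_p = max_p,
                 min_joint_count = as.integer(min_joint_count)),
            class = "cn_filter_spec")
}

#' Apply threshold and statistical filters to metagraph edges
#'
#' An edge is retained iff it passes *all* thresholds
#' (`|residual| >= min_abs_residual`, `p <= max_p`,
#' `count >= min_joint_count`) or is pinned; removed edges never come
#' back.  Filtering always re-evaluates the full (non-removed) edge
#' set, so it is idempotent and monotone in the thresholds.  Subnodes
#' and their weights are untouched.  The spec is appended to the
#' replayable history.
#'
#' @param g a `cn_metagraph`.
#' @param f a [filter_spec()].
#' @return the filtered `cn_metagraph`.
#' @export
filter_edges <- function(g, f) {
  stopifnot(inherits(g, "cn_metagraph"), inherits(f, "cn_filter_spec"))
  e <- g$edges
  pass <- abs(e$residual) >= f$min_abs_residual &
    e$p <= f$max_p & e$count >= f$min_joint_count
  g$edges$retained <- !e$removed & (pass | e$pinned)
  g$history <- c(g$history, list(list(op = "filter", spec = unclass(f))))
  g
}

.edge_index <- function(g, j, M, k, N) {
  if (j > k) { tmp <- j; j <- k; k <- tmp; tmp <- M; M <- N; N <- tmp }
  idx <- which(g$edges$j == j & g$edges$k == k & g$edges$M == M & g$edges$N == N)
  if (length(idx) != 1L)
    stop(sprintf("no edge (%d,%s)-(%d,%s) in the metagraph", j, M, k, N))
  idx
}

#' Pin or remove a dependency edge
#'
#' Pinned edges are immune to all subsequent filters (the analyst's
#' "keep this Watson-Crick pair regardless of weight" action); removed
#' edges are deleted from the retained set permanently.  An edge
#' cannot be both.  Both edits are appended to the replayable history.
#'
#' @param g a `cn_metagraph`.
#' @param j,M,k,N edge endpoints `(j, M)`-`(k, N)` (order-insensitive).
#' @return the edited `cn_metagraph`.
#' @export
pin_edge <- function(g, j, M, k, N) {
  stopifnot(inherits(g, "cn_metagraph"))
  idx <- .edge_index(g, j, M, k, N)
  if (g$edges$removed[idx]) stop("cannot pin a removed edge")
  g$edges$pinned[idx] <- TRUE
  g$edges$retained[idx] <- TRUE
  g$history <- c(g$history, list(list(op = "pin", j = j, M = M, k = k, N = N)))
  g
}

#' @rdname pin_edge
#' @export
remove_edge <- function(g, j, M, k, N) {
  stopifnot(inherits(g, "cn_metagraph"))
  idx <- .edge_index(g, j, M, k, N)
  if (g$edges$pinned[idx]) stop("cannot remove a pinned edge")
  g$edges$removed[idx] <- TRUE
  g$edges$retained[idx] <- FALSE
  g$history <- c(g$history, list(list(op = "remove", j = j, M = M, k = k, N = N)))
  g
}

#' Replay a filter/edit history onto a metagraph
#'
#' Applying a recorded history to a freshly rebuilt raw metagraph
#' reproduces the retained edge set exactly — the interactive
#' refinement session as a reproducible script.
#'
#' @param g a raw `cn_metagraph` (same alignment).
#' @param history a history list from another `cn_metagraph`.
#' @return the replayed `cn_metagraph`.
#' @export
replay_history <- function(g, history) {
  stopifnot(inherits(g, "cn_metagraph"))
  for (h in history) {
    g <- switch(h$op,
      filter = filter_edges(g, do.call(filter_spec, h$spec)),
      pin = pin_edge(g, h$j, h$M, h$k, h$N),
      remove = remove_edge(g, h$j, h$M, h$k, h$N),
      stop(sprintf("unknown history op '%s'", h$op)))
  }
  g
}

.retained_igraph <- function(g, level = c("subnode", "node")) {
  level <- match.arg(level)
  e <- g$edges[g$edges$retained, , drop = FALSE]
  if (level == "subnode") {
    verts <- paste0(g$subnodes$j, ":", g$subnodes$M)
    ig <- igraph::graph_from_data_frame(
      data.frame(from = paste0(e$j, ":", e$M), to = paste0(e$k, ":", e$N)),
      directed = FALSE, vertices = data.frame(name = verts))
  } else {
    pairs <- unique(e[, c("j", "k")])
    ig <- igraph::graph_from_data_frame(
      data.frame(from = as.character(pairs$j), to = as.character(pairs$k)),
      directed = FALSE,
      vertices = data.frame(name = as.character(seq_len(g$L))))
  }
  ig
}

#' Detect cycles among retained dependency edges
#'
#' Cycles in the dependency structure are what make a graphical model
#' hard to train, so they are flagged for the analyst.  At the default
#' `"node"` level the test runs on the position projection, where two
#' positions are adjacent iff *any* retained edge joins their subnodes
#' (parallel subnode edges such as the X-shaped Watson-Crick pattern
#' collapse to a single projected edge and form no cycle).  At the
#' `"subnode"` level it runs on the subnode graph itself.  Every edge
#' lying on at least one cycle gets its `in_cycle` flag set.
#'
#' @param g a `cn_metagraph`.
#' @param level `"node"` (default) or `"subnode"`.
#' @return a list of class `cn_cycles` with `metagraph` (flags
#'   updated), `cycles` (list of vertex-name vectors, one fundamental
#'   cycle per independent cycle), and `level`.
#' @export
detect_cycles <- function(g, level = c("node", "subnode")) {
  level <- match.arg(level)
  ig <- .retained_igraph(g, level)
  keep <- igraph::degree(ig) > 0
  ig <- igraph::induced_subgraph(ig, which(keep))
  in_cyc_names <- character(0)
  cycles <- list()
  if (igraph::ecount(ig) > 0) {
    br <- igraph::bridges(ig)
    cyc_edges <- setdiff(seq_len(igraph::ecount(ig)), as.integer(br))
    ends <- igraph::ends(ig, igraph::E(ig), names = TRUE)
    in_cyc_names <- apply(ends[cyc_edges, , drop = FALSE], 1L, function(x)
      paste(sort(x), collapse = "|"))
    # fundamental cycles from a spanning forest
    forest <- igraph::mst(ig)
    fends <- igraph::ends(forest, igraph::E(forest), names = TRUE)
    forest_keys <- apply(fends, 1L, function(x) paste(sort(x), collapse = "|"))
    all_keys <- apply(ends, 1L, function(x) paste(sort(x), collapse = "|"))
    extra <- which(!(all_keys %in% forest_keys) | duplicated(all_keys))
    for (ei in extra) {
      uv <- ends[ei, ]
      p <- igraph::shortest_paths(forest, from = uv[1L], to = uv[2L],
                                  output = "vpath")$vpath[[1L]]
      if (length(p) > 0) cycles <- c(cycles, list(igraph::as_ids(p)))
    }
  }
  e <- g$edges
  flag <- rep(FALSE, nrow(e))
  if (length(in_cyc_names)) {
    key <- if (level == "node")
      paste(pmin(e$j, e$k), pmax(e$j, e$k), sep = "|")
    else
      mapply(function(a, b) paste(sort(c(a, b)), collapse = "|"),
             paste0(e$j, ":", e$M), paste0(e$k, ":", e$N))
    flag <- e$retained & key %in% in_cyc_names
  }
  g$edges$in_cycle <- flag
  structure(list(metagraph = g, cycles = cycles, level = level),
            class = "cn_cycles")
}

#' Label disjoint dependency subnetworks
#'
#' Connected components of the retained subnode graph get distinct
#' integer labels (the "disjoint subnetworks" an analyst colors and
#' reasons about as coherent groups).  Labels are deterministic:
#' components are numbered by their smallest member position, ties
#' broken by alphabet order of the category at that position.
#'
#' @param g a `cn_metagraph`.
#' @return the `cn_metagraph` with `component_id` set on retained
#'   edges (`NA` elsewhere).
#' @export
label_components <- function(g) {
  stopifnot(inherits(g, "cn_metagraph"))
  e <- g$edges
  g$edges$component_id <- NA_integer_
  ret <- which(e$retained)
  if (!length(ret)) return(g)
  ig <- .retained_igraph(g, "subnode")
  comp <- igraph::components(ig)
  verts <- igraph::V(ig)$name
  touched <- unique(comp$membership[match(
    c(paste0(e$j[ret], ":", e$M[ret]), paste0(e$k[ret], ":", e$N[ret])), verts)])
  # deterministic relabeling by smallest (position, category) member
  keyrank <- vapply(touched, function(cid) {
    members <- verts[comp$membership == cid]
    jj <- as.integer(sub(":.*", "", members))
    mm <- sub(".*:", "", members)
    o <- order(jj, match(mm, g$alphabet$symbols))
    jj[o[1L]] * (length(g$alphabet$symbols) + 1L) +
      match(mm[o[1L]], g$alphabet$symbols)
  }, numeric(1))
  newid <- match(touched, touched[order(keyrank)])
  emem <- comp$membership[match(paste0(e$j[ret], ":", e$M[ret]), verts)]
  g$edges$component_id[ret] <- newid[match(emem, touched)]
  g
}

#' @export
print.cn_metagraph <- function(x, ...) {
  cat(sprintf(
    "<cn_metagraph> L=%d, %d subnodes, %d edges (%d retained, %d pinned, %d removed), %d history step(s)\n",
    x$L, nrow(x$subnodes), nrow(x$edges), sum(x$edges$retained),
    sum(x$edges$pinned), sum(x$edges$removed), length(x$history)))
  invisible(x)
}
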