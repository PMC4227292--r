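#' Build a pairwise CRF scoring model from a refined metagraph
#'
#' Node potentials are the logs of the additively smoothed marginals,
#' `log[(count_j(M) + alpha) / (n + alpha * |A|)]`.  For every
#' position pair carrying at least one retained edge, the edge
#' potential table holds the log-ratio of the smoothed joint to the
#' product of the smoothed marginals,
#' `log[(count_jk(M,N) + alpha) / (n + alpha * |A|^2)] - node_j(M) -
#' node_k(N)`; positive entries mark category pairs that co-occur
#' above expectation, mirroring the residual sign.  Potentials are
#' read directly from the counts — no iterative training — and the
#' model is unnormalized: scores are meaningful comparatively (see
#' [relative_score()]).  Smoothing is mandatory so unseen pairs score
#' finitely.
#'
#' @param g a `cn_metagraph` built from `aln` (checked by digest).
#' @param aln the training `cn_alignment`.
#' @param alpha positive smoothing mass (default 0.5, Jeffreys-style).
#' @return an object of class `cn_crf` with `node_potentials`
#'   (categories x positions), `edge_potentials` (named list
#'   `"j:k"` -> categories x categories matrix), `retained_edges`,
#'   `alpha`, `alphabet`, `L`, and provenance.
#' @examples
#' fam <- generate_stemloop_family(n = 100, seed = 1)
#' g <- filter_edges(build_metagraph(fam$alignment), filter_spec(0.05, 0.001, 3))
#' m <- build_crf(g, fam$alignment)
#' @export
build_crf <- function(g, aln, alpha = 0.5) {
  stopifnot(inherits(g, "cn_metagraph"), inherits(aln, "cn_alignment"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a single positive number")
  if (!identical(g$provenance$digest, .alignment_digest(aln)))
    stop("metagraph was not built from this alignment")
  syms <- aln$alphabet$symbols
  S <- length(syms)
  n <- nrow(aln$matrix)
  marg <- compute_marginals(aln, 0)
  node_pot <- log(marg$counts + alpha) - log(n + alpha * S)
  ret <- g$edges[g$edges$retained, , drop = FALSE]
  pairs <- unique(ret[, c("j", "k")])
  edge_pot <- list()
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$j, pairs$k), , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      j <- pairs$j[i]; k <- pairs$k[i]
      joint <- compute_joint(aln, j, k)
      lp <- log(joint$counts + alpha) - log(n + alpha * S^2)
      pot <- lp - outer(node_pot[, j], node_pot[, k], "+")
      edge_pot[[sprintf("%d:%d", j, k)]] <- pot
    }
  }
  structure(list(node_potentials = node_pot, edge_potentials = edge_pot,
                 retained_edges = ret[, c("j", "k", "M", "N")],
                 alpha = alpha, alphabet = aln$alphabet, L = ncol(aln$matrix),
                 provenance = list(metagraph_digest = g$provenance$digest,
                                   n = n)),
            class = "cn_crf")
}

.as_symbol_vector <- function(m, seq) {
  if (length(seq) == 1L && is.character(seq)) seq <- strsplit(seq, "")[[1L]]
  seq <- toupper(as.character(seq))
  if (length(seq) != m$L)
    stop(sprintf("sequence length %d does not match model length %d",
                 length(seq), m$L))
  bad <- !(seq %in% m$alphabet$symbols)
  if (any(bad))
    stop(sprintf("symbol '%s' at position %d is not in the model alphabet",
                 seq[which(bad)[1L]], which(bad)[1L]))
  seq
}

#' Score one sequence under a CRF model
#'
#' The log score integrates across the nodes and edges the sequence
#' selects: the sum of node potentials at every position plus the sum
#' of edge potentials over the retained position pairs, evaluated at
#' the observed category pair.
#'
#' @param m a `cn_crf`.
#' @param seq a character string or character vector of length `L`.
#' @param id optional sequence identifier for the report.
#' @return a one-row `data.frame` with `id`, `log_score`, `node_term`,
#'   `edge_term` (`log_score = node_term + edge_term`).
#' @export
score_sequence <- function(m, seq, id = "seq") {
  stopifnot(inherits(m, "cn_crf"))
  seq <- .as_symbol_vector(m, seq)
  node_term <- sum(m$node_potentials[cbind(match(seq, m$alphabet$symbols),
                                           seq_len(m$L))])
  edge_term <- 0
  for (key in names(m$edge_potentials)) {
    jk <- as.integer(strsplit(key, ":")[[1L]])
    edge_term <- edge_term + m$edge_potentials[[key]][seq[jk[1L]], seq[jk[2L]]]
  }
  data.frame(id = id, log_score = node_term + edge_term,
             node_term = node_term, edge_term = edge_term,
             stringsAsFactors = FALSE)
}

#' Fold score of a sequence relative to a reference
#'
#' Returns `exp(log_score(seq) - log_score(reference))`; the reference
#' scores exactly 1 by construction.  This is the convention used for
#' reporting mutant scores against a wild-type sequence.
#'
#' @param m a `cn_crf`.
#' @param seq,reference sequences valid for the model.
#' @return a dimensionless fold ratio.
#' @export
relative_score <- function(m, seq, reference) {
  exp(score_sequence(m, seq)$log_score -
        score_sequence(m, reference)$log_score)
}

#' Score every row of an alignment against a reference row
#'
#' @param m a `cn_crf`.
#' @param aln a `cn_alignment` of candidates (rows of model length).
#' @param reference id of the reference row within `aln`.
#' @return a `data.frame` in input order with `id`, `log_score`,
#'   `node_term`, `edge_term`, and `relative` (fold vs the reference).
#' @export
score_alignment <- function(m, aln, reference) {
  stopifnot(inherits(m, "cn_crf"), inherits(aln, "cn_alignment"))
  ri <- match(reference, aln$ids)
  if (is.na(ri)) stop(sprintf("reference id '%s' not found", reference))
  rows <- lapply(seq_len(nrow(aln$matrix)), function(i)
    score_sequence(m, aln$matrix[i, ], id = aln$ids[i]))
  out <- do.call(rbind, rows)
  out$relative <- exp(out$log_score - out$log_score[ri])
  out
}

#' @export
print.cn_crf <- function(x, ...) {
  cat(sprintf("<cn_crf> L=%d, %d retained edge(s) over %d position pair(s), alpha=%g\n",
              x$L, nrow(x$retained_edges), length(x$edge_potentials), x$alpha))
  invisible(x)
}
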