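# Small in-code fixtures and independent oracles shared across tests.

make_aln <- function(seqs, alphabet = nt_alphabet(), ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%d", seq_along(seqs))
  new_alignment(ids, do.call(rbind, strsplit(seqs, "")), alphabet)
}

# forced-dependency toy: A1A2 or T1T2, nothing else
aa_tt_family <- function() make_aln(c(rep("AA", 4), rep("TT", 4)))

# perfectly independent 2-column toy
indep_family <- function() make_aln(c("AA", "AT", "TA", "TT"))

WC <- c(A = "T", C = "G", G = "C", T = "A")

# independent oracle: exhaustive fixed-margin enumeration with exact
# binomial-coefficient point probabilities
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(1)
  r1 <- a + b
  c1 <- a + c
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  pp <- function(x) choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  probs <- vapply(xs, pp, numeric(1))
  min(1, sum(probs[probs <= pp(a) * (1 + 1e-9)]))
}

# independent oracle: union-find connected components over an edge list
oracle_components <- function(edges) {
  verts <- unique(c(paste0(edges$j, ":", edges$M), paste0(edges$k, ":", edges$N)))
  parent <- stats::setNames(seq_along(verts), verts)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(edges))) {
    a <- find(paste0(edges$j[i], ":", edges$M[i]))
    b <- find(paste0(edges$k[i], ":", edges$N[i]))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(verts, find, numeric(1))
  length(unique(roots))
}

# consistent base sequence for a stem-loop family: per-column modal
# symbol, with paired columns forced to Watson-Crick complementarity
stem_base_sequence <- function(fam) {
  base <- apply(fam$alignment$matrix, 2, function(x)
    names(sort(table(x), decreasing = TRUE))[1])
  for (pr in fam$truth$pairs) base[pr[2]] <- WC[base[pr[1]]]
  base
}

# all Hamming-2 mutants of `base` within one planted pair, split into
# complementarity-consistent and -violating sets
stem_pair_mutants <- function(fam, base) {
  consistent <- list()
  violating <- list()
  nt <- c("A", "C", "G", "T")
  for (pr in fam$truth$pairs) {
    j <- pr[1]; k <- pr[2]
    for (x in setdiff(nt, base[j])) {
      for (y in setdiff(nt, base[k])) {
        mut <- base
        mut[j] <- x
        mut[k] <- y
        if (y == WC[x]) consistent <- c(consistent, list(mut))
        else violating <- c(violating, list(mut))
      }
    }
  }
  list(consistent = consistent, violating = violating)
}

log_scores <- function(model, seqs) {
  vapply(seqs, function(s) score_sequence(model, s)$log_score, numeric(1))
}

# a metagraph assembled by hand (for echo/cycle tests on exact edge sets)
manual_metagraph <- function(edges, L, alphabet = nt_alphabet()) {
  ep <- unique(rbind(data.frame(j = edges$j, M = edges$M),
                     data.frame(j = edges$k, M = edges$N)))
  ep <- ep[order(ep$j, ep$M), ]
  e <- edges
  defaults <- list(count = 1L, expected = 0, residual = 0.1, p = 1e-6,
                   pinned = FALSE, removed = FALSE, retained = TRUE,
                   component_id = NA_integer_, in_cycle = FALSE)
  for (nm in names(defaults))
    if (is.null(e[[nm]])) e[[nm]] <- defaults[[nm]]
  structure(list(L = L, alphabet = alphabet,
                 subnodes = data.frame(j = ep$j, M = ep$M, weight = 0.5,
                                       count = 1L),
                 edges = e, history = list(),
                 provenance = list(digest = "manual", n = 1L)),
            class = "cn_metagraph")
}

# fraction of carrier rows whose realignment shift matches the planted
# offset, up to the arbitrary global translation of the realigned frame
echo_recovery <- function(total_shift, truth) {
  carr <- truth$carrier
  d <- truth$offsets[carr] - total_shift[carr]
  max(table(d)) / sum(carr)
}
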