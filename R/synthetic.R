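# Seed hygiene: generators are deterministic in `seed` and restore the
# caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.base_symbols <- c("A", "C", "G", "T")
.wc_complement <- c(A = "T", C = "G", G = "C", T = "A")

.background_matrix <- function(n, L, probs) {
  matrix(sample(names(probs), n * L, replace = TRUE, prob = probs), n, L)
}

.apply_noise <- function(m, noise, symbols) {
  if (noise <= 0) return(m)
  hit <- matrix(stats::runif(length(m)) < noise, nrow(m))
  m[hit] <- sample(symbols, sum(hit), replace = TRUE)
  m
}

#' Generate an independent-column null family
#'
#' Every column is drawn independently from its stated category
#' distribution — the null model against which dependency detection
#' is calibrated (no true edges exist; every flagged pair is a false
#' positive).
#'
#' @param n number of sequences.
#' @param L number of positions.
#' @param probs named numeric vector of category probabilities
#'   (default uniform over A, C, G, T), or a list of length `L` of
#'   such vectors for per-column distributions.  Each must sum to 1.
#' @param seed integer seed; identical inputs give byte-identical
#'   output.
#' @param alphabet alphabet for the resulting alignment.
#' @return a list with `alignment` (a `cn_alignment`) and `truth`
#'   (the per-column distributions).
#' @examples
#' fam <- generate_independent_family(n = 50, L = 8, seed = 1)
#' @export
generate_independent_family <- function(n = 200, L = 20, probs = NULL,
                                        seed = 1, alphabet = nt_alphabet()) {
  if (is.null(probs)) probs <- stats::setNames(rep(0.25, 4), .base_symbols)
  plist <- if (is.list(probs)) probs else rep(list(probs), L)
  if (length(plist) != L) stop("probs list must have one entry per column")
  for (p in plist)
    if (abs(sum(p) - 1) > 1e-8) stop("column distribution must sum to 1")
  m <- .with_seed(seed, {
    cols <- lapply(plist, function(p)
      sample(names(p), n, replace = TRUE, prob = p))
    do.call(cbind, cols)
  })
  aln <- new_alignment(sprintf("seq%03d", seq_len(n)), m, alphabet)
  list(alignment = aln,
       truth = list(structure = "independent", probs = plist, seed = seed))
}

#' Generate a Watson-Crick stem-loop family
#'
#' For each planted position pair `(j, k)` the symbol at `j` is drawn
#' from `paired_probs` and the symbol at `k` is set to its
#' Watson-Crick complement; every symbol is then independently
#' corrupted with probability `noise` (replaced by a uniform draw
#' over A, C, G, T).  Unpaired columns are independent background.
#' The defaults emulate a four-base-pair stem read across a loop.
#'
#' @param n number of sequences.
#' @param L number of positions.
#' @param pairs list of disjoint `c(j, k)` position pairs.
#' @param noise per-symbol corruption probability in `[0, 1)`.
#' @param paired_probs distribution of the 5' symbol of each pair
#'   (default uniform).
#' @param seed integer seed.
#' @param alphabet alphabet for the alignment.
#' @return a list with `alignment` and `truth`; `truth$edges` lists
#'   the planted complementary subnode edges (4 per pair), and
#'   `truth$pairs` the planted position pairs.
#' @export
generate_stemloop_family <- function(n = 500, L = 30,
                                     pairs = list(c(5, 28), c(6, 27),
                                                  c(7, 26), c(8, 25)),
                                     noise = 0.05, paired_probs = NULL,
                                     seed = 1, alphabet = nt_alphabet()) {
  if (noise < 0 || noise >= 1) stop("noise must be in [0, 1)")
  flat <- unlist(pairs)
  if (anyDuplicated(flat)) stop("planted pairs must be disjoint")
  if (any(flat < 1 | flat > L)) stop("planted pair positions outside 1..L")
  if (is.null(paired_probs))
    paired_probs <- stats::setNames(rep(0.25, 4), .base_symbols)
  m <- .with_seed(seed, {
    bg <- stats::setNames(rep(0.25, 4), .base_symbols)
    mm <- .background_matrix(n, L, bg)
    for (pr in pairs) {
      five <- sample(names(paired_probs), n, replace = TRUE,
                     prob = paired_probs)
      mm[, pr[1L]] <- five
      mm[, pr[2L]] <- .wc_complement[five]
    }
    .apply_noise(mm, noise, .base_symbols)
  })
  aln <- new_alignment(sprintf("seq%03d", seq_len(n)), m, alphabet)
  edges <- do.call(rbind, lapply(pairs, function(pr)
    data.frame(j = pr[1L], k = pr[2L], M = .base_symbols,
               N = unname(.wc_complement[.base_symbols]),
               stringsAsFactors = FALSE)))
  rownames(edges) <- NULL
  list(alignment = aln,
       truth = list(structure = "stemloop", pairs = pairs, edges = edges,
                    noise = noise, seed = seed))
}

#' Generate a shifted-motif "echo" family
#'
#' Emulates a family in which a conserved motif — carrying a forced
#' category pair at a fixed lag — occurs in several subsets of the
#' sequences, each subset shifted slightly from the next.  In the
#' original column frame the motif leaves no overwhelming marginal
#' pattern, but the pairwise dependency network shows the same
#' category-pair dependency repeated at consecutive columns: the echo
#' fingerprint of misalignment.
#'
#' A fraction `occupancy` of rows carry the motif (written over
#' background at `anchor + offset`, the offset drawn from `shifts`);
#' the rest are pure background.  Noise corrupts every symbol
#' independently.
#'
#' @param n number of sequences.
#' @param L number of positions.
#' @param motif character vector of forced motif symbols (default
#'   `c("T", "C", "A")`: a T...A dependency at lag 2 with a conserved
#'   interior base).
#' @param anchor 1-based column of the motif's first symbol at offset
#'   0.
#' @param shifts integer vector of candidate offsets (default `0:3`).
#' @param shift_probs probabilities over `shifts` (default uniform).
#' @param occupancy fraction of rows carrying the motif.
#' @param noise per-symbol corruption probability.
#' @param seed integer seed.
#' @param alphabet alphabet for the alignment.
#' @return a list with `alignment` and `truth`; `truth$offsets` holds
#'   each row's true offset (`NA` for non-carriers), `truth$carrier`
#'   the carrier flags, plus the motif geometry (`anchor`, `lag`).
#' @export
generate_echo_family <- function(n = 400, L = 30, motif = c("T", "C", "A"),
                                 anchor = 14, shifts = 0:3,
                                 shift_probs = NULL, occupancy = 0.4,
                                 noise = 0.02, seed = 1,
                                 alphabet = nt_alphabet()) {
  motif <- toupper(motif)
  if (anchor + max(shifts) + length(motif) - 1L > L)
    stop("motif plus maximum shift exceeds the alignment length")
  if (anchor + min(shifts) < 1L) stop("motif shifted before position 1")
  if (is.null(shift_probs)) shift_probs <- rep(1 / length(shifts), length(shifts))
  if (abs(sum(shift_probs) - 1) > 1e-8) stop("shift_probs must sum to 1")
  res <- .with_seed(seed, {
    bg <- stats::setNames(rep(0.25, 4), .base_symbols)
    mm <- .background_matrix(n, L, bg)
    carrier <- stats::runif(n) < occupancy
    offs <- ifelse(carrier,
                   sample(shifts, n, replace = TRUE, prob = shift_probs),
                   NA_integer_)
    for (i in which(carrier)) {
      at <- anchor + offs[i]
      mm[i, at:(at + length(motif) - 1L)] <- motif
    }
    list(m = .apply_noise(mm, noise, .base_symbols),
         carrier = carrier, offs = offs)
  })
  aln <- new_alignment(sprintf("seq%03d", seq_len(n)), res$m, alphabet)
  list(alignment = aln,
       truth = list(structure = "echo", motif = motif, anchor = anchor,
                    lag = length(motif) - 1L, shifts = shifts,
                    occupancy = occupancy, noise = noise,
                    carrier = res$carrier, offsets = res$offs, seed = seed))
}

#' Packaged nine-column toy family
#'
#' A small fixed nucleotide family built deterministically in code:
#' two Watson-Crick stem pairs at positions (6, 9) and (7, 8), and a
#' correlated triple across columns 2-4 (three triplet variants whose
#' joint usage carries information invisible to per-column summaries).
#' Columns 1 and 5 are background.  Used throughout the documentation
#' and tests as the desk-scale example: 9 columns means exactly 36
#' position pairs.
#'
#' @return a list with `alignment` (60 sequences x 9 positions) and
#'   `truth` (stem pairs, planted edges, triplet variants).
#' @export
toy_nine_column_family <- function() {
  n <- 60L
  variants <- c("GCT", "ATC", "CGA")
  res <- .with_seed(20090, {
    bg <- stats::setNames(rep(0.25, 4), .base_symbols)
    mm <- .background_matrix(n, 9L, bg)
    pick <- sample(variants, n, replace = TRUE, prob = c(0.4, 0.35, 0.25))
    mm[, 2:4] <- do.call(rbind, strsplit(pick, ""))
    for (pr in list(c(6L, 9L), c(7L, 8L))) {
      five <- sample(.base_symbols, n, replace = TRUE)
      mm[, pr[1L]] <- five
      mm[, pr[2L]] <- .wc_complement[five]
    }
    list(m = .apply_noise(mm, 0.02, .base_symbols), pick = pick)
  })
  aln <- new_alignment(sprintf("toy%02d", seq_len(n)), res$m, nt_alphabet())
  edges <- do.call(rbind, lapply(list(c(6L, 9L), c(7L, 8L)), function(pr)
    data.frame(j = pr[1L], k = pr[2L], M = .base_symbols,
               N = unname(.wc_complement[.base_symbols]),
               stringsAsFactors = FALSE)))
  list(alignment = aln,
       truth = list(structure = "toy9", pairs = list(c(6L, 9L), c(7L, 8L)),
                    edges = edges, triple_columns = 2:4,
                    triple_variants = res$pick))
}
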