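#' Detect shifted "echo" dependency runs
#'
#' A misaligned family leaves a fingerprint in the dependency
#' network: the same category pair at the same lag, significant at a
#' run of consecutive start columns (one copy per shifted subset of
#' the sequences).  Retained edges are grouped by `(M, N, lag = k - j)`
#' and maximal runs of consecutive start positions of length at least
#' `min_run` are returned, sorted by run length (descending), then lag
#' (descending: the longer-range fingerprint spans more consensus
#' columns), then start position.
#'
#' @param g a filtered `cn_metagraph`.
#' @param min_run minimum number of consecutive shifted copies
#'   (default 3; a run of 2 is too easily produced by chance).
#' @param include_gap if `FALSE` (default), edges whose categories
#'   include the gap character are ignored: runs of gap-gap
#'   co-occurrence are the trivial by-product of rigid translation
#'   padding, not a content dependency.
#' @return a list of `cn_echo_pattern` objects with fields `M`, `N`,
#'   `lag`, `start_j`, `run_length`, and `member_edges`.
#' @export
detect_echoes <- function(g, min_run = 3, include_gap = FALSE) {
  stopifnot(inherits(g, "cn_metagraph"))
  if (min_run < 2) stop("min_run must be at least 2")
  e <- g$edges[g$edges$retained, , drop = FALSE]
  if (!include_gap && !is.null(g$alphabet) && !is.na(g$alphabet$gap))
    e <- e[e$M != g$alphabet$gap & e$N != g$alphabet$gap, , drop = FALSE]
  if (!nrow(e)) return(list())
  e$lag <- e$k - e$j
  pats <- list()
  for (grp in split(e, list(e$M, e$N, e$lag), drop = TRUE)) {
    js <- sort(unique(grp$j))
    brk <- c(0L, which(diff(js) != 1L), length(js))
    for (b in seq_len(length(brk) - 1L)) {
      run <- js[(brk[b] + 1L):brk[b + 1L]]
      if (length(run) < min_run) next
      memb <- grp[grp$j %in% run, , drop = FALSE]
      memb <- memb[order(memb$j), , drop = FALSE]
      rownames(memb) <- NULL
      pats <- c(pats, list(structure(
        list(M = grp$M[1L], N = grp$N[1L], lag = grp$lag[1L],
             start_j = run[1L], run_length = length(run),
             member_edges = memb),
        class = "cn_echo_pattern")))
    }
  }
  ord <- order(-vapply(pats, `[[`, numeric(1), "run_length"),
               -vapply(pats, `[[`, numeric(1), "lag"),
               vapply(pats, `[[`, numeric(1), "start_j"))
  pats[ord]
}

#' @export
print.cn_echo_pattern <- function(x, ...) {
  cat(sprintf("<cn_echo_pattern> (%s,%s) lag %d: run of %d starting at position %d\n",
              x$M, x$N, x$lag, x$run_length, x$start_j))
  invisible(x)
}

#' Assign a per-sequence offset against an echo pattern
#'
#' Realignment aligns the dependencies, not the symbols.  The
#' candidate offsets are `s` in `-1 .. run_length - 1` (the run's
#' member edges sit at `start_j .. start_j + run_length - 1`, so a
#' participating subset lies at a non-negative offset from the
#' anchor; one negative slot guards against a leading run member
#' lost to the filter; all offsets are restricted to the alignment
#' bounds and satisfy `|s| <= run_length - 1`).  A sequence matching
#' the pattern's category pair (`M` at `start_j + s`, `N` at
#' `start_j + lag + s`) at exactly one candidate offset is anchored
#' there.  The anchored sequences then define a motif-frame
#' consensus: within a window around the pair, columns whose modal
#' symbol (across anchored rows, in their offset frame) reaches
#' frequency 0.6 are taken as conserved motif columns.  A sequence
#' with full pair matches at *several* offsets is placed at the
#' full-match offset maximizing agreement with that consensus, ties
#' broken toward smallest `|s|`, then toward negative `s`.  Sequences
#' without a full pair match at any offset do not participate in the
#' echo and keep offset 0 (shifting them would inflate the pattern's
#' marginals without adding joint mass, diluting the dependency being
#' aligned).  Finally the participating offsets are re-centered on
#' their mode, so the densest subset stays in place and the smaller
#' subsets translate onto it.  `support` records how many of the two
#' pattern cells match at the chosen offset.
#'
#' @param aln the `cn_alignment` the pattern's metagraph was built
#'   from.
#' @param pattern a `cn_echo_pattern`.
#' @return a `data.frame` of class `cn_shifts` with columns `id`,
#'   `shift`, `support`; the pattern is attached as an attribute.
#' @export
assign_shifts <- function(aln, pattern) {
  stopifnot(inherits(aln, "cn_alignment"), inherits(pattern, "cn_echo_pattern"))
  L <- ncol(aln$matrix)
  n <- nrow(aln$matrix)
  st <- pattern$start_j
  lag <- pattern$lag
  cand <- (-1L):(pattern$run_length - 1L)
  cand <- cand[st + cand >= 1L & st + lag + cand <= L]
  if (!length(cand)) stop("pattern does not fit inside the alignment")
  mA <- vapply(cand, function(s) aln$matrix[, st + s] == pattern$M, logical(n))
  mB <- vapply(cand, function(s) aln$matrix[, st + lag + s] == pattern$N,
               logical(n))
  mA <- matrix(mA, nrow = n)
  mB <- matrix(mB, nrow = n)
  cells <- mA + mB                     # 0..2 pattern cells matched
  full <- cells == 2L
  nfull <- rowSums(full)
  shift <- integer(n)
  support <- integer(n)
  anchored <- which(nfull == 1L)
  shift[anchored] <- cand[apply(full[anchored, , drop = FALSE], 1L,
                                which.max)]
  support[anchored] <- 2L
  # adaptive motif-frame consensus: conserved columns (modal frequency
  # >= 0.6 across the anchored subset) in a window around the pair
  rel <- (-3L):(lag + 3L)
  cons <- rep(NA_character_, length(rel))
  if (length(anchored)) {
    for (ti in seq_along(rel)) {
      cols <- st + shift[anchored] + rel[ti]
      ok <- cols >= 1L & cols <= L
      if (!any(ok)) next
      sym <- aln$matrix[cbind(anchored[ok], cols[ok])]
      tab <- sort(table(sym), decreasing = TRUE)
      if (tab[1L] / sum(tab) >= 0.6) cons[ti] <- names(tab)[1L]
    }
  }
  cons[rel == 0L] <- pattern$M
  cons[rel == lag] <- pattern$N
  keep_t <- which(!is.na(cons))
  # only sequences with a full pair match participate in the echo;
  # ambiguous ones (several full matches) are placed by consensus
  # agreement.  Shifting partial matchers would inflate the pattern's
  # marginals without joint mass and dilute the very dependency being
  # aligned.
  rest <- which(nfull >= 2L)
  tie_rank <- order(abs(cand), cand)   # smallest |s| first, then negative
  for (i in rest) {
    sc <- vapply(seq_along(cand), function(ci) {
      if (!full[i, ci]) return(-Inf)
      cols <- st + cand[ci] + rel[keep_t]
      ok <- cols >= 1L & cols <= L
      sum(aln$matrix[i, cols[ok]] == cons[keep_t][ok])
    }, numeric(1))
    best <- tie_rank[which.max(sc[tie_rank])]
    shift[i] <- cand[best]
    support[i] <- cells[i, best]
  }
  idle <- which(nfull == 0L)
  zi <- which(cand == 0L)
  if (length(zi)) support[idle] <- cells[idle, zi]
  # re-center on the modal participant offset: the densest copy stays
  # put and the other subsets move onto it, so iteration repairs
  # stragglers instead of translating the whole family
  part <- support == 2L
  if (any(part)) {
    tab <- table(shift[part])
    modes <- as.integer(names(tab)[tab == max(tab)])
    m <- modes[order(abs(modes), modes)][1L]
    shift[part] <- shift[part] - m
  }
  out <- data.frame(id = aln$ids, shift = shift, support = support,
                    stringsAsFactors = FALSE)
  attr(out, "pattern") <- pattern
  class(out) <- c("cn_shifts", "data.frame")
  out
}

#' Translate sequences by their assigned offsets
#'
#' Each row `i` is rigidly translated by `-shift[i]`, so that pattern
#' copies land on the pattern anchor; vacated cells are filled with
#' the alphabet's gap character.  `"trim"` (default) keeps the
#' original length `L`, dropping overhanging symbols; `"extend"`
#' widens the alignment to hold every translated symbol.  Row order
#' and ids are preserved.
#'
#' @param aln a `cn_alignment`.
#' @param shifts a `cn_shifts` table (or integer vector of length
#'   `n`).
#' @param pad_policy `"trim"` or `"extend"`.
#' @return the translated `cn_alignment`.
#' @export
apply_shifts <- function(aln, shifts, pad_policy = c("trim", "extend")) {
  stopifnot(inherits(aln, "cn_alignment"))
  pad_policy <- match.arg(pad_policy)
  s <- if (is.data.frame(shifts)) shifts$shift else as.integer(shifts)
  n <- nrow(aln$matrix)
  L <- ncol(aln$matrix)
  if (length(s) != n) stop("one shift per sequence is required")
  gap <- aln$alphabet$gap
  if (is.na(gap) || !(gap %in% aln$alphabet$symbols))
    stop("pad character must be a category of the alphabet")
  if (pad_policy == "trim") {
    cols <- seq_len(L)
    out <- matrix(gap, n, L)
    for (i in seq_len(n)) {
      src <- cols + s[i]
      ok <- src >= 1L & src <= L
      out[i, cols[ok]] <- aln$matrix[i, src[ok]]
    }
  } else {
    lo <- 1L - max(0L, max(s))
    hi <- L - min(0L, min(s))
    width <- hi - lo + 1L
    out <- matrix(gap, n, width)
    for (i in seq_len(n)) {
      out[i, (1L - s[i]) - lo + 1L + 0:(L - 1L)] <- aln$matrix[i, ]
    }
  }
  new_alignment(aln$ids, out, aln$alphabet)
}

#' Iteratively realign a family by its echo patterns
#'
#' Repeats build-metagraph / filter / detect-echo / assign / apply
#' until no echo of run length `min_run` survives the filter, an
#' oscillation is detected (a shift assignment exactly reversing the
#' previous one), or `max_iter` is reached.  The strongest pattern is
#' resolved at each iteration.
#'
#' @param aln a `cn_alignment`.
#' @param f a [filter_spec()] applied before echo detection.
#' @param min_run minimum echo run length (see [detect_echoes()]).
#' @param max_iter maximum number of realignment iterations.
#' @param pad_policy passed to [apply_shifts()].
#' @return a list with `alignment` (realigned), `metagraph` (built
#'   and filtered from the final alignment), `log` (per-iteration
#'   pattern and shift histogram), `total_shift` (per-sequence sum of
#'   applied shifts), `iterations`, and `converged`.
#' @export
iterative_realign <- function(aln, f = filter_spec(0.02, 0.001, 0),
                              min_run = 3, max_iter = 10,
                              pad_policy = "trim") {
  stopifnot(inherits(aln, "cn_alignment"))
  if (max_iter < 1) stop("max_iter must be at least 1")
  log <- list()
  total <- stats::setNames(integer(nrow(aln$matrix)), aln$ids)
  prev_shift <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- filter_edges(build_metagraph(aln), f)
    pats <- detect_echoes(g, min_run)
    if (!length(pats)) { converged <- TRUE; break }
    top <- pats[[1L]]
    sh <- assign_shifts(aln, top)
    hist <- table(factor(sh$shift,
                         levels = sort(unique(c(0L, sh$shift)))))
    entry <- list(iteration = it,
                  pattern = sprintf("(%s,%s) lag %d run %d @ %d", top$M,
                                    top$N, top$lag, top$run_length,
                                    top$start_j),
                  shifts = stats::setNames(as.integer(hist), names(hist)),
                  oscillation = FALSE)
    if (all(sh$shift == 0L)) {
      log <- c(log, list(entry))
      converged <- TRUE
      break
    }
    if (!is.null(prev_shift) && all(sh$shift == -prev_shift)) {
      entry$oscillation <- TRUE
      log <- c(log, list(entry))
      break
    }
    log <- c(log, list(entry))
    aln <- apply_shifts(aln, sh, pad_policy)
    total <- total + sh$shift
    prev_shift <- sh$shift
  }
  g <- filter_edges(build_metagraph(aln), f)
  list(alignment = aln, metagraph = g, log = log, total_shift = total,
       iterations = length(log), converged = converged)
}
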