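#' Per-position marginal category profile (PSSM)
#'
#' Counts each alphabet category at each position and converts to
#' relative frequencies, optionally with additive smoothing.  With
#' `pseudocount = 0` the frequencies are the exact empirical
#' proportions; this is the setting used for residuals and exact
#' tests, so that the conservation identities hold exactly.
#' Smoothing is reserved for CRF potential estimation.
#'
#' @param aln a `cn_alignment`.
#' @param pseudocount non-negative smoothing mass added to every cell.
#' @return an object of class `cn_marginals` with `counts` and `freq`
#'   (categories x positions matrices), `n`, and `pseudocount`.
#'   Frequencies at each position sum to 1.
#' @examples
#' aln <- toy_nine_column_family()$alignment
#' m <- compute_marginals(aln)
#' colSums(m$freq)  # all 1
#' @export
compute_marginals <- function(aln, pseudocount = 0) {
  stopifnot(inherits(aln, "cn_alignment"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  syms <- aln$alphabet$symbols
  S <- length(syms)
  counts <- vapply(seq_len(ncol(aln$matrix)), function(j)
    vapply(syms, function(s) sum(aln$matrix[, j] == s), integer(1)),
    integer(S))
  counts <- matrix(counts, nrow = S, dimnames = list(syms, NULL))
  tot <- colSums(counts)  # < n only under a gap-tolerant non-category policy
  freq <- sweep(counts + pseudocount, 2L, tot + pseudocount * S, "/")
  structure(list(counts = counts, freq = freq, n = nrow(aln$matrix),
                 column_totals = tot, pseudocount = pseudocount,
                 alphabet = aln$alphabet),
            class = "cn_marginals")
}

#' Joint co-occurrence table for one position pair
#'
#' Counts, over sequences, every ordered category pair `(M at j, N at
#' k)`.  Pairs are stored canonically with `j < k`; query the
#' transpose for the symmetric view.
#'
#' @param aln a `cn_alignment`.
#' @param j,k 1-based positions with `j < k`.
#' @return an object of class `cn_joint` with fields `j`, `k`,
#'   `counts` (categories x categories), and `n`.  All cells sum to
#'   the number of sequences.
#' @export
compute_joint <- function(aln, j, k) {
  stopifnot(inherits(aln, "cn_alignment"))
  L <- ncol(aln$matrix)
  if (!(j >= 1 && k <= L && j < k))
    stop(sprintf("positions must satisfy 1 <= j < k <= %d (got j=%s, k=%s)",
                 L, j, k))
  syms <- aln$alphabet$symbols
  cj <- factor(aln$matrix[, j], levels = syms)
  ck <- factor(aln$matrix[, k], levels = syms)
  counts <- table(cj, ck, dnn = NULL)
  counts <- matrix(as.integer(counts), nrow = length(syms),
                   dimnames = list(syms, syms))
  structure(list(j = as.integer(j), k = as.integer(k), counts = counts,
                 n = nrow(aln$matrix)),
            class = "cn_joint")
}

#' Residuals of a joint table against the independence expectation
#'
#' The residual for cell `(M, N)` is the observed joint probability
#' minus the product of the marginal probabilities,
#' `r = counts[M,N]/n - freq_j[M] * freq_k[N]`.  Positive residuals
#' mark category pairs that co-occur more often than independence
#' predicts (drawn solid), negative ones less often (drawn dashed).
#' At `pseudocount = 0` every row, column, and the full matrix of
#' residuals sums to zero.
#'
#' @param joint a `cn_joint`.
#' @param marg a `cn_marginals` from the same alignment.
#' @param units `"probability"` (default) or `"count"` (multiplies by
#'   `n`).
#' @param type `"simple"` (default: plain difference) or `"pearson"`
#'   (difference divided by the square root of the expectation, in
#'   matching units).
#' @return an object of class `cn_residuals` with `j`, `k`, `r`, and
#'   `expected`.
#' @export
compute_residuals <- function(joint, marg, units = c("probability", "count"),
                              type = c("simple", "pearson")) {
  stopifnot(inherits(joint, "cn_joint"), inherits(marg, "cn_marginals"))
  units <- match.arg(units)
  type <- match.arg(type)
  if (joint$n != marg$n)
    stop("joint table and marginal profile disagree on the number of sequences")
  fj <- marg$freq[, joint$j]
  fk <- marg$freq[, joint$k]
  expected <- outer(fj, fk)
  r <- joint$counts / joint$n - expected
  if (type == "pearson") r <- r / sqrt(pmax(expected, .Machine$double.eps))
  if (units == "count") {
    r <- r * joint$n
    expected <- expected * joint$n
  }
  structure(list(j = joint$j, k = joint$k, r = r, expected = expected,
                 units = units, type = type),
            class = "cn_residuals")
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Point-probability convention: the p-value is the sum of
#' hypergeometric probabilities of all tables sharing the observed
#' margins whose point probability does not exceed that of the
#' observed table (relative tolerance 1e-9 to break floating-point
#' ties conservatively).  The all-zero table is defined to have
#' p = 1.  Vectorized over table entries.
#'
#' @param a,b,c,d non-negative integer cell counts of the 2x2 table
#'   `rbind(c(a, b), c(c, d))`.
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' fisher_pvalue(4, 0, 0, 4)  # 2/70
#' fisher_pvalue(1, 1, 1, 1)  # 1
#' @export
fisher_pvalue <- function(a, b, c, d) {
  n <- length(a)
  if (length(b) != n || length(c) != n || length(d) != n)
    stop("a, b, c, d must have equal length")
  if (any(a < 0 | b < 0 | c < 0 | d < 0) || any((a + b + c + d) %% 1 != 0))
    stop("cells must be non-negative integers")
  vapply(seq_len(n), function(i) .fisher_p1(a[i], b[i], c[i], d[i]), numeric(1))
}

.fisher_p1 <- function(a, b, c, d) {
  tot <- a + b + c + d
  if (tot == 0) return(1)
  m1 <- a + b
  m2 <- c + d
  kk <- a + c
  lo <- max(0, kk - m2)
  hi <- min(kk, m1)
  pr <- stats::dhyper(lo:hi, m1, m2, kk)
  po <- stats::dhyper(a, m1, m2, kk)
  min(1, sum(pr[pr <= po * (1 + 1e-9)]))
}

#' Exact test of association for one subnode pair
#'
#' Collapses a joint table to the 2x2 `(M at j?) x (N at k?)` table
#' `a = counts[M,N]`, `b = row_M - a`, `c = col_N - a`,
#' `d = n - a - b - c`, and applies [fisher_pvalue()].
#'
#' @param joint a `cn_joint`.
#' @param M,N categories present in the alphabet.
#' @return a list of class `cn_signif` with `j`, `k`, `M`, `N`,
#'   `two_by_two` (named a, b, c, d), and `p_value`.
#' @export
subnode_pair_test <- function(joint, M, N) {
  stopifnot(inherits(joint, "cn_joint"))
  syms <- rownames(joint$counts)
  if (!(M %in% syms)) stop(sprintf("category '%s' is not in the alphabet", M))
  if (!(N %in% syms)) stop(sprintf("category '%s' is not in the alphabet", N))
  a <- joint$counts[M, N]
  b <- sum(joint$counts[M, ]) - a
  c <- sum(joint$counts[, N]) - a
  d <- joint$n - a - b - c
  structure(list(j = joint$j, k = joint$k, M = M, N = N,
                 two_by_two = c(a = a, b = b, c = c, d = d),
                 p_value = .fisher_p1(a, b, c, d)),
            class = "cn_signif")
}

#' Number of unordered position pairs
#'
#' `L * (L - 1) / 2`: the number of pairwise contingency tables a
#' family of `L` positions requires (36 for a 9-column family, 44850
#' for 300 positions).
#'
#' @param L positive integer number of positions.
#' @return integer pair count.
#' @export
count_position_pairs <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || L < 1 || L %% 1 != 0)
    stop("L must be a positive integer")
  as.integer(L * (L - 1) / 2)
}

#' Scan every position pair for dependent category pairs
#'
#' Visits all `count_position_pairs(L)` position pairs in canonical
#' order (j ascending, then k) and, for every category pair whose two
#' marginal counts are both nonzero, records the joint count, the
#' independence expectation, the signed residual, and the two-sided
#' Fisher exact p-value of the collapsed 2x2 table.  This is the full
#' statistical substrate from which a metagraph is built.
#'
#' @param aln a `cn_alignment`.
#' @param pseudocount smoothing for the marginal frequencies used in
#'   the expectation (default 0; see [compute_marginals()]).
#' @param residual_type `"simple"` or `"pearson"`, see
#'   [compute_residuals()].
#' @param units `"probability"` or `"count"` residual units.
#' @return a `data.frame` of class `cn_scan` with columns `j`, `k`,
#'   `M`, `N`, `count`, `expected` (probability units), `residual`,
#'   `p`, plus attributes `n`, `L`, `alphabet`, `digest`.
#' @export
scan_all_pairs <- function(aln, pseudocount = 0,
                           residual_type = c("simple", "pearson"),
                           units = c("probability", "count")) {
  stopifnot(inherits(aln, "cn_alignment"))
  residual_type <- match.arg(residual_type)
  units <- match.arg(units)
  L <- ncol(aln$matrix)
  if (L < 2) stop("alignment must have at least 2 positions")
  n <- nrow(aln$matrix)
  syms <- aln$alphabet$symbols
  S <- length(syms)
  marg <- compute_marginals(aln, pseudocount)
  code <- matrix(match(aln$matrix, syms), nrow = n)
  onehot <- lapply(seq_len(L), function(j) {
    oh <- matrix(0L, n, S)
    oh[cbind(seq_len(n), code[, j])] <- 1L
    oh
  })
  out <- vector("list", count_position_pairs(L))
  idx <- 0L
  for (j in seq_len(L - 1L)) {
    for (k in seq.int(j + 1L, L)) {
      J <- crossprod(onehot[[j]], onehot[[k]])
      rs <- rowSums(J)
      cs <- colSums(J)
      keep <- which(outer(rs > 0, cs > 0, "&"), arr.ind = TRUE)
      Mi <- keep[, 1L]
      Ni <- keep[, 2L]
      a <- J[keep]
      bb <- rs[Mi] - a
      cc <- cs[Ni] - a
      dd <- n - a - bb - cc
      p <- vapply(seq_along(a), function(i)
        .fisher_p1(a[i], bb[i], cc[i], dd[i]), numeric(1))
      expected <- (marg$freq[, j][Mi]) * (marg$freq[, k][Ni])
      resid <- a / n - expected
      if (residual_type == "pearson")
        resid <- resid / sqrt(pmax(expected, .Machine$double.eps))
      if (units == "count") resid <- resid * n
      ord <- order(Mi, Ni)
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        j = j, k = k, M = syms[Mi[ord]], N = syms[Ni[ord]],
        count = as.integer(a[ord]), expected = expected[ord],
        residual = resid[ord],
        p = p[ord], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n") <- n
  attr(res, "L") <- L
  attr(res, "alphabet") <- aln$alphabet
  attr(res, "digest") <- .alignment_digest(aln)
  attr(res, "pseudocount") <- pseudocount
  class(res) <- c("cn_scan", "data.frame")
  res
}
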