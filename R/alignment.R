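#' Construct an alignment object
#'
#' An alignment is an `n x L` matrix of single-character categories,
#' one row per sequence, together with its alphabet.  All user-facing
#' position coordinates are 1-based.
#'
#' @param ids character vector of sequence identifiers (unique).
#' @param matrix character matrix, `n` sequences by `L` positions.
#' @param alphabet a [make_alphabet()] object.
#' @return an object of class `cn_alignment`.
#' @export
new_alignment <- function(ids, matrix, alphabet) {
  if (!inherits(alphabet, "cn_alphabet")) stop("alphabet must be a cn_alphabet")
  if (!is.matrix(matrix) || !is.character(matrix))
    stop("matrix must be a character matrix")
  if (nrow(matrix) < 1L) stop("alignment must contain at least one sequence")
  if (ncol(matrix) < 2L) stop("alignment must have at least 2 positions")
  ids <- as.character(ids)
  if (length(ids) != nrow(matrix)) stop("ids must match number of rows")
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  matrix <- toupper(matrix)
  bad <- !(matrix %in% alphabet$symbols)
  if (!is.na(alphabet$gap)) bad <- bad & matrix != alphabet$gap
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("symbol '%s' at sequence %s, position %d is not in the alphabet",
                 matrix[idx[1L], idx[2L]], ids[idx[1L]], idx[2L]))
  }
  dimnames(matrix) <- NULL
  structure(list(ids = ids, matrix = matrix, alphabet = alphabet),
            class = "cn_alignment")
}

#' Read a fixed-length categorical alignment from FASTA
#'
#' Records must all have the same length (it is an *aligned* family).
#' Symbols are upper-cased; ambiguity codes are rejected or mapped to
#' the gap character according to the alphabet's `ambiguity` policy.
#'
#' @param path path to an aligned FASTA file.
#' @param alphabet a [make_alphabet()] object; default nucleotide with
#'   gap as a category.
#' @return a `cn_alignment`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "ACGA"), fa)
#' aln <- read_alignment(fa)
#' dim(aln$matrix)
#' @export
read_alignment <- function(path, alphabet = nt_alphabet()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("FASTA file contains no records")
  ids <- vapply(strsplit(names(recs), "[ \t]"), `[`, character(1), 1L)
  lens <- Biostrings::width(recs)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1L])[1L]
    stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                 ids[off], lens[off], lens[1L]))
  }
  chars <- toupper(as.character(recs))
  m <- matrix(unlist(strsplit(chars, ""), use.names = FALSE),
              nrow = length(recs), byrow = TRUE)
  amb <- .ambiguity_codes(alphabet$kind)
  hit <- m %in% amb & !(m %in% alphabet$symbols)
  if (any(hit)) {
    if (alphabet$ambiguity == "gap") {
      if (is.na(alphabet$gap))
        stop("ambiguity codes present but alphabet has no gap to map them to")
      m[hit] <- alphabet$gap
    } else {
      idx <- which(matrix(hit, nrow(m)), arr.ind = TRUE)[1L, ]
      stop(sprintf("ambiguity code '%s' at sequence %s, position %d (policy: reject)",
                   m[idx[1L], idx[2L]], ids[idx[1L]], idx[2L]))
    }
  }
  new_alignment(ids, m, alphabet)
}

#' Write an alignment to FASTA
#'
#' `read_alignment(write_alignment(a))` reproduces `a`'s ids and matrix
#' exactly.
#'
#' @param aln a `cn_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "cn_alignment"))
  seqs <- apply(aln$matrix, 1L, paste, collapse = "")
  x <- Biostrings::BStringSet(seqs)
  names(x) <- aln$ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Summarize per-column category usage
#'
#' Pure reporting: returns per-column category counts and flags any
#' column whose observed categories fall outside the alphabet (can
#' only happen for gap characters under a gap-tolerant,
#' non-category policy).  Never mutates its input.
#'
#' @param aln a `cn_alignment`.
#' @return a list with `n`, `L`, `counts` (categories x positions
#'   integer matrix over all observed symbols) and `out_of_alphabet`
#'   (positions holding symbols that are not alphabet categories).
#' @export
validate_alignment <- function(aln) {
  stopifnot(inherits(aln, "cn_alignment"))
  obs <- sort(unique(as.vector(aln$matrix)))
  counts <- vapply(seq_len(ncol(aln$matrix)), function(j)
    vapply(obs, function(s) sum(aln$matrix[, j] == s), integer(1)),
    integer(length(obs)))
  counts <- matrix(counts, nrow = length(obs),
                   dimnames = list(obs, NULL))
  extra <- setdiff(obs, aln$alphabet$symbols)
  bad_cols <- if (length(extra))
    which(colSums(counts[extra, , drop = FALSE]) > 0) else integer(0)
  structure(list(n = nrow(aln$matrix), L = ncol(aln$matrix),
                 counts = counts, out_of_alphabet = bad_cols),
            class = "cn_validation")
}

#' @export
print.cn_alignment <- function(x, ...) {
  cat(sprintf("<cn_alignment> %d sequences x %d positions, alphabet [%s]\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$alphabet$symbols, collapse = "")))
  invisible(x)
}

#' @export
print.cn_validation <- function(x, ...) {
  cat(sprintf("<cn_validation> n=%d L=%d; %d column(s) outside alphabet\n",
              x$n, x$L, length(x$out_of_alphabet)))
  invisible(x)
}

# Canonical digest of an alignment (provenance tracking).
.alignment_digest <- function(aln) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(c(paste(aln$ids, collapse = "\t"),
               apply(aln$matrix, 1L, paste, collapse = "")), tf)
  unname(tools::md5sum(tf))
}

# Number of sequences / positions.
.aln_n <- function(aln) nrow(aln$matrix)
.aln_L <- function(aln) ncol(aln$matrix)
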