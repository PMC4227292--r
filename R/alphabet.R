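#' Define an alphabet of single-character categories
#'
#' An alphabet fixes the ordered set of categories an alignment may
#' contain, whether the gap character is itself a category, and how
#' ambiguity codes are handled.  The category *order* is part of the
#' model: it drives deterministic edge ordering and the fixed vertical
#' placement of category glyphs in the cylinder layout.
#'
#' @param kind one of `"nt"` (A, C, G, T), `"aa"` (the 20 standard
#'   amino acids), or `"custom"` (supply `symbols`).
#' @param symbols character vector of single-character categories for
#'   `kind = "custom"`; ignored otherwise.
#' @param gap gap character, or `NA` to disallow gaps entirely.
#' @param gap_as_category if `TRUE` (default) the gap character is a
#'   first-class category appended to the symbol set (so the protein
#'   alphabet has 21 categories); if `FALSE` gaps are tolerated on
#'   input but excluded from counting.
#' @param ambiguity `"reject"` (default) to error on ambiguity codes
#'   (N, X, ...), or `"gap"` to map them to the gap character.
#'
#' @return an object of class `cn_alphabet` with fields `symbols`,
#'   `gap`, `gap_as_category`, `ambiguity`, `kind`.
#' @examples
#' nt_alphabet()
#' make_alphabet("custom", symbols = c("0", "1"), gap = NA)
#' @export
make_alphabet <- function(kind = c("nt", "aa", "custom"), symbols = NULL,
                          gap = "-", gap_as_category = TRUE,
                          ambiguity = c("reject", "gap")) {
  kind <- match.arg(kind)
  ambiguity <- match.arg(ambiguity)
  base <- switch(kind,
    nt = c("A", "C", "G", "T"),
    aa = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
    custom = {
      if (is.null(symbols)) stop("custom alphabet requires `symbols`")
      toupper(as.character(symbols))
    })
  if (anyDuplicated(base)) stop("alphabet symbols must be unique")
  if (any(nchar(base) != 1L)) stop("alphabet symbols must be single characters")
  if (!is.na(gap) && nchar(gap) != 1L) stop("gap must be a single character")
  syms <- base
  if (!is.na(gap) && gap_as_category && !(gap %in% syms)) syms <- c(syms, gap)
  structure(list(symbols = syms, gap = if (is.na(gap)) NA_character_ else gap,
                 gap_as_category = isTRUE(gap_as_category) && !is.na(gap),
                 ambiguity = ambiguity, kind = kind),
            class = "cn_alphabet")
}

#' @rdname make_alphabet
#' @export
nt_alphabet <- function(gap = "-", gap_as_category = TRUE,
                        ambiguity = c("reject", "gap")) {
  make_alphabet("nt", gap = gap, gap_as_category = gap_as_category,
                ambiguity = ambiguity)
}

#' @rdname make_alphabet
#' @export
aa_alphabet <- function(gap = "-", gap_as_category = TRUE,
                        ambiguity = c("reject", "gap")) {
  make_alphabet("aa", gap = gap, gap_as_category = gap_as_category,
                ambiguity = ambiguity)
}

#' @export
print.cn_alphabet <- function(x, ...) {
  cat(sprintf("<cn_alphabet> %s: %d categories [%s]%s\n", x$kind,
              length(x$symbols), paste(x$symbols, collapse = ""),
              if (x$gap_as_category) sprintf(" (gap '%s' is a category)", x$gap)
              else ""))
  invisible(x)
}

# Ambiguity codes recognized for mapping/rejection.
.ambiguity_codes <- function(kind) {
  switch(kind,
         nt = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U"),
         aa = c("X", "B", "Z", "J", "U", "O"),
         character(0))
}
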