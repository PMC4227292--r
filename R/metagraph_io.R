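#' Export / import a metagraph
#'
#' Three formats are supported.  `"json"` persists the full model —
#' subnodes, edges with pin/removal flags, the replayable filter/edit
#' history, and provenance — and round-trips exactly.  `"graphml"`
#' writes the subnode graph with all edge attributes (no history).
#' `"tsv"` writes the edge table only (subnodes are reconstructed
#' from edge endpoints on import, without weights).
#'
#' @param g a `cn_metagraph`.
#' @param path output (input) file path.
#' @param format `"json"`, `"graphml"`, or `"tsv"`; inferred from the
#'   file extension when missing.
#' @return `path` invisibly for export; a `cn_metagraph` for import.
#' @export
export_metagraph <- function(g, path, format = c("json", "graphml", "tsv")) {
  stopifnot(inherits(g, "cn_metagraph"))
  format <- if (missing(format)) .guess_format(path) else match.arg(format)
  switch(format,
    json = {
      payload <- list(
        format = "covarnet-metagraph", version = 1L,
        L = g$L,
        alphabet = unclass(g$alphabet),
        subnodes = g$subnodes,
        edges = g$edges,
        history = g$history,
        provenance = g$provenance)
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
    },
    graphml = {
      ig <- igraph::graph_from_data_frame(
        data.frame(from = paste0(g$edges$j, ":", g$edges$M),
                   to = paste0(g$edges$k, ":", g$edges$N),
                   count = g$edges$count, expected = g$edges$expected,
                   residual = g$edges$residual, p = g$edges$p,
                   pinned = g$edges$pinned, removed = g$edges$removed,
                   retained = g$edges$retained,
                   component_id = ifelse(is.na(g$edges$component_id), -1L,
                                         g$edges$component_id),
                   in_cycle = g$edges$in_cycle),
        directed = FALSE,
        vertices = data.frame(name = paste0(g$subnodes$j, ":", g$subnodes$M),
                              j = g$subnodes$j, M = g$subnodes$M,
                              weight = g$subnodes$weight,
                              count = g$subnodes$count))
      igraph::write_graph(ig, path, format = "graphml")
    },
    tsv = {
      utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  invisible(path)
}

#' @rdname export_metagraph
#' @export
import_metagraph <- function(path, format = c("json", "graphml", "tsv")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  format <- if (missing(format)) .guess_format(path) else match.arg(format)
  g <- switch(format,
    json = {
      x <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
      if (!identical(x$format, "covarnet-metagraph"))
        stop(sprintf("%s: not a covarnet metagraph JSON file", path))
      alph <- x$alphabet
      alphabet <- structure(list(
        symbols = as.character(alph$symbols),
        gap = if (is.null(alph$gap)) NA_character_ else alph$gap,
        gap_as_category = isTRUE(alph$gap_as_category),
        ambiguity = alph$ambiguity, kind = alph$kind), class = "cn_alphabet")
      edges <- as.data.frame(x$edges)
      edges$component_id <- as.integer(edges$component_id)
      raw_hist <- jsonlite::read_json(path, simplifyVector = FALSE)$history
      hist <- lapply(raw_hist, function(h) {
        if (identical(h$op, "filter"))
          list(op = "filter", spec = lapply(h$spec, identity))
        else
          list(op = h$op, j = as.integer(h$j), M = as.character(h$M),
               k = as.integer(h$k), N = as.character(h$N))
      })
      structure(list(L = as.integer(x$L), alphabet = alphabet,
                     subnodes = as.data.frame(x$subnodes), edges = edges,
                     history = hist,
                     provenance = x$provenance),
                class = "cn_metagraph")
    },
    graphml = {
      ig <- igraph::read_graph(path, format = "graphml")
      vd <- igraph::as_data_frame(ig, what = "vertices")
      ed <- igraph::as_data_frame(ig, what = "edges")
      sub <- data.frame(j = as.integer(vd$j), M = vd$M,
                        weight = vd$weight, count = as.integer(vd$count),
                        stringsAsFactors = FALSE)
      sub <- sub[order(sub$j, sub$M), ]
      rownames(sub) <- NULL
      pj <- as.integer(sub("(\\d+):.*", "\\1", ed$from))
      pM <- sub("\\d+:", "", ed$from)
      pk <- as.integer(sub("(\\d+):.*", "\\1", ed$to))
      pN <- sub("\\d+:", "", ed$to)
      flip <- pj > pk
      edges <- data.frame(
        j = ifelse(flip, pk, pj), k = ifelse(flip, pj, pk),
        M = ifelse(flip, pN, pM), N = ifelse(flip, pM, pN),
        count = as.integer(ed$count), expected = ed$expected,
        residual = ed$residual, p = ed$p,
        pinned = as.logical(ed$pinned), removed = as.logical(ed$removed),
        retained = as.logical(ed$retained),
        component_id = ifelse(ed$component_id < 0, NA_integer_,
                              as.integer(ed$component_id)),
        in_cycle = as.logical(ed$in_cycle), stringsAsFactors = FALSE)
      edges <- edges[order(edges$j, edges$k, edges$M, edges$N), ]
      rownames(edges) <- NULL
      structure(list(L = max(edges$k, sub$j), alphabet = NULL,
                     subnodes = sub, edges = edges, history = list(),
                     provenance = list()),
                class = "cn_metagraph")
    },
    tsv = {
      edges <- utils::read.table(path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
      need <- c("j", "k", "M", "N", "count", "residual", "p")
      miss <- setdiff(need, names(edges))
      if (length(miss))
        stop(sprintf("%s: missing column(s) %s", path,
                     paste(miss, collapse = ", ")))
      ep <- unique(rbind(data.frame(j = edges$j, M = edges$M),
                         data.frame(j = edges$k, M = edges$N)))
      ep <- ep[order(ep$j, ep$M), ]
      rownames(ep) <- NULL
      structure(list(L = max(edges$k), alphabet = NULL,
                     subnodes = data.frame(j = ep$j, M = ep$M,
                                           weight = NA_real_,
                                           count = NA_integer_),
                     edges = edges, history = list(), provenance = list()),
                class = "cn_metagraph")
    })
  if (any(g$edges$j == g$edges$k))
    stop(sprintf("%s: invariant violation: edge connects two subnodes of position %d",
                 path, g$edges$j[which(g$edges$j == g$edges$k)[1L]]))
  g
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, json = "json", graphml = "graphml", xml = "graphml",
         tsv = "tsv", txt = "tsv",
         stop(sprintf("cannot infer metagraph format from extension '.%s'", ext)))
}
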