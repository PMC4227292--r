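#' Cylinder layout parameters
#'
#' @param radius cylinder radius in display units.
#' @param jitter logical; apply the deterministic per-position angular
#'   jitter (magnitude at most `min(0.1 * 2*pi/L, 0.02)` rad, derived
#'   from the position index via the golden ratio — no randomness).
#' @param glyph_scale multiplier for glyph radii; glyph *area* is
#'   proportional to the marginal weight, so visual weight is linear
#'   in probability.
#' @param height unit height between the lowest and highest category
#'   levels.
#' @return a `cn_layout_params` list.
#' @export
layout_params <- function(radius = 1, jitter = TRUE, glyph_scale = 0.1,
                          height = 1) {
  if (radius <= 0 || glyph_scale <= 0 || height <= 0)
    stop("layout dimensions must be positive")
  structure(list(radius = radius, jitter = isTRUE(jitter),
                 glyph_scale = glyph_scale, height = height),
            class = "cn_layout_params")
}

.position_angles <- function(L, params) {
  base <- 2 * pi * (seq_len(L) - 1L) / L
  if (!params$jitter) return(base)
  jmax <- min(0.1 * 2 * pi / L, 0.02)
  frac <- (seq_len(L) * 0.618033988749895) %% 1
  base + jmax * (2 * frac - 1)
}

#' Compute the cylinder layout of a metagraph
#'
#' Positions become parallel categorical axes arranged uniformly
#' around a cylinder (angle `2*pi*(j-1)/L` plus the deterministic
#' jitter); categories take fixed, strictly increasing heights in
#' alphabet order; each observed subnode sits at
#' `(R cos(theta_j), R sin(theta_j), h_M)` with a glyph whose area is
#' proportional to its marginal weight.  The layout depends only on
#' the alignment dimensions, the alphabet, and the marginals — never
#' on the edge filter state — so subnode coordinates are stable while
#' the analyst refines edges.
#'
#' @param g a `cn_metagraph`.
#' @param params a [layout_params()].
#' @return an object of class `cn_layout` with `theta`, `heights`,
#'   and a `subnodes` data frame (`j`, `M`, `x`, `y`, `z`,
#'   `glyph_radius`).
#' @export
compute_layout <- function(g, params = layout_params()) {
  stopifnot(inherits(g, "cn_metagraph"), inherits(params, "cn_layout_params"))
  if (g$L < 2) stop("a cylinder layout needs at least 2 positions")
  syms <- g$alphabet$symbols
  S <- length(syms)
  theta <- .position_angles(g$L, params)
  heights <- stats::setNames(
    if (S > 1) params$height * (seq_len(S) - 1) / (S - 1) else 0, syms)
  sn <- g$subnodes
  out <- data.frame(
    j = sn$j, M = sn$M,
    x = params$radius * cos(theta[sn$j]),
    y = params$radius * sin(theta[sn$j]),
    z = unname(heights[sn$M]),
    glyph_radius = params$glyph_scale * sqrt(sn$weight),
    stringsAsFactors = FALSE)
  structure(list(L = g$L, alphabet = g$alphabet, theta = theta,
                 heights = heights, subnodes = out, params = params),
            class = "cn_layout")
}

.edge_table <- function(edges) {
  if (inherits(edges, "cn_metagraph"))
    edges <- edges$edges[edges$edges$retained, , drop = FALSE]
  stopifnot(is.data.frame(edges),
            all(c("j", "M", "k", "N") %in% names(edges)))
  edges
}

.edge_coords <- function(layout, edges) {
  key <- paste0(layout$subnodes$j, ":", layout$subnodes$M)
  i1 <- match(paste0(edges$j, ":", edges$M), key)
  i2 <- match(paste0(edges$k, ":", edges$N), key)
  if (anyNA(i1) || anyNA(i2))
    stop("edge endpoint missing from the layout's subnode set")
  sn <- layout$subnodes
  cbind(x1 = sn$x[i1], y1 = sn$y[i1], z1 = sn$z[i1],
        x2 = sn$x[i2], y2 = sn$y[i2], z2 = sn$z[i2])
}

#' Certify that no edge is occluded within another
#'
#' Tests every pair of distinct edge segments for colinear overlap in
#' 3D (direction and offset colinear within relative tolerance 1e-9,
#' with an overlap of positive length).  An empty result certifies
#' the layout: every edge is individually visible from some
#' viewpoint.
#'
#' @param layout a `cn_layout`.
#' @param edges edge table (or a `cn_metagraph`, whose retained edges
#'   are used).
#' @param tol colinearity tolerance.
#' @return a `data.frame` of violating edge pairs (`edge1`, `edge2`
#'   as `"j:M-k:N"` labels); zero rows means certified.
#' @export
check_occlusion <- function(layout, edges, tol = 1e-9) {
  stopifnot(inherits(layout, "cn_layout"))
  edges <- .edge_table(edges)
  if (!nrow(edges))
    return(data.frame(edge1 = character(0), edge2 = character(0)))
  co <- .edge_coords(layout, edges)
  lab <- sprintf("%d:%s-%d:%s", edges$j, edges$M, edges$k, edges$N)
  p1 <- co[, 1:3, drop = FALSE]
  p2 <- co[, 4:6, drop = FALSE]
  d <- p2 - p1
  len <- sqrt(rowSums(d^2))
  viol <- list()
  ne <- nrow(edges)
  for (a in seq_len(ne - 1L)) {
    for (b in seq.int(a + 1L, ne)) {
      cr <- .cross3(d[a, ], d[b, ])
      if (sqrt(sum(cr^2)) > tol * len[a] * len[b]) next
      w <- p1[b, ] - p1[a, ]
      cw <- .cross3(d[a, ], w)
      if (sqrt(sum(cw^2)) > tol * len[a] * max(len[a], sqrt(sum(w^2)), 1)) next
      # colinear: check 1D overlap along segment a
      t1 <- sum((p1[b, ] - p1[a, ]) * d[a, ]) / len[a]^2
      t2 <- sum((p2[b, ] - p1[a, ]) * d[a, ]) / len[a]^2
      lohi <- sort(c(t1, t2))
      ov <- min(1, lohi[2L]) - max(0, lohi[1L])
      if (ov > tol) viol <- c(viol, list(c(lab[a], lab[b])))
    }
  }
  if (!length(viol))
    return(data.frame(edge1 = character(0), edge2 = character(0)))
  out <- do.call(rbind, viol)
  data.frame(edge1 = out[, 1L], edge2 = out[, 2L], stringsAsFactors = FALSE)
}

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Export a renderable scene
#'
#' `"json"` writes glyph positions/sizes and edge segments with sign
#' styling (`"solid"` for positive residuals, `"dashed"` for
#' negative) plus component and cycle annotations when present;
#' re-export of the same inputs is byte-identical.  `"obj"` writes a
#' Wavefront line set (subnode vertices + one line element per edge)
#' for external viewers.
#'
#' @param layout a `cn_layout`.
#' @param edges edge table or `cn_metagraph` (retained edges).
#' @param path output file.
#' @param format `"json"` or `"obj"`.
#' @return `path`, invisibly.
#' @export
export_scene <- function(layout, edges, path, format = c("json", "obj")) {
  stopifnot(inherits(layout, "cn_layout"))
  format <- match.arg(format)
  edges <- .edge_table(edges)
  sn <- layout$subnodes
  if (format == "json") {
    ed <- NULL
    if (nrow(edges)) {
      co <- .edge_coords(layout, edges)
      ed <- data.frame(
        j = edges$j, M = edges$M, k = edges$k, N = edges$N,
        x1 = co[, "x1"], y1 = co[, "y1"], z1 = co[, "z1"],
        x2 = co[, "x2"], y2 = co[, "y2"], z2 = co[, "z2"],
        weight = if ("residual" %in% names(edges)) edges$residual else NA_real_,
        style = if ("residual" %in% names(edges))
          ifelse(edges$residual < 0, "dashed", "solid") else "solid",
        component_id = if ("component_id" %in% names(edges))
          edges$component_id else NA_integer_,
        in_cycle = if ("in_cycle" %in% names(edges))
          edges$in_cycle else FALSE,
        stringsAsFactors = FALSE)
    }
    payload <- list(format = "covarnet-scene", version = 1L,
                    cylinder = list(radius = layout$params$radius,
                                    L = layout$L,
                                    heights = as.list(layout$heights)),
                    glyphs = sn[sn$glyph_radius > 0, , drop = FALSE],
                    edges = ed)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                         na = "null", null = "null")
  } else {
    lines <- c("# covarnet cylinder scene",
               sprintf("v %.6f %.6f %.6f", sn$x, sn$y, sn$z))
    if (nrow(edges)) {
      key <- paste0(sn$j, ":", sn$M)
      i1 <- match(paste0(edges$j, ":", edges$M), key)
      i2 <- match(paste0(edges$k, ":", edges$N), key)
      lines <- c(lines, sprintf("l %d %d", i1, i2))
    }
    writeLines(lines, path)
  }
  invisible(path)
}
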