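#' Persist / load a CRF model as JSON
#'
#' @param m a `cn_crf`.
#' @param path output (input) JSON path.
#' @return `path` invisibly (export); a `cn_crf` (import).
#' @export
export_crf <- function(m, path) {
  stopifnot(inherits(m, "cn_crf"))
  payload <- list(
    format = "covarnet-crf", version = 1L, L = m$L, alpha = m$alpha,
    alphabet = unclass(m$alphabet),
    node_potentials = m$node_potentials,
    edge_potentials = m$edge_potentials,
    retained_edges = m$retained_edges,
    provenance = m$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null", null = "null")
  invisible(path)
}

#' @rdname export_crf
#' @export
import_crf <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "covarnet-crf"))
    stop(sprintf("%s: not a covarnet CRF JSON file", path))
  alph <- structure(list(symbols = as.character(x$alphabet$symbols),
                         gap = if (is.null(x$alphabet$gap)) NA_character_
                               else x$alphabet$gap,
                         gap_as_category = isTRUE(x$alphabet$gap_as_category),
                         ambiguity = x$alphabet$ambiguity,
                         kind = x$alphabet$kind),
                    class = "cn_alphabet")
  syms <- alph$symbols
  np <- matrix(as.numeric(x$node_potentials), nrow = length(syms),
               dimnames = list(syms, NULL))
  ep <- lapply(x$edge_potentials, function(mm)
    matrix(as.numeric(mm), nrow = length(syms), byrow = FALSE,
           dimnames = list(syms, syms)))
  structure(list(node_potentials = np, edge_potentials = ep,
                 retained_edges = as.data.frame(x$retained_edges),
                 alpha = x$alpha, alphabet = alph, L = as.integer(x$L),
                 provenance = x$provenance),
            class = "cn_crf")
}

#' Assemble a pipeline run configuration
#'
#' A fully serializable description of an end-to-end run; identical
#' configurations on identical inputs produce identical outputs.
#'
#' @param input path to an aligned FASTA training family.
#' @param outdir output directory (created if needed).
#' @param alphabet_kind `"nt"`, `"aa"`, or a custom symbol string.
#' @param gap_policy `"category"` (gap is a category) or `"drop"`.
#' @param min_abs_residual,max_p,min_joint_count edge filter (see
#'   [filter_spec()]).
#' @param alpha CRF smoothing.
#' @param reference reference sequence id for relative scores
#'   (default: first training sequence).
#' @param candidates optional FASTA of candidate sequences to score
#'   (default: the training family itself).
#' @param realign logical: run [iterative_realign()] first.
#' @param min_run,max_iter echo parameters.
#' @param layout_radius,layout_jitter cylinder layout parameters.
#' @param seed seed recorded in the manifest (the pipeline stages are
#'   deterministic; the seed feeds any generator-based input).
#' @return a `cn_run_config`.
#' @export
run_config <- function(input, outdir, alphabet_kind = "nt",
                       gap_policy = c("category", "drop"),
                       min_abs_residual = 0.05, max_p = 0.001,
                       min_joint_count = 0, alpha = 0.5, reference = NULL,
                       candidates = NULL, realign = FALSE, min_run = 3,
                       max_iter = 10, layout_radius = 1,
                       layout_jitter = TRUE, seed = 1) {
  gap_policy <- match.arg(gap_policy)
  structure(list(input = input, outdir = outdir,
                 alphabet_kind = alphabet_kind, gap_policy = gap_policy,
                 min_abs_residual = min_abs_residual, max_p = max_p,
                 min_joint_count = min_joint_count, alpha = alpha,
                 reference = reference, candidates = candidates,
                 realign = isTRUE(realign), min_run = min_run,
                 max_iter = max_iter, layout_radius = layout_radius,
                 layout_jitter = isTRUE(layout_jitter), seed = seed),
            class = "cn_run_config")
}

#' @rdname run_config
#' @param path JSON (or YAML, if the yaml package is installed)
#'   configuration file whose keys mirror the [run_config()]
#'   arguments.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

.cfg_alphabet <- function(cfg) {
  if (cfg$alphabet_kind %in% c("nt", "aa"))
    make_alphabet(cfg$alphabet_kind,
                  gap_as_category = cfg$gap_policy == "category")
  else
    make_alphabet("custom", symbols = strsplit(cfg$alphabet_kind, "")[[1L]],
                  gap_as_category = cfg$gap_policy == "category")
}

#' Execute the full dependency-network pipeline
#'
#' Runs read / (optional realign) / scan / build / filter /
#' components / cycles / CRF / score / layout in sequence and writes
#' `edges.tsv`, `refined.json`, `model.json`, `scores.tsv`, and
#' `scene.json` to the configured output directory.  Floats in TSV
#' outputs are written with 6 significant digits so outputs are
#' byte-stable across platforms.
#'
#' @param cfg a [run_config()].
#' @return a list of class `cn_manifest` with `files` (name, path,
#'   md5), `log` (per-stage counts), and `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "cn_run_config"))
  stage <- "validate"
  result <- tryCatch({
    alphabet <- .cfg_alphabet(cfg)
    aln <- read_alignment(cfg$input, alphabet)
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    log <- list(n = nrow(aln$matrix), L = ncol(aln$matrix))
    if (cfg$realign) {
      stage <- "realign"
      rl <- iterative_realign(
        aln, filter_spec(cfg$min_abs_residual, cfg$max_p,
                         cfg$min_joint_count),
        min_run = cfg$min_run, max_iter = cfg$max_iter)
      aln <- rl$alignment
      log$realign_iterations <- rl$iterations
      write_alignment(aln, file.path(cfg$outdir, "realigned.fasta"))
    }
    stage <- "deps"
    scan <- scan_all_pairs(aln)
    tsv <- scan
    for (col in c("expected", "residual", "p"))
      tsv[[col]] <- signif(tsv[[col]], 6)
    utils::write.table(tsv, file.path(cfg$outdir, "edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage <- "filter"
    g <- build_metagraph(aln, scan)
    log$raw_edges <- nrow(g$edges)
    g <- filter_edges(g, filter_spec(cfg$min_abs_residual, cfg$max_p,
                                     cfg$min_joint_count))
    log$retained_edges <- sum(g$edges$retained)
    g <- label_components(g)
    log$components <- length(unique(stats::na.omit(g$edges$component_id)))
    cyc <- detect_cycles(g, "node")
    g <- cyc$metagraph
    log$cycles <- length(cyc$cycles)
    export_metagraph(g, file.path(cfg$outdir, "refined.json"), "json")
    stage <- "crf"
    model <- build_crf(g, aln, cfg$alpha)
    export_crf(model, file.path(cfg$outdir, "model.json"))
    stage <- "score"
    cand <- if (is.null(cfg$candidates)) aln
            else read_alignment(cfg$candidates, alphabet)
    ref <- if (is.null(cfg$reference)) cand$ids[1L] else cfg$reference
    scores <- score_alignment(model, cand, ref)
    for (col in c("log_score", "node_term", "edge_term", "relative"))
      scores[[col]] <- signif(scores[[col]], 6)
    utils::write.table(scores, file.path(cfg$outdir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage <- "layout"
    lay <- compute_layout(g, layout_params(radius = cfg$layout_radius,
                                           jitter = cfg$layout_jitter))
    export_scene(lay, g, file.path(cfg$outdir, "scene.json"), "json")
    files <- c("edges.tsv", "refined.json", "model.json", "scores.tsv",
               "scene.json", if (cfg$realign) "realigned.fasta")
    paths <- file.path(cfg$outdir, files)
    structure(list(files = data.frame(name = files, path = paths,
                                      md5 = unname(tools::md5sum(paths)),
                                      stringsAsFactors = FALSE),
                   log = log, config = cfg),
              class = "cn_manifest")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

#' @export
print.cn_manifest <- function(x, ...) {
  cat(sprintf("<cn_manifest> %d file(s) in %s\n", nrow(x$files),
              x$config$outdir))
  cat(sprintf("  raw edges %s -> retained %s; %s component(s), %s cycle(s)\n",
              x$log$raw_edges, x$log$retained_edges, x$log$components,
              x$log$cycles))
  invisible(x)
}
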