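# The three presentation modes of gene set-level TGx scoring: radar chart
# (one condition, all sets), time-course heat map, and score-colored
# supervised pathway network. All renderers are deterministic: fixed
# styling, no timestamps, C locale number formatting.

# Diverging blue-white-red color for a signed score under fixed symmetric
# limits. Pure function of (score, limit); equal scores always map to the
# identical color.
score_color <- function(score, limit) {
  if (limit <= 0) limit <- 1
  z <- max(-1, min(1, score / limit))
  if (z >= 0) grDevices::rgb(1, 1 - z, 1 - z) else grDevices::rgb(1 + z, 1 + z, 1)
}

open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    svg = grDevices::svg(path, width = width, height = height),
    png = grDevices::png(path, width = width * 96, height = height * 96,
                         res = 96),
    pdf = grDevices::pdf(path, width = width, height = height),
    stop("unsupported image extension: ", ext, call. = FALSE))
}

#' Radar chart of gene-set scores for one condition
#'
#' One axis per gene set, in collection order; absolute score values are
#' plotted (the radar presentation of the field shows |D-score|), as a red
#' polyline over a blue reference circle drawn at `reference_level`
#' (default 20, the conventional "strong response" D-score level).
#'
#' @param scores A `score_table` or named numeric vector (one condition's
#'   column).
#' @param condition Condition (column) to plot when `scores` is a table.
#' @param reference_level Radius of the blue reference circle.
#' @param path Output image path (`.svg`, `.png` or `.pdf`).
#' @param title Plot title; defaults to the condition name.
#' @return The output path, invisibly.
#' @export
radar_chart <- function(scores, condition = NULL, reference_level = 20,
                        path, title = NULL) {
  if (is.matrix(scores)) {
    if (is.null(condition)) condition <- colnames(scores)[1]
    v <- scores[, condition]
    if (is.null(title)) title <- condition
  } else {
    v <- scores
    if (is.null(title)) title <- ""
  }
  n <- length(v)
  if (n < 3) stop("radar chart needs at least 3 gene sets", call. = FALSE)
  v_abs <- abs(v)
  lim <- max(v_abs, reference_level) * 1.1
  theta <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n  # clockwise from 12 o'clock

  open_device(path, 8, 8)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(-1.45, 1.45) * lim, ylim = c(-1.45, 1.45) * lim,
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = title)
  for (i in seq_len(n)) {
    graphics::segments(0, 0, lim * cos(theta[i]), lim * sin(theta[i]),
                       col = "grey85")
  }
  circ <- seq(0, 2 * pi, length.out = 241)
  graphics::lines(reference_level * cos(circ), reference_level * sin(circ),
                  col = "blue", lwd = 1.5)
  graphics::polygon(v_abs * cos(theta), v_abs * sin(theta),
                    border = "red", lwd = 2)
  lab_r <- 1.12 * lim
  graphics::text(lab_r * cos(theta), lab_r * sin(theta), names(v),
                 cex = if (n > 30) 0.45 else 0.7, xpd = NA)
  invisible(path)
}

#' Time-course heat map of a score table
#'
#' Gene sets as rows and conditions as columns, on a diverging
#' red-white-blue scale centered at zero with symmetric limits
#' `+/- max(|score|)`, so up- and down-regulation are directly comparable
#' across sets. `ordering = "cluster"` reorders rows by hierarchical
#' clustering (Euclidean distance, average linkage); `"input"` keeps
#' collection order.
#'
#' @param scores A `score_table`.
#' @param path Output image path.
#' @param ordering `"input"` or `"cluster"`.
#' @return Invisibly, a list with `path` and `row_order` (the rendered
#'   top-to-bottom gene-set order).
#' @export
heat_map <- function(scores, path, ordering = c("input", "cluster")) {
  ordering <- match.arg(ordering)
  m <- unclass(scores)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty score table", call. = FALSE)
  lim <- max(abs(m))
  if (lim == 0) lim <- 1
  ph <- pheatmap::pheatmap(
    m,
    color = grDevices::colorRampPalette(c("blue", "white", "red"))(100),
    breaks = seq(-lim, lim, length.out = 101),
    cluster_rows = ordering == "cluster" && nrow(m) > 1,
    cluster_cols = FALSE,
    clustering_distance_rows = "euclidean",
    clustering_method = "average",
    fontsize_row = if (nrow(m) > 30) 5 else 8,
    silent = TRUE)
  row_order <- if (ordering == "cluster" && nrow(m) > 1) {
    rownames(m)[ph$tree_row$order]
  } else rownames(m)
  open_device(path, 7, max(4, 0.14 * nrow(m) + 1))
  on.exit(grDevices::dev.off())
  grid::grid.draw(ph$gtable)
  invisible(list(path = path, row_order = row_order))
}

#' Read a supervised-network specification
#'
#' A supervised network is a curated, pre-defined graph of biological and
#' toxicological relationships among gene sets onto which per-set scores
#' are painted (as opposed to a network inferred from data). The topology
#' file is a TSV edge list with columns `from` and `to` and an optional
#' `label`.
#'
#' @param path Path to the TSV file.
#' @return A list of class `supervised_network_spec` with `nodes` and
#'   `edges`.
#' @export
read_network_spec <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("from", "to") %in% names(df))) {
    stop("network spec needs 'from' and 'to' columns", call. = FALSE)
  }
  new_network_spec(df)
}

new_network_spec <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  structure(list(nodes = nodes, edges = edges),
            class = "supervised_network_spec")
}

#' Render a score-colored supervised network
#'
#' Writes a Graphviz DOT file in which every node of the curated network is
#' filled with the diverging color of its signed score (red = up-regulated,
#' blue = down-regulated, white = no change) under symmetric limits
#' `+/- max(|score|)`. Nodes absent from the score column are filled
#' neutrally with a warning. If a Graphviz layout engine is on the PATH an
#' image is rendered next to the DOT file; otherwise the DOT file alone is
#' produced (with a message).
#'
#' @param spec A `supervised_network_spec`.
#' @param scores A `score_table` or named numeric vector.
#' @param condition Condition column used when `scores` is a table.
#' @param out_prefix Output path prefix; writes `<prefix>.dot` and, when a
#'   layout engine is available, `<prefix>.svg`.
#' @return Named list of the files written, invisibly.
#' @export
render_supervised_network <- function(spec, scores, condition = NULL,
                                      out_prefix) {
  stopifnot(inherits(spec, "supervised_network_spec"))
  if (is.matrix(scores)) {
    if (is.null(condition)) condition <- colnames(scores)[1]
    v <- scores[, condition]
  } else v <- scores
  dangling <- setdiff(c(spec$edges$from, spec$edges$to), spec$nodes)
  if (length(dangling)) {
    stop("edge endpoint(s) missing from node list: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(spec$nodes, names(v))
  if (length(missing)) {
    warning("node(s) without a score filled neutrally: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  lim <- max(abs(v), 1e-12)
  fill <- vapply(spec$nodes, function(nm)
    if (nm %in% names(v)) score_color(v[[nm]], lim) else "#FFFFFF",
    character(1))
  esc <- function(x) gsub('"', '\\\\"', x)
  node_lines <- sprintf(
    '  "%s" [style=filled, fillcolor="%s", score="%s"];',
    esc(spec$nodes), fill,
    ifelse(spec$nodes %in% names(v),
           formatC(v[spec$nodes], format = "g", digits = 6), "NA"))
  lab <- if ("label" %in% names(spec$edges)) {
    sprintf(' [label="%s"]', esc(spec$edges$label))
  } else ""
  edge_lines <- sprintf('  "%s" -> "%s"%s;', esc(spec$edges$from),
                        esc(spec$edges$to), lab)
  dot_path <- paste0(out_prefix, ".dot")
  writeLines(c("digraph supervised_tgx {", "  rankdir=TB;",
               "  node [shape=box, fontsize=10];",
               node_lines, edge_lines, "}"), dot_path)
  out <- list(dot = dot_path)
  engine <- Sys.which("dot")
  if (nzchar(engine)) {
    img_path <- paste0(out_prefix, ".svg")
    status <- system2(engine, c("-Tsvg", "-o", shQuote(img_path),
                                shQuote(dot_path)))
    if (status == 0) out$image <- img_path
  } else {
    message("no Graphviz layout engine on PATH; DOT file only")
  }
  invisible(out)
}
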