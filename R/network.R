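# Gaussian graphical model over gene-set score profiles and phenotype
# changing levels: shrinkage-regularized partial correlations, edge
# selection, and network export.

#' Assemble the condition x feature matrix for network inference
#'
#' Joins a gene set x condition score table with an optional condition x
#' endpoint phenotype table on their shared conditions, drops rows with any
#' missing value (listwise), drops zero-variance columns with a warning,
#' and standardizes every column to mean 0 / unit variance so gene-set
#' scores and phenotype endpoints are commensurate.
#'
#' @param scores A `score_table` (gene sets x conditions).
#' @param phenos Optional numeric matrix (conditions x endpoints) from
#'   [read_phenotypes()].
#' @return A standardized numeric matrix, conditions as rows, with
#'   attribute `kinds`: `"gene_set"` or `"phenotype"` per column.
#' @export
assemble_features <- function(scores, phenos = NULL) {
  x <- t(unclass(scores))  # conditions x sets
  attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <- NULL
  kinds <- rep("gene_set", ncol(x))
  if (!is.null(phenos)) {
    shared <- intersect(rownames(x), rownames(phenos))
    if (length(shared) < 3) {
      stop("fewer than 3 conditions shared between scores and phenotypes",
           call. = FALSE)
    }
    dup <- intersect(colnames(x), colnames(phenos))
    if (length(dup)) {
      stop("duplicate feature names across scores and phenotypes: ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    x <- cbind(x[shared, , drop = FALSE], phenos[shared, , drop = FALSE])
    kinds <- c(kinds, rep("phenotype", ncol(phenos)))
  }
  complete <- stats::complete.cases(x)
  if (any(!complete)) {
    message(sum(!complete), " condition(s) dropped for missing values")
    x <- x[complete, , drop = FALSE]
  }
  if (nrow(x) < 3) stop("fewer than 3 usable conditions", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance column(s) dropped: ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    kinds <- kinds[sds > 0]
    x <- x[, sds > 0, drop = FALSE]
  }
  x <- scale(x)
  attr(x, "scaled:center") <- attr(x, "scaled:scale") <- NULL
  attr(x, "kinds") <- setNames(kinds, colnames(x))
  x
}

#' Partial correlations from a correlation matrix
#'
#' Core GGM computation: shrink the correlation matrix toward the identity,
#' invert, and rescale the negated off-diagonal precision entries,
#' \deqn{S^* = (1-\lambda) S + \lambda I, \quad \Omega = (S^*)^{-1}, \quad
#'   \rho_{ij} = -\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}},}
#' with \eqn{\rho_{ii} = 1}. At \eqn{\lambda = 0} this is the classical
#' partial correlation given all remaining variables; \eqn{\lambda = 1}
#' collapses to the identity (no edges).
#'
#' @param S Symmetric correlation matrix.
#' @param lambda Shrinkage intensity in \[0, 1\].
#' @return Symmetric matrix of partial correlations, unit diagonal.
#' @examples
#' S <- matrix(0.5, 3, 3); diag(S) <- 1
#' partial_cor(S)  # all off-diagonals 1/3
#' @export
partial_cor <- function(S, lambda = 0) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), lambda >= 0, lambda <= 1)
  p <- nrow(S)
  S_star <- (1 - lambda) * S + lambda * diag(p)
  omega <- tryCatch(solve(S_star), error = function(e)
    stop("shrunken correlation matrix is numerically singular; ",
         "use lambda > 0 (or 'auto')", call. = FALSE))
  d <- sqrt(diag(omega))
  rho <- -omega / tcrossprod(d)
  diag(rho) <- 1
  dimnames(rho) <- dimnames(S)
  # enforce exact symmetry against inversion round-off
  (rho + t(rho)) / 2
}

#' Analytic shrinkage intensity for correlation shrinkage toward identity
#'
#' The Ledoit-Wolf-style closed-form estimator for the identity-target
#' correlation shrinkage (the small-n-large-p workhorse of gene-network
#' inference): the ratio of the summed estimated variances of the empirical
#' correlations to their summed squares, clipped to \[0, 1\].
#'
#' @param x Numeric data matrix, observations x variables.
#' @return Shrinkage intensity in \[0, 1\].
#' @export
shrinkage_lambda <- function(x) {
  n <- nrow(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  xs <- scale(x)  # unit variance, so cross-products estimate correlations
  r <- crossprod(xs) / (n - 1)
  p <- ncol(x)
  var_sum <- 0
  for (j in seq_len(p)) {
    w <- xs * xs[, j]                         # w_kij for all i at this j
    wbar <- colMeans(w)
    v <- n / (n - 1)^3 * colSums(sweep(w, 2, wbar)^2)
    v[j] <- 0
    var_sum <- var_sum + sum(v)
  }
  r2_sum <- sum(r^2) - p
  if (r2_sum <= 0) return(1)
  min(1, max(0, var_sum / r2_sum))
}

#' Estimate a partial-correlation network over gene sets and phenotypes
#'
#' Fits a Gaussian graphical model to a standardized condition x feature
#' matrix (see [assemble_features()]): the sample correlation matrix is
#' shrunk toward the identity with intensity `lambda` and inverted, and the
#' negated rescaled precision entries give the partial correlation between
#' each pair of features conditioned on all others. With ~60 features and
#' ~150 conditions the shrinkage keeps the estimate well-conditioned.
#'
#' @param features Standardized matrix from [assemble_features()] (rows
#'   conditions, columns features).
#' @param lambda Shrinkage intensity in \[0, 1\], or `"auto"` for the
#'   analytic estimator of [shrinkage_lambda()].
#' @return An object of class `tgx_ggm`: list with `pcor` (partial
#'   correlation matrix), `lambda`, `nodes` (data.frame of `name`, `kind`),
#'   `n`, `p`, and the `features` matrix (kept for permutation testing).
#' @seealso [select_edges()], [export_network()]
#' @export
estimate_pcor <- function(features, lambda = "auto") {
  stopifnot(is.matrix(features), is.numeric(features))
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  }
  if (identical(lambda, "auto")) lambda <- shrinkage_lambda(features)
  S <- stats::cor(features)
  rho <- partial_cor(S, lambda)
  kinds <- attr(features, "kinds")
  if (is.null(kinds)) kinds <- setNames(rep("gene_set", ncol(features)),
                                        colnames(features))
  structure(list(
    pcor = rho, lambda = lambda,
    nodes = data.frame(name = colnames(features),
                       kind = unname(kinds[colnames(features)]),
                       stringsAsFactors = FALSE),
    n = nrow(features), p = ncol(features),
    features = features), class = "tgx_ggm")
}

#' @export
print.tgx_ggm <- function(x, ...) {
  cat(sprintf("tgx_ggm: %d nodes (%d gene sets, %d phenotypes), n = %d conditions\n",
              x$p, sum(x$nodes$kind == "gene_set"),
              sum(x$nodes$kind == "phenotype"), x$n))
  cat(sprintf("shrinkage lambda = %.4f\n", x$lambda))
  off <- abs(x$pcor[upper.tri(x$pcor)])
  cat(sprintf("|partial correlation| off-diagonal: median %.3f, max %.3f\n",
              stats::median(off), max(off)))
  invisible(x)
}

#' @export
summary.tgx_ggm <- function(object, threshold = 0.1, ...) {
  edges <- select_edges(object, rule = "abs_threshold", threshold = threshold)
  cat(sprintf("tgx_ggm with %d nodes, n = %d, lambda = %.4f\n",
              object$p, object$n, object$lambda))
  cat(sprintf("%d edge(s) at |rho| >= %g (%d positive, %d negative)\n",
              nrow(edges), threshold, sum(edges$pcor > 0), sum(edges$pcor < 0)))
  invisible(structure(list(network = object, edges = edges, threshold = threshold),
                      class = "summary.tgx_ggm"))
}

#' @export
coef.tgx_ggm <- function(object, ...) object$pcor

#' Plot a fitted partial-correlation network
#'
#' Draws the selected edges with igraph: positive partial correlations in
#' purple, negative in green, edge width proportional to \eqn{|\rho|}
#' (the conventional encoding of signed GGM edges in this field).
#'
#' @param x A `tgx_ggm`.
#' @param edges Optional edge list from [select_edges()]; defaults to
#'   `abs_threshold` at 0.1.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.tgx_ggm <- function(x, edges = NULL, ...) {
  if (is.null(edges)) edges <- select_edges(x, rule = "abs_threshold", threshold = 0.1)
  g <- as_igraph(x, edges)
  igraph::plot.igraph(
    g,
    edge.color = ifelse(igraph::E(g)$sign == "positive", "purple4", "darkgreen"),
    edge.width = 1 + 4 * abs(igraph::E(g)$weight),
    vertex.color = ifelse(igraph::V(g)$kind == "phenotype", "gold", "skyblue"),
    vertex.label.cex = 0.7,
    layout = igraph::layout_with_fr(g, niter = 500, weights = NA),
    ...)
  invisible(x)
}

as_igraph <- function(network, edges) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to, weight = edges$pcor,
               sign = ifelse(edges$pcor >= 0, "positive", "negative"),
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = network$nodes)
  g
}

#' Select network edges
#'
#' Three selection rules over the fitted partial correlations:
#' `abs_threshold` keeps pairs with \eqn{|\rho| \ge t}; `top_k` keeps the k
#' largest \eqn{|\rho|}; `perm_fdr` permutes every feature column
#' independently B times, refits the network at the same shrinkage
#' intensity, and keeps the largest edge set whose empirical false
#' discovery rate is at most q.
#'
#' @param network A `tgx_ggm` from [estimate_pcor()].
#' @param rule One of `"abs_threshold"`, `"top_k"`, `"perm_fdr"`.
#' @param threshold Absolute partial-correlation cutoff (abs_threshold).
#' @param k Number of edges to keep (top_k).
#' @param q Target FDR (perm_fdr).
#' @param B Number of permutations (perm_fdr).
#' @param seed Integer seed making the permutation null reproducible.
#' @return A `data.frame` with columns `from`, `to`, `pcor`, ordered by
#'   decreasing \eqn{|\rho|} (ties broken by node names).
#' @export
select_edges <- function(network, rule = c("abs_threshold", "top_k", "perm_fdr"),
                         threshold = 0.1, k = NULL, q = 0.05, B = 200,
                         seed = 1L) {
  rule <- match.arg(rule)
  rho <- network$pcor
  p <- nrow(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  all_edges <- data.frame(from = rownames(rho)[ut[, 1]],
                          to = colnames(rho)[ut[, 2]],
                          pcor = rho[ut], stringsAsFactors = FALSE)
  ord <- order(-abs(all_edges$pcor), all_edges$from, all_edges$to)
  all_edges <- all_edges[ord, , drop = FALSE]
  rownames(all_edges) <- NULL
  edges <- switch(rule,
    abs_threshold = all_edges[abs(all_edges$pcor) >= threshold, , drop = FALSE],
    top_k = {
      if (is.null(k)) stop("rule 'top_k' needs k", call. = FALSE)
      if (k > p * (p - 1) / 2) {
        stop(sprintf("k = %d exceeds the %d possible edges", k, p * (p - 1) / 2),
             call. = FALSE)
      }
      all_edges[seq_len(k), , drop = FALSE]
    },
    perm_fdr = {
      if (is.null(network$features)) {
        stop("perm_fdr needs the feature matrix stored in the network object",
             call. = FALSE)
      }
      null_abs <- permutation_null(network, B = B, seed = seed)
      obs <- abs(all_edges$pcor)
      m <- length(obs)
      # empirical FDR at each observed cutoff: mean null exceedances / observed
      fdr <- vapply(obs, function(t)
        (sum(null_abs >= t) / B) / max(1, sum(obs >= t)), numeric(1))
      # enforce monotonicity (step-up over the sorted |rho|)
      fdr <- rev(cummin(rev(fdr)))
      keep <- which(fdr <= q)
      if (length(keep) == 0) all_edges[0, , drop = FALSE]
      else all_edges[seq_len(max(keep)), , drop = FALSE]
    })
  rownames(edges) <- NULL
  edges
}

# Pooled null |rho| from column-wise independent permutations at the
# network's own shrinkage intensity.
permutation_null <- function(network, B, seed) {
  x <- network$features
  n <- nrow(x)
  set.seed(as.integer(seed))
  unlist(lapply(seq_len(B), function(b) {
    xp <- apply(x, 2, function(col) col[sample.int(n)])
    rho <- partial_cor(stats::cor(xp), network$lambda)
    abs(rho[upper.tri(rho)])
  }))
}

#' Export a partial-correlation network
#'
#' Writes the selected edges in one of three formats: `graphml`
#' (Cytoscape-loadable; node attribute `kind`, edge attributes `weight` and
#' `sign`), `dot` (Graphviz; purple edges for positive and green for
#' negative partial correlations, `penwidth` proportional to \eqn{|\rho|}),
#' or `tsv` (plain edge list, lossless round trip via [read_edges()]).
#'
#' @param network A `tgx_ggm`.
#' @param edges Edge list from [select_edges()].
#' @param path Output file path.
#' @param format `"graphml"`, `"dot"` or `"tsv"`.
#' @export
export_network <- function(network, edges, path,
                           format = c("graphml", "dot", "tsv")) {
  format <- match.arg(format)
  switch(format,
    graphml = {
      g <- as_igraph(network, edges)
      igraph::write_graph(g, path, format = "graphml")
    },
    dot = writeLines(network_dot(network, edges), path),
    tsv = {
      out <- data.frame(from = edges$from, to = edges$to,
                        pcor = formatC(edges$pcor, format = "g", digits = 17),
                        stringsAsFactors = FALSE)
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  invisible(path)
}

network_dot <- function(network, edges) {
  esc <- function(x) gsub('"', '\\\\"', x)
  node_lines <- sprintf('  "%s" [kind=%s, shape=%s];',
                        esc(network$nodes$name), network$nodes$kind,
                        ifelse(network$nodes$kind == "phenotype", "box", "ellipse"))
  edge_lines <- sprintf('  "%s" -- "%s" [color=%s, penwidth=%.3f, weight="%.6g"];',
                        esc(edges$from), esc(edges$to),
                        ifelse(edges$pcor >= 0, "purple", "green"),
                        0.5 + 4 * abs(edges$pcor), edges$pcor)
  c("graph tgx_network {", "  overlap=false;", node_lines, edge_lines, "}")
}

#' Read a TSV edge list written by [export_network()]
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `from`, `to`, `pcor`.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$pcor <- as.numeric(df$pcor)
  df
}
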