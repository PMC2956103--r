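#' Read a log2 expression matrix and optional detection calls
#'
#' Reads a tab-delimited probe-by-sample matrix of log2 intensities and,
#' optionally, a matching matrix of Affymetrix-style detection calls
#' (`P`resent / `M`arginal / `A`bsent). Detection calls carry the per-probe
#' data-quality information used by the D-score; when no calls file is
#' supplied every call defaults to `P` (full quality), which makes the
#' D-score a pure mean-change score.
#'
#' @param path_values Path to a TSV file: first column probe IDs, header row
#'   sample IDs, cells log2 intensities.
#' @param path_calls Optional path to a TSV file of identical layout whose
#'   cells are detection-call tokens in `{P, M, A}`.
#' @param linear If `TRUE`, values are taken to be on the linear intensity
#'   scale and are transformed by `log2(pmax(x, 1))` on read.
#' @return An object of class `expression_bundle`: a list with components
#'   `values` (numeric matrix, probes x samples), `calls` (character matrix,
#'   same dimnames), `probe_ids`, `sample_ids`.
#' @examples
#' d <- tempfile(fileext = ".tsv")
#' write.table(matrix(rnorm(6, 8), 3, 2,
#'                    dimnames = list(c("p1", "p2", "p3"), c("S1", "S2"))),
#'             d, sep = "\t", quote = FALSE, col.names = NA)
#' b <- read_expression(d)
#' all(b$calls == "P")
#' @export
read_expression <- function(path_values, path_calls = NULL, linear = FALSE) {
  values <- read_keyed_tsv(path_values, numeric = TRUE)
  if (linear) values <- log2(pmax(values, 1))
  if (!is.null(path_calls)) {
    calls <- read_keyed_tsv(path_calls, numeric = FALSE)
    check_index_match(values, calls, "values", "calls")
    calls <- calls[rownames(values), colnames(values), drop = FALSE]
    bad <- !calls %in% c("P", "M", "A")
    if (any(bad)) {
      stop("invalid detection call token(s): ",
           paste(unique(calls[bad]), collapse = ", "),
           " (expected P, M or A)", call. = FALSE)
    }
  } else {
    calls <- matrix("P", nrow(values), ncol(values), dimnames = dimnames(values))
  }
  new_expression_bundle(values, calls)
}

new_expression_bundle <- function(values, calls) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyDuplicated(rownames(values))) stop("duplicate probe IDs", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs", call. = FALSE)
  if (!all(is.finite(values))) {
    ij <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at probe '%s', sample '%s'",
                 rownames(values)[ij[1]], colnames(values)[ij[2]]), call. = FALSE)
  }
  structure(list(values = values, calls = calls,
                 probe_ids = rownames(values), sample_ids = colnames(values)),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf("expression_bundle: %d probes x %d samples\n",
              length(x$probe_ids), length(x$sample_ids)))
  tab <- table(factor(x$calls, levels = c("P", "M", "A")))
  cat(sprintf("detection calls: P=%d M=%d A=%d\n", tab["P"], tab["M"], tab["A"]))
  invisible(x)
}

# Shared TSV reader: first column row key, header row of column keys.
read_keyed_tsv <- function(path, numeric) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = if (numeric) NA else "character",
                          comment.char = "#")
  m <- as.matrix(df)
  if (numeric && !is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                   m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                   colnames(m)[bad[1, 2]], path), call. = FALSE)
    }
    storage.mode(m) <- "double"
  }
  m
}

check_index_match <- function(a, b, name_a, name_b) {
  miss_b <- setdiff(colnames(a), colnames(b))
  miss_a <- setdiff(colnames(b), colnames(a))
  if (length(miss_a) || length(miss_b)) {
    stop(sprintf("sample headers differ between %s and %s (only in %s: %s; only in %s: %s)",
                 name_a, name_b,
                 name_a, paste(miss_b, collapse = ","),
                 name_b, paste(miss_a, collapse = ",")), call. = FALSE)
  }
  if (!setequal(rownames(a), rownames(b))) {
    stop(sprintf("probe IDs differ between %s and %s", name_a, name_b), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a gene-set collection from a GMT file
#'
#' Parses the Broad GMT dialect: one set per line,
#' `name TAB description TAB member TAB member ...`. Set order is preserved.
#' Duplicate members within one set are removed with a warning; a duplicated
#' set name is an error. Biomarker gene sets routinely share members, so
#' overlap *between* sets is allowed.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: a list with `sets`
#'   (named list of character vectors of probe IDs) and `descriptions`
#'   (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and >=1 member",
                   i, length(fields)), call. = FALSE)
    }
    name <- fields[1]
    if (name %in% names(sets)) {
      stop(sprintf("duplicate gene set name '%s' (GMT line %d)", name, i),
           call. = FALSE)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': %d duplicate member(s) removed", name,
                      sum(duplicated(members))), call. = FALSE)
      members <- unique(members)
    }
    sets[[name]] <- members
    descriptions[name] <- fields[2]
  }
  new_gene_set_collection(sets, descriptions)
}

new_gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(sets)), names(sets))
  if (anyDuplicated(names(sets))) stop("duplicate set names", call. = FALSE)
  if (any(lengths(sets) == 0)) {
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "), call. = FALSE)
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, member counts %s\n",
              length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an experimental design table
#'
#' The design table maps samples to treatment conditions. Required columns:
#' `sample_id`, `condition_id`, `role` (one of `control`, `treated`);
#' optional annotation columns `compound`, `dose`, `timepoint_h` are kept if
#' present. Every condition must have at least one control and one treated
#' sample, so group-mean log2 ratios are always defined.
#'
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame` of class `design_table`.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  new_design_table(df)
}

new_design_table <- function(df) {
  required <- c("sample_id", "condition_id", "role")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("design table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$role %in% c("control", "treated"))) {
    stop("design role must be 'control' or 'treated'", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in design", call. = FALSE)
  by_cond <- split(df$role, df$condition_id)
  bad <- names(by_cond)[!vapply(by_cond, function(r)
    any(r == "control") && any(r == "treated"), logical(1))]
  if (length(bad)) {
    stop("condition(s) without both control and treated samples: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("design_table", "data.frame")
  df
}

#' Read a phenotype changing-level table
#'
#' Conditions are rows, endpoints (organ weight, blood chemistry,
#' hematology parameters, ...) are columns; cells are signed changing levels
#' versus control on whatever scale the user supplies. Empty cells or `NA`
#' become explicit `NA` and are resolved listwise by the network module.
#'
#' @param path Path to a TSV file: first column condition IDs, header row
#'   endpoint names.
#' @return A numeric matrix (conditions x endpoints), possibly with `NA`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), comment.char = "#")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (any(is.infinite(m))) stop("infinite phenotype value", call. = FALSE)
  m
}

#' Write a score table to TSV
#'
#' Gene sets are rows, conditions are columns; values are written at full
#' double precision (17 significant digits) so a write/read round trip is
#' lossless.
#'
#' @param scores A `score_table` (see [score_all()]) or plain numeric matrix.
#' @param path Output path.
#' @param header_comments Optional character vector written as leading
#'   `#`-prefixed comment lines (provenance).
#' @export
write_scores <- function(scores, path, header_comments = NULL) {
  m <- unclass(scores)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  con <- file(path, "wb")  # binary: force LF line endings on every platform
  on.exit(close(con))
  if (!is.null(header_comments)) {
    writeLines(paste0("# ", header_comments), con, sep = "\n")
  }
  writeLines(paste(c("gene_set", colnames(m)), collapse = "\t"), con, sep = "\n")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], trimws(formatC(m[i, ], format = "g", digits = 17))),
          collapse = "\t")
  }, character(1))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path Path to the TSV file.
#' @return A `score_table` matrix (gene sets x conditions).
#' @export
read_scores <- function(path) {
  m <- read_keyed_tsv(path, numeric = TRUE)
  new_score_table(m, method = "unknown", scale = NA_real_)
}

# Write a keyed matrix (first column = row key) as LF-terminated TSV at
# full precision. Used by the writers below.
write_keyed_tsv <- function(m, path, key_name) {
  con <- file(path, "wb")
  on.exit(close(con))
  fmt <- function(v) {
    if (!is.numeric(v)) return(v)
    out <- trimws(formatC(v, format = "g", digits = 17))
    out[is.na(v)] <- "NA"
    out
  }
  writeLines(paste(c(key_name, colnames(m)), collapse = "\t"), con, sep = "\n")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"), character(1))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Write an expression bundle to disk
#'
#' Writes the values matrix and (unless all-Present) the calls matrix as
#' TSV files that [read_expression()] reads back losslessly.
#'
#' @param bundle An `expression_bundle`.
#' @param path_values Output path for the values TSV.
#' @param path_calls Optional output path for the calls TSV.
#' @export
write_expression <- function(bundle, path_values, path_calls = NULL) {
  write_keyed_tsv(bundle$values, path_values, "probe_id")
  if (!is.null(path_calls)) write_keyed_tsv(bundle$calls, path_calls, "probe_id")
  invisible(path_values)
}

#' Write a design table
#'
#' @param design A `design_table`.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(design), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(lapply(design, as.character), sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Write a phenotype table
#'
#' @param phenos Numeric matrix, conditions x endpoints.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenos, path) {
  write_keyed_tsv(phenos, path, "condition_id")
}
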