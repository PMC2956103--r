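# Gene set-level scoring: TGP1 score and quality-weighted D-score.
#
# Both scores start from one GeneChangeTable per condition: the per-probe
# signed effect e_i (mean treated log2 minus mean control log2) and a
# quality weight w_i in [0, 1] derived from detection calls.

CALL_WEIGHTS <- c(P = 1.0, M = 0.5, A = 0.0)

#' Per-probe expression changes and quality weights for one condition
#'
#' For each probe, the effect is the mean log2 value over the condition's
#' treated samples minus the mean over its control samples (a log2 ratio on
#' group means). The quality weight is the mean detection-call weight over
#' *all* samples of the condition, with Present = 1, Marginal = 0.5,
#' Absent = 0 — so probes that are mostly undetected contribute little to a
#' quality-weighted score.
#'
#' @param bundle An `expression_bundle` from [read_expression()].
#' @param design A `design_table` from [read_design()].
#' @param condition A condition ID present in `design`.
#' @return A `data.frame` of class `gene_change_table` with columns
#'   `probe_id`, `effect`, `weight`, and attribute `condition`.
#' @examples
#' b <- new_expression_bundle(
#'   matrix(c(8, 8, 9, 9), 1, 4,
#'          dimnames = list("p1", paste0("S", 1:4))),
#'   matrix("P", 1, 4, dimnames = list("p1", paste0("S", 1:4))))
#' d <- new_design_table(data.frame(
#'   sample_id = paste0("S", 1:4), condition_id = "C1",
#'   role = rep(c("control", "treated"), each = 2)))
#' compute_changes(b, d, "C1")  # effect 1.0, weight 1.0
#' @export
compute_changes <- function(bundle, design, condition) {
  rows <- design[design$condition_id == condition, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown condition: ", condition, call. = FALSE)
  missing <- setdiff(rows$sample_id, bundle$sample_ids)
  if (length(missing)) {
    stop(sprintf("condition '%s': sample(s) not in expression data: %s",
                 condition, paste(missing, collapse = ", ")), call. = FALSE)
  }
  ctrl <- rows$sample_id[rows$role == "control"]
  trt <- rows$sample_id[rows$role == "treated"]
  v <- bundle$values[, rows$sample_id, drop = FALSE]
  if (!all(is.finite(v))) {
    bad <- rownames(v)[!apply(is.finite(v), 1, all)]
    stop(sprintf("condition '%s': non-finite value(s) for probe(s): %s",
                 condition, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  effect <- rowMeans(bundle$values[, trt, drop = FALSE]) -
    rowMeans(bundle$values[, ctrl, drop = FALSE])
  wm <- matrix(CALL_WEIGHTS[bundle$calls[, rows$sample_id, drop = FALSE]],
               nrow = nrow(bundle$values))
  weight <- rowMeans(wm)
  structure(
    data.frame(probe_id = bundle$probe_ids, effect = unname(effect),
               weight = unname(weight), stringsAsFactors = FALSE),
    class = c("gene_change_table", "data.frame"),
    condition = condition)
}

# Resolve a gene set against a change table; drops unknown probes with a
# warning, errors if nothing is left.
match_set_probes <- function(changes, set, set_name = "gene set") {
  idx <- match(set, changes$probe_id)
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    warning(sprintf("%s: %d probe(s) absent from the array were dropped",
                    set_name, dropped), call. = FALSE)
  }
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    stop(sprintf("%s: no member probe is present on the array", set_name),
         call. = FALSE)
  }
  idx
}

#' TGP1 score of a gene set
#'
#' The expression ratio-based score used in large-scale TGx screening: the
#' product of a direction index and a magnitude index over the probes of a
#' biomarker gene set. With n retained probes, n_up of them up-regulated
#' (e_i > 0) and n_down down-regulated (e_i < 0),
#' \deqn{D = (n_{up} - n_{down}) / n, \quad M = \frac{1}{n}\sum_i |e_i|,
#'   \quad TGP1 = D \times M.}
#' The sign follows the majority direction, the score approaches zero when
#' directions are divergent, and it grows with the magnitude of uniform
#' changes. Probes with e_i = 0 count in n but in neither n_up nor n_down.
#'
#' @param changes A `gene_change_table` from [compute_changes()].
#' @param set Character vector of member probe IDs.
#' @param set_name Label used in warnings/errors.
#' @return A single numeric score.
#' @examples
#' ch <- data.frame(probe_id = paste0("p", 1:4),
#'                  effect = c(1, 1, 1, -1), weight = 1)
#' tgp1_score(ch, paste0("p", 1:4))  # D = 0.5, M = 1 -> 0.5
#' @export
tgp1_score <- function(changes, set, set_name = "gene set") {
  idx <- match_set_probes(changes, set, set_name)
  e <- changes$effect[idx]
  n <- length(e)
  direction <- (sum(e > 0) - sum(e < 0)) / n
  magnitude <- mean(abs(e))
  direction * magnitude
}

#' Quality-weighted D-score of a gene set
#'
#' The differentially-expressed gene score weights each probe's log2 change
#' by its detection-call quality, so unreliable (Absent-call) measurements
#' are discounted:
#' \deqn{D\text{-}score = C \cdot \frac{1}{n} \sum_{i \in set} w_i e_i}
#' with scale constant C (default 10, so a uniform 2-fold change at full
#' quality scores 10, and the conventional radar-chart reference circle sits
#' at 20, i.e. a uniform 4-fold change). The score is signed: up-regulated
#' sets score positive, down-regulated sets negative.
#'
#' @inheritParams tgp1_score
#' @param C Scale constant (default 10).
#' @return A single numeric score.
#' @examples
#' ch <- data.frame(probe_id = c("p1", "p2"), effect = c(2, 2), weight = 1)
#' d_score(ch, c("p1", "p2"))  # 20
#' @export
d_score <- function(changes, set, C = 10, set_name = "gene set") {
  idx <- match_set_probes(changes, set, set_name)
  C * mean(changes$weight[idx] * changes$effect[idx])
}

new_score_table <- function(m, method, scale) {
  stopifnot(is.matrix(m), is.numeric(m))
  structure(m, method = method, scale = scale,
            class = c("score_table", "matrix", "array"))
}

#' Score every gene set under every condition
#'
#' Computes the dense gene set x condition score matrix that drives all
#' downstream presentation and network inference. Deterministic: the same
#' inputs always produce the identical table.
#'
#' @param bundle An `expression_bundle`.
#' @param design A `design_table`.
#' @param sets A `gene_set_collection`.
#' @param method `"dscore"` (quality-weighted, default) or `"tgp1"`.
#' @param C Scale constant for the D-score; ignored for TGP1.
#' @param min_abs_effect Optional per-probe filter: probes with
#'   `|effect| < min_abs_effect` are excluded from scoring (default 0,
#'   i.e. no filtering).
#' @return A `score_table`: numeric matrix (sets x conditions) with
#'   attributes `method` and `scale`.
#' @export
score_all <- function(bundle, design, sets, method = c("dscore", "tgp1"),
                      C = 10, min_abs_effect = 0) {
  method <- match.arg(method)
  conditions <- unique(design$condition_id)
  out <- matrix(NA_real_, length(sets$sets), length(conditions),
                dimnames = list(names(sets$sets), conditions))
  for (cond in conditions) {
    changes <- tryCatch(compute_changes(bundle, design, cond), error = function(e)
      stop(sprintf("condition '%s': %s", cond, conditionMessage(e)), call. = FALSE))
    if (min_abs_effect > 0) {
      changes <- changes[abs(changes$effect) >= min_abs_effect, , drop = FALSE]
    }
    for (nm in names(sets$sets)) {
      out[nm, cond] <- tryCatch(
        if (method == "dscore") d_score(changes, sets$sets[[nm]], C = C, set_name = nm)
        else tgp1_score(changes, sets$sets[[nm]], set_name = nm),
        error = function(e) stop(sprintf("condition '%s': %s", cond,
                                         conditionMessage(e)), call. = FALSE))
    }
  }
  new_score_table(out, method = method,
                  scale = if (method == "dscore") C else NA_real_)
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table (%s%s): %d gene sets x %d conditions\n",
              attr(x, "method"),
              if (!is.na(attr(x, "scale"))) paste0(", C=", attr(x, "scale")) else "",
              nrow(x), ncol(x)))
  m <- unclass(x)
  attr(m, "method") <- attr(m, "scale") <- NULL
  print(utils::head(m, 6), digits = 3)
  if (nrow(x) > 6) cat(sprintf("... (%d more rows)\n", nrow(x) - 6))
  invisible(x)
}
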