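# Independent oracles and small fixture builders shared across test files.

# Brute-force partial correlation: correlation of the residuals of each
# pair of variables regressed on all remaining variables. Independent of
# the precision-inversion route used by the package.
pcor_bruteforce <- function(x) {
  p <- ncol(x)
  out <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- x[, -c(i, j), drop = FALSE]
      ri <- stats::residuals(stats::lm.fit(cbind(1, others), x[, i]))
      rj <- stats::residuals(stats::lm.fit(cbind(1, others), x[, j]))
      out[i, j] <- out[j, i] <- stats::cor(ri, rj)
    }
  }
  dimnames(out) <- list(colnames(x), colnames(x))
  out
}

# Canonical undirected edge keys for precision/recall computations.
edge_keys <- function(from, to) paste(pmin(from, to), pmax(from, to))

# Minimal in-memory expression fixture: explicit values/calls matrices and
# a one-condition design.
tiny_bundle <- function(values, calls = NULL) {
  if (is.null(calls)) {
    calls <- matrix("P", nrow(values), ncol(values), dimnames = dimnames(values))
  }
  tgxtools:::new_expression_bundle(values, calls)
}

tiny_design <- function(samples, roles, condition = "C1") {
  tgxtools:::new_design_table(data.frame(
    sample_id = samples, condition_id = condition, role = roles,
    stringsAsFactors = FALSE))
}

# A gene-change table straight from effects/weights (bypasses expression).
tiny_changes <- function(effect, weight = rep(1, length(effect)),
                         probes = sprintf("p%03d", seq_along(effect))) {
  data.frame(probe_id = probes, effect = effect, weight = weight,
             stringsAsFactors = FALSE)
}

# Write a small GMT with n sets of the given members.
write_tiny_gmt <- function(path, sets) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  path
}
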