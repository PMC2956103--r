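# Seeded synthetic-data generators with planted ground truth, at two
# levels: probe-level expression with perturbed biomarker sets (exercises
# the scoring path) and condition-level features drawn from a known sparse
# precision matrix (exercises GGM edge recovery), plus an end-to-end
# hepatotoxicant-like time course.

#' Simulation configuration for synthetic expression data
#'
#' Collects the knobs of the expression generator with defaults emulating a
#' small Affymetrix-style rat-liver study: 58 biomarker gene sets of 10-20
#' probes, 3 replicates per group, log2 baselines around 8 +/- 1.5,
#' replicate noise SD 0.3 log2 units, and a detection-call model in which
#' the probability of a Present call rises logistically with log2 intensity
#' (midpoint 6, scale 1), so dim probes carry low quality weights.
#'
#' @param n_sets Number of gene sets.
#' @param set_size Length-2 integer range of probes per set.
#' @param n_extra_probes Background probes belonging to no set.
#' @param replicates Samples per group (control and treated each).
#' @param baseline_mean,baseline_sd Mean/SD of per-probe baseline log2 intensity.
#' @param noise_sd Replicate noise SD (log2).
#' @param perturbed Named numeric vector of planted log2 effects per set
#'   (positive = up in treated), or a matrix with one column per timepoint.
#' @param timepoints Numeric vector of timepoints (hours); one condition each.
#' @param call_midpoint,call_scale Logistic parameters of the Present-call
#'   probability as a function of log2 intensity.
#' @param marginal_band Half-width (log2) of the intensity band around
#'   `call_midpoint` where a non-Present call is Marginal rather than Absent.
#' @param overlap If `TRUE`, sets share 20% of members with their neighbour
#'   set; by default sets are disjoint so recovery checks are crisp.
#' @param seed Integer seed; fully determines all generator output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_sets = 58, set_size = c(10, 20),
                              n_extra_probes = 100, replicates = 3,
                              baseline_mean = 8, baseline_sd = 1.5,
                              noise_sd = 0.3, perturbed = NULL,
                              timepoints = 24, call_midpoint = 6,
                              call_scale = 1, marginal_band = 1,
                              overlap = FALSE, seed = 1L) {
  stopifnot(n_sets >= 1, length(set_size) == 2, set_size[1] >= 1,
            set_size[2] >= set_size[1], replicates >= 1,
            baseline_sd >= 0, noise_sd >= 0, call_scale > 0,
            marginal_band >= 0, length(timepoints) >= 1)
  cfg <- list(n_sets = n_sets, set_size = as.integer(set_size),
              n_extra_probes = n_extra_probes, replicates = replicates,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, perturbed = perturbed,
              timepoints = timepoints, call_midpoint = call_midpoint,
              call_scale = call_scale, marginal_band = marginal_band,
              overlap = overlap, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# Expand cfg$perturbed into a full n_sets x n_timepoints delta matrix.
perturbation_matrix <- function(cfg, set_names, cond_names) {
  delta <- matrix(0, length(set_names), length(cond_names),
                  dimnames = list(set_names, cond_names))
  p <- cfg$perturbed
  if (is.null(p)) return(delta)
  if (is.matrix(p)) {
    if (ncol(p) != length(cond_names)) {
      stop("perturbation matrix needs one column per timepoint", call. = FALSE)
    }
    bad <- setdiff(rownames(p), set_names)
    if (length(bad)) stop("perturbed set(s) not generated: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    delta[rownames(p), ] <- p
  } else {
    bad <- setdiff(names(p), set_names)
    if (length(bad)) stop("perturbed set(s) not generated: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    delta[names(p), ] <- p  # same effect at every timepoint
  }
  delta
}

#' Simulate an expression study with planted gene-set perturbations
#'
#' Generates probe-level log2 expression for one condition per timepoint
#' (each with matched control and treated replicates), a design table, a
#' gene-set collection, and the planted ground truth. Per probe, a baseline
#' log2 intensity is drawn once; each sample adds Gaussian replicate noise,
#' and treated samples of a perturbed set add the planted log2 effect
#' delta. Detection calls are drawn per cell: Present with probability
#' `plogis((value - midpoint) / scale)`, otherwise Marginal inside the
#' `marginal_band` around the midpoint and Absent outside it.
#'
#' @param cfg A [simulation_config()].
#' @param set_names Optional character vector of gene-set names (default
#'   `set01 ...`).
#' @return A list with components `bundle` (`expression_bundle`), `design`
#'   (`design_table`), `sets` (`gene_set_collection`), and `truth` (list
#'   with the planted `delta` matrix, sets x conditions).
#' @examples
#' sim <- simulate_expression(simulation_config(
#'   n_sets = 5, perturbed = c(set01 = 1), seed = 7))
#' st <- score_all(sim$bundle, sim$design, sim$sets)
#' which.max(abs(st[, 1]))  # set01
#' @export
simulate_expression <- function(cfg, set_names = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  if (is.null(set_names)) {
    set_names <- sprintf("set%02d", seq_len(cfg$n_sets))
  }
  stopifnot(length(set_names) == cfg$n_sets)

  sizes <- sample(seq(cfg$set_size[1], cfg$set_size[2]), cfg$n_sets,
                  replace = TRUE)
  n_probes <- sum(sizes) + cfg$n_extra_probes
  probe_ids <- sprintf("p%05d", seq_len(n_probes))
  bounds <- cumsum(c(0, sizes))
  sets <- lapply(seq_len(cfg$n_sets), function(i)
    probe_ids[(bounds[i] + 1):bounds[i + 1]])
  names(sets) <- set_names
  if (cfg$overlap && cfg$n_sets > 1) {
    # each set borrows ~20% of its members from the next set
    for (i in seq_len(cfg$n_sets - 1)) {
      n_share <- max(1, floor(0.2 * sizes[i]))
      sets[[i]][seq_len(n_share)] <- sets[[i + 1]][seq_len(min(n_share, sizes[i + 1]))]
      sets[[i]] <- unique(sets[[i]])
    }
  }
  collection <- new_gene_set_collection(
    sets, setNames(rep("synthetic biomarker set", cfg$n_sets), set_names))

  cond_names <- sprintf("T%02dh", cfg$timepoints)
  delta <- perturbation_matrix(cfg, set_names, cond_names)
  # probe x condition planted effect (probes in no set get 0)
  probe_delta <- matrix(0, n_probes, length(cond_names),
                        dimnames = list(probe_ids, cond_names))
  for (nm in set_names) probe_delta[sets[[nm]], ] <-
    probe_delta[sets[[nm]], , drop = FALSE] + rep(delta[nm, ], each = length(sets[[nm]]))

  r <- cfg$replicates
  design <- do.call(rbind, lapply(cond_names, function(cn) {
    data.frame(
      sample_id = paste0(cn, "_", rep(c("ctl", "trt"), each = r), seq_len(r)),
      condition_id = cn,
      role = rep(c("control", "treated"), each = r),
      compound = "synthetic", dose = "single",
      timepoint_h = cfg$timepoints[match(cn, cond_names)],
      stringsAsFactors = FALSE)
  }))
  design <- new_design_table(design)

  baseline <- stats::rnorm(n_probes, cfg$baseline_mean, cfg$baseline_sd)
  n_samp <- nrow(design)
  values <- baseline +
    matrix(stats::rnorm(n_probes * n_samp, 0, cfg$noise_sd), n_probes, n_samp)
  treated <- design$role == "treated"
  values[, treated] <- values[, treated] +
    probe_delta[, design$condition_id[treated], drop = FALSE]
  dimnames(values) <- list(probe_ids, design$sample_id)

  p_present <- stats::plogis((values - cfg$call_midpoint) / cfg$call_scale)
  u <- matrix(stats::runif(length(values)), nrow(values))
  calls <- ifelse(u < p_present, "P",
                  ifelse(abs(values - cfg$call_midpoint) < cfg$marginal_band,
                         "M", "A"))
  dimnames(calls) <- dimnames(values)

  list(bundle = new_expression_bundle(values, calls),
       design = design, sets = collection,
       truth = list(delta = delta, config = cfg))
}

#' Random sparse precision matrix with planted edges
#'
#' Places `n_edges` off-diagonal entries at random positions with random
#' signs and magnitudes uniform in `magnitude`, unit diagonal, then adds
#' the minimal ridge needed to make the matrix positive definite
#' (smallest eigenvalue at least `min_eigen`).
#'
#' @param p Number of variables.
#' @param n_edges Number of planted edges.
#' @param magnitude Length-2 range of absolute off-diagonal values.
#' @param min_eigen Smallest allowed eigenvalue after the ridge.
#' @param seed Integer seed.
#' @return A list: `omega` (p x p precision matrix), `edges` (data.frame of
#'   planted pairs `i`, `j`), and `pcor` (population partial correlations).
#' @export
random_precision <- function(p, n_edges, magnitude = c(0.2, 0.4),
                             min_eigen = 0.05, seed = 1L) {
  stopifnot(n_edges <= p * (p - 1) / 2)
  set.seed(as.integer(seed))
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  pick <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
  omega <- diag(p)
  vals <- sample(c(-1, 1), n_edges, replace = TRUE) *
    stats::runif(n_edges, magnitude[1], magnitude[2])
  omega[pick] <- vals
  omega[pick[, 2:1, drop = FALSE]] <- vals
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < min_eigen) omega <- omega + (min_eigen - ev) * diag(p)
  dimnames(omega) <- list(paste0("V", seq_len(p)), paste0("V", seq_len(p)))
  d <- sqrt(diag(omega))
  pcor <- -omega / tcrossprod(d)
  diag(pcor) <- 1
  list(omega = omega,
       edges = data.frame(i = pick[, 1], j = pick[, 2]),
       pcor = pcor)
}

#' Simulate condition-level features from a known Gaussian graphical model
#'
#' Draws `n_conditions` i.i.d. rows from the multivariate normal with
#' covariance equal to the inverse of `omega`, so the nonzero off-diagonal
#' precision entries are exactly the network's true edges and the
#' population partial correlations are
#' \eqn{-\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}}.
#'
#' @param n_conditions Number of rows (conditions) to draw.
#' @param omega Symmetric positive-definite precision matrix.
#' @param seed Integer seed.
#' @param n_phenotypes How many trailing columns to label as phenotype
#'   endpoints (the rest are gene-set scores).
#' @return A list: `features` (matrix with `kinds` attribute), `truth`
#'   (list with `omega`, true `edges`, population `pcor`).
#' @export
simulate_features <- function(n_conditions, omega, seed = 1L,
                              n_phenotypes = 0) {
  stopifnot(is.matrix(omega), nrow(omega) == ncol(omega),
            max(abs(omega - t(omega))) < 1e-12)
  p <- nrow(omega)
  ch <- tryCatch(chol(omega), error = function(e)
    stop("precision matrix is not positive definite", call. = FALSE))
  sigma <- chol2inv(ch)
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n_conditions * p), n_conditions, p)
  x <- z %*% chol(sigma)
  nm <- colnames(omega)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  colnames(x) <- nm
  rownames(x) <- sprintf("cond%03d", seq_len(n_conditions))
  kinds <- rep(c("gene_set", "phenotype"),
               c(p - n_phenotypes, n_phenotypes))
  attr(x, "kinds") <- setNames(kinds, nm)
  ut <- which(upper.tri(omega) & omega != 0, arr.ind = TRUE)
  d <- sqrt(diag(omega))
  pcor <- -omega / tcrossprod(d)
  diag(pcor) <- 1
  list(features = x,
       truth = list(omega = omega,
                    edges = data.frame(i = ut[, 1], j = ut[, 2],
                                       from = nm[ut[, 1]], to = nm[ut[, 2]]),
                    pcor = pcor))
}

# Named biomarker-like sets of the hepatotoxicant case study and their
# planted log2-effect schedule over the 2/6/12/24 h time course:
# glutathione depletion and DNA damage lead at 6 h, oxidative stress and
# inflammation rise at 12 h together with feedback activation of
# glutathione homeostasis, inflammation peaks at 24 h while the energy
# metabolism sets (cholesterol synthesis, glycolysis) are suppressed.
case_study_schedule <- function() {
  tp <- c(2, 6, 12, 24)
  sched <- rbind(
    glutathione_depletion   = c(0.5, 1.6, 0.8, 0.6),
    DNA_damage              = c(0.0, 1.3, 0.8, 1.5),
    oxidative_stress        = c(0.0, 0.0, 1.5, 1.0),
    inflammation            = c(0.0, 0.0, 1.2, 2.0),
    glutathione_homeostasis = c(0.0, 0.0, 1.0, 0.8),
    cholesterol_synthesis   = c(0.0, 0.0, -0.4, -1.2),
    glycolysis              = c(0.0, 0.0, -0.3, -1.0))
  colnames(sched) <- sprintf("T%02dh", tp)
  list(timepoints = tp, delta = sched)
}

#' Simulate a hepatotoxicant-like time-course case study
#'
#' Generates a four-timepoint (2, 6, 12, 24 h) study of 58 gene sets in
#' which seven named sets follow a planted mechanistic schedule: an early
#' glutathione-depletion / DNA-damage signal at 6 h, oxidative stress and
#' inflammation at 12 h with compensatory glutathione-homeostasis
#' activation, peak inflammation at 24 h, and down-regulated energy
#' metabolism (cholesterol synthesis, glycolysis) at 24 h. The remaining 51
#' sets are unperturbed background. The planted schedule is returned as
#' ground truth so the pattern is assertable.
#'
#' @param seed Integer seed.
#' @param dir Optional directory; when given, all tables (expression,
#'   calls, design, GMT, planted schedule) are written there as TSV/GMT.
#' @param cfg Optional [simulation_config()] override; its `perturbed`,
#'   `timepoints` and `seed` fields are replaced by the case-study schedule.
#' @return As [simulate_expression()], plus `paths` when `dir` is given.
#' @export
simulate_case_study <- function(seed = 1L, dir = NULL, cfg = NULL) {
  sched <- case_study_schedule()
  n_named <- nrow(sched$delta)
  if (is.null(cfg)) cfg <- simulation_config()
  cfg$perturbed <- sched$delta
  cfg$timepoints <- sched$timepoints
  cfg$seed <- as.integer(seed)
  set_names <- c(rownames(sched$delta),
                 sprintf("background_%02d", seq_len(cfg$n_sets - n_named)))
  sim <- simulate_expression(cfg, set_names = set_names)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(values = file.path(dir, "expression.tsv"),
                  calls = file.path(dir, "calls.tsv"),
                  design = file.path(dir, "design.tsv"),
                  gmt = file.path(dir, "gene_sets.gmt"),
                  truth = file.path(dir, "planted_schedule.tsv"))
    write_expression(sim$bundle, paths$values, paths$calls)
    write_design(sim$design, paths$design)
    write_gmt(sim$sets, paths$gmt)
    write_keyed_tsv(sim$truth$delta, paths$truth, "gene_set")
    sim$paths <- paths
  }
  sim
}
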