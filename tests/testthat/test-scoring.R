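test_that("per-probe changes are group-mean log2 ratios with call-mean weights", {
  samples <- paste0("S", 1:4)
  v <- matrix(c(8, 8, 9, 9,      # p1: control 8, treated 9 -> effect 1
                7, 7, 7, 7,      # p2: no change
                5, 6, 8, 7), 3, 4, byrow = TRUE,
              dimnames = list(paste0("p", 1:3), samples))
  calls <- matrix("P", 3, 4, dimnames = dimnames(v))
  calls[2, ] <- c("P", "P", "A", "A")
  calls[3, ] <- c("M", "M", "M", "M")
  b <- tiny_bundle(v, calls)
  d <- tiny_design(samples, rep(c("control", "treated"), each = 2))

  ch <- compute_changes(b, d, "C1")
  expect_equal(ch$effect, c(1, 0, 2))
  expect_equal(ch$weight, c(1, 0.5, 0.5))  # mean over ALL 4 samples
  expect_identical(attr(ch, "condition"), "C1")
  expect_error(compute_changes(b, d, "C9"), "unknown condition")
})

test_that("TGP1 score multiplies majority direction by mean magnitude", {
  expect_equal(tgp1_score(tiny_changes(c(1, 1, 1, -1)),
                          sprintf("p%03d", 1:4)), 0.5)
  # no change scores zero; fully divergent scores zero at any magnitude
  expect_identical(tgp1_score(tiny_changes(c(0, 0, 0)), sprintf("p%03d", 1:3)), 0)
  expect_identical(tgp1_score(tiny_changes(c(2, -2)), sprintf("p%03d", 1:2)), 0)
  # zero effects count in n but in neither direction, pulling D toward 0
  expect_equal(tgp1_score(tiny_changes(c(1, 1, 0, 0)), sprintf("p%03d", 1:4)),
               (2 / 4) * (2 / 4))
})

test_that("D-score is the scaled quality-weighted mean change", {
  expect_equal(d_score(tiny_changes(c(2, 2)), sprintf("p%03d", 1:2)), 20)
  # all-Absent data is discounted entirely, whatever the apparent effect
  expect_identical(d_score(tiny_changes(c(5, 5), weight = c(0, 0)),
                           sprintf("p%03d", 1:2)), 0)
  # scale constant is linear
  expect_equal(d_score(tiny_changes(c(1, 3)), sprintf("p%03d", 1:2), C = 5), 10)
})

test_that("set membership is resolved against the array with warnings", {
  ch <- tiny_changes(c(1, 2), probes = c("p1", "p2"))
  expect_warning(s <- d_score(ch, c("p1", "p2", "ghost")), "1 probe")
  expect_equal(s, 15)
  expect_error(suppressWarnings(d_score(ch, c("ghostA", "ghostB"))),
               "no member probe")
})

test_that("score algebra: anti-symmetry, bounds, divergence, monotonicity", {
  set.seed(101)
  probes <- sprintf("p%03d", 1:12)
  for (rep in 1:50) {
    e <- rnorm(12, sd = 2)
    w <- runif(12)
    ch_pos <- tiny_changes(e, w)
    ch_neg <- tiny_changes(-e, w)
    # exact odd symmetry for both scores
    expect_identical(tgp1_score(ch_neg, probes), -tgp1_score(ch_pos, probes))
    expect_identical(d_score(ch_neg, probes), -d_score(ch_pos, probes))
    # |TGP1| <= max |e| since |D| <= 1 and M <= max|e|
    expect_lte(abs(tgp1_score(ch_pos, probes)), max(abs(e)) + 1e-15)
  }
  # symmetric +/- pairs give exactly zero for both scores
  e_sym <- c(1.3, -1.3, 0.4, -0.4, 2.2, -2.2)
  ch <- tiny_changes(e_sym)
  expect_identical(tgp1_score(ch, sprintf("p%03d", 1:6)), 0)
  expect_equal(d_score(ch, sprintf("p%03d", 1:6)), 0)
  # strict monotonicity in a uniform effect at full quality
  deltas <- c(0.2, 0.5, 1, 2, 4)
  tgp1 <- vapply(deltas, function(d)
    tgp1_score(tiny_changes(rep(d, 5)), sprintf("p%03d", 1:5)), numeric(1))
  ds <- vapply(deltas, function(d)
    d_score(tiny_changes(rep(d, 5)), sprintf("p%03d", 1:5)), numeric(1))
  expect_true(all(diff(tgp1) > 0) && all(diff(ds) > 0))
})

test_that("zero-weight probes affect the D-score only via the normalizer", {
  probes <- sprintf("p%03d", 1:4)
  base <- tiny_changes(c(1, 2, 3), weight = c(1, 0.5, 1),
                       probes = probes[1:3])
  with_dead <- tiny_changes(c(1, 2, 3, 50), weight = c(1, 0.5, 1, 0),
                            probes = probes)
  s3 <- d_score(base, probes[1:3])
  s4 <- d_score(with_dead, probes)
  # identical weighted sum, so the ratio is exactly n/(n+1)
  expect_equal(s4, s3 * 3 / 4)
})

test_that("score_all builds the dense set x condition table deterministically", {
  sim <- simulate_expression(simulation_config(
    n_sets = 6, set_size = c(4, 6), n_extra_probes = 10,
    timepoints = c(2, 6, 12, 24), perturbed = c(set01 = 1), seed = 4))
  st <- score_all(sim$bundle, sim$design, sim$sets)
  expect_equal(dim(st), c(6, 4))
  expect_identical(rownames(st), names(sim$sets$sets))
  expect_identical(attr(st, "method"), "dscore")
  st2 <- score_all(sim$bundle, sim$design, sim$sets)
  expect_identical(unclass(st), unclass(st2))
  # tgp1 variant shares the shape, differs in values
  st_t <- score_all(sim$bundle, sim$design, sim$sets, method = "tgp1")
  expect_identical(attr(st_t, "method"), "tgp1")
  expect_false(identical(unclass(st), unclass(st_t)))
  # the min-abs-effect filter drops small effects before scoring; with a
  # mild cutoff scores change but every set keeps some probes
  st_f <- suppressWarnings(
    score_all(sim$bundle, sim$design, sim$sets, min_abs_effect = 0.01))
  expect_false(identical(unclass(st_f), unclass(st)))
  # a cutoff beyond every effect empties the sets, which is an error
  expect_error(suppressWarnings(
    score_all(sim$bundle, sim$design, sim$sets, min_abs_effect = 10)),
    "no member probe")
})

test_that("identical treated and control values give an all-zero column", {
  samples <- paste0("S", 1:4)
  v <- matrix(8, 4, 4, dimnames = list(paste0("p", 1:4), samples))
  b <- tiny_bundle(v)
  d <- tiny_design(samples, rep(c("control", "treated"), each = 2))
  gs <- tgxtools:::new_gene_set_collection(
    list(s1 = c("p1", "p2"), s2 = c("p3", "p4")))
  st <- score_all(b, d, gs)
  expect_true(all(st == 0))
})
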