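test_that("feature assembly intersects, drops, standardizes", {
  set.seed(7)
  st <- tgxtools:::new_score_table(
    matrix(rnorm(5 * 10), 5, 10,
           dimnames = list(paste0("set", 1:5), paste0("C", 1:10))),
    method = "dscore", scale = 10)
  ph <- matrix(rnorm(8 * 2), 8, 2,
               dimnames = list(paste0("C", 1:8), c("ALT", "liver_weight")))
  ph["C3", "ALT"] <- NA

  expect_message(x <- assemble_features(st, ph), "dropped")
  # conditions intersected to C1..C8, then C3 dropped listwise
  expect_equal(nrow(x), 7)
  expect_equal(ncol(x), 7)
  expect_false("C3" %in% rownames(x))
  expect_equal(unname(attr(x, "kinds")),
               c(rep("gene_set", 5), rep("phenotype", 2)))
  # standardized columns: mean 0, unit variance within 1e-10
  expect_lt(max(abs(colMeans(x))), 1e-10)
  expect_lt(max(abs(apply(x, 2, sd) - 1)), 1e-10)

  # scores alone: all columns are gene sets
  x2 <- assemble_features(st)
  expect_true(all(attr(x2, "kinds") == "gene_set"))

  # constant phenotype column dropped with a warning
  ph2 <- ph; ph2[, "ALT"] <- 1
  expect_warning(x3 <- suppressMessages(assemble_features(st, ph2)),
                 "zero-variance")
  expect_false("ALT" %in% colnames(x3))

  # duplicate feature names across blocks are refused
  ph3 <- ph; colnames(ph3)[1] <- "set1"
  expect_error(assemble_features(st, ph3), "duplicate feature")

  # too little overlap is an error
  ph4 <- matrix(rnorm(4), 2, 2,
                dimnames = list(c("C1", "C2"), c("A", "B")))
  expect_error(assemble_features(st, ph4), "fewer than 3")
})

test_that("partial correlations hit the equicorrelation closed form", {
  # p features at pairwise correlation r give pcor r / (1 + (p-2) r)
  for (p in c(3, 5, 8)) {
    for (r in c(0.2, 0.5, 0.7)) {
      S <- matrix(r, p, p); diag(S) <- 1
      rho <- partial_cor(S, lambda = 0)
      expect_equal(unname(rho[1, 2]), r / (1 + (p - 2) * r), tolerance = 1e-12)
    }
  }
  # exact 1/3 in the classic 3-variable half-correlation case
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  expect_equal(unname(partial_cor(S)[upper.tri(S)]), rep(1 / 3, 3),
               tolerance = 1e-14)
})

test_that("estimates match the regression-residual oracle at lambda = 0", {
  set.seed(11)
  for (p in c(4, 6, 8)) {
    gt <- random_precision(p, p, magnitude = c(0.2, 0.4), seed = p)
    x <- simulate_features(5000, gt$omega, seed = p + 50)$features
    net <- estimate_pcor(x, lambda = 0)
    expect_lt(max(abs(net$pcor - pcor_bruteforce(x))), 1e-8)
  }
})

test_that("shrinkage behaves at its limits and is continuous", {
  set.seed(13)
  x <- matrix(rnorm(60 * 5), 60, 5)
  S <- cor(x)
  # full shrinkage collapses the network to the identity
  expect_equal(partial_cor(S, lambda = 1), diag(5), ignore_attr = TRUE)
  lambdas <- seq(0, 1, by = 0.05)
  paths <- sapply(lambdas, function(l) partial_cor(S, l)[1, 2])
  expect_lt(max(abs(diff(paths))), 0.15)     # no jumps along the path
  expect_equal(paths[length(paths)], 0)
  # independent features at large n have near-zero partial correlations
  xz <- matrix(rnorm(4000 * 6), 4000, 6)
  rho <- estimate_pcor(xz, lambda = 0)$pcor
  expect_lt(max(abs(rho[upper.tri(rho)])), 4 / sqrt(4000))
  # analytic lambda: near-total shrinkage for pure noise, light shrinkage
  # for strongly structured data at large n
  l_noise <- shrinkage_lambda(xz[1:20, ])
  expect_true(l_noise >= 0 && l_noise <= 1)
  expect_gt(l_noise, 0.5)
  gt <- random_precision(6, 8, seed = 99)
  xr <- simulate_features(2000, gt$omega, seed = 100)$features
  expect_lt(shrinkage_lambda(xr), 0.1)
  # singular case without shrinkage advises lambda > 0
  xs <- matrix(rnorm(4 * 10), 4, 10)  # p > n
  expect_error(estimate_pcor(xs, lambda = 0), "lambda > 0")
})

test_that("edge selection rules honor their contracts", {
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[3, 4] <- rho[4, 3] <- 0.01
  dimnames(rho) <- list(paste0("V", 1:4), paste0("V", 1:4))
  net <- structure(list(pcor = rho, lambda = 0,
                        nodes = data.frame(name = paste0("V", 1:4),
                                           kind = "gene_set"),
                        n = 10, p = 4, features = NULL),
                   class = "tgx_ggm")
  e <- select_edges(net, "abs_threshold", threshold = 0.1)
  expect_equal(nrow(e), 1)
  expect_equal(e$pcor, 0.9)

  e3 <- select_edges(net, "top_k", k = 3)
  expect_equal(nrow(e3), 3)
  expect_equal(e3$pcor[1], 0.9)           # ordered by |rho|
  expect_error(select_edges(net, "top_k", k = 7), "exceeds")
})

test_that("permutation FDR is seeded, reproducible and calibrated", {
  set.seed(29)
  x <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(NULL, paste0("V", 1:10)))
  net <- estimate_pcor(x, lambda = 0)
  e1 <- select_edges(net, "perm_fdr", q = 0.05, B = 100, seed = 77)
  e2 <- select_edges(net, "perm_fdr", q = 0.05, B = 100, seed = 77)
  expect_identical(e1, e2)
  # independent features: at most a handful of the 45 pairs survive
  counts <- vapply(1:10, function(s) {
    xs <- matrix(rnorm(100 * 10), 100, 10,
                 dimnames = list(NULL, paste0("V", 1:10)))
    nets <- estimate_pcor(xs, lambda = 0)
    nrow(select_edges(nets, "perm_fdr", q = 0.05, B = 100, seed = s))
  }, numeric(1))
  expect_lt(mean(counts), 0.05 * 45 + 2)
})

test_that("network export round-trips and encodes sign", {
  set.seed(31)
  gt <- random_precision(5, 5, seed = 3)
  net <- estimate_pcor(simulate_features(200, gt$omega, seed = 4)$features,
                       lambda = 0.1)
  edges <- select_edges(net, "top_k", k = 5)

  # TSV round trip is exact
  f <- tempfile(fileext = ".tsv")
  export_network(net, edges, f, "tsv")
  back <- read_edges(f)
  expect_equal(back$from, edges$from)
  expect_equal(back$pcor, edges$pcor, tolerance = 1e-14)

  # GraphML is loadable and carries node kinds and edge weights
  fg <- tempfile(fileext = ".graphml")
  export_network(net, edges, fg, "graphml")
  g <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::gorder(g), 5)
  expect_equal(igraph::gsize(g), 5)
  expect_equal(sort(igraph::E(g)$weight), sort(edges$pcor), tolerance = 1e-6)
  expect_true(all(igraph::V(g)$kind %in% c("gene_set", "phenotype")))

  # DOT encodes positive edges purple and negative green, width by |rho|
  fake <- edges[1:2, ]
  fake$pcor <- c(0.6, -0.4)
  fd <- tempfile(fileext = ".dot")
  export_network(net, fake, fd, "dot")
  dot <- readLines(fd)
  expect_true(any(grepl("color=purple", dot)))
  expect_true(any(grepl("color=green", dot)))
  expect_error(export_network(net, edges, tempfile(), "bogus"))
})

test_that("the fitted GGM object behaves like a model object", {
  set.seed(37)
  gt <- random_precision(6, 6, seed = 8)
  net <- estimate_pcor(simulate_features(120, gt$omega, seed = 9)$features)
  expect_s3_class(net, "tgx_ggm")
  expect_identical(coef(net), net$pcor)
  expect_output(print(net), "tgx_ggm")
  expect_output(s <- summary(net, threshold = 0.15), "edge")
  f <- tempfile(fileext = ".png")
  png(f); plot(net); dev.off()
  expect_true(file.exists(f))
})
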