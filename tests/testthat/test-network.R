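# Co-expression network construction and degree centrality.

test_that("log transform is log2(x + 1) on nonnegative input", {
  expect_equal(log_transform(matrix(c(0, 1, 7, 3), 1)),
               matrix(c(0, 1, 3, 2), 1))
  expect_error(log_transform(matrix(c(1, -0.1), 1)), "nonnegative")
  expect_error(log_transform(matrix(c(1, NA), 1)), "missing")
})

test_that("edges follow the signed correlation threshold", {
  x <- c(1, 2, 3, 4, 5)
  m <- rbind(a = x, b = x + 10,      # r = 1
             c = -x,                 # r = -1 with a, b
             d = c(2, 1, 4, 3, 6))   # positively but imperfectly correlated
  net <- pearson_network(m, threshold = 0.7)
  expect_true(net$adjacency["a", "b"])
  # anti-correlation never makes an edge under the signed convention
  expect_false(net$adjacency["a", "c"])
  expect_false(net$adjacency["c", "b"])
  expect_true(isSymmetric(net$adjacency))
  expect_false(any(diag(net$adjacency)))
  expect_error(pearson_network(m[, 1:2]), "3 samples")
})

test_that("two identical pairs with zero cross-correlation give degrees 1,1,1,1", {
  x <- c(1, 2, 3, 4)
  y <- c(1, -1, -1, 1)  # exactly uncorrelated with x
  m <- rbind(g1 = x, g2 = x * 2 + 1, g3 = y, g4 = y * 3 - 2)
  expect_equal(cor(x, y), 0)
  net <- pearson_network(m, threshold = 0.7)
  deg <- degree_and_neighbors(net)
  expect_equal(deg$degree, rep(1L, 4))
  expect_equal(deg$neighbors[[1]], "g2")
  expect_equal(deg$neighbors[[3]], "g4")
})

test_that("the network is invariant to positive affine gene transforms", {
  x <- gen_expression(expression_sim_config(n_genes = 12, n_samples = 30,
                                            module_assignment = c(rep(1L, 6),
                                                                  rep(NA, 6)),
                                            seed = 97))
  L <- log_transform(x)
  net1 <- pearson_network(L)
  scale <- runif(12, 0.5, 3)
  shift <- rnorm(12)
  net2 <- pearson_network(L * scale + shift)
  expect_equal(net1$adjacency, net2$adjacency)
})

test_that("zero-variance genes are dropped, not fatal", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), flat = rep(5, 4))
  expect_message(net <- pearson_network(m), "zero-variance")
  expect_equal(net$dropped, "flat")
  expect_setequal(net$genes, c("a", "b"))
})

test_that("degree equals a brute-force row scan; unknown genes suggest names", {
  x <- gen_expression(expression_sim_config(seed = 101))
  net <- pearson_network(log_transform(x))
  deg <- degree_and_neighbors(net)
  for (g in sample(net$genes, 5)) {
    row <- net$r[g, ]
    expect_equal(deg$degree[deg$gene == g],
                 sum(row[names(row) != g] >= net$threshold))
  }
  one <- degree_and_neighbors(net, focal = net$genes[1])
  expect_equal(one$degree, length(one$neighbors))
  expect_error(degree_and_neighbors(net, focal = "GENE0001X"), "closest matches")
})

test_that("a tight synthetic module is (almost) fully connected", {
  full <- vapply(1:20, function(s) {
    x <- gen_expression(expression_sim_config(
      n_genes = 5, n_samples = 50, module_assignment = rep(1L, 5),
      within_module_r = 0.95, seed = 200 + s
    ))
    net <- pearson_network(log_transform(x), threshold = 0.7)
    all(degree_and_neighbors(net)$degree == 4L)
  }, logical(1))
  expect_gte(mean(full), 0.9)
})

test_that("within-module degree exceeds between-module degree", {
  x <- gen_expression(expression_sim_config(
    n_genes = 40, n_samples = 60,
    module_assignment = c(rep(1L, 12), rep(NA_integer_, 28)),
    within_module_r = 0.85, seed = 103
  ))
  deg <- degree_and_neighbors(pearson_network(log_transform(x)))$degree
  expect_gt(mean(deg[1:12]), mean(deg[13:40]))
})

test_that("edge weights rescale the correlation window", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5) * 2)
  net <- pearson_network(m, threshold = 0.7)
  ew <- edge_weight_scaling(net, w_min_r = 0.5)
  expect_equal(ew$weight, 1)  # r = 1
  # linear rescale inside the window, clipped at the ends
  expect_equal((0.85 - 0.7) / (1 - 0.7), 0.5)
  net$r[] <- 0.85
  net$adjacency[] <- TRUE; diag(net$adjacency) <- FALSE
  expect_equal(edge_weight_scaling(net, w_min_r = 0.7)$weight, 0.5)
  net$r[] <- 0.5
  expect_equal(edge_weight_scaling(net, w_min_r = 0.5)$weight, 0)
  expect_error(edge_weight_scaling(net, w_min_r = 1), "< 1")
})
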