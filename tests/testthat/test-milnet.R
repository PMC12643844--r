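test_that("split_subgroups routes posts to one quadrant and two marginals", {
  labels <- data.frame(post_id = paste0("p", 1:4),
                       sfm = c("HIGH", "HIGH", "LOW", "LOW"),
                       pom = c("HIGH", "LOW", "HIGH", "LOW"),
                       stringsAsFactors = FALSE)
  m <- matrix(1L, 4, 2, dimnames = list(labels$post_id, c("a", "b")))
  sg <- split_subgroups(labels, m)
  expect_named(sg, c("S1", "S0", "P1", "P0", "S1P1", "S1P0", "S0P1", "S0P0"))
  # (SFM=High, POM=Low) member of S1, P0, S1P0
  expect_true("p2" %in% rownames(sg$S1))
  expect_true("p2" %in% rownames(sg$P0))
  expect_identical(rownames(sg$S1P0), "p2")
  # one post per quadrant -> marginals have 2 rows each
  expect_equal(unname(vapply(sg[1:4], nrow, 1L)), rep(2L, 4))
  # each post: exactly 1 quadrant + 2 marginals
  for (p in labels$post_id) {
    hits <- vapply(sg, function(x) p %in% rownames(x), logical(1))
    expect_equal(sum(hits[1:4]), 2)
    expect_equal(sum(hits[5:8]), 1)
  }
  # empty input -> 8 empty matrices
  sg0 <- split_subgroups(labels[0, ], m[0, , drop = FALSE])
  expect_true(all(vapply(sg0, nrow, 1L) == 0))
  labels$sfm[1] <- NA
  expect_error(split_subgroups(labels, m), "SFM and POM")
})

test_that("glasso solution satisfies its KKT optimality conditions", {
  # independent oracle for the solver: stationarity of the penalized
  # log-likelihood, checked on random covariance inputs
  set.seed(42)
  for (rep in 1:5) {
    p <- sample(4:8, 1)
    X <- matrix(rnorm(60 * p), 60, p)
    S <- cor(X)
    rho <- runif(1, 0.05, 0.3)
    fit <- milscope:::.glasso_cpp(S, rho)
    Th <- fit$wi
    W <- solve(Th)
    G <- S - W
    off <- upper.tri(S)
    nz <- off & Th != 0
    z <- off & Th == 0
    if (any(nz)) expect_lt(max(abs(G[nz] + rho * sign(Th[nz]))), 1e-4)
    if (any(z)) expect_lt(max(abs(G[z])), rho + 1e-4)
    # diagonal unpenalized: fitted covariance keeps sample variances
    expect_equal(diag(W), diag(S), tolerance = 1e-6)
  }
})

test_that("estimate_network recovers planted structure and EBIC is minimal", {
  g <- gen_gaussian(make_precision(5, "chain", -0.4), n = 2000, seed = 3)
  net <- estimate_network(g$x, gamma = 0.5)
  er <- edge_recovery(net, g$edges)
  expect_equal(er$precision, 1)
  expect_equal(er$recall, 1)
  # EBIC at the chosen lambda is the grid minimum
  expect_equal(min(net$ebic), net$ebic[match(net$lambda, net$lambda_grid)])
  # partial-correlation scale, symmetric, zero diagonal
  expect_true(all(abs(net$weights) <= 1))
  expect_equal(unname(diag(net$weights)), rep(0, 5))
  expect_true(isSymmetric(unname(net$weights)))

  # independent columns -> empty edge set
  g0 <- gen_gaussian(make_precision(6, "empty"), n = 500, seed = 4)
  expect_equal(estimate_network(g0$x)$n_edges, 0)

  # row permutation invariance
  set.seed(9)
  net2 <- estimate_network(g$x[sample(nrow(g$x)), ], gamma = 0.5)
  expect_equal(net2$weights, net$weights)

  # gamma = 0 reduces the criterion to BIC
  netb <- estimate_network(g$x, gamma = 0)
  i <- match(netb$lambda, netb$lambda_grid)
  expect_equal(netb$ebic[i], min(netb$ebic))

  expect_error(estimate_network(g$x[1:2, ]), "at least 3")
  # zero-variance column dropped with warning
  xz <- cbind(g$x, zv = 1)
  expect_warning(netz <- estimate_network(xz), "zero-variance")
  expect_equal(netz$p, 5)
})

test_that("expected influence equals signed row sums", {
  w <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  w["a", "b"] <- w["b", "a"] <- 0.3
  w["a", "c"] <- w["c", "a"] <- -0.1
  ei <- expected_influence(w)
  expect_equal(ei$expected_influence_raw[ei$node == "a"], 0.2)
  # z-scores standardized
  expect_equal(mean(ei$expected_influence_z), 0)
  expect_equal(sd(ei$expected_influence_z), 1)
  # empty network -> all zero
  ei0 <- expected_influence(matrix(0, 4, 4))
  expect_equal(ei0$expected_influence_raw, rep(0, 4))
  expect_equal(ei0$expected_influence_z, rep(0, 4))
})

test_that("density follows 2E/(N(N-1))", {
  expect_equal(network_density(5, 10), 1)
  expect_equal(network_density(4, 3), 0.5)
  expect_equal(network_density(10, 0), 0)
  expect_error(network_density(1, 0), "at least 2")
})

test_that("modularity matches closed forms and igraph", {
  set.seed(7)
  for (rep in 1:20) {
    A <- random_adjacency(sample(4:7, 1))
    # all-one-community partition -> Q = 0
    expect_equal(modularity_q(A, rep(1, nrow(A))), 0)
  }
  # two disconnected edges partitioned by edge -> Q = 0.5
  A2 <- matrix(0, 4, 4)
  A2[1, 2] <- A2[2, 1] <- 1
  A2[3, 4] <- A2[4, 3] <- 1
  expect_equal(modularity_q(A2, c(1, 1, 2, 2)), 0.5)
  # invariant under relabeling
  expect_equal(modularity_q(A2, c(9, 9, 4, 4)), 0.5)
  # cross-check against igraph on random weighted graphs
  set.seed(8)
  for (rep in 1:10) {
    A <- random_adjacency(6)
    if (sum(A) == 0) next
    g <- igraph::graph_from_adjacency_matrix(A, "undirected", weighted = TRUE)
    memb <- sample(1:3, 6, replace = TRUE)
    expect_equal(modularity_q(A, memb),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight))
  }
  expect_error(modularity_q(A2, c(1, 1, NA, 2)), "cover")
})

test_that("louvain separates two cliques joined by a bridge", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1
  diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 1
  part <- louvain_communities(A, seed = 1)
  expect_equal(part$n_communities, 2)
  expect_length(unique(part$membership[1:4]), 1)
  expect_length(unique(part$membership[5:8]), 1)
  expect_equal(part$Q, brute_force_best_q(A))
  # Q at least that of the singleton partition (= never worse than trivial)
  expect_gte(part$Q, modularity_q(A, seq_len(8)))
  # determinism under fixed seed
  part2 <- louvain_communities(A, seed = 1)
  expect_identical(part$membership, part2$membership)
  # single edge graph matches brute force
  A1 <- matrix(0, 3, 3); A1[1, 2] <- A1[2, 1] <- 1
  p1 <- louvain_communities(A1, seed = 2)
  expect_equal(p1$Q, brute_force_best_q(A1))
})

test_that("compare_networks: identical inputs give zero differences", {
  g <- gen_gaussian(make_precision(5, "chain", -0.4), n = 400, seed = 12)
  cmp <- compare_networks(g$x, g$x, n_perm = 10, seed = 1, nlambda = 20)
  expect_equal(cmp$global_strength_diff, 0)
  expect_equal(cmp$max_weight_diff, 0)
  # identical networks: every permutation statistic >= 0 = observed -> p = 1
  expect_equal(cmp$p_strength, 1)
  expect_true(cmp$p_weight >= 0 && cmp$p_weight <= 1)
  xb <- g$x; colnames(xb) <- c("a", colnames(g$x)[-1])
  expect_error(compare_networks(g$x, xb, n_perm = 5), "column sets")
})

test_that("compare_networks detects a planted strong edge", {
  # b has one strong extra dependency absent in a
  oa <- make_precision(5, "empty")
  ob <- make_precision(5, "empty")
  ob$omega[1, 2] <- ob$omega[2, 1] <- -0.5
  a <- gen_gaussian(oa, n = 1000, seed = 31)
  b <- gen_gaussian(ob, n = 1000, seed = 32)
  cmp <- compare_networks(a$x, b$x, n_perm = 100, seed = 5, nlambda = 20)
  expect_lte(cmp$p_weight, 0.05)
  expect_lte(cmp$p_strength, 0.05)
})
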