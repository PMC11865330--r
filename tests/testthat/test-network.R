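test_that("prevalence filter keeps taxa at or above the occupancy cutoff", {
  m <- matrix(0, 3, 36, dimnames = list(c("in18", "in17", "full"), NULL))
  m["in18", 1:18] <- 5
  m["in17", 1:17] <- 5
  m["full", ] <- 2
  f <- prevalence_filter(m, 0.5)
  expect_setequal(rownames(f), c("in18", "full"))
  expect_identical(prevalence_filter(m, 0), m)
})

test_that("log-Pearson correlation matrix is exact and scale-invariant", {
  set.seed(1)
  x <- stats::rlnorm(10)
  m <- rbind(a = x, b = 2 * x, c = stats::rlnorm(10))
  r <- correlation_matrix(m)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "b"], 1, tolerance = 1e-12)   # log-linear invariance
  expect_equal(r, t(r))
  # hand computation on a 3-taxon fixture via the product-moment formula
  fix <- rbind(t1 = c(1, 2, 4, 8, 3), t2 = c(2, 1, 6, 3, 9),
               t3 = c(5, 5, 2, 1, 1))
  rr <- correlation_matrix(fix)
  lx <- log(fix)
  hand <- function(u, v) {
    n <- length(u)
    num <- sum(u * v) - sum(u) * sum(v) / n
    den <- sqrt((sum(u^2) - sum(u)^2 / n) * (sum(v^2) - sum(v)^2 / n))
    num / den
  }
  expect_equal(rr["t1", "t2"], hand(lx[1, ], lx[2, ]), tolerance = 1e-12)
  expect_equal(rr["t1", "t3"], hand(lx[1, ], lx[3, ]), tolerance = 1e-12)
  # constant taxon flagged, correlation set to zero
  cm <- rbind(k = rep(3, 8), x = stats::rlnorm(8))
  rc <- correlation_matrix(cm)
  expect_identical(attr(rc, "flagged"), "k")
  expect_equal(rc["k", "x"], 0)
  expect_error(correlation_matrix(m[, 1:3]), "4 samples")
})

test_that("network construction thresholds |r| and keeps signs", {
  r <- matrix(c(1, 0.8, -0.69, 0.8, 1, 0.71, -0.69, 0.71, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  net <- build_network(r, 0.7)
  expect_setequal(net$nodes, c("a", "b", "c"))
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$r[net$edges$from == "a"], 0.8)
  expect_error(build_network(r, 0), "threshold")
  # brute-force edge count on random matrices
  for (s in 1:5) {
    set.seed(s)
    n <- 12
    m <- matrix(stats::runif(n * n, -1, 1), n)
    m <- (m + t(m)) / 2; diag(m) <- 1
    dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
    t0 <- 0.5
    net <- build_network(m, t0)
    brute <- sum(abs(m[upper.tri(m)]) >= t0)
    expect_equal(nrow(net$edges), brute)
  }
})

test_that("edge sets are monotone non-increasing in the threshold", {
  set.seed(3)
  n <- 20
  m <- matrix(stats::runif(n * n, -1, 1), n)
  m <- (m + t(m)) / 2; diag(m) <- 1
  dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
  counts <- vapply(seq(0.2, 0.9, 0.1),
                   function(t) nrow(build_network(m, t)$edges), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("module detection separates canonical structures", {
  clique <- function(ids) {
    p <- t(utils::combn(ids, 2))
    data.frame(from = p[, 1], to = p[, 2], r = 0.9,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(clique(paste0("a", 1:5)), clique(paste0("b", 1:5)),
                 data.frame(from = "a1", to = "b1", r = 0.9))
  net <- make_net(edges)
  mod <- detect_modules(net)
  expect_equal(length(unique(mod$membership)), 2)
  expect_true(all(mod$membership[paste0("a", 1:5)] ==
                    mod$membership[["a1"]]))
  expect_gt(mod$modularity, 0.3)
  # disconnected components never share a module
  edges2 <- rbind(clique(paste0("x", 1:4)), clique(paste0("y", 1:4)))
  mod2 <- detect_modules(make_net(edges2))
  expect_false(mod2$membership[["x1"]] == mod2$membership[["y1"]])
  # partition beats random relabelings
  g_adj <- make_net(edges)
  q_rand <- vapply(1:100, function(s) {
    set.seed(s)
    perm <- sample(mod$membership)
    names(perm) <- names(mod$membership)
    ig <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::modularity(ig, perm[igraph::V(ig)$name])
  }, numeric(1))
  expect_true(all(mod$modularity >= q_rand))
})

test_that("Zi-Pi follows the Guimera-Amaral formulation", {
  clique <- function(ids) {
    p <- t(utils::combn(ids, 2))
    data.frame(from = p[, 1], to = p[, 2], r = 0.8,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(clique(paste0("a", 1:4)), clique(paste0("b", 1:4)))
  net <- make_net(edges)
  mem <- stats::setNames(rep(1:2, each = 4), c(paste0("a", 1:4),
                                               paste0("b", 1:4)))
  zp <- compute_zipi(net, mem)
  expect_true(all(zp$pi == 0))            # all links inside own module
  # node with 4 links split 2/2 across two modules: Pi = 0.5
  edges2 <- data.frame(from = "hub", to = c("a1", "a2", "b1", "b2"),
                       r = 0.9, stringsAsFactors = FALSE)
  edges2 <- rbind(edges2, clique(c("a1", "a2", "a3")),
                  clique(c("b1", "b2", "b3")))
  net2 <- make_net(edges2)
  mem2 <- stats::setNames(c(1, rep(2, 3), rep(3, 3)),
                          c("hub", paste0("a", 1:3), paste0("b", 1:3)))
  zp2 <- compute_zipi(net2, mem2)
  expect_equal(zp2$pi[zp2$node == "hub"], 0.5)
  # within-module Zi scores are standardised
  for (m in unique(zp2$module)) {
    z <- zp2$zi[zp2$module == m]
    if (length(z) > 1 && stats::sd(z) > 0) {
      expect_equal(mean(z), 0, tolerance = 1e-12)
      expect_equal(stats::sd(z), 1, tolerance = 1e-12)
    }
  }
  # brute-force agreement on random graphs
  for (s in 1:5) {
    net3 <- random_signed_graph(9, 0.5, seed = 40 + s)
    if (nrow(net3$edges) < 3) next
    mod <- detect_modules(net3)
    got <- compute_zipi(net3, mod$membership)
    want <- oracle_zipi(net3, mod$membership)
    expect_equal(got$zi, want$zi[match(got$node, want$node)],
                 tolerance = 1e-9)
    expect_equal(got$pi, want$pi[match(got$node, want$node)],
                 tolerance = 1e-9)
  }
})

test_that("node roles obey the Zi >= 2.5 / Pi >= 0.62 rule", {
  expect_identical(classify_node_role(1.0, 0.70), "connector")
  expect_identical(classify_node_role(2.5, 0.1), "module hub")
  expect_identical(classify_node_role(3.0, 0.62), "network hub")
  expect_identical(classify_node_role(0, 0), "peripheral")
})

test_that("topology summary matches canonical values and brute force", {
  tri <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                    r = 0.9, stringsAsFactors = FALSE)
  ts <- topology_summary(make_net(tri))
  expect_equal(ts$clustering, 1)
  expect_equal(ts$mean_path, 1)
  expect_equal(ts$positive_edge_frac, 1)
  star <- data.frame(from = "hub", to = paste0("leaf", 1:18), r = 0.7,
                     stringsAsFactors = FALSE)
  ts2 <- topology_summary(make_net(star))
  expect_equal(length(ts2$neighbors[["hub"]]), 18)
  expect_equal(ts2$n_nodes, 19)
  for (s in 1:5) {
    net <- random_signed_graph(8, 0.5, seed = 70 + s)
    if (length(net$nodes) < 3) next
    got <- topology_summary(net)
    want <- oracle_topology(net)
    expect_equal(got$mean_degree, want$mean_degree, tolerance = 1e-9)
    expect_equal(got$clustering, want$clustering, tolerance = 1e-9)
    expect_equal(got$mean_path, want$mean_path, tolerance = 1e-9)
  }
})
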