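test_that("MCL recovers obvious structure", {
  g <- two_triangles()
  sol <- mcl(g)
  expect_equal(sol$n_clusters, 2)
  # exactly the two triangles
  m <- sol$membership
  expect_equal(length(unique(m[c("a", "b", "c")])), 1)
  expect_equal(length(unique(m[c("d", "e", "f")])), 1)
  expect_true(m[["a"]] != m[["d"]])
  expect_true(sol$converged)

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(mcl(k5)$n_clusters, 1)
})

test_that("MCL never merges disconnected components", {
  set.seed(11)
  for (i in 1:50) {
    g <- random_small_graph(sample(5:30, 1), runif(1, 0.1, 0.4))
    sol <- suppressWarnings(mcl(g))
    comp <- igraph::components(g)$membership
    m <- sol$membership[names(comp)]
    # every MCL cluster lies inside one component
    expect_true(all(tapply(comp, m, function(x) length(unique(x))) == 1),
                info = paste("graph", i))
  }
})

test_that("MCL is invariant under node relabeling and weight scaling", {
  set.seed(5)
  g <- random_small_graph(20, 0.25)
  sol <- suppressWarnings(mcl(g))

  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  sol2 <- suppressWarnings(mcl(g2))
  common <- igraph::V(g)$name
  expect_equal(ari(sol$membership[common], sol2$membership[common]), 1)

  g3 <- g
  igraph::E(g3)$weight <- igraph::E(g3)$weight * 7.3
  sol3 <- suppressWarnings(mcl(g3))
  expect_equal(ari(sol$membership[common], sol3$membership[common]), 1)
  expect_equal(modularity_q(g, sol$membership),
               modularity_q(g3, sol$membership))
})

test_that("non-convergence yields a warning with a usable partition", {
  set.seed(14)
  g <- random_small_graph(20, 0.25)  # irregular weights: no 1-step fixpoint
  expect_warning(sol <- mcl(g, mcl_config(max_iter = 1)), "converge")
  expect_false(sol$converged)
  expect_equal(length(sol$membership), 20)
})

test_that("modularity matches closed forms and a brute-force oracle", {
  set.seed(6)
  g <- random_small_graph(12, 0.3)
  one <- setNames(rep(1, 12), igraph::V(g)$name)
  expect_equal(modularity_q(g, one), 0)

  g2 <- igraph::disjoint_union(igraph::make_full_graph(5),
                               igraph::make_full_graph(5))
  igraph::V(g2)$name <- paste0("n", 1:10)
  nat <- setNames(rep(1:2, each = 5), paste0("n", 1:10))
  expect_equal(modularity_q(g2, nat), 0.5)

  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  singles <- setNames(1:3, c("a", "b", "c"))
  expect_equal(modularity_q(k3, singles), -1 / 3)

  # brute-force pairwise summation oracle on random weighted graphs
  for (i in 1:10) {
    g <- random_small_graph(sample(5:15, 1), 0.4)
    if (igraph::ecount(g) == 0) next
    memb <- setNames(sample(1:3, igraph::vcount(g), replace = TRUE),
                     igraph::V(g)$name)
    A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
    diag(A) <- 0
    two_m <- sum(A)
    k <- rowSums(A)
    q_brute <- 0
    for (u in seq_len(nrow(A))) for (v in seq_len(ncol(A))) {
      if (memb[rownames(A)[u]] == memb[colnames(A)[v]]) {
        q_brute <- q_brute + A[u, v] - k[u] * k[v] / two_m
      }
    }
    q_brute <- unname(q_brute / two_m)
    expect_equal(modularity_q(g, memb), q_brute, tolerance = 1e-12)
    # independent library implementation agrees too
    expect_equal(modularity_q(g, memb),
                 igraph::modularity(g, memb[igraph::V(g)$name],
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }

  gE <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(gE)$name <- c("a", "b", "c")
  expect_warning(q0 <- modularity_q(gE, setNames(1:3, c("a", "b", "c"))),
                 "empty")
  expect_equal(q0, 0)
})

test_that("inflation tuning maximizes modularity with ties to smaller r", {
  g <- two_triangles()
  t1 <- tune_inflation(g, grid = 2.4)
  expect_equal(t1$inflation, 2.4)

  t2 <- tune_inflation(g, grid = c(1.5, 2, 4))
  expect_equal(t2$inflation, 1.5)       # identical partitions, tie to low r
  expect_equal(length(unique(t2$grid_Q)), 1)
  expect_equal(t2$solution$n_clusters, 2)

  set.seed(8)
  g3 <- random_small_graph(18, 0.3)
  t3 <- suppressWarnings(tune_inflation(g3, grid = c(1.4, 2, 3)))
  expect_equal(t3$Q, max(t3$grid_Q))
})

test_that("cluster recovery improves as planted communities separate", {
  run_ari <- function(p_in, seeds) {
    mean(vapply(seeds, function(s) {
      spec <- synthetic_spec(p_in = p_in, p_out = 0.01, seed = s)
      net <- generate_network(spec)
      g <- build_enhanced_graph(net$edges, filter_degs(net$degs))
      sol <- suppressWarnings(mcl(g, mcl_config(inflation = 1.5)))
      genes <- names(sol$membership)
      ari(sol$membership, net$truth$clusters[genes])
    }, numeric(1)))
  }
  seeds <- 1:5
  weak <- run_ari(0.08, seeds)
  strong <- run_ari(0.3, seeds)
  expect_gte(strong, weak)
  expect_gte(strong, 0.9)
})

test_that("cluster selection needs >20 genes in one quadrant", {
  set.seed(9)
  up <- setNames(runif(25, 0.5, 2), paste0("u", 1:25))
  mixed <- setNames(c(runif(13, 0.2, 1), runif(12, -1, -0.2)),
                    paste0("m", 1:25))
  small <- setNames(runif(15, -2, -0.5), paste0("s", 1:15))
  memb <- setNames(rep(1:3, c(25, 25, 15)), c(names(up), names(mixed),
                                              names(small)))
  fc <- c(up, mixed, small)
  st <- cluster_stats(memb, fc)
  expect_equal(st$direction, c("up", "mixed", "down"))
  expect_equal(filter_clusters(memb, fc, min_size = 20), 1)

  # a whisker outlier of opposite sign does not veto the quadrant label,
  # and the outlier stays a member
  out_fc <- c(setNames(rnorm(24, 1, 0.05), paste0("o", 1:24)),
              o25 = -5)
  memb2 <- setNames(rep(1, 25), names(out_fc))
  st2 <- cluster_stats(memb2, out_fc)
  expect_equal(st2$direction, "up")
  expect_equal(st2$size, 25)
  expect_equal(filter_clusters(memb2, out_fc), 1)
})
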