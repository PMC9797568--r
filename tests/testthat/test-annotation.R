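test_that("centralities match hand computations on canonical graphs", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  memb <- setNames(rep(1, 6), igraph::V(star)$name)
  cent <- centralities(star, memb)
  h <- cent[cent$gene == "hub", ]
  expect_equal(h$degree, 5)
  expect_equal(h$betweenness, 10)    # all C(5,2) leaf pairs route via hub
  expect_equal(h$closeness, 1)
  expect_equal(h$eigenvector, 1)     # scaled principal eigenvector entry
  expect_true(all(cent$eigenvector[cent$gene != "hub"] < 1))

  path <- igraph::graph_from_literal(A - B, B - C)
  pc <- centralities(path, setNames(rep(1, 3), c("A", "B", "C")))
  expect_equal(pc$betweenness[pc$gene == "B"], 1)
  expect_equal(pc$betweenness[pc$gene %in% c("A", "C")], c(0, 0))

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  kc <- centralities(k4, setNames(rep(1, 4), letters[1:4]))
  for (m in c("degree", "betweenness", "closeness", "eigenvector")) {
    expect_equal(length(unique(kc[[m]])), 1)
    expect_true(all(kc[[paste0("rank_", m)]] == 1))
  }

  # singleton cluster: all metrics zero
  g <- igraph::graph_from_literal(A - B)
  g <- igraph::add_vertices(g, 1, name = "L")
  sc <- centralities(g, setNames(c(1, 1, 2), c("A", "B", "L")))
  lone <- sc[sc$gene == "L", ]
  expect_equal(unlist(lone[c("degree", "betweenness", "closeness",
                             "eigenvector")]),
               c(degree = 0, betweenness = 0, closeness = 0,
                 eigenvector = 0))
})

test_that("hub selection applies the rank rule with deterministic ties", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  cent <- centralities(star, setNames(rep(1, 6), igraph::V(star)$name))
  hubs <- select_hubs(cent, top_k = 1, min_metrics = 4)
  expect_equal(hubs$gene, "hub")

  # complete graph: everything tied; cap yields exactly top_k, lexicographic
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- c("f", "a", "d", "b", "e", "c")
  centk <- centralities(k6, setNames(rep(1, 6), igraph::V(k6)$name))
  hubk <- select_hubs(centk, top_k = 3, min_metrics = 3)
  expect_equal(sort(hubk$gene), c("a", "b", "c"))

  # bridge + core cluster: high-betweenness bridge and high-degree core
  # both qualify at top_k = 2, min_metrics = 2
  g <- igraph::graph_from_literal(
    core - a, core - b, core - c, core - bridge, bridge - x,
    x - y, x - z, a - b)
  memb <- setNames(rep(1, igraph::vcount(g)), igraph::V(g)$name)
  cent2 <- centralities(g, memb)
  hubs2 <- select_hubs(cent2, top_k = 2, min_metrics = 2)
  expect_true(all(c("core", "bridge") %in% hubs2$gene))

  # invariant under node relabeling
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  hubs3 <- select_hubs(centralities(g2, memb), top_k = 2, min_metrics = 2)
  expect_setequal(hubs2$gene, hubs3$gene)
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  universe <- paste0("g", 1:20)
  term <- list(T1 = paste0("g", 1:5))
  res <- enrich_terms(paste0("g", 1:5), universe, term)
  expect_equal(res$pvalue, 1 / choose(20, 5))
  expect_equal(res$fold_enrichment, 4)

  res0 <- enrich_terms(paste0("g", 6:10), universe,
                       list(T1 = paste0("g", 1:5)))
  expect_equal(res0$pvalue, 1)        # P(X >= 0) = 1
  expect_equal(res0$fold_enrichment, 0)

  expect_error(enrich_terms(c("g1", "zz"), universe, term), "subset")
  expect_warning(enrich_terms("g1", universe, list(T0 = "absent")),
                 "skipped")
})

test_that("enrichment p-values agree with brute-force draw enumeration", {
  universe <- paste0("g", 1:20)
  term_genes <- paste0("g", 1:6)
  cluster <- c("g1", "g2", "g3", "g7", "g8")
  res <- enrich_terms(cluster, universe, list(T = term_genes))
  # enumerate all C(20,5) cluster draws; exact upper-tail probability
  draws <- combn(20, 5)
  in_term <- draws <= 6
  overlap_obs <- res$overlap
  p_enum <- mean(colSums(in_term) >= overlap_obs)
  expect_equal(res$pvalue, p_enum, tolerance = 1e-12)
})

test_that("BH adjustment is monotone over sorted p-values", {
  set.seed(10)
  universe <- paste0("g", 1:25)
  terms <- lapply(1:8, function(i) sample(universe, sample(3:10, 1)))
  names(terms) <- paste0("T", 1:8)
  res <- enrich_terms(sample(universe, 6), universe, terms)
  expect_true(all(diff(res$FDR[order(res$pvalue)]) >= -1e-12))
  expect_true(all(res$FDR >= res$pvalue - 1e-12))
})

test_that("cluster labeling picks the lowest-FDR covering term", {
  enr <- data.frame(term = c("A", "B", "C"),
                    overlap = c(6, 9, 10), term_size = c(8, 12, 30),
                    cluster_size = 10, universe_size = 100,
                    fold_enrichment = c(3, 2, 1),
                    pvalue = c(1e-7, 1e-5, 0.5),
                    FDR = c(1e-6, 1e-4, 0.5))
  expect_equal(label_cluster(enr), "A")       # lowest FDR among passing
  expect_equal(label_cluster(enr[3, ]), "unlabeled")
  expect_equal(label_cluster(enr[2, ]), "B")
  # coverage below 50% disqualifies
  enr2 <- enr[1, ]; enr2$overlap <- 4
  expect_equal(label_cluster(enr2), "unlabeled")
})
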