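# Adjusted Rand index between two labelings (chance-corrected agreement);
# independent of the clustering code under test.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# Random small weighted graph with a few components, for oracle checks.
random_small_graph <- function(n, p = 0.3) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.2, 1)
  }
  g
}

# Two disjoint unit-weight triangles.
two_triangles <- function() {
  g <- igraph::graph_from_literal(a - b, b - c, a - c, d - e, e - f, d - f)
  igraph::E(g)$weight <- 1
  g
}

# Hand-computed 4-node enhanced-graph fixture: fold changes and edge
# scores derived by direct arithmetic (max edge distance = 2).
enhance_fixture <- function() {
  list(
    edges = data.frame(
      gene_a = c("A", "A", "B", "C"),
      gene_b = c("B", "C", "D", "D"),
      ppi_score = c(0.9, 0.8, 0.75, 0.9)),
    degs = data.frame(
      gene = c("A", "B", "C", "D"),
      log2FC = c(1, 2, -1, 0.5),
      FDR = 1e-4),
    # |dFC|: AB 1, AC 2, BD 1.5, CD 1.5; max_distance 2
    expected = data.frame(
      gene_a = c("A", "A", "B", "C"),
      gene_b = c("B", "C", "D", "D"),
      fc_score = c(0.5, 0, 0.25, 0.25),
      enhanced = c(0.45, 0, 0.1875, 0.225))
  )
}
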