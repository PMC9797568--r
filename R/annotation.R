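#' Four centrality metrics per gene within its cluster
#'
#' Computes degree, betweenness, closeness and eigenvector centrality on
#' each cluster's induced subgraph. Topology is unweighted by default;
#' with `weighted = TRUE` betweenness/closeness use distance =
#' 1/enhanced_score and eigenvector uses the weights. Closeness is the
#' normalized (n-1)/sum-of-distances form, computed within a node's
#' connected component; eigenvector scores are scaled to max 1 per
#' cluster. Singletons get all-zero metrics.
#'
#' @param graph The enhanced igraph graph.
#' @param membership Named vector gene -> cluster (or `cluster_solution`).
#' @param weighted Use edge weights for betweenness/closeness/eigenvector.
#' @return Data frame: gene, cluster, degree, betweenness, closeness,
#'   eigenvector, and per-metric within-cluster ranks (`rank_*`, 1 = best,
#'   ties share the best rank).
#' @export
centralities <- function(graph, membership, weighted = FALSE) {
  if (inherits(membership, "cluster_solution")) {
    membership <- membership$membership
  }
  nm <- igraph::V(graph)$name
  if (!all(nm %in% names(membership))) {
    stop("membership does not cover all graph nodes")
  }
  res <- lapply(sort(unique(membership[nm])), function(cl) {
    genes <- nm[membership[nm] == cl]
    sub <- igraph::induced_subgraph(graph, genes)
    n <- igraph::vcount(sub)
    if (n == 1 || igraph::ecount(sub) == 0) {
      return(data.frame(gene = genes, cluster = cl, degree = 0,
                        betweenness = 0, closeness = 0, eigenvector = 0))
    }
    w <- if (weighted && "weight" %in% igraph::edge_attr_names(sub)) {
      1 / igraph::E(sub)$weight
    } else {
      NA
    }
    deg <- igraph::degree(sub)
    btw <- igraph::betweenness(sub, weights = w)
    # closeness within each component: (n_comp - 1) / sum distances
    comp <- igraph::components(sub)$membership
    d <- igraph::distances(sub, weights = w)
    clo <- vapply(seq_len(n), function(i) {
      peers <- which(comp == comp[i])
      peers <- setdiff(peers, i)
      if (!length(peers)) return(0)
      length(peers) / sum(d[i, peers])
    }, numeric(1))
    ew <- if (weighted && "weight" %in% igraph::edge_attr_names(sub)) {
      igraph::E(sub)$weight
    } else {
      NA
    }
    eig <- igraph::eigen_centrality(sub, weights = ew)$vector
    eig <- eig / max(eig)
    eig <- round(eig, 10)  # kill eigensolver noise so ties rank as ties
    data.frame(gene = igraph::V(sub)$name, cluster = cl,
               degree = unname(deg), betweenness = unname(btw),
               closeness = clo, eigenvector = unname(eig))
  })
  out <- do.call(rbind, res)
  for (m in c("degree", "betweenness", "closeness", "eigenvector")) {
    out[[paste0("rank_", m)]] <- stats::ave(
      -out[[m]], out$cluster, FUN = function(x) rank(x, ties.method = "min")
    )
  }
  rownames(out) <- NULL
  out
}

#' Select hub genes per cluster
#'
#' A gene qualifies as a hub when it ranks in the top `top_k` of at least
#' `min_metrics` of the four centralities within its cluster. When ties
#' make more than `top_k` genes qualify, the hub set is capped at `top_k`
#' per cluster by (rank sum, gene id) — deterministic under relabeling.
#'
#' @param cent Output of [centralities()].
#' @param top_k Rank cutoff per metric (default 3).
#' @param min_metrics Metrics the cutoff must hold for (default 3 of 4).
#' @return Data frame: gene, cluster, n_top_metrics, rank_sum.
#' @export
select_hubs <- function(cent, top_k = 3, min_metrics = 3) {
  metrics <- c("degree", "betweenness", "closeness", "eigenvector")
  rk <- as.matrix(cent[, paste0("rank_", metrics)])
  n_top <- rowSums(rk <= top_k)
  cand <- cent[n_top >= min_metrics, c("gene", "cluster")]
  cand$n_top_metrics <- n_top[n_top >= min_metrics]
  cand$rank_sum <- rowSums(rk)[n_top >= min_metrics]
  out <- do.call(rbind, lapply(split(cand, cand$cluster), function(d) {
    d <- d[order(d$rank_sum, d$gene), , drop = FALSE]
    utils::head(d, top_k)
  }))
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation of terms in a gene cluster
#'
#' Upper-tail hypergeometric p-value per term (probability of at least the
#' observed overlap when drawing the cluster from the universe), BH FDR
#' across terms within the cluster, and fold enrichment = observed /
#' expected overlap.
#'
#' @param cluster_genes Character vector (must be a subset of `universe`).
#' @param universe Background gene set (e.g. the coding genome).
#' @param terms Named list term -> member genes (GMT-style); memberships
#'   are intersected with the universe. Empty terms are skipped with a
#'   warning.
#' @return Data frame: term, overlap, term_size, cluster_size,
#'   universe_size, fold_enrichment, pvalue, FDR; sorted by p-value.
#' @export
enrich_terms <- function(cluster_genes, universe, terms) {
  if (!length(universe)) stop("empty universe")
  if (!all(cluster_genes %in% universe)) {
    stop("cluster genes must be a subset of the universe")
  }
  N <- length(universe)
  n <- length(cluster_genes)
  rows <- lapply(names(terms), function(tn) {
    tg <- intersect(terms[[tn]], universe)
    if (!length(tg)) {
      warning("term ", tn, " has no genes in the universe; skipped")
      return(NULL)
    }
    K <- length(tg)
    k <- length(intersect(tg, cluster_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tn, overlap = k, term_size = K, cluster_size = n,
               universe_size = N,
               fold_enrichment = k / (K * n / N),
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), overlap = integer(),
                      term_size = integer(), cluster_size = integer(),
                      universe_size = integer(), fold_enrichment = numeric(),
                      pvalue = numeric(), FDR = numeric()))
  }
  out$FDR <- stats::p.adjust(out$pvalue, method = "BH")
  out[order(out$pvalue), , drop = FALSE]
}

#' Functional label for one cluster from its enrichment results
#'
#' Among terms with FDR <= `fdr_max` that cover at least `coverage_min` of
#' the cluster, returns the lowest-FDR term; ties broken by larger
#' coverage, then term id. `"unlabeled"` when nothing passes.
#'
#' @param enrichment Output of [enrich_terms()] for one cluster.
#' @param coverage_min Minimum overlap / cluster_size (default 0.5).
#' @param fdr_max FDR cutoff (default 0.01).
#' @return Character scalar: the term name or `"unlabeled"`.
#' @export
label_cluster <- function(enrichment, coverage_min = 0.5, fdr_max = 0.01) {
  if (!nrow(enrichment)) return("unlabeled")
  cov <- enrichment$overlap / enrichment$cluster_size
  ok <- enrichment$FDR <= fdr_max & cov >= coverage_min
  if (!any(ok)) return("unlabeled")
  cand <- enrichment[ok, , drop = FALSE]
  cand$coverage <- cov[ok]
  cand <- cand[order(cand$FDR, -cand$coverage, cand$term), , drop = FALSE]
  cand$term[1]
}
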