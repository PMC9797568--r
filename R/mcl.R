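#' Markov clustering configuration
#'
#' @param inflation Inflation exponent r > 1; larger r gives finer clusters.
#' @param expansion Integer matrix power >= 2 for the expansion step.
#' @param pruning Entries below this are zeroed after each inflation
#'   (sparsity control), in \[0, 0.01\].
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the largest entry change between
#'   successive iterates (idempotence test).
#' @return An `mcl_config` list.
#' @export
mcl_config <- function(inflation = 2, expansion = 2, pruning = 1e-5,
                       max_iter = 200, tol = 1e-8) {
  stopifnot(inflation > 1, expansion >= 2, expansion == round(expansion),
            pruning >= 0, pruning <= 0.01, tol > 0, max_iter >= 1)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 pruning = pruning, max_iter = max_iter, tol = tol),
            class = "mcl_config")
}

# Column-normalize a matrix to stochastic form; zero columns get a unit
# self-entry so the walk never leaks mass.
.col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  zero <- cs == 0
  if (any(zero)) {
    M[cbind(which(zero), which(zero))] <- 1
    cs[zero] <- 1
  }
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Runs the MCL process on the graph's weighted adjacency matrix: add
#' self-loops (each node's loop weight is its maximum incident edge
#' weight), column-normalize to a stochastic matrix, then alternate
#' expansion (matrix power) and inflation (entrywise power, renormalize),
#' pruning small entries, until the matrix is idempotent within tolerance.
#' Clusters are read off the attractor structure; a node attracted by more
#' than one attractor system is assigned to the larger cluster, ties to the
#' lexicographically smallest member set.
#'
#' @param graph An [igraph][igraph::igraph-package] graph; edge attribute
#'   `weight` (the enhanced score) is used unless `weighted = FALSE`.
#' @param config An [mcl_config()].
#' @param weighted Use edge weights (default) or binary topology.
#' @return A `cluster_solution`: list with `membership` (named integer
#'   vector gene -> cluster id), `n_clusters`, `converged`, `iterations`,
#'   `inflation`.
#' @export
mcl <- function(graph, config = mcl_config(), weighted = TRUE) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph")
  names_v <- igraph::V(graph)$name
  if (is.null(names_v)) names_v <- as.character(seq_len(n))

  use_w <- weighted && "weight" %in% igraph::edge_attr_names(graph)
  A <- igraph::as_adjacency_matrix(graph, attr = if (use_w) "weight" else NULL,
                                   sparse = TRUE)
  A <- methods::as(A, "generalMatrix")
  A <- (A + Matrix::t(A)) / 2          # enforce symmetry
  Matrix::diag(A) <- 0
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1                 # isolated nodes: unit self-loop
  Matrix::diag(A) <- loop

  M <- .col_normalize(A)
  converged <- FALSE
  it <- 0
  while (it < config$max_iter) {
    it <- it + 1
    M_new <- M
    for (k in seq_len(config$expansion - 1)) M_new <- M_new %*% M  # expansion
    M_new <- M_new^config$inflation                                # inflation
    M_new <- .col_normalize(M_new)
    M_new@x[M_new@x < config$pruning] <- 0
    M_new <- Matrix::drop0(M_new)
    M_new <- .col_normalize(M_new)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", config$max_iter,
            " iterations; returning best-effort partition")
  }

  membership <- .read_attractors(M, names_v)
  structure(list(membership = membership,
                 n_clusters = length(unique(membership)),
                 converged = converged,
                 iterations = it,
                 inflation = config$inflation),
            class = "cluster_solution")
}

# Interpret the limit matrix: attractors are nodes with positive
# self-value; each attractor row lists the nodes it attracts. Attractors
# sharing any node form one attractor system (= one cluster). Overlapping
# membership is broken toward the larger cluster, then the
# lexicographically smallest cluster (by its smallest member name).
.read_attractors <- function(M, names_v) {
  n <- nrow(M)
  Md <- as.matrix(M)
  attractors <- which(diag(Md) > 0)
  clusters <- list()
  if (length(attractors)) {
    # union attractor rows that overlap (attractor systems)
    rows <- lapply(attractors, function(i) which(Md[i, ] > 0))
    sys_id <- seq_along(rows)
    repeat {
      changed <- FALSE
      for (a in seq_along(rows)) for (b in seq_along(rows)) {
        if (sys_id[a] != sys_id[b] &&
            length(intersect(rows[[a]], rows[[b]]))) {
          sys_id[sys_id == sys_id[b]] <- sys_id[a]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    clusters <- lapply(unique(sys_id), function(s) {
      sort(unique(unlist(rows[sys_id == s])))
    })
  }
  membership <- rep(NA_integer_, n)
  if (length(clusters)) {
    sizes <- vapply(clusters, length, integer(1))
    min_name <- vapply(clusters, function(cl) min(names_v[cl]), character(1))
    ord <- order(-sizes, min_name)        # larger first, then lexicographic
    for (ci in ord) {
      take <- clusters[[ci]][is.na(membership[clusters[[ci]]])]
      membership[take] <- ci
    }
  }
  # nodes attracted by nothing (fully pruned columns): singletons
  lone <- which(is.na(membership))
  if (length(lone)) {
    membership[lone] <- max(c(0L, membership), na.rm = TRUE) + seq_along(lone)
  }
  # relabel 1..k deterministically by smallest member name
  min_name <- tapply(names_v, membership, min)
  old_ids <- as.integer(names(min_name))[order(min_name)]
  stats::setNames(match(membership, old_ids), names_v)
}

#' Weighted Newman modularity of a partition
#'
#' Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * [c_i == c_j], with edge
#' weights as A (self-loops excluded), k the weighted degrees and m the
#' total edge weight.
#'
#' @param graph igraph graph; `weight` edge attribute used when present
#'   and `weighted = TRUE`.
#' @param membership Named vector gene -> cluster covering all nodes, or a
#'   `cluster_solution`.
#' @param weighted Use edge weights (default).
#' @return Q in \[-0.5, 1\]. Returns 0 with a warning for an empty edge set.
#' @export
modularity_q <- function(graph, membership, weighted = TRUE) {
  if (inherits(membership, "cluster_solution")) {
    membership <- membership$membership
  }
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
  if (!all(nm %in% names(membership))) {
    stop("membership does not cover all graph nodes")
  }
  if (igraph::ecount(graph) == 0) {
    warning("empty edge set; modularity defined as 0")
    return(0)
  }
  comm <- membership[nm]
  A <- igraph::as_adjacency_matrix(
    graph,
    attr = if (weighted && "weight" %in% igraph::edge_attr_names(graph))
      "weight" else NULL,
    sparse = TRUE
  )
  A <- as.matrix(A)
  diag(A) <- 0
  two_m <- sum(A)
  k <- rowSums(A)
  same <- outer(comm, comm, "==")
  sum((A - outer(k, k) / two_m) * same) / two_m
}

#' Tune the MCL inflation parameter by modularity
#'
#' Runs [mcl()] at every grid value and returns the solution maximizing
#' weighted modularity Q; ties go to the smaller inflation.
#'
#' @param graph igraph graph.
#' @param grid Inflation values, each > 1 (default 1.2 to 5.0 by 0.2).
#' @param config Base [mcl_config()]; its inflation is overridden per grid
#'   point.
#' @param weighted Passed to [mcl()] and [modularity_q()].
#' @return List with `inflation`, `Q`, `solution` (the winning
#'   `cluster_solution`), and `grid_Q` (named vector of Q per grid value).
#' @export
tune_inflation <- function(graph, grid = seq(1.2, 5, by = 0.2),
                           config = mcl_config(), weighted = TRUE) {
  stopifnot(length(grid) >= 1, all(grid > 1))
  grid <- sort(grid)
  best <- NULL
  qs <- stats::setNames(numeric(length(grid)), format(grid))
  for (i in seq_along(grid)) {
    cfg <- config
    cfg$inflation <- grid[i]
    sol <- mcl(graph, cfg, weighted = weighted)
    q <- modularity_q(graph, sol, weighted = weighted)
    qs[i] <- q
    if (is.null(best) || q > best$Q + 1e-12) {
      best <- list(inflation = grid[i], Q = q, solution = sol)
    }
  }
  best$grid_Q <- qs
  best
}

#' Per-cluster fold-change summary and direction labels
#'
#' For each cluster: size, median/Q1/Q3/IQR of member log2 fold changes,
#' and a direction label. The label is `"up"`/`"down"` when every member
#' inside the 1.5 x IQR whiskers is strictly positive/negative, `"mixed"`
#' otherwise.
#'
#' @param membership Named vector gene -> cluster (or `cluster_solution`).
#' @param log2fc Named vector gene -> log2FC.
#' @return Data frame, one row per cluster: `cluster`, `size`, `median`,
#'   `q1`, `q3`, `iqr`, `direction`.
#' @export
cluster_stats <- function(membership, log2fc) {
  if (inherits(membership, "cluster_solution")) {
    membership <- membership$membership
  }
  genes <- names(membership)
  if (!all(genes %in% names(log2fc))) {
    stop("log2FC missing for some clustered genes")
  }
  do.call(rbind, lapply(sort(unique(membership)), function(cl) {
    fc <- log2fc[genes[membership == cl]]
    qs <- stats::quantile(fc, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- qs[3] - qs[1]
    inside <- fc >= qs[1] - 1.5 * iqr & fc <= qs[3] + 1.5 * iqr
    direction <- if (all(fc[inside] > 0)) "up"
      else if (all(fc[inside] < 0)) "down"
      else "mixed"
    data.frame(cluster = cl, size = length(fc), median = qs[2],
               q1 = qs[1], q3 = qs[3], iqr = iqr, direction = direction)
  }))
}

#' Select clusters by size and coherent regulation direction
#'
#' Keeps a cluster iff it has more than `min_size` genes and all member
#' fold changes inside the 1.5 x IQR whiskers share one strict sign
#' (the cluster sits in one quadrant, above or below zero). Whisker
#' outliers remain cluster members; they only do not veto the label.
#'
#' @param membership Named vector gene -> cluster (or `cluster_solution`).
#' @param log2fc Named vector gene -> log2FC.
#' @param min_size Size threshold; kept clusters are strictly larger
#'   (default 20).
#' @return Integer vector of selected cluster ids.
#' @export
filter_clusters <- function(membership, log2fc, min_size = 20) {
  st <- cluster_stats(membership, log2fc)
  st$cluster[st$size > min_size & st$direction %in% c("up", "down")]
}
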