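#' Differential-expression significance filter
#'
#' Default thresholds: FDR <= 0.01 and |log2FC| >= 0.5. An optional raw
#' p-value cutoff can be added (some summaries additionally require
#' p < 0.05 together with |log2FC| >= 1; both regimes are expressible).
#'
#' @param fdr_max Maximum FDR.
#' @param abs_log2fc_min Minimum absolute log2 fold change.
#' @param pvalue_max Optional maximum raw p-value (`NULL` disables).
#' @return A `deg_filter` list.
#' @export
deg_filter <- function(fdr_max = 0.01, abs_log2fc_min = 0.5,
                       pvalue_max = NULL) {
  stopifnot(fdr_max > 0, abs_log2fc_min >= 0)
  if (!is.null(pvalue_max)) stopifnot(pvalue_max > 0)
  structure(list(fdr_max = fdr_max, abs_log2fc_min = abs_log2fc_min,
                 pvalue_max = pvalue_max),
            class = "deg_filter")
}

#' Filter a differential-expression table to significant genes
#'
#' @param degs Data frame with columns `gene`, `log2FC`, `FDR` (and
#'   `PValue` if the filter uses a raw p-value cutoff).
#' @param filter A [deg_filter()].
#' @return The rows passing all thresholds.
#' @export
filter_degs <- function(degs, filter = deg_filter()) {
  req <- c("gene", "log2FC", "FDR")
  miss <- setdiff(req, names(degs))
  if (length(miss)) {
    stop("DEG table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(degs$gene)) {
    stop("duplicate gene ids in DEG table: ",
         paste(unique(degs$gene[duplicated(degs$gene)]), collapse = ", "))
  }
  keep <- degs$FDR <= filter$fdr_max &
    abs(degs$log2FC) >= filter$abs_log2fc_min
  if (!is.null(filter$pvalue_max)) {
    if (!"PValue" %in% names(degs)) {
      stop("DEG table missing column(s): PValue")
    }
    keep <- keep & degs$PValue < filter$pvalue_max
  }
  degs[keep & !is.na(keep), , drop = FALSE]
}

#' Fold-change similarity score between two genes
#'
#' 1 - |Xi - Xj| / max_distance: 1 for identical log2 fold changes, 0 for
#' the most dissimilar pair in the network. `max_distance` is the largest
#' pairwise |log2FC| difference used for normalization (over retained edges
#' by default in [build_enhanced_graph()]).
#'
#' @param xi,xj log2 fold changes of the two genes.
#' @param max_distance Normalizing constant, > 0 (0 allowed only when all
#'   compared values are equal).
#' @return Score in \[0, 1\].
#' @export
fold_change_score <- function(xi, xj, max_distance) {
  d <- abs(xi - xj)
  if (max_distance == 0) {
    if (any(d > 0)) stop("max_distance is 0 but fold changes differ")
    return(rep(1, length(d)))
  }
  if (max_distance < 0) stop("max_distance must be non-negative")
  1 - d / max_distance
}

#' Combine fold-change similarity and interaction confidence
#'
#' Default combiner is the product (preserves \[0,1\], monotone in each
#' argument, zero for maximally dissimilar pairs); `"mean"` gives the
#' arithmetic mean.
#'
#' @param fc_score,ppi_score Scores in \[0, 1\].
#' @param mode `"product"` or `"mean"`.
#' @return Enhanced edge score in \[0, 1\].
#' @export
enhanced_score <- function(fc_score, ppi_score, mode = c("product", "mean")) {
  mode <- match.arg(mode)
  if (any(fc_score < 0 | fc_score > 1, na.rm = TRUE) ||
      any(ppi_score < 0 | ppi_score > 1, na.rm = TRUE)) {
    stop("scores must lie in [0, 1]")
  }
  if (mode == "product") fc_score * ppi_score else (fc_score + ppi_score) / 2
}

#' Build the attribute-enhanced interaction graph
#'
#' Restricts a STRING-style edge list to high-confidence interactions
#' (ppi_score >= `confidence_threshold`) between genes with fold-change
#' records, attaches each gene's log2FC as a node attribute, and scores
#' every retained edge with `ppi_score`, `foldChange_score` and
#' `enhanced_score` (the edge `weight`).
#'
#' Scores on a STRING 0-1000 integer scale are rescaled to \[0,1\]
#' automatically when the maximum exceeds 1.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `ppi_score`
#'   (aliases `protein1`, `protein2`, `combined_score` accepted).
#' @param degs Data frame with columns `gene`, `log2FC` (typically the
#'   output of [filter_degs()]).
#' @param confidence_threshold Minimum ppi_score (default 0.7, the STRING
#'   high-confidence cutoff).
#' @param mode Combiner for [enhanced_score()].
#' @param normalize `"edges"` (default) normalizes the fold-change distance
#'   by the maximum over retained edges; `"pairs"` uses all node pairs.
#' @return An [igraph][igraph::igraph-package] undirected graph with node
#'   attribute `log2FC`, edge attributes `ppi_score`, `foldChange_score`,
#'   `enhanced_score` and `weight` (= enhanced_score), and graph attributes
#'   `max_distance` and `mode`. Empty (zero-edge) result is returned, with
#'   a warning, when no edge survives filtering.
#' @export
build_enhanced_graph <- function(edges, degs, confidence_threshold = 0.7,
                                 mode = c("product", "mean"),
                                 normalize = c("edges", "pairs")) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  aliases <- c(gene_a = "protein1", gene_b = "protein2",
               ppi_score = "combined_score")
  for (canon in names(aliases)) {
    if (!canon %in% names(edges) && aliases[[canon]] %in% names(edges)) {
      names(edges)[names(edges) == aliases[[canon]]] <- canon
    }
  }
  req <- c("gene_a", "gene_b", "ppi_score")
  miss <- setdiff(req, names(edges))
  if (length(miss)) {
    stop("edge table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(c("gene", "log2FC") %in% names(degs))) {
    stop("fold-change table needs columns gene, log2FC")
  }
  if (nrow(edges) > 0 && max(edges$ppi_score) > 1) {
    edges$ppi_score <- edges$ppi_score / 1000
  }
  if (any(edges$ppi_score < 0 | edges$ppi_score > 1)) {
    stop("ppi_score outside [0, 1] after rescaling")
  }

  fc <- stats::setNames(degs$log2FC, degs$gene)
  known <- edges$gene_a %in% names(fc) & edges$gene_b %in% names(fc)
  n_dropped <- sum(!known)
  if (n_dropped > 0) {
    warning(n_dropped, " edge(s) dropped: endpoint without fold-change record")
  }
  edges <- edges[known & edges$ppi_score >= confidence_threshold, ,
                 drop = FALSE]
  if (nrow(edges) == 0) {
    warning("no edges pass the confidence threshold; returning empty graph")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_graph_attr(g, "max_distance", 0)
    g <- igraph::set_graph_attr(g, "mode", mode)
    return(g)
  }

  d <- abs(fc[edges$gene_a] - fc[edges$gene_b])
  max_distance <- if (normalize == "edges") {
    max(d)
  } else {
    genes_used <- unique(c(edges$gene_a, edges$gene_b))
    vals <- fc[genes_used]
    max(vals) - min(vals)  # max pairwise |difference| over nodes
  }
  fc_score <- fold_change_score(fc[edges$gene_a], fc[edges$gene_b],
                                max_distance)
  enh <- enhanced_score(fc_score, edges$ppi_score, mode)

  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$gene_a, to = edges$gene_b,
               ppi_score = edges$ppi_score,
               foldChange_score = unname(fc_score),
               enhanced_score = unname(enh),
               weight = unname(enh)),
    directed = FALSE
  )
  igraph::V(g)$log2FC <- unname(fc[igraph::V(g)$name])
  g <- igraph::set_graph_attr(g, "max_distance", max_distance)
  igraph::set_graph_attr(g, "mode", mode)
}
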