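#' Sign of a gene -> pathway/phenotype edge
#'
#' +1 (direct) when the gene's fold change points in the same direction as
#' the altered target, -1 (inverse) otherwise. Genes with log2FC exactly 0
#' have no defined direction; callers skip such edges.
#'
#' @param log2fc Gene log2 fold change (nonzero).
#' @param target_direction `"up"` (activated/increased) or `"down"`
#'   (repressed/decreased).
#' @return +1 or -1.
#' @export
edge_sign <- function(log2fc, target_direction = c("up", "down")) {
  target_direction <- match.arg(target_direction)
  if (log2fc == 0) stop("log2FC of 0 has no direction")
  gene_dir <- if (log2fc > 0) "up" else "down"
  if (gene_dir == target_direction) 1 else -1
}

.relation_for_weight <- function(w) {
  c(`-1` = "inverse", `0` = "neutral", `1` = "direct")[as.character(w)]
}

#' Assemble the signed multi-omics integration network
#'
#' Builds the directed, typed network variant -> gene -> pathway/phenotype:
#' \itemize{
#'   \item gene -> pathway edges for genes belonging to significantly
#'     perturbed pathways (perturbation FDR <= `fdr_max`), weighted +1
#'     when the gene's fold change matches the pathway's perturbation
#'     direction and -1 otherwise;
#'   \item gene -> phenotype edges for passing association records,
#'     weighted by the association sign;
#'   \item variant -> gene edges (weight 0, neutral) for variants with
#'     MODERATE or HIGH predicted impact.
#' }
#' Edges whose gene has log2FC = 0 are skipped with a warning; dangling
#' references are collected in a rejects report rather than failing.
#'
#' @param genes Data frame: `gene`, `log2FC`, optional `cluster`,
#'   optional logical flag columns `fermentation_ethanol`, `ros_redox`.
#' @param memberships Data frame: `gene`, `pathway`.
#' @param perturbations Data frame: `pathway`, `direction`
#'   (`"activated"`/`"repressed"` or `"up"`/`"down"`), `FDR`.
#' @param associations Data frame: `gene`, `phenotype`, `sign`, `passes`
#'   (from [associate_all()]).
#' @param variants Data frame: `variant_id`, `gene`, `tier` (from
#'   [classify_variants()]); only MODERATE/HIGH rows create edges.
#' @param phenotype_directions Optional named vector phenotype ->
#'   `"up"`/`"down"` (e.g. from physiology comparisons); stored as a node
#'   attribute.
#' @param fdr_max Perturbation significance cutoff (default 0.01).
#' @return An `integration_network`: list with `nodes` (id, kind, log2FC,
#'   cluster, fermentation_ethanol, ros_redox, direction), `edges` (from,
#'   to, weight, relation), `rejects` (character vector of dangling
#'   references).
#' @export
assemble <- function(genes, memberships, perturbations, associations,
                     variants, phenotype_directions = NULL,
                     fdr_max = 0.01) {
  stopifnot(all(c("gene", "log2FC") %in% names(genes)))
  fc <- stats::setNames(genes$log2FC, genes$gene)
  rejects <- character()
  edges <- list()

  # gene -> pathway
  sig <- perturbations[perturbations$FDR <= fdr_max, , drop = FALSE]
  dir_map <- c(activated = "up", up = "up", repressed = "down", down = "down")
  pw_dir <- stats::setNames(dir_map[sig$direction], sig$pathway)
  mem <- memberships[memberships$pathway %in% sig$pathway, , drop = FALSE]
  for (i in seq_len(nrow(mem))) {
    g <- mem$gene[i]
    if (!g %in% names(fc)) {
      rejects <- c(rejects, paste0("membership gene ", g))
      next
    }
    if (fc[[g]] == 0) {
      warning("gene ", g, " has log2FC 0; pathway edge skipped")
      next
    }
    w <- edge_sign(fc[[g]], pw_dir[[mem$pathway[i]]])
    edges[[length(edges) + 1L]] <- data.frame(
      from = g, to = mem$pathway[i], weight = w,
      from_kind = "gene", to_kind = "pathway")
  }

  # gene -> phenotype
  assoc <- associations[associations$passes %in% TRUE, , drop = FALSE]
  for (i in seq_len(nrow(assoc))) {
    g <- assoc$gene[i]
    if (!g %in% names(fc)) {
      rejects <- c(rejects, paste0("association gene ", g))
      next
    }
    w <- if (assoc$sign[i] == "+") 1 else -1
    edges[[length(edges) + 1L]] <- data.frame(
      from = g, to = assoc$phenotype[i], weight = w,
      from_kind = "gene", to_kind = "phenotype")
  }

  # variant -> gene
  vv <- variants[variants$tier %in% c("MODERATE", "HIGH"), , drop = FALSE]
  for (i in seq_len(nrow(vv))) {
    g <- vv$gene[i]
    if (!g %in% names(fc)) {
      rejects <- c(rejects, paste0("variant gene ", g))
      next
    }
    edges[[length(edges) + 1L]] <- data.frame(
      from = vv$variant_id[i], to = g, weight = 0,
      from_kind = "variant", to_kind = "gene")
  }

  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), weight = numeric(),
               from_kind = character(), to_kind = character())
  ed <- unique(ed)
  ed <- ed[order(ed$from_kind, ed$from, ed$to), , drop = FALSE]
  ed$relation <- unname(.relation_for_weight(ed$weight))
  rownames(ed) <- NULL

  node_ids <- unique(c(ed$from, ed$to))
  kind <- rep(NA_character_, length(node_ids))
  kind[node_ids %in% ed$from[ed$from_kind == "variant"]] <- "variant"
  kind[node_ids %in% genes$gene] <- "gene"
  kind[node_ids %in% ed$to[ed$to_kind == "pathway"]] <- "pathway"
  kind[node_ids %in% ed$to[ed$to_kind == "phenotype"]] <- "phenotype"
  nodes <- data.frame(id = node_ids, kind = kind, stringsAsFactors = FALSE)
  nodes$log2FC <- ifelse(nodes$kind == "gene", fc[nodes$id], NA_real_)
  if ("cluster" %in% names(genes)) {
    cl <- stats::setNames(genes$cluster, genes$gene)
    nodes$cluster <- ifelse(nodes$kind == "gene", cl[nodes$id], NA)
  }
  for (flag in c("fermentation_ethanol", "ros_redox")) {
    if (flag %in% names(genes)) {
      fl <- stats::setNames(genes[[flag]], genes$gene)
      nodes[[flag]] <- ifelse(nodes$kind == "gene", fl[nodes$id], NA)
    }
  }
  if (!is.null(phenotype_directions)) {
    nodes$direction <- ifelse(nodes$kind == "phenotype",
                              phenotype_directions[nodes$id], NA_character_)
  }
  nodes <- nodes[order(match(nodes$kind,
                             c("variant", "gene", "pathway", "phenotype")),
                       nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes,
                 edges = ed[, c("from", "to", "weight", "relation")],
                 rejects = rejects),
            class = "integration_network")
}

#' Restrict the integration network to hub/flag-anchored edges
#'
#' Keeps edges with at least one endpoint among the anchor genes (hubs
#' plus fermentation/ethanol- or ROS/redox-flagged genes) and drops nodes
#' left isolated. Idempotent.
#'
#' @param network An `integration_network` from [assemble()].
#' @param hub_genes,flagged_genes Character vectors of gene ids.
#' @return A filtered `integration_network`.
#' @export
extract_anchor_subnetwork <- function(network, hub_genes,
                                      flagged_genes = character()) {
  anchors <- union(hub_genes, flagged_genes)
  if (!length(anchors)) {
    warning("empty anchor set; returning empty network")
  }
  ed <- network$edges
  keep <- ed$from %in% anchors | ed$to %in% anchors
  ed <- ed[keep, , drop = FALSE]
  used <- unique(c(ed$from, ed$to))
  nodes <- network$nodes[network$nodes$id %in% used, , drop = FALSE]
  rownames(ed) <- NULL
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = ed, rejects = network$rejects),
            class = "integration_network")
}

#' Tabulate the integration network as one row per gene
#'
#' One row per gene node with at least one edge: its signed phenotype and
#' pathway links and whether a moderate/high-impact variant hits it.
#' Also reports the counts of positive and negative gene-source edges.
#'
#' @param network An `integration_network`.
#' @return List: `table` (data frame gene, cluster, phenotype_links,
#'   pathway_links, has_variant), `n_positive`, `n_negative`.
#' @export
tabulate_model <- function(network) {
  ed <- network$edges
  nodes <- network$nodes
  kind <- stats::setNames(nodes$kind, nodes$id)
  gene_edges <- ed[kind[ed$from] == "gene", , drop = FALSE]
  variant_targets <- ed$to[kind[ed$from] == "variant"]
  genes <- sort(unique(c(gene_edges$from, variant_targets)))
  fmt_links <- function(d) {
    if (!nrow(d)) return("")
    paste0(d$to, " (", ifelse(d$weight > 0, "+", "-"), ")", collapse = "; ")
  }
  rows <- lapply(genes, function(g) {
    mine <- gene_edges[gene_edges$from == g, , drop = FALSE]
    data.frame(
      gene = g,
      cluster = if ("cluster" %in% names(nodes))
        nodes$cluster[nodes$id == g] else NA,
      phenotype_links = fmt_links(mine[kind[mine$to] == "phenotype", ]),
      pathway_links = fmt_links(mine[kind[mine$to] == "pathway", ]),
      has_variant = g %in% variant_targets,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(gene = character(), cluster = integer(),
                      phenotype_links = character(),
                      pathway_links = character(),
                      has_variant = logical())
  }
  list(table = tab,
       n_positive = sum(gene_edges$weight == 1),
       n_negative = sum(gene_edges$weight == -1))
}

#' Convert an integration network to igraph
#'
#' @param network An `integration_network`.
#' @return Directed igraph graph with node attribute `kind` and edge
#'   attributes `weight` and `relation`; use
#'   [igraph::write_graph()] for GraphML export.
#' @export
integration_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}
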