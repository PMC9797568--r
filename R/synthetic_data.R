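#' Specification of a synthetic multi-omics study
#'
#' Defines the planted structure from which every pipeline input is
#' generated: a planted-community interaction graph, cluster-correlated
#' log2 fold changes, phenotypes linearly driven by cluster activity, and
#' variants spanning all zygosity and impact classes. Defaults emulate the
#' study conditions: four co-expressed clusters of 30 genes, dense
#' intra-cluster wiring (p_in = 0.3) with rare low-confidence inter-cluster
#' edges (p_out = 0.01, confidence below the 0.7 filter), up- and
#' down-regulated clusters at log2FC +/-2, a phenotype driven positively by
#' an up cluster (ethanol production rate) and one driven negatively by a
#' down cluster (biomass yield).
#'
#' @param n_clusters Number of planted clusters.
#' @param cluster_sizes Genes per cluster (recycled to `n_clusters`).
#' @param p_in,p_out Intra-/inter-cluster edge probabilities, with
#'   0 <= p_out < p_in <= 1.
#' @param ppi_in_range,ppi_out_range Confidence-score intervals for intra-
#'   and inter-cluster edges.
#' @param cluster_fc_means Per-cluster log2FC centers; must contain at
#'   least one positive and one negative value (up- and down-regulated
#'   clusters).
#' @param fc_noise_sd SD of per-gene log2FC noise around the cluster mean
#'   (also used as the per-sample expression noise SD).
#' @param n_samples Number of expression/phenotype samples (>= 4; split
#'   evenly into control and treated).
#' @param phenotype_effects Data frame with columns `phenotype`, `cluster`,
#'   `effect`: each phenotype is `effect` times the mean expression of its
#'   driver cluster plus noise.
#' @param pheno_noise_sd SD of phenotype noise.
#' @param n_variants Number of variants to generate.
#' @param variant_class_probs Probabilities over the 12 zygosity x impact
#'   classes (named `<zygosity>.<tier>`); default uniform.
#' @param seed Integer seed driving all sub-generators.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_clusters = 4,
                           cluster_sizes = rep(30, n_clusters),
                           p_in = 0.3, p_out = 0.01,
                           ppi_in_range = c(0.75, 0.99),
                           ppi_out_range = c(0.40, 0.69),
                           cluster_fc_means = rep(c(2, -2),
                                                  length.out = n_clusters),
                           fc_noise_sd = 0.3,
                           n_samples = 50,
                           phenotype_effects = data.frame(
                             phenotype = c("qEthanol", "biomass_yield"),
                             cluster = c(1L, 2L),
                             effect = c(1, -1)),
                           pheno_noise_sd = 0.1,
                           n_variants = 200,
                           variant_class_probs = NULL,
                           seed = 1L) {
  cluster_sizes <- rep(cluster_sizes, length.out = n_clusters)
  cluster_fc_means <- rep(cluster_fc_means, length.out = n_clusters)
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  rng_ok <- function(r) length(r) == 2 && all(r >= 0 & r <= 1) && r[1] <= r[2]
  if (!rng_ok(ppi_in_range) || !rng_ok(ppi_out_range)) {
    stop("ppi score ranges must be increasing intervals within [0, 1]")
  }
  if (!any(cluster_fc_means > 0) || !any(cluster_fc_means < 0)) {
    stop("cluster_fc_means needs at least one positive and one negative value")
  }
  if (n_samples < 4) stop("n_samples must be >= 4")
  if (!all(phenotype_effects$cluster %in% seq_len(n_clusters))) {
    stop("phenotype_effects references an unknown cluster")
  }
  zyg <- c("homozygous", "het_with_ref", "het_without_ref")
  tiers <- c("MODIFIER", "LOW", "MODERATE", "HIGH")
  classes <- as.vector(outer(zyg, tiers, paste, sep = "."))
  if (is.null(variant_class_probs)) {
    variant_class_probs <- stats::setNames(rep(1 / 12, 12), classes)
  }
  if (!setequal(names(variant_class_probs), classes)) {
    stop("variant_class_probs must be named over all zygosity x tier classes")
  }
  if (any(variant_class_probs < 0) ||
      abs(sum(variant_class_probs) - 1) > 1e-8) {
    stop("variant_class_probs must be non-negative and sum to 1")
  }
  structure(list(n_clusters = n_clusters, cluster_sizes = cluster_sizes,
                 p_in = p_in, p_out = p_out,
                 ppi_in_range = ppi_in_range, ppi_out_range = ppi_out_range,
                 cluster_fc_means = cluster_fc_means,
                 fc_noise_sd = fc_noise_sd, n_samples = n_samples,
                 phenotype_effects = phenotype_effects,
                 pheno_noise_sd = pheno_noise_sd,
                 n_variants = n_variants,
                 variant_class_probs = variant_class_probs[classes],
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate the planted-community interaction network and fold changes
#'
#' Draws a planted-partition graph: each within-cluster pair is an edge
#' with probability `p_in` (confidence uniform in `ppi_in_range`), each
#' between-cluster pair with probability `p_out` (confidence in
#' `ppi_out_range`). Gene log2 fold changes are the cluster center plus
#' Gaussian noise. Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `edges` (gene_a, gene_b, ppi_score), `degs` (gene,
#'   log2FC, PValue, FDR), and `truth` (list: `clusters` named vector
#'   gene -> planted cluster id, `phenotype_signs` named vector
#'   phenotype -> planted sign).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- sum(spec$cluster_sizes)
  genes <- sprintf("G%03d", seq_len(n))
  clusters <- rep(seq_len(spec$n_clusters), times = spec$cluster_sizes)
  names(clusters) <- genes

  pairs <- utils::combn(n, 2)
  same <- clusters[pairs[1, ]] == clusters[pairs[2, ]]
  p <- ifelse(same, spec$p_in, spec$p_out)
  keep <- stats::runif(ncol(pairs)) < p
  lo <- ifelse(same[keep], spec$ppi_in_range[1], spec$ppi_out_range[1])
  hi <- ifelse(same[keep], spec$ppi_in_range[2], spec$ppi_out_range[2])
  edges <- data.frame(
    gene_a = genes[pairs[1, keep]],
    gene_b = genes[pairs[2, keep]],
    ppi_score = stats::runif(sum(keep), lo, hi),
    stringsAsFactors = FALSE
  )

  log2fc <- spec$cluster_fc_means[clusters] +
    stats::rnorm(n, 0, spec$fc_noise_sd)
  degs <- data.frame(
    gene = genes,
    log2FC = log2fc,
    PValue = stats::runif(n, 1e-8, 1e-3),
    FDR = stats::runif(n, 1e-6, 5e-3),
    stringsAsFactors = FALSE
  )

  signs <- ifelse(spec$phenotype_effects$effect >= 0, "+", "-")
  truth <- list(
    clusters = clusters,
    phenotype_signs = stats::setNames(signs, spec$phenotype_effects$phenotype)
  )
  list(edges = edges, degs = degs, truth = truth)
}

#' Generate per-sample expression and phenotype tables
#'
#' Samples split evenly into control and treated. Expression of gene g in
#' sample s is a gene baseline plus, for treated samples, the gene's
#' log2FC, plus Gaussian noise (`fc_noise_sd`). Each phenotype is
#' effect x (mean expression of its driver cluster) + noise
#' (`pheno_noise_sd`).
#'
#' @param degs Fold-change table from [generate_network()].
#' @param truth Ground truth from [generate_network()].
#' @param spec The [synthetic_spec()].
#' @return List with `expression` (genes x samples matrix, log2 scale) and
#'   `phenotypes` (data frame: sample, condition, one column per
#'   phenotype).
#' @export
generate_phenotypes <- function(degs, truth, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  genes <- degs$gene
  n <- length(genes)
  ns <- spec$n_samples
  cond <- rep(c(0, 1), each = ceiling(ns / 2))[seq_len(ns)]
  baseline <- stats::rnorm(n, 8, 1)
  expr <- matrix(baseline, n, ns) +
    outer(degs$log2FC, cond) +
    matrix(stats::rnorm(n * ns, 0, spec$fc_noise_sd), n, ns)
  rownames(expr) <- genes
  colnames(expr) <- sprintf("S%02d", seq_len(ns))

  pheno <- data.frame(sample = colnames(expr),
                      condition = ifelse(cond == 1, "treated", "control"),
                      stringsAsFactors = FALSE)
  pe <- spec$phenotype_effects
  for (ph in unique(pe$phenotype)) {
    rows <- pe[pe$phenotype == ph, , drop = FALSE]
    if (!all(rows$cluster %in% truth$clusters)) {
      stop("phenotype_effects references an unknown cluster")
    }
    val <- rep(0, ns)
    for (j in seq_len(nrow(rows))) {
      members <- names(truth$clusters)[truth$clusters == rows$cluster[j]]
      val <- val + rows$effect[j] * colMeans(expr[members, , drop = FALSE])
    }
    pheno[[ph]] <- val + stats::rnorm(ns, 0, spec$pheno_noise_sd)
  }
  list(expression = expr, phenotypes = pheno)
}

# Representative VEP-style consequence terms per impact tier; drawn from
# when a synthetic variant of that tier is generated.
.tier_terms <- list(
  MODIFIER = c("intron_variant", "5_prime_UTR_variant",
               "3_prime_UTR_variant", "upstream_gene_variant",
               "downstream_gene_variant", "intergenic_variant"),
  LOW      = c("synonymous_variant", "splice_region_variant",
               "stop_retained_variant"),
  MODERATE = c("missense_variant", "inframe_insertion", "inframe_deletion"),
  HIGH     = c("frameshift_variant", "stop_gained",
               "splice_acceptor_variant", "splice_donor_variant")
)

.zygosity_gt <- c(homozygous = "1/1", het_with_ref = "0/1",
                  het_without_ref = "1/2")

#' Generate synthetic variant calls and consequence annotations
#'
#' Draws `spec$n_variants` variants over the gene set: a zygosity x impact
#' class per the spec's class probabilities, a genotype string realizing
#' the zygosity, a consequence term realizing the tier, and a host gene.
#' A small fraction of variants (~5%, at least one) is annotated to two
#' genes, so per-gene consequence rows can exceed the distinct variant
#' count.
#'
#' @param genes Character vector of gene ids.
#' @param spec The [synthetic_spec()].
#' @return List with `vcf` (data frame of VCF columns CHROM, POS, ID, REF,
#'   ALT, QUAL, FILTER, INFO, FORMAT, sample), `consequences` (data frame:
#'   variant_id, gene, consequence), and `truth` (data frame: variant_id,
#'   zygosity, tier).
#' @export
generate_variants <- function(genes, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  nv <- spec$n_variants
  classes <- names(spec$variant_class_probs)
  cls <- sample(classes, nv, replace = TRUE,
                prob = spec$variant_class_probs)
  parts <- strsplit(cls, ".", fixed = TRUE)
  zyg <- vapply(parts, `[`, "", 1)
  tier <- vapply(parts, `[`, "", 2)
  gt <- .zygosity_gt[zyg]
  alt <- ifelse(zyg == "het_without_ref", "T,G", "T")
  vcf <- data.frame(
    CHROM = "chrI",
    POS = sort(sample.int(1e6, nv)),
    ID = sprintf("v%04d", seq_len(nv)),
    REF = "A",
    ALT = alt,
    QUAL = 60,
    FILTER = "PASS",
    INFO = ".",
    FORMAT = "GT",
    sample = unname(gt),
    stringsAsFactors = FALSE
  )
  term <- vapply(tier, function(t) sample(.tier_terms[[t]], 1), "")
  host <- sample(genes, nv, replace = TRUE)
  cons <- data.frame(variant_id = vcf$ID, gene = host,
                     consequence = unname(term), stringsAsFactors = FALSE)
  # annotate ~5% (>= 1) of variants to a second gene
  n_multi <- max(1L, round(0.05 * nv))
  multi <- sample.int(nv, n_multi)
  second <- vapply(host[multi], function(g) sample(setdiff(genes, g), 1), "")
  cons <- rbind(cons, data.frame(variant_id = vcf$ID[multi], gene = second,
                                 consequence = unname(term[multi]),
                                 stringsAsFactors = FALSE))
  cons <- cons[order(cons$variant_id, cons$gene), ]
  rownames(cons) <- NULL
  list(vcf = vcf, consequences = cons,
       truth = data.frame(variant_id = vcf$ID, zygosity = unname(zyg),
                          tier = unname(tier), stringsAsFactors = FALSE))
}

#' Generate a GMT-style term catalogue from the planted clusters
#'
#' One term per planted cluster (its member genes), emulating functional
#' classes that coincide with co-expression structure, plus one broad term
#' covering half of all genes as background signal.
#'
#' @param truth Ground truth from [generate_network()].
#' @return Named list term -> character vector of genes.
#' @export
generate_terms <- function(truth) {
  cl <- truth$clusters
  terms <- lapply(sort(unique(cl)), function(k) names(cl)[cl == k])
  names(terms) <- sprintf("TERM_C%d", sort(unique(cl)))
  terms$TERM_BROAD <- names(cl)[seq_len(floor(length(cl) / 2))]
  terms
}

#' Generate a pathway perturbation table from the planted clusters
#'
#' Each cluster term is reported perturbed in the direction of its fold
#' change center, with a significant FDR, emulating an upstream pathway
#' perturbation analysis.
#'
#' @param spec The [synthetic_spec()].
#' @return Data frame: pathway, direction ("activated"/"repressed"),
#'   fold_enrichment, FDR.
#' @export
generate_perturbations <- function(spec) {
  data.frame(
    pathway = sprintf("TERM_C%d", seq_len(spec$n_clusters)),
    direction = ifelse(spec$cluster_fc_means > 0, "activated", "repressed"),
    fold_enrichment = 2 + abs(spec$cluster_fc_means),
    FDR = 1e-4,
    stringsAsFactors = FALSE
  )
}

#' Generate the complete synthetic study
#'
#' Convenience wrapper running every generator off the single spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `edges`, `degs`, `truth`, `expression`, `phenotypes`,
#'   `vcf`, `consequences`, `variant_truth`, `terms`, `perturbations`.
#' @export
generate_study <- function(spec = synthetic_spec()) {
  net <- generate_network(spec)
  ph <- generate_phenotypes(net$degs, net$truth, spec)
  var <- generate_variants(net$degs$gene, spec)
  list(edges = net$edges, degs = net$degs, truth = net$truth,
       expression = ph$expression, phenotypes = ph$phenotypes,
       vcf = var$vcf, consequences = var$consequences,
       variant_truth = var$truth,
       terms = generate_terms(net$truth),
       perturbations = generate_perturbations(spec))
}
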