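# Small hand-built study for integration tests.
integration_fixture <- function() {
  list(
    genes = data.frame(
      gene = c("g1", "g2", "g3", "g4", "g5"),
      log2FC = c(1.2, -0.8, 2.0, -1.5, 0.6),
      cluster = c(1, 1, 2, 2, 3)),
    memberships = data.frame(
      gene = c("g1", "g2", "g3", "g4"),
      pathway = c("P1", "P1", "P2", "P2")),
    perturbations = data.frame(
      pathway = c("P1", "P2"),
      direction = c("activated", "repressed"),
      fold_enrichment = c(3, 2), FDR = c(1e-4, 1e-3)),
    associations = data.frame(
      gene = c("g1", "g4", "g5"),
      phenotype = c("qEthanol", "biomass_yield", "qEthanol"),
      sign = c("+", "-", NA), passes = c(TRUE, TRUE, FALSE)),
    variants = data.frame(
      variant_id = c("v1", "v2", "v3"),
      gene = c("g1", "g3", "g5"),
      tier = c("MODERATE", "HIGH", "LOW"))
  )
}

test_that("edge sign encodes direct vs inverse regulation", {
  expect_equal(edge_sign(1.2, "up"), 1)     # both upregulated: direct
  expect_equal(edge_sign(-0.8, "up"), -1)   # opposed: inverse
  expect_equal(edge_sign(-0.8, "down"), 1)
  expect_error(edge_sign(0, "up"), "direction")
})

test_that("assembly realizes the layer rules on hand-built fixtures", {
  fx <- integration_fixture()
  net <- assemble(fx$genes, fx$memberships, fx$perturbations,
                  fx$associations, fx$variants,
                  phenotype_directions = c(qEthanol = "up",
                                           biomass_yield = "down"))
  ed <- net$edges
  # expected by hand: g1->P1 +1 (up/activated), g2->P1 -1 (down/activated),
  # g3->P2 -1 (up/repressed), g4->P2 +1 (down/repressed),
  # g1->qEthanol +1, g4->biomass_yield -1 (association signs),
  # v1->g1 0, v2->g3 0 (moderate/high only; v3 LOW excluded)
  expect_equal(nrow(ed), 8)
  get_w <- function(f, t) ed$weight[ed$from == f & ed$to == t]
  expect_equal(get_w("g1", "P1"), 1)
  expect_equal(get_w("g2", "P1"), -1)
  expect_equal(get_w("g3", "P2"), -1)
  expect_equal(get_w("g4", "P2"), 1)
  expect_equal(get_w("g1", "qEthanol"), 1)
  expect_equal(get_w("g4", "biomass_yield"), -1)
  expect_equal(get_w("v1", "g1"), 0)
  expect_equal(get_w("v2", "g3"), 0)
  expect_equal(length(get_w("v3", "g5")), 0)
  expect_equal(ed$relation[ed$weight == 0], rep("neutral", 2))

  # one gene, one activated pathway, one homozygous missense variant
  net2 <- assemble(
    data.frame(gene = "g", log2FC = 1),
    data.frame(gene = "g", pathway = "P"),
    data.frame(pathway = "P", direction = "activated", FDR = 1e-3),
    data.frame(gene = character(), phenotype = character(),
               sign = character(), passes = logical()),
    data.frame(variant_id = "v", gene = "g", tier = "MODERATE"))
  expect_equal(nrow(net2$edges), 2)
  expect_equal(sort(net2$edges$weight), c(0, 1))

  empty <- assemble(
    data.frame(gene = character(), log2FC = numeric()),
    data.frame(gene = character(), pathway = character()),
    data.frame(pathway = character(), direction = character(),
               FDR = numeric()),
    data.frame(gene = character(), phenotype = character(),
               sign = character(), passes = logical()),
    data.frame(variant_id = character(), gene = character(),
               tier = character()))
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 0)
})

test_that("assembly is order-invariant and reports dangling references", {
  fx <- integration_fixture()
  dirs <- c(qEthanol = "up", biomass_yield = "down")
  net <- assemble(fx$genes, fx$memberships, fx$perturbations,
                  fx$associations, fx$variants, dirs)
  shuffle <- function(d) d[sample(nrow(d)), , drop = FALSE]
  set.seed(77)
  net2 <- assemble(shuffle(fx$genes), shuffle(fx$memberships),
                   shuffle(fx$perturbations), shuffle(fx$associations),
                   shuffle(fx$variants), dirs)
  expect_equal(net$edges, net2$edges)
  expect_equal(net$nodes, net2$nodes)

  fx$variants$gene[1] <- "unknown_gene"
  net3 <- assemble(fx$genes, fx$memberships, fx$perturbations,
                   fx$associations, fx$variants, dirs)
  expect_match(net3$rejects, "unknown_gene", all = FALSE)
})

test_that("weight alphabet and layer directionality hold on random inputs", {
  for (s in 1:20) {
    st <- generate_study(synthetic_spec(seed = 100 + s, n_samples = 8))
    degs <- filter_degs(st$degs)
    genes <- data.frame(gene = degs$gene, log2FC = degs$log2FC)
    mem <- do.call(rbind, lapply(names(st$terms), function(tn) {
      data.frame(gene = st$terms[[tn]], pathway = tn)
    }))
    assoc <- associate_all(st$expression[sample(rownames(st$expression),
                                                10), ],
                           st$phenotypes)
    cl <- classify_variants(st$vcf, st$consequences)
    net <- assemble(genes, mem, st$perturbations, assoc, cl)
    ed <- net$edges
    kind <- setNames(net$nodes$kind, net$nodes$id)
    expect_true(all(ed$weight %in% c(-1, 0, 1)))
    expect_true(all(ed$weight[kind[ed$from] == "variant"] == 0))
    expect_true(all(abs(ed$weight[kind[ed$from] == "gene"]) == 1))
    expect_true(all(kind[ed$from] %in% c("variant", "gene")))
    expect_true(all(kind[ed$to] %in% c("gene", "pathway", "phenotype")))
    expect_true(all(kind[ed$to][kind[ed$from] == "variant"] == "gene"))
    # variant nodes: out-degree only; pathway/phenotype: in-degree only
    expect_false(any(ed$to %in% net$nodes$id[net$nodes$kind == "variant"]))
    expect_false(any(ed$from %in%
                       net$nodes$id[net$nodes$kind %in%
                                      c("pathway", "phenotype")]))
    expect_true(all((ed$relation == "direct") == (ed$weight == 1)))
    expect_true(all((ed$relation == "inverse") == (ed$weight == -1)))
  }
})

test_that("anchor extraction keeps incident edges and is idempotent", {
  fx <- integration_fixture()
  net <- assemble(fx$genes, fx$memberships, fx$perturbations,
                  fx$associations, fx$variants)
  all_genes <- fx$genes$gene
  expect_equal(extract_anchor_subnetwork(net, all_genes)$edges, net$edges)
  expect_warning(e0 <- extract_anchor_subnetwork(net, character()),
                 "empty anchor")
  expect_equal(nrow(e0$edges), 0)

  sub <- extract_anchor_subnetwork(net, "g1")
  expect_setequal(unique(c(sub$edges$from, sub$edges$to)),
                  c("g1", "P1", "qEthanol", "v1"))
  expect_true(all(sub$edges$from == "g1" | sub$edges$to == "g1"))
  sub2 <- extract_anchor_subnetwork(sub, "g1")
  expect_equal(sub2$edges, sub$edges)
  expect_equal(sub2$nodes, sub$nodes)
})

test_that("model table lists signed links with conserved edge counts", {
  fx <- integration_fixture()
  net <- assemble(fx$genes, fx$memberships, fx$perturbations,
                  fx$associations, fx$variants)
  tm <- tabulate_model(net)
  expect_equal(tm$n_positive + tm$n_negative,
               sum(net$edges$weight != 0))
  g1 <- tm$table[tm$table$gene == "g1", ]
  expect_match(g1$phenotype_links, "qEthanol \\(\\+\\)")
  expect_match(g1$pathway_links, "P1 \\(\\+\\)")
  expect_true(g1$has_variant)
  expect_false(tm$table$has_variant[tm$table$gene == "g2"])
  expect_false("g5" %in% tm$table$gene)   # no edges -> excluded
})
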