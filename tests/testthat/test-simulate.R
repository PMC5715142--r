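test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- simulationConfig(seed = 11, n_compounds = 50, pass_fraction = 0.4,
                          n_modules = 4, module_size = 6, p_in = 0.8,
                          p_out = 0.05, n_terms = 10,
                          bipartite_density = 0.3, n_disease_genes = 10)
  expect_identical(genCompoundTable(cfg), genCompoundTable(cfg))
  expect_identical(genPlantedPPI(cfg), genPlantedPPI(cfg))
  ppi <- genPlantedPPI(cfg)
  expect_identical(genBipartiteTargets(c("c1", "c2"), ppi$genes, cfg),
                   genBipartiteTargets(c("c1", "c2"), ppi$genes, cfg))
  expect_identical(genAnnotation(ppi$genes, cfg),
                   genAnnotation(ppi$genes, cfg))
  expect_identical(genDiseaseGenes(ppi$genes, ppi$genes[1:10], cfg),
                   genDiseaseGenes(ppi$genes, ppi$genes[1:10], cfg))
})

test_that("generators restore the caller's RNG state", {
  cfg <- simulationConfig(seed = 11, n_compounds = 5)
  set.seed(99)
  before <- .Random.seed
  invisible(genCompoundTable(cfg))
  expect_identical(.Random.seed, before)
})

test_that("compound pass rates hit their targets", {
  cfg1 <- simulationConfig(seed = 1, n_compounds = 100, pass_fraction = 1.0)
  expect_true(all(applyAdmeFilter(genCompoundTable(cfg1))$retained$compound_id ==
                    genCompoundTable(cfg1)$compound_id))
  cfg0 <- simulationConfig(seed = 1, n_compounds = 100, pass_fraction = 0.0)
  expect_equal(nrow(applyAdmeFilter(genCompoundTable(cfg0))$retained), 0L)
  # binomial bound: n = 10000, p = 0.3, within 3 standard errors
  cfg <- simulationConfig(seed = 7, n_compounds = 10000, pass_fraction = 0.3)
  tab <- genCompoundTable(cfg)
  rate <- nrow(applyAdmeFilter(tab)$retained) / nrow(tab)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(rate - 0.3), 3 * se)
  # ground-truth labels agree with the filter by direct recount
  expect_identical(applyAdmeFilter(tab)$retained$compound_id,
                   tab$compound_id[tab$true_pass])
})

test_that("planted PPI respects edge probabilities and is simple", {
  # p_in = 1, p_out = 0: disjoint union of cliques
  cfg <- simulationConfig(seed = 3, n_modules = 3, module_size = 5,
                          p_in = 1, p_out = 0)
  ppi <- genPlantedPPI(cfg)
  expect_equal(nrow(ppi$edges), 3 * choose(5, 2))
  expect_true(all(ppi$labels[ppi$edges$node_a] == ppi$labels[ppi$edges$node_b]))
  # binomial bound on within-module edges
  cfg2 <- simulationConfig(seed = 1, n_modules = 3, module_size = 8,
                           p_in = 0.9, p_out = 0.02)
  ppi2 <- genPlantedPPI(cfg2)
  within <- sum(ppi2$labels[ppi2$edges$node_a] == ppi2$labels[ppi2$edges$node_b])
  mu <- 0.9 * choose(8, 2) * 3
  se <- sqrt(3 * choose(8, 2) * 0.9 * 0.1)
  expect_lt(abs(within - mu), 3 * se)
  # simple graph: canonical, no loops, no duplicates
  expect_true(all(ppi2$edges$node_a < ppi2$edges$node_b))
  expect_false(anyDuplicated(paste(ppi2$edges$node_a, ppi2$edges$node_b)) > 0)
  # confidences inside the configured range
  expect_true(all(ppi2$edges$confidence >= 0.2 & ppi2$edges$confidence <= 1))
  expect_error(simulationConfig(seed = 1, p_in = 0.3, p_out = 0.5), "p_out")
})

test_that("bipartite association density is honored", {
  cfg1 <- simulationConfig(seed = 5, bipartite_density = 1)
  full <- genBipartiteTargets(c("c1", "c2"), c("g1", "g2", "g3"), cfg1)
  expect_equal(nrow(full), 6L)
  cfg0 <- simulationConfig(seed = 5, bipartite_density = 0)
  expect_equal(nrow(genBipartiteTargets(c("c1"), c("g1"), cfg0)), 0L)
  # paper-scale binomial bound: 77 x 432 at density 0.52
  cfg <- simulationConfig(seed = 3, bipartite_density = 0.52)
  comp <- sprintf("C%02d", 1:77)
  genes <- sprintf("G%04d", 1:432)
  assoc <- genBipartiteTargets(comp, genes, cfg)
  mu <- 0.52 * 77 * 432
  se <- sqrt(77 * 432 * 0.52 * 0.48)
  expect_lt(abs(nrow(assoc) - mu), 3 * se)
  expect_false(anyDuplicated(paste(assoc$compound_id, assoc$gene_id)) > 0)
  expect_error(genBipartiteTargets(character(), genes, cfg), "non-empty")
})

test_that("annotation generator plants terms as configured", {
  labels <- labelledUniverse(200, 20)
  genes <- names(labels)
  # infinite strength: the term set equals its module's gene set
  cfg <- simulationConfig(seed = 9, n_terms = 5, term_density = 0.05,
                          planted_terms = list(list(term_id = "TP", module = 2,
                                                    strength = Inf)))
  ann <- genAnnotation(genes, cfg, module_labels = labels)
  expect_setequal(ann$catalog@terms[["TP"]], genes[labels == 2])
  # unknown module is rejected at configuration time
  expect_error(simulationConfig(seed = 9, n_terms = 5, n_modules = 3,
                                planted_terms = list(list(term_id = "TP",
                                                          module = 99,
                                                          strength = 2))),
               "unknown module")
  # null catalog: no term set should preferentially hit one module
  cfg0 <- simulationConfig(seed = 9, n_terms = 30, term_density = 0.1)
  ann0 <- genAnnotation(genes, cfg0, module_labels = labels)
  expect_length(ann0$planted, 0L)
  expect_s4_class(ann0$catalog, "AnnotationCatalog")
  expect_true(all(lengths(ann0$catalog@terms) >= 1L))
})

test_that("disease gene overlap fraction is honored", {
  genes <- sprintf("G%04d", 1:600)
  targets <- genes[1:300]
  cfg0 <- simulationConfig(seed = 2, disease_overlap_fraction = 0,
                           n_disease_genes = 50)
  d0 <- genDiseaseGenes(genes, targets, cfg0)
  expect_length(intersect(d0$genes, targets), 0L)
  cfg1 <- simulationConfig(seed = 2, disease_overlap_fraction = 1,
                           n_disease_genes = 50)
  d1 <- genDiseaseGenes(genes, targets, cfg1)
  expect_true(all(d1$genes %in% targets))
  # n = 131, overlap = 0.5: within 3 binomial SE of 65.5
  cfg <- simulationConfig(seed = 11, disease_overlap_fraction = 0.5,
                          n_disease_genes = 131)
  d <- genDiseaseGenes(genes, targets, cfg)
  expect_length(d$genes, 131L)
  se <- sqrt(131 * 0.25)
  expect_lt(abs(length(intersect(d$genes, targets)) - 65.5), 3 * se)
  expect_setequal(d$shared, intersect(d$genes, targets))
  # list longer than universe is an error
  big <- simulationConfig(seed = 1, n_disease_genes = 9999)
  expect_error(genDiseaseGenes(genes, targets, big), "longer than")
})

test_that("simulation config validates fractions", {
  expect_error(simulationConfig(seed = 1, pass_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulationConfig(seed = 1, confidence_range = c(0.9, 0.1)),
               "confidence_range")
})
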