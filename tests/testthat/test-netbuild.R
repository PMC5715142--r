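test_that("PPI confidence filter is strictly greater-than and deduplicates", {
  ed <- data.frame(node_a = c("A", "B", "C", "A", "B"),
                   node_b = c("B", "C", "D", "B", "A"),
                   confidence = c(0.39, 0.40, 0.41, 0.5, 0.7))
  out <- filterPPI(ed)
  expect_setequal(edgeKeysForTest(out), c("A|B", "C|D"))
  # duplicate (A,B,0.5) / (B,A,0.7) keeps the maximum
  expect_equal(out$confidence[out$node_a == "A" & out$node_b == "B"], 0.7)
  expect_error(filterPPI(data.frame(node_a = "A", node_b = "B",
                                    confidence = 1.5)), "malformed")
  expect_error(filterPPI(data.frame(node_a = "A", node_b = "B",
                                    confidence = NA_real_)), "malformed")
})

test_that("disease network is the induced subgraph with isolated genes dropped", {
  ppi <- data.frame(node_a = c("A", "A"), node_b = c("B", "X"),
                    confidence = c(0.9, 0.9))
  net <- buildDiseaseNetwork(c("A", "B", "C"), ppi)
  expect_setequal(nodes(net)$id, c("A", "B"))
  expect_equal(numEdges(net), 1L)
  expect_true(all(nodes(net)$role == "disease_target"))
  # no within-set edge at all: empty network
  net2 <- buildDiseaseNetwork(c("A", "B"), data.frame(node_a = "A",
                                                      node_b = "X",
                                                      confidence = 0.9))
  expect_equal(numNodes(net2), 0L)
  expect_error(buildDiseaseNetwork(character(), ppi), "empty")
})

test_that("a 131-gene list with 113 interacting genes yields a 113-node network", {
  genes <- sprintf("D%03d", 1:131)
  connected <- genes[1:113]
  cyc <- data.frame(node_a = connected,
                    node_b = c(connected[-1L], connected[1L]),
                    confidence = 0.9)
  # the other 18 genes interact only with non-disease proteins
  stray <- data.frame(node_a = genes[114:131],
                      node_b = sprintf("X%03d", 1:18),
                      confidence = 0.9)
  net <- buildDiseaseNetwork(genes, rbind(cyc, stray))
  expect_equal(numNodes(net), 113L)
  expect_equal(numEdges(net), 113L)
})

test_that("bipartite network counts nodes and edges per distinct pair", {
  assoc <- expand.grid(compound_id = c("c1", "c2"),
                       gene_id = c("g1", "g2", "g3"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  net <- buildBipartiteNetwork(assoc)
  expect_equal(numNodes(net), 5L)
  expect_equal(numEdges(net), 6L)
  roles <- nodeRoles(net)
  expect_setequal(names(roles)[roles == "compound"], c("c1", "c2"))
  expect_setequal(names(roles)[roles == "compound_target"],
                  c("g1", "g2", "g3"))
  # duplicated association rows collapse to one edge
  expect_equal(numEdges(buildBipartiteNetwork(rbind(assoc, assoc))), 6L)
  empty <- buildBipartiteNetwork(data.frame(compound_id = character(),
                                            gene_id = character()))
  expect_equal(numNodes(empty), 0L)
  expect_error(buildBipartiteNetwork(data.frame(compound_id = "A",
                                                gene_id = "A")),
               "collision")
})

test_that("paper-scale bipartite layer has 509 nodes", {
  cfg <- simulationConfig(seed = 3, bipartite_density = 0.52)
  assoc <- genBipartiteTargets(sprintf("C%02d", 1:77),
                               sprintf("G%04d", 1:432), cfg)
  net <- buildBipartiteNetwork(assoc)
  expect_equal(numNodes(net), 509L)
  expect_equal(sum(nodeRoles(net) == "compound"), 77L)
  expect_equal(sum(nodeRoles(net) == "compound_target"), 432L)
})

test_that("merging takes exact unions, recomputes roles, reports increments", {
  drug <- buildBipartiteNetwork(data.frame(compound_id = c("c1", "c1"),
                                           gene_id = c("A", "B")))
  disease <- buildDiseaseNetwork(c("A", "P", "Q"),
                                 data.frame(node_a = c("A", "P"),
                                            node_b = c("P", "Q"),
                                            confidence = 0.9))
  merged <- mergeNetworks(drug, disease,
                          data.frame(node_a = "B", node_b = "Q",
                                     confidence = 0.9))
  expect_setequal(nodes(merged)$id,
                  union(nodes(drug)$id, nodes(disease)$id))
  roles <- nodeRoles(merged)
  expect_identical(roles[["A"]], "shared_target")
  expect_identical(roles[["B"]], "compound_target")
  expect_identical(roles[["P"]], "disease_target")
  expect_identical(roles[["c1"]], "compound")
  # drug edges (2) + disease edges (2) + PPI edge among merged proteins (1)
  expect_equal(numEdges(merged), 5L)
  inc <- networkIncrement(merged, drug)
  expect_equal(unname(inc["nodes"]), numNodes(merged) - numNodes(drug))
  expect_equal(unname(inc["edges"]), numEdges(merged) - numEdges(drug))
  # disjoint components with no extra PPI: pure union arithmetic
  d2 <- buildDiseaseNetwork(c("P", "Q"), data.frame(node_a = "P", node_b = "Q",
                                                    confidence = 0.9))
  m2 <- mergeNetworks(drug, d2, data.frame(node_a = character(),
                                           node_b = character(),
                                           confidence = numeric()))
  expect_equal(numNodes(m2), numNodes(drug) + numNodes(d2))
  expect_equal(numEdges(m2), numEdges(drug) + numEdges(d2))
})

test_that("role partition is exhaustive and exclusive on simulated inputs", {
  cfg <- simulationConfig(seed = 21, n_compounds = 10, n_modules = 5,
                          module_size = 8, p_in = 0.8, p_out = 0.05,
                          bipartite_density = 0.3, n_disease_genes = 12,
                          disease_overlap_fraction = 0.5)
  ppi <- genPlantedPPI(cfg)
  assoc <- genBipartiteTargets(sprintf("C%02d", 1:10), ppi$genes[1:20], cfg)
  dis <- genDiseaseGenes(ppi$genes, unique(assoc$gene_id), cfg)
  ppiF <- filterPPI(ppi$edges)
  merged <- mergeNetworks(buildBipartiteNetwork(assoc),
                          buildDiseaseNetwork(dis$genes, ppiF), ppiF)
  roles <- nodeRoles(merged)
  expect_true(all(roles %in% c("compound", "compound_target",
                               "disease_target", "shared_target")))
  shared <- names(roles)[roles == "shared_target"]
  expect_setequal(shared,
                  intersect(unique(assoc$gene_id),
                            nodes(buildDiseaseNetwork(dis$genes, ppiF))$id))
})

test_that("expansion adds exactly the first PPI neighborhood", {
  core <- typedNetwork(c("A"), role = "compound_target")
  ppi <- data.frame(node_a = c("A", "X"), node_b = c("X", "Y"),
                    confidence = c(0.9, 0.9))
  ex <- expandNetwork(core, ppi)
  expect_setequal(nodes(ex)$id, c("A", "X"))
  expect_equal(numEdges(ex), 1L)
  # an edge between two added neighbors is included
  core2 <- typedNetwork(c("A"), role = "compound_target")
  ppi2 <- data.frame(node_a = c("A", "A", "X"), node_b = c("X", "Y", "Y"),
                     confidence = 0.9)
  ex2 <- expandNetwork(core2, ppi2)
  expect_equal(numEdges(ex2), 3L)
  # added disease genes keep the disease role
  ex3 <- expandNetwork(core2, ppi2, disease_genes = "Y")
  expect_identical(nodeRoles(ex3)[["Y"]], "disease_target")
  expect_identical(nodeRoles(ex3)[["X"]], "other_protein")
})

test_that("all constructed graphs are simple and canonical", {
  cfg <- simulationConfig(seed = 8, n_modules = 4, module_size = 6,
                          p_in = 0.9, p_out = 0.1)
  ppi <- genPlantedPPI(cfg)
  for (net in list(buildDiseaseNetwork(ppi$genes[1:10], filterPPI(ppi$edges)),
                   expandNetwork(typedNetwork(ppi$genes[1],
                                              role = "compound_target"),
                                 filterPPI(ppi$edges)))) {
    ed <- edges(net)
    expect_true(all(ed$node_a < ed$node_b))
    expect_false(anyDuplicated(paste(ed$node_a, ed$node_b)) > 0)
  }
})

test_that("TypedNetwork validity rejects malformed graphs", {
  expect_error(typedNetwork("A", data.frame(node_a = "A", node_b = "A")),
               "self-loop")
  expect_error(typedNetwork(data.frame(id = "A", role = "hero")), "role")
  expect_error(typedNetwork("A", data.frame(node_a = "A", node_b = "B")),
               "missing")
})

test_that("networks round-trip through SIF and write GraphML", {
  net <- buildBipartiteNetwork(data.frame(compound_id = c("c1", "c2"),
                                          gene_id = c("g1", "g1")))
  sif <- withr::local_tempfile(fileext = ".sif")
  writeSIF(net, sif)
  back <- readSIF(sif)
  expect_setequal(edgeKeysForTest(back), edgeKeysForTest(edges(net)))
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), numNodes(net))
  expect_equal(igraph::ecount(g), numEdges(net))
  expect_setequal(igraph::V(g)$role, nodes(net)$role)
})
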