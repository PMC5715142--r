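test_that("vertex weights match hand-enumerated cases", {
  # isolated node (degree 0)
  net <- typedNetwork(c("a", "b", "z"),
                      data.frame(node_a = "a", node_b = "b"),
                      role = "other_protein")
  w <- vertexWeights(net, mcodeParams(degree_cutoff = 0))
  expect_equal(w[["z"]], 0)
  # any node of a 5-clique: closed neighborhood K5, k_max 4, density 1
  w5 <- vertexWeights(cliqueEdges(paste0("k", 1:5)))
  expect_true(all(w5 == 4))
  # middle node of a 3-path with degree cutoff 0: 1-core of density 2/3
  wp <- vertexWeights(pathEdges(c("x1", "x2", "x3")),
                      mcodeParams(degree_cutoff = 0))
  expect_equal(wp[["x2"]], 2 / 3)
  # degree cutoff 2 zeroes out the degree-1 endpoints but not the middle
  wp2 <- vertexWeights(pathEdges(c("x1", "x2", "x3")))
  expect_equal(unname(wp2[c("x1", "x3")]), c(0, 0))
  expect_equal(wp2[["x2"]], 2 / 3)
})

test_that("stage-1 weights equal an independent k-core oracle on small graphs", {
  for (n in 4:10) {
    for (p in c(0.2, 0.5, 0.8)) {
      for (s in 1:3) {
        ed <- randomGraphEdges(n, p, seed = 10000 + 100 * n + 10 * p * 10 + s)
        if (nrow(ed) == 0L) next
        ids <- sort(unique(c(ed$node_a, ed$node_b)))
        got <- vertexWeights(ed)
        want <- oracleVertexWeights(ed, degree_cutoff = 2L)
        expect_equal(got, want[names(got)], tolerance = 1e-12,
                     info = sprintf("n=%d p=%.1f seed=%d", n, p, s))
      }
    }
  }
})

test_that("trees yield no clusters", {
  expect_length(mcode(pathEdges(paste0("t", 1:8))), 0L)
  star <- data.frame(node_a = "hub", node_b = paste0("leaf", 1:6))
  expect_length(mcode(star), 0L)
})

test_that("a 5-clique with a pendant vertex gives one cluster of score 5", {
  ed <- rbind(cliqueEdges(paste0("n", 1:5)),
              data.frame(node_a = "n5", node_b = "pendant"))
  res <- mcode(ed)
  expect_length(res, 1L)
  expect_setequal(clusterMembers(res)[[1L]], paste0("n", 1:5))
  expect_equal(clusterScores(res), 5.0)
})

test_that("two disjoint 4-cliques give two score-4 clusters, ties lexicographic", {
  ed <- rbind(cliqueEdges(paste0("b", 1:4)), cliqueEdges(paste0("a", 1:4)))
  res <- mcode(ed)
  expect_length(res, 2L)
  expect_equal(clusterScores(res), c(4, 4))
  expect_identical(clusterSeeds(res), c("a1", "b1"))
  expect_setequal(clusterMembers(res)[[1L]], paste0("a", 1:4))
})

test_that("cluster scores equal density times size recomputed from members", {
  cfg <- simulationConfig(seed = 13, n_modules = 4, module_size = 8,
                          p_in = 0.9, p_out = 0.05)
  ppi <- genPlantedPPI(cfg)
  res <- mcode(ppi$edges)
  expect_gt(length(res), 0L)
  keys <- edgeKeysForTest(ppi$edges)
  for (i in seq_along(res)) {
    m <- clusterMembers(res)[[i]]
    pr <- utils::combn(sort(m), 2L)
    e <- sum(paste(pr[1L, ], pr[2L, ], sep = "|") %in% keys)
    nc <- length(m)
    expect_equal(clusterScores(res)[i], 2 * e / (nc * (nc - 1)) * nc)
  }
})

test_that("clusters are node-disjoint, contain their seed, and are deterministic", {
  cfg <- simulationConfig(seed = 29, n_modules = 5, module_size = 7,
                          p_in = 0.85, p_out = 0.08)
  ppi <- genPlantedPPI(cfg)
  res1 <- mcode(ppi$edges)
  res2 <- mcode(ppi$edges)
  expect_identical(clusterMembers(res1), clusterMembers(res2))
  expect_identical(clusterScores(res1), clusterScores(res2))
  all_members <- unlist(clusterMembers(res1))
  expect_false(anyDuplicated(all_members) > 0)
  # seeds sit in the dense part of these fixtures, so haircut keeps them
  expect_true(all(mapply(`%in%`, clusterSeeds(res1), clusterMembers(res1))))
  # ranked by score descending
  expect_true(all(diff(clusterScores(res1)) <= 1e-12))
})

test_that("max_depth bounds the growth radius", {
  # long path of triangles: depth-1 search cannot reach far vertices
  ed <- rbind(cliqueEdges(c("a1", "a2", "a3")),
              data.frame(node_a = "a3", node_b = "b1"),
              cliqueEdges(c("b1", "b2", "b3")))
  shallow <- mcode(ed, mcodeParams(max_depth = 1L, node_score_cutoff = 1))
  deep <- mcode(ed, mcodeParams(max_depth = 100L, node_score_cutoff = 1))
  expect_lt(length(clusterMembers(shallow)[[1L]]),
            length(clusterMembers(deep)[[1L]]))
})

test_that("planted-module recovery is perfect on disjoint cliques", {
  cfg <- simulationConfig(seed = 17, n_modules = 3, module_size = 6,
                          p_in = 1, p_out = 0)
  ppi <- genPlantedPPI(cfg)
  res <- mcode(ppi$edges)
  rec <- recoverPlanted(res, ppi$labels)
  expect_equal(rec$mean_jaccard, 1.0)
  # empty cluster list scores zero
  empty <- mcode(pathEdges(paste0("p", 1:5)))
  expect_equal(recoverPlanted(empty, ppi$labels)$mean_jaccard, 0.0)
})

test_that("fluff adds dense neighbors when enabled", {
  # K4 with an extra vertex attached to two clique members: haircut-safe
  ed <- rbind(cliqueEdges(paste0("k", 1:4)),
              data.frame(node_a = c("k1", "k2"), node_b = c("f", "f")))
  res <- mcode(ed, mcodeParams(node_score_cutoff = 0, fluff = TRUE,
                               fluff_density_cutoff = 0.5, haircut = FALSE))
  expect_true("f" %in% clusterMembers(res)[[1L]])
})
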