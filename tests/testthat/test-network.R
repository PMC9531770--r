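ppmi_stub <- function(x, y, w) {
  structure(data.frame(x = x, y = y, weight = w, stringsAsFactors = FALSE),
            class = c("ppmi_matrix", "data.frame"),
            retained = sort(unique(c(x, y))), n_posts = 100L)
}

test_that("graph construction keeps edge-incident nodes and honours exclusions", {
  m <- ppmi_stub(c("a", "a", "b"), c("b", "c", "c"), c(1, 1, 1))
  g <- build_graph(m)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  g2 <- build_graph(m, exclusions = "c")
  expect_equal(sort(igraph::V(g2)$name), c("a", "b"))
  expect_equal(igraph::ecount(g2), 1)
  g0 <- build_graph(ppmi_stub(character(0), character(0), numeric(0)))
  expect_equal(igraph::vcount(g0), 0)
})

test_that("weighted modularity matches hand-evaluated fixtures", {
  g <- bridged_triangles()
  mem <- c(a = 0, b = 0, c = 0, d = 1, e = 1, f = 1)
  # 2 * (3/7 - (7/14)^2) = 5/14
  expect_equal(modularity_q(g, mem, 1), 5 / 14, tolerance = 1e-12)
  # one community: Q = 1 - gamma
  one <- stats::setNames(rep(0, 6), names(mem))
  expect_equal(modularity_q(g, one, 1), 0, tolerance = 1e-12)
  expect_equal(modularity_q(g, one, 0.6), 0.4, tolerance = 1e-12)
  # all-singleton partition is negative at gamma = 1
  solo <- stats::setNames(0:5, names(mem))
  expect_lt(modularity_q(g, solo, 1), 0)
  expect_error(modularity_q(g, mem[-1], 1), "cover")
})

test_that("modularity agrees with igraph's implementation on random graphs", {
  set.seed(77)
  for (i in 1:10) {
    g <- random_test_graph(sample(5:12, 1))
    mem <- sample(0:2, igraph::vcount(g), replace = TRUE)
    names(mem) <- igraph::V(g)$name
    for (gam in c(0.6, 1, 1.4)) {
      expect_equal(modularity_q(g, mem, gam),
                   igraph::modularity(g, mem + 1,
                                      weights = igraph::E(g)$weight,
                                      resolution = gam),
                   tolerance = 1e-12)
    }
  }
})

test_that("degree centrality is the unweighted edge count", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3", "l4")
  igraph::E(star)$weight <- c(10, 0.1, 3, 7)   # weights must be ignored
  d <- degree_centrality(star)
  expect_equal(d[["hub"]], 4)
  expect_equal(unname(d[c("l1", "l2", "l3", "l4")]), rep(1L, 4))
})

test_that("average clustering coefficient matches hand computations", {
  tri <- igraph::make_graph(~ a - b, a - c, b - c)
  expect_equal(avg_clustering_coefficient(tri), 1)
  path <- igraph::make_graph(~ a - b, b - c)
  expect_equal(avg_clustering_coefficient(path), 0)
  # triangle {a,b,c} plus pendant d on c: (1 + 1 + 1/3 + 0) / 4 = 7/12
  pend <- igraph::make_graph(~ a - b, a - c, b - c, c - d)
  expect_equal(avg_clustering_coefficient(pend), 7 / 12, tolerance = 1e-12)
})

test_that("brute-force oracle evaluates every set partition", {
  e <- igraph::make_graph(~ a - b)
  igraph::E(e)$weight <- 1
  bf <- brute_force_best_partition(e, 1)
  expect_equal(bf$n_communities, 1)      # split scores -0.5, merge scores 0
  expect_equal(bf$quality, 0)
  bf <- brute_force_best_partition(bridged_triangles(), 1)
  expect_equal(bf$quality, 5 / 14, tolerance = 1e-12)
  expect_equal(bf$n_communities, 2)
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(brute_force_best_partition(empty, 1)$n_communities, 0)
  big <- igraph::make_ring(11)
  expect_error(brute_force_best_partition(big, 1), "10 nodes")
})

test_that("leiden recovers components, merges cliques, and matches the oracle on small graphs", {
  # two disjoint triangles: exactly the components
  two <- igraph::make_graph(~ a - b, a - c, b - c, d - e, d - f, e - f)
  igraph::E(two)$weight <- 1
  p <- leiden(two, resolution = 1, seed = 3)
  expect_equal(p$n_communities, 2)
  expect_equal(unname(p$membership[c("a", "b", "c")]), rep(0L, 3))
  # a single triangle collapses to one community
  tri <- igraph::make_graph(~ a - b, a - c, b - c)
  igraph::E(tri)$weight <- 1
  expect_equal(leiden(tri, resolution = 1, seed = 3)$n_communities, 1)
  # random small graphs: optimum within 1e-9 of the exhaustive maximum
  set.seed(303)
  for (i in 1:10) {
    g <- random_test_graph(sample(3:8, 1))
    for (gam in c(0.6, 1)) {
      p <- leiden(g, resolution = gam, seed = 11)
      bf <- brute_force_best_partition(g, gam)
      expect_lt(abs(p$quality - bf$quality), 1e-9)
    }
  }
})

test_that("leiden is deterministic under a seed and returns connected communities", {
  set.seed(404)
  g <- random_test_graph(25, p = 0.18)
  p1 <- leiden(g, resolution = 1, seed = 9)
  p2 <- leiden(g, resolution = 1, seed = 9)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$quality, p2$quality)
  for (cm in unique(unname(p1$membership))) {
    nodes <- names(p1$membership)[p1$membership == cm]
    expect_true(igraph::is_connected(igraph::induced_subgraph(g, nodes)))
  }
  # at least as good as the singleton partition
  solo <- stats::setNames(seq_along(p1$membership) - 1L,
                          names(p1$membership))
  expect_gte(p1$quality, modularity_q(g, solo, 1))
  # labels are 0-based, contiguous, sized in decreasing order
  sizes <- as.integer(table(p1$membership))
  expect_equal(sort(unique(unname(p1$membership))),
               seq_along(sizes) - 1L)
  expect_true(all(diff(as.integer(table(factor(p1$membership)))) <= 0))
})

test_that("leiden quality is competitive with igraph's implementation", {
  set.seed(505)
  g <- random_test_graph(40, p = 0.12)
  for (gam in c(0.6, 1)) {
    mine <- leiden(g, resolution = gam, seed = 2)$quality
    ig <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = gam,
                                 weights = igraph::E(g)$weight,
                                 n_iterations = 10)
    ig_q <- modularity_q(g, stats::setNames(ig$membership - 1,
                                            igraph::V(g)$name), gam)
    expect_gte(mine, ig_q - 1e-9)
  }
})

test_that("community count does not increase as resolution decreases", {
  set.seed(606)
  g <- random_test_graph(30, p = 0.15)
  gammas <- c(1.4, 1.0, 0.6, 0.3, 0.1)
  counts <- vapply(gammas, function(gam) {
    leiden(g, resolution = gam, seed = 4)$n_communities
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster summaries report shares and degree-ranked top substances", {
  m <- ppmi_stub(c("a", "a", "a", "e"), c("b", "c", "d", "f"),
                 c(1, 1, 1, 1))
  g <- build_graph(m)
  part <- leiden(g, resolution = 1, seed = 1)
  s <- cluster_summary(g, part, k = 10)
  expect_equal(s$n_nodes, 6)
  shares <- vapply(s$communities, `[[`, numeric(1), "share_pct")
  expect_equal(sum(shares), 100)
  # star community of 4: hub first (degree 3), leaves tie lexicographically
  star_comm <- s$communities[[1]]
  expect_equal(star_comm$top$concept_id[1], "a")
  expect_equal(star_comm$top$concept_id[2:4], c("b", "c", "d"))
  # k truncation
  s3 <- cluster_summary(g, part, k = 2)
  expect_lte(max(vapply(s3$communities, function(cm) nrow(cm$top),
                        integer(1))), 2)
  expect_error(cluster_summary(g, part, k = 0), ">= 1")
})

test_that("graph export round-trips and is byte-identical across calls", {
  m <- ppmi_stub(c("a", "a", "b"), c("b", "c", "c"), c(1.5, 0.5, 1))
  g <- build_graph(m)
  part <- leiden(g, resolution = 1, seed = 1)
  # GraphML round-trip through igraph's reader
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, part, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 3)
  expect_equal(sort(igraph::V(back)$id), c("a", "b", "c"))
  expect_equal(sort(igraph::E(back)$weight), c(0.5, 1, 1.5))
  # GEXF parses and carries node/edge counts and attributes
  gexf <- withr::local_tempfile(fileext = ".gexf")
  export_graph(g, part, gexf, "gexf")
  doc <- xml2::read_xml(gexf)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, ".//d1:node", ns), 3)
  expect_length(xml2::xml_find_all(doc, ".//d1:edge", ns), 3)
  # determinism: same input twice gives identical bytes
  gexf2 <- withr::local_tempfile(fileext = ".gexf")
  export_graph(g, part, gexf2, "gexf")
  expect_identical(readBin(gexf, "raw", file.size(gexf)),
                   readBin(gexf2, "raw", file.size(gexf2)))
  # empty graph still yields a valid document
  g0 <- build_graph(ppmi_stub(character(0), character(0), numeric(0)))
  e0 <- withr::local_tempfile(fileext = ".gexf")
  export_graph(g0, NULL, e0, "gexf")
  expect_silent(xml2::read_xml(e0))
})
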