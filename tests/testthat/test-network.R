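test_that("confidence threshold is inclusive and 0-1000 scores normalize", {
  edges <- tibble::tibble(
    protein_a = c("a", "a", "b"), protein_b = c("b", "c", "c"),
    confidence = c(0.39, 0.40, 0.80)
  )
  g <- build_marker_graph(c("a", "b", "c"), edges)
  ig <- g$graph
  got <- igraph::as_data_frame(ig)
  expect_identical(nrow(got), 2L)               # 0.39 dropped, 0.40 kept
  expect_false(any(got$confidence < 0.4))

  # same edges on the database's 0-1000 scale
  edges1000 <- edges
  edges1000$confidence <- edges$confidence * 1000
  g2 <- build_marker_graph(c("a", "b", "c"), edges1000)
  expect_equal(sort(igraph::as_data_frame(g2$graph)$confidence),
               sort(got$confidence))

  expect_error(
    build_marker_graph("a", tibble::tibble(protein_a = "a",
                                           protein_b = "b",
                                           confidence = 2000)),
    class = "lfq_validation_error"
  )
})

test_that("markers without qualifying edges are unmapped, not silently lost", {
  fx <- load_fixture("table1")
  sixteen <- c(fx$markers$gene_name, paste0("Extra", 1:4))
  g <- build_marker_graph(sixteen, fx$edges)
  expect_equal(igraph::vcount(g$graph), 12)
  expect_setequal(g$unmapped, paste0("Extra", 1:4))

  # empty edge list: empty graph, every marker unmapped
  none <- build_marker_graph(sixteen, fx$edges[0, ])
  expect_equal(igraph::vcount(none$graph), 0)
  expect_setequal(none$unmapped, sixteen)
})

test_that("graph construction ignores row order, endpoint order and duplicates", {
  edges <- tibble::tibble(
    protein_a = c("a", "b", "c", "b"),
    protein_b = c("b", "a", "a", "c"),
    confidence = c(0.5, 0.9, 0.6, 0.7)
  )
  g <- build_marker_graph(c("a", "b", "c"), edges)
  df <- igraph::as_data_frame(g$graph)
  expect_identical(nrow(df), 3L)
  # duplicate a-b pair keeps the highest confidence
  ab <- df$confidence[(df$from == "a" & df$to == "b") |
                        (df$from == "b" & df$to == "a")]
  expect_equal(ab, 0.9)

  shuffled <- edges[c(4, 2, 1, 3), ]
  g2 <- build_marker_graph(c("a", "b", "c"), shuffled)
  expect_equal(igraph::as_data_frame(g2$graph)[order(
    igraph::as_data_frame(g2$graph)$from), ],
    df[order(df$from), ], ignore_attr = TRUE)
})

test_that("raising the confidence threshold only shrinks the graph", {
  edges <- random_edges(15, 0.4, seed = 5)
  set.seed(6)
  edges$confidence <- runif(nrow(edges), 0.2, 1)
  nodes <- sprintf("N%02d", 1:15)
  prev <- build_marker_graph(nodes, edges, min_confidence = 0.2)
  for (th in c(0.4, 0.6, 0.8)) {
    cur <- build_marker_graph(nodes, edges, min_confidence = th)
    expect_lte(igraph::ecount(cur$graph), igraph::ecount(prev$graph))
    expect_true(all(igraph::V(cur$graph)$name %in%
                      igraph::V(prev$graph)$name))
    prev <- cur
  }
})

test_that("subnetwork decomposition matches a brute-force component-label scan", {
  set.seed(9)
  for (rep in 1:5) {
    edges <- random_edges(10, 0.25, seed = rep)
    nodes <- sprintf("N%02d", 1:10)
    g <- build_marker_graph(nodes, edges, min_confidence = 0)
    present <- igraph::V(g$graph)$name
    if (length(present) == 0) next
    labels <- setNames(sample(c("f1", "f2"), 10, replace = TRUE), nodes)
    subs <- decompose_subnetworks(g, labels)

    comp <- igraph::components(g$graph)$membership
    oracle_key <- paste(comp[present], labels[present])
    expect_identical(sort(subs$size),
                     sort(unname(as.vector(table(oracle_key)))))
    # partition property: sizes sum to the node count
    expect_identical(sum(subs$size), length(present))
    # isolated iff the component holds a single label
    for (i in seq_len(nrow(subs))) {
      labs_in_comp <- unique(labels[present[comp[present] ==
                                              subs$component[i]]])
      expect_identical(subs$isolated[i], length(labs_in_comp) == 1)
    }
  }

  # single-label connected graph: one subnetwork, isolated
  tri <- tibble::tibble(protein_a = c("a", "b"), protein_b = c("b", "c"),
                        confidence = 0.9)
  g <- build_marker_graph(c("a", "b", "c"), tri)
  subs <- decompose_subnetworks(g, c(a = "f", b = "f", c = "f"))
  expect_identical(nrow(subs), 1L)
  expect_true(subs$isolated)

  expect_error(decompose_subnetworks(g, c(a = "f", b = "f")),
               class = "lfq_config_error")
})

test_that("centrality ranking matches enumeration oracles", {
  # star K1,4: center carries all 6 leaf pairs
  star <- tibble::tibble(protein_a = "hub",
                         protein_b = paste0("leaf", 1:4),
                         confidence = 0.9)
  g <- build_marker_graph(c("hub", paste0("leaf", 1:4)), star)
  cent <- rank_centrality(g)
  expect_identical(cent$protein_id[1], "hub")
  expect_equal(cent$betweenness[1], 6)
  expect_equal(cent$degree[1], 4)

  # complete graph: all betweenness 0, ranking falls back to names
  k4 <- tibble::tibble(
    protein_a = c("a", "a", "a", "b", "b", "c"),
    protein_b = c("b", "c", "d", "c", "d", "d"), confidence = 0.9
  )
  g <- build_marker_graph(letters[1:4], k4)
  cent <- rank_centrality(g)
  expect_true(all(cent$betweenness == 0))
  expect_identical(cent$protein_id, letters[1:4])

  # random graphs <= 12 nodes vs exhaustive path enumeration
  for (seed in 1:4) {
    edges <- random_edges(9, 0.3, seed = seed)
    nodes <- sprintf("N%02d", 1:9)
    g <- build_marker_graph(nodes, edges, min_confidence = 0)
    if (igraph::vcount(g$graph) == 0) next
    cent <- rank_centrality(g)
    oracle <- oracle_betweenness(
      igraph::as_data_frame(g$graph) |>
        dplyr::rename(protein_a = from, protein_b = to),
      igraph::V(g$graph)$name
    )
    expect_equal(setNames(cent$betweenness, cent$protein_id)[names(oracle)],
                 oracle, tolerance = 1e-10)
  }
})

test_that("packaged interactome fixtures reproduce the published structure", {
  male <- load_fixture("table1")
  g <- build_marker_graph(male$markers$gene_name, male$edges)
  expect_equal(igraph::vcount(g$graph), 12)
  comp_sizes <- sort(igraph::components(g$graph)$csize)
  expect_identical(comp_sizes, c(2, 10))
  subs <- decompose_subnetworks(g, male$category_map)
  expect_identical(
    subs$subnetwork[subs$isolated], "Energy metabolism")
  expect_identical(subs$size[subs$subnetwork == "Energy metabolism"], 2L)
  expect_identical(sum(subs$size[!subs$isolated]), 10L)
  # the synaptic hub is the top-ranked node of the fixture map
  expect_identical(rank_centrality(g)$protein_id[1], "Amph")

  female <- load_fixture("table2")
  gf <- build_marker_graph(female$markers$gene_name, female$edges)
  expect_equal(igraph::vcount(gf$graph), 35)
  subsf <- decompose_subnetworks(gf, female$category_map)
  expect_identical(subsf$size[1:2], c(10L, 8L))
  expect_identical(subsf$subnetwork[1:2],
                   c("Oxidative stress", "Energy metabolism"))
  expect_setequal(subsf$subnetwork[subsf$isolated],
                  c("Septin cytoskeleton", "Cell cycle"))
  top3 <- rank_centrality(gf)$protein_id[1:3]
  expect_setequal(top3, c("Fkbp1a", "Hspa1b", "Eno2"))
})

test_that("node tables and GraphML export cover mapped and unmapped markers", {
  fx <- load_fixture("table1")
  g <- build_marker_graph(c(fx$markers$gene_name, "Orphan1"), fx$edges)
  cmap <- c(fx$category_map, Orphan1 = "Unassigned")
  tbl <- node_table(g, cmap)
  expect_identical(nrow(tbl), 13L)
  expect_false(tbl$mapped[tbl$protein_id == "Orphan1"])
  expect_identical(sum(tbl$mapped), 12L)

  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), 12)
  expect_setequal(igraph::V(back)$name, igraph::V(g$graph)$name)
})
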