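test_that("interactome loading merges duplicates and drops self-loops", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tsource\tevidence",
               "A\tB\tdb1\tphysical",
               "B\tA\tdb2\tcomplex"), f1)
  merged <- load_interactome(f1)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$source, "db1;db2")
  expect_equal(merged$evidence, "complex;physical")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tsource\tevidence",
               "A\tA\tdb1\tphysical"), f2)
  expect_error(suppressMessages(load_interactome(f2)), "no usable edges")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tsource\tevidence",
               "C\tD\tdb3\tphysical"), f3)
  both <- load_interactome(c(f1, f3))
  expect_equal(nrow(both), 2L)
  expect_setequal(both$protein_a, c("A", "C"))
})

test_that("minimal PSI-MITAB input is parsed with source column 13", {
  f <- withr::local_tempfile(fileext = ".mitab")
  hdr <- paste(c("#ID(s) interactor A", "ID(s) interactor B",
                 paste0("col", 3:15)), collapse = "\t")
  row1 <- paste(c("uniprotkb:P1", "uniprotkb:P2", rep("-", 10),
                  "psi-mi:intact", "-", "-"), collapse = "\t")
  row2 <- paste(c("uniprotkb:P2", "uniprotkb:P1", rep("-", 10),
                  "psi-mi:mint", "-", "-"), collapse = "\t")
  writeLines(c(hdr, row1, row2, "malformed"), f)
  expect_message(net <- load_interactome(f), "malformed")
  expect_equal(nrow(net), 1L)
  expect_equal(net$protein_a, "P1")
  expect_equal(net$source, "intact;mint")
})

test_that("group networks are induced on the union list with isolates dropped", {
  calls <- rbind(toy_calls(c("a", "b", "c"), "II", c(1, -1, 0.5)),
                 toy_calls(c("a", "b", "c"), "III", c(0.2, 0.1, 0.3),
                           status = "unchanged"))
  inter <- edges_df(rbind(c("a", "b"), c("b", "d")))
  g <- build_group_network(calls, "II", inter)
  expect_setequal(igraph::V(g)$name, c("a", "b"))  # c isolated, d not diff
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::V(g)$modulation[igraph::V(g)$name == "a"],
               "up-regulated")
  expect_equal(igraph::V(g)$modulation[igraph::V(g)$name == "b"],
               "down-regulated")

  ## annotation uses THIS group's fold changes: same topology, new classes
  g3 <- build_group_network(calls, "III", inter)
  expect_setequal(igraph::V(g3)$name, igraph::V(g)$name)
  expect_true(all(igraph::V(g3)$modulation == "un-regulated"))

  ## the modulation cutoff is strict: exactly 0.263 is un-regulated
  calls_b <- toy_calls(c("a", "b"), "II", c(0.263, -0.263), status = "up")
  gb <- build_group_network(calls_b, "II", edges_df(rbind(c("a", "b"))))
  expect_true(all(igraph::V(gb)$modulation == "un-regulated"))

  disjoint <- edges_df(rbind(c("x", "y")))
  expect_error(build_group_network(calls, "II", disjoint), "no edge")
})

test_that("giant connected component extraction and tie-breaks", {
  pairs <- rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"),
                 c("x", "y"))
  g <- graph_from_pairs(pairs)
  gcc <- extract_gcc(g)
  expect_equal(gcc$size, 5L)
  expect_setequal(igraph::V(gcc$subnetwork)$name, c("a", "b", "c", "d", "e"))

  conn <- graph_from_pairs(rbind(c("a", "b"), c("b", "c")))
  expect_equal(extract_gcc(conn)$size, igraph::vcount(conn))

  ## two size-3 components: keep the one with the smallest id
  tie <- graph_from_pairs(rbind(c("z1", "z2"), c("z2", "z3"),
                                c("a1", "a2"), c("a2", "a3")))
  expect_setequal(igraph::V(extract_gcc(tie)$subnetwork)$name,
                  c("a1", "a2", "a3"))

  ## GCC size invariant to edge-list order
  perm <- graph_from_pairs(pairs[c(5, 3, 1, 4, 2), ])
  expect_equal(extract_gcc(perm)$size, 5L)
})

test_that("centralities match the all-pairs-shortest-path oracle", {
  ## 4-leaf star: centre DC 4, BC C(4,2) = 6, CC 1, clustering 0
  star <- graph_from_pairs(cbind("hub", paste0("leaf", 1:4)))
  cs <- centralities(star)
  hubrow <- cs[cs$protein_id == "hub", ]
  expect_equal(hubrow$dc, 4)
  expect_equal(hubrow$bc, 6)
  expect_equal(hubrow$cc, 1)
  expect_equal(hubrow$clustering, 0)
  leaf <- cs[cs$protein_id == "leaf1", ]
  expect_equal(leaf$bc, 0)
  expect_equal(leaf$cc, 4 / (1 + 2 * 3))

  tri <- graph_from_pairs(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  ct <- centralities(tri)
  expect_equal(ct$dc, rep(2, 3))
  expect_equal(ct$bc, rep(0, 3))
  expect_equal(ct$clustering, rep(1, 3))

  path <- graph_from_pairs(rbind(c("a", "b"), c("b", "c")))
  expect_equal(centralities(path)$bc[2], 1)

  ## random graphs up to 12 nodes, including disconnected ones
  set.seed(17)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    A <- random_small_graph(n, p = runif(1, 0.15, 0.6))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    got <- centralities(g)
    want <- apsp_centralities(A[got$protein_id, got$protein_id])
    expect_equal(got$dc, unname(want$dc))
    expect_equal(got$bc, want$bc, tolerance = 1e-10)
    expect_equal(got$cc, want$cc, tolerance = 1e-12)
    expect_equal(got$clustering, want$clustering, tolerance = 1e-12)
  }
})

test_that("node size follows (DC + 1) * (|log2FC| + 1)", {
  expect_equal(node_size(0, 0), 1)
  expect_equal(node_size(-1, 3), 8)
  expect_equal(node_size(0.263, 9), 12.63)
  expect_error(node_size(1, -2), "dc")
})

test_that("hub ranking uses |log2FC x degree| with degree tie-breaks", {
  ## star around 'hub' (DC 4) plus leaf-leaf edge to vary degrees
  calls <- toy_calls(c("hub", "leaf1", "leaf2", "leaf3", "leaf4"), "II",
                     c(0.5, -2.4, 2.0, 0.1, 0.1),
                     status = c("up", "down", "up", "up", "up"))
  inter <- edges_df(rbind(cbind("hub", paste0("leaf", 1:4)),
                          c("leaf1", "leaf2")))
  g <- annotate_network(build_group_network(calls, "II", inter))
  hubs <- hub_rank(g, k = 3)
  expect_equal(hubs$protein_id[1], "leaf1")       # |-2.4 * 2| = 4.8
  expect_equal(hubs$hub_score[1], -4.8)           # sign retained
  expect_equal(hubs$protein_id[2], "leaf2")       # 2.0 * 2 = 4.0
  expect_equal(hubs$protein_id[3], "hub")         # 0.5 * 4 = 2.0

  ## ties by higher degree then id: equal |score|, different DC
  calls2 <- toy_calls(c("a", "b", "c", "d", "e", "f"), "II",
                      c(0.5, 1, 1, 1, 1, 1))
  inter2 <- edges_df(rbind(c("a", "c"), c("a", "d"), c("a", "e"),
                           c("a", "f"), c("b", "c"), c("b", "d")))
  g2 <- annotate_network(build_group_network(calls2, "II", inter2))
  h2 <- hub_rank(g2, k = 3)
  ## scores tie at 2.0: DC 4 beats DC 2; among DC 2 ties, ids break them
  expect_equal(h2$hub_score, c(2, 2, 2))
  expect_equal(h2$protein_id, c("a", "b", "c"))

  ## top-k equals brute-force sort over all nodes
  all_rows <- suppressWarnings(hub_rank(g2, k = 100))
  ord <- order(-abs(all_rows$hub_score), -all_rows$dc, all_rows$protein_id)
  expect_equal(all_rows$protein_id, all_rows$protein_id[ord])
  expect_warning(hub_rank(g2, k = 100), "exceeds node count")
})

test_that("GCC permutation significance is reproducible and calibrated", {
  sq <- sim_quant(300, 0.2, seed = 31)
  net <- sim_interactome(sq, 250, 2, planted_module_size = 0, seed = 31)
  a <- gcc_significance(net$edges, 40, 12, n_permutations = 1000, seed = 5)
  b <- gcc_significance(net$edges, 40, 12, n_permutations = 1000, seed = 5)
  expect_identical(a, b)
  expect_equal(a$z, (12 - a$null_mean) / a$null_sd)
  expect_gte(a$empirical_p, 1 / 1001)

  ## observed at the null mean gives z ~ 0
  c0 <- gcc_significance(net$edges, 40, round(a$null_mean),
                         n_permutations = 1000, seed = 5)
  expect_lt(abs(c0$z), 0.5)

  ## 10x more permutations moves z by less than 3 null standard errors
  big <- gcc_significance(net$edges, 40, 12, n_permutations = 10000,
                          seed = 5)
  se_z <- 3 / sqrt(1000)
  expect_lt(abs(big$z - a$z), 3 * max(se_z, 0.2))

  expect_error(gcc_significance(net$edges, 40, 12, n_permutations = 500,
                                seed = 1), "n_permutations")
  expect_error(gcc_significance(net$edges, 10000, 12, seed = 1), "exceeds")
})

test_that("a planted dense module is detected as a significant GCC", {
  sq <- sim_quant(500, 0.2, seed = 8)
  net <- sim_interactome(sq, 400, 2, planted_module_size = 20,
                         planted_density = 0.8, seed = 8)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  sub <- igraph::induced_subgraph(g, net$module)
  obs <- extract_gcc(sub)$size
  sig <- gcc_significance(net$edges, 20, obs, n_permutations = 1000,
                          seed = 99)
  expect_gt(sig$z, 3)
  expect_lt(sig$empirical_p, 0.01)
})

test_that("annotated networks round-trip through GraphML and GEXF", {
  calls <- toy_calls(c("a", "b", "c"), "II", c(1.2, -0.8, 0.5))
  inter <- edges_df(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                    source = c("HPRD", "IntAct", "MINT"),
                    evidence = c("physical", "complex", "kinase-substrate"))
  g <- annotate_network(build_group_network(calls, "II", inter))

  edge_key <- function(gr) {
    el <- igraph::as_edgelist(gr)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  for (fmt in c("graphml", "gexf")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(g, path, fmt)
    back <- import_network(path, fmt)
    expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
    expect_equal(edge_key(back), edge_key(g))
    ord <- match(igraph::V(g)$name, igraph::V(back)$name)
    for (at in c("log2_fc", "node_size", "hub_score", "dc", "bc", "cc",
                 "clustering"))
      expect_equal(igraph::vertex_attr(back, at)[ord],
                   igraph::vertex_attr(g, at), tolerance = 1e-9,
                   label = paste(fmt, at))
    expect_equal(igraph::vertex_attr(back, "modulation")[ord],
                 igraph::vertex_attr(g, "modulation"))
    expect_setequal(igraph::edge_attr(back, "source"),
                    igraph::edge_attr(g, "source"))
  }

  ## cross-format consistency: same node and edge multisets
  p1 <- withr::local_tempfile(fileext = ".graphml")
  p2 <- withr::local_tempfile(fileext = ".gexf")
  export_network(g, p1, "graphml")
  export_network(g, p2, "gexf")
  g1 <- import_network(p1, "graphml")
  g2 <- import_network(p2, "gexf")
  expect_setequal(igraph::V(g1)$name, igraph::V(g2)$name)
  expect_equal(edge_key(g1), edge_key(g2))

  ## refusing to export an unannotated network names the missing attribute
  raw <- build_group_network(calls, "II", inter)
  expect_error(export_network(raw, tempfile(), "gexf"), "hub_score")
  g_noev <- igraph::delete_edge_attr(g, "evidence")
  expect_error(export_network(g_noev, tempfile(), "gexf"), "evidence")
  expect_error(export_network(g, tempfile(), "dot"), "arg")
})
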