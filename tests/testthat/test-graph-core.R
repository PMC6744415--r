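test_that("edge lists parse with multiplicity and the self-loop convention", {
  p <- withr::local_tempfile(lines = c("a b", "b c", "a b"))
  G <- read_edge_list(p)
  expect_equal(G$nodes, c("a", "b", "c"))
  expect_equal(G$m, 3)
  expect_equal(unname(G$deg), c(2, 3, 1))
  ab <- which(G$ei == 1 & G$ej == 2)
  expect_equal(G$mult[ab], 2)

  p2 <- withr::local_tempfile(lines = c("# comment", "a a"))
  G2 <- read_edge_list(p2)
  expect_equal(unname(G2$deg), 2)  # one self-loop counts 2
  expect_equal(G2$m, 1)
})

test_that("malformed and empty edge-list files are rejected with context", {
  p <- withr::local_tempfile(lines = c("a b", "lonely"))
  expect_error(read_edge_list(p), "line 2")
  p2 <- withr::local_tempfile(lines = c("# nothing", ""))
  expect_error(read_edge_list(p2), "no edges")
})

test_that("the bundled karate fixture is the standard 34-node, 78-edge network", {
  G <- read_edge_list(karate_path())
  expect_equal(G$n, 34)
  expect_equal(G$m, 78)
  expect_equal(sum(G$deg), 2 * 78)
  expect_equal(length(graph_components(G)$sizes), 1)
})

test_that("edge-list round trip preserves the adjacency up to node order", {
  G <- rand_graph(12, seed = 5)
  p <- withr::local_tempfile()
  write_edge_list(G, p)
  G2 <- read_edge_list(p)
  key <- function(g) sort(paste(pmin(g$nodes[g$ei], g$nodes[g$ej]),
                                pmax(g$nodes[g$ei], g$nodes[g$ej]), g$mult))
  expect_equal(key(G2), key(G))
  expect_equal(sort(unname(G2$deg[G$nodes])), sort(unname(G$deg)))
})

test_that("GraphML files read through igraph keep multiplicities", {
  skip_if_not_installed("igraph")
  ig <- igraph::graph_from_edgelist(
    matrix(c("A", "B", "B", "C", "A", "B"), ncol = 2, byrow = TRUE),
    directed = FALSE)
  p <- withr::local_tempfile(fileext = ".graphml")
  igraph::write_graph(ig, p, format = "graphml")
  G <- read_graphml(p)
  expect_equal(G$n, 3)
  expect_equal(G$m, 3)
})

test_that("weight columns are ignored by default and usable as multiplicity", {
  p <- withr::local_tempfile(lines = c("a b 3", "b c 1"))
  expect_equal(read_edge_list(p)$m, 2)
  expect_equal(read_edge_list(p, weights = "multiplicity")$m, 4)
})

test_that("block_summary matches closed-form examples", {
  tri <- multigraph(c("a", "b", "c"), c("b", "c", "a"))
  g1 <- as_partition(c(a = 1, b = 1, c = 1), B = 1)
  bs <- block_summary(tri, g1)
  expect_equal(bs$m[1, 1], 6)
  expect_equal(bs$kappa, 6)
  expect_equal(unname(bs$k_plus), c(2, 2, 2))

  e <- multigraph("a", "b")
  g2 <- as_partition(c(a = 1, b = 2))
  bs2 <- block_summary(e, g2)
  expect_equal(bs2$m, matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(bs2$k_plus), c(0, 0))
  expect_equal(unname(bs2$k_minus), c(1, 1))
})

test_that("block_summary agrees with the brute-force double loop", {
  for (s in 1:5) {
    G <- rand_graph(20, seed = s)
    g <- rand_partition(G, B = 3, seed = s + 10)
    bs <- block_summary(G, g)
    or <- brute_summary(G, g)
    expect_equal(bs$m, or$m)
    expect_equal(unname(bs$k_plus), or$k_plus)
    # conservation invariants
    expect_equal(rowSums(bs$m), bs$kappa)
    expect_equal(sum(bs$kappa), 2 * G$m)
    expect_equal(sum(bs$n_r), G$n)
    expect_equal(unname(bs$k_plus + bs$k_minus), unname(as.numeric(G$deg)))
  }
})

test_that("self-loops count fully toward k_plus and the diagonal of m_rs", {
  G <- multigraph(c("a", "a", "a"), c("a", "b", "b"))
  g <- as_partition(c(a = 1, b = 2))
  bs <- block_summary(G, g)
  expect_equal(bs$m[1, 1], 2)       # the loop only
  expect_equal(unname(bs$k_plus["a"]), 2)
  expect_equal(unname(bs$k_minus["a"]), 2)
})

test_that("random edge removal is exact, seeded, and invariant-preserving", {
  G <- rand_graph(15, seed = 3)
  expect_identical(remove_random_edges(G, 0), G)
  ten <- multigraph(rep(letters[1:5], 2), rep(letters[c(2:5, 1)], 2))
  expect_equal(ten$m, 10)
  half <- remove_random_edges(ten, 0.5, seed = 9)
  expect_equal(half$m, 5)
  expect_equal(half$nodes, ten$nodes)  # node set kept
  a <- remove_random_edges(G, 0.3, seed = 4)
  b <- remove_random_edges(G, 0.3, seed = 4)
  expect_equal(a$mult, b$mult)
  expect_equal(a$ei, b$ei)
  expect_equal(sum(a$deg), 2 * a$m)
  expect_error(remove_random_edges(G, 1), "fraction")
  expect_error(remove_random_edges(G, -0.1), "fraction")
})

test_that("partition files round-trip and reject bad input", {
  g <- as_partition(c(x = 1, y = 2, z = 1), B = 2)
  p <- withr::local_tempfile()
  write_partition(g, p)
  g2 <- read_partition(p)
  expect_equal(unclass(g2)[names(g)], unclass(g)[names(g)],
               ignore_attr = TRUE)

  pd <- withr::local_tempfile(lines = c("x 1", "x 2"))
  expect_error(read_partition(pd), "duplicate")
  pe <- withr::local_tempfile(lines = "# only a comment")
  expect_error(read_partition(pe), "empty")

  G <- multigraph("x", "y")
  pu <- withr::local_tempfile(lines = c("x 1", "q 2"))
  expect_error(read_partition(pu, graph = G), "unknown|missing")
})

test_that("graph_components separates disconnected pieces", {
  G <- multigraph(c("a", "b", "c", "d"), c("b", "a", "d", "c"))
  cc <- graph_components(G)
  expect_equal(sort(cc$sizes), c(2, 2))
  expect_equal(cc$membership[["a"]], cc$membership[["b"]])
  expect_false(cc$membership[["a"]] == cc$membership[["c"]])
  expect_equal(graph_components(two_cliques())$sizes, c(5, 5))
})
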