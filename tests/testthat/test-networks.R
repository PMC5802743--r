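test_that("ER generator honors the mean-degree parameterization", {
  g <- generate_er(5, 4, seed = 1) # p = 1: complete graph
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 10)

  g0 <- generate_er(5, 0, seed = 1)
  expect_equal(igraph::ecount(g0), 0)

  expect_error(generate_er(5, 5, seed = 1), "mean_degree")

  # mean edge count over seeds matches the Binomial(C(n,2), k/(n-1)) mean
  n <- 1000
  k <- 6
  p <- k / (n - 1)
  npairs <- choose(n, 2)
  e <- vapply(1:100, function(s) igraph::ecount(generate_er(n, k, s)), 1)
  sd_mean <- sqrt(npairs * p * (1 - p) / 100)
  expect_lt(abs(mean(e) - npairs * p), 3 * sd_mean)
})

test_that("ER and BA generators are reproducible from the seed", {
  expect_identical(edge_set(generate_er(60, 4, seed = 7)),
                   edge_set(generate_er(60, 4, seed = 7)))
  expect_identical(edge_set(generate_ba(60, 3, seed = 7)),
                   edge_set(generate_ba(60, 3, seed = 7)))
  expect_false(identical(edge_set(generate_er(60, 4, seed = 7)),
                         edge_set(generate_er(60, 4, seed = 8))))
})

test_that("BA generator: minimum degree m, mean degree near 2m, hubs exist", {
  g <- generate_ba(1000, 3, seed = 3)
  deg <- igraph::degree(g)
  expect_true(all(deg >= 3))
  expect_lt(abs(mean(deg) - 6) / 6, 0.02)
  expect_error(generate_ba(3, 3, seed = 1), "n > m")

  gbig <- generate_ba(10000, 3, seed = 4)
  expect_gt(length(hub_set(gbig)), 0)
})

test_that("edge-list reader collapses duplicates, drops loops, flags bad lines", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "0\t1", "1 0", "1\t2"), f)
  g <- load_edge_list(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::V(g)$orig_id, c(0, 1, 2))

  writeLines(character(0), f)
  expect_equal(igraph::vcount(load_edge_list(f)), 0)

  writeLines(c("0 1", "2 2", "3 4"), f)
  expect_message(g2 <- load_edge_list(f), "1 self-loop")
  expect_equal(igraph::ecount(g2), 2)

  writeLines(c("0 1", "oops"), f)
  expect_error(load_edge_list(f), "line 2")
})

test_that("write_edge_list / load_edge_list round-trips", {
  g <- largest_connected_component(generate_er(40, 4, seed = 9))
  f <- withr::local_tempfile(fileext = ".txt")
  write_edge_list(g, f)
  g2 <- load_edge_list(f)
  expect_identical(edge_set(g), edge_set(g2))
})

test_that("largest connected component extraction", {
  g <- generate_er(30, 3, seed = 2)
  glcc <- largest_connected_component(g)
  expect_equal(igraph::components(glcc)$no, 1)

  # triangle plus a disjoint edge -> the triangle
  g2 <- igraph::graph_from_edgelist(
    cbind(c(1, 2, 3, 4), c(2, 3, 1, 5)), directed = FALSE)
  lcc <- largest_connected_component(g2)
  expect_equal(igraph::vcount(lcc), 3)
  expect_equal(igraph::ecount(lcc), 3)

  # connected graph comes back unchanged (up to relabeling)
  g3 <- path_graph(6)
  expect_equal(igraph::vcount(largest_connected_component(g3)), 6)
})

test_that("hub set: degree >= sqrt(N), monotone under edge additions", {
  expect_identical(hub_set(star_graph(10)), 1L) # center: 9 >= sqrt(10)

  reg <- igraph::sample_k_regular(100, 3)
  expect_length(hub_set(reg), 0) # 3 < 10

  set.seed(5)
  for (i in 1:20) {
    g <- generate_ba(80, 2, seed = i)
    before <- hub_set(g)
    non_edges <- which(!as.matrix(igraph::as_adjacency_matrix(g)), arr.ind = TRUE)
    non_edges <- non_edges[non_edges[, 1] < non_edges[, 2], , drop = FALSE]
    pick <- non_edges[sample.int(nrow(non_edges), 1), ]
    g2 <- igraph::add_edges(g, pick)
    expect_true(all(before %in% hub_set(g2)))
  }
})

test_that("graph_stats reports size, mean degree, clustering, hub share", {
  g <- igraph::make_full_graph(5)
  st <- graph_stats(g)
  expect_equal(st$n, 5)
  expect_equal(st$e, 10)
  expect_equal(st$mean_degree, 4)
  expect_equal(st$clustering, 1)
  expect_equal(st$hub_fraction, 1) # degree 4 >= sqrt(5)
})
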