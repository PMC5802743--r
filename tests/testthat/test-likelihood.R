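test_that("BFS tree: smallest-id parents, depths equal graph distances", {
  # 4-cycle rooted at 1: node 3 is reachable through 2 or 4 -> parent 2
  g4 <- igraph::make_ring(4)
  tr <- bfs_tree(g4, 1)
  expect_equal(tr$parent[3], 2)
  expect_equal(tr$depth, c(0L, 1L, 2L, 1L))

  # a tree graph reproduces itself
  gt <- igraph::make_tree(7, children = 2, mode = "undirected")
  trt <- bfs_tree(gt, 1)
  expect_equal(trt$parent[-1], c(1L, 1L, 2L, 2L, 3L, 3L))

  # depth map equals single-source shortest-path distances (independent oracle)
  for (i in 1:50) {
    g <- generate_er(25, 3, seed = i)
    root <- (i %% 25) + 1
    tr <- bfs_tree(g, root)
    d <- igraph::distances(g, v = root)[1, ]
    d[is.infinite(d)] <- NA
    expect_equal(as.numeric(tr$depth), as.numeric(d))
  }
})

test_that("observed delays are anchored at observer one, translation invariant", {
  rep <- observer_report(c(1, 2, 3), c(0, 2, 3))
  expect_equal(observed_delays(rep), c(2, 3))

  tied <- observer_report(c(1, 2, 3), c(4, 4, 4))
  expect_equal(observed_delays(tied), c(0, 0))

  shifted <- observer_report(c(1, 2, 3), c(0, 2, 3) + 7.25)
  expect_identical(observed_delays(shifted), observed_delays(rep))
})

test_that("deterministic delays come from BFS depths times mu", {
  g <- path_graph(5)
  # symmetric candidate: zero expected delay between end observers
  tr3 <- bfs_tree(g, 3)
  expect_equal(deterministic_delays(tr3, c(1, 5), mu = 2), 0)
  # off-center candidate: mu * (3 - 1) = 4
  tr2 <- bfs_tree(g, 2)
  expect_equal(deterministic_delays(tr2, c(1, 5), mu = 2), 4)

  # against an independent distance oracle on a star
  gs <- star_graph(6)
  trs <- bfs_tree(gs, 2)
  dd <- igraph::distances(gs, v = 2)[1, ]
  expect_equal(deterministic_delays(trs, c(3, 4, 1), mu = 1.5),
               1.5 * (dd[c(4, 1)] - dd[3]), ignore_attr = TRUE)
})

test_that("delay covariance counts shared tree edges", {
  g <- path_graph(5)
  tr <- bfs_tree(g, 3)
  expect_equal(delay_covariance(tr, c(1, 5), sigma2 = 2),
               matrix(8, 1, 1)) # the 4-edge path times sigma2

  gs <- star_graph(5) # center 1, leaves 2..5
  trc <- bfs_tree(gs, 1)
  lam <- delay_covariance(trc, c(2, 3, 4), sigma2 = 1.5)
  expect_equal(lam, 1.5 * matrix(c(2, 1, 1, 2), 2, 2)) # shared edge o1-center
})

test_that("delay covariance is symmetric and positive semi-definite", {
  set.seed(77)
  for (i in 1:150) {
    g <- largest_connected_component(
      generate_er(sample(8:20, 1), 3, seed = i))
    nn <- igraph::vcount(g)
    if (nn < 4) next
    k <- sample(3:min(6, nn), 1)
    obs <- sample.int(nn, k)
    root <- sample.int(nn, 1)
    tr <- bfs_tree(g, root)
    lam <- delay_covariance(tr, obs, sigma2 = 2)
    expect_identical(lam, t(lam))
    ev <- eigen(lam, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9 * sum(diag(lam)))
    # diagonal: sigma2 times the tree-path length from observer one
    expect_true(all(diag(lam) > 0 | obs[-1] == obs[1]))
  }
})

test_that("score: closed-form scalar case, maximum at d = mu_s, invariances", {
  # K = 2 scalar: phi = -log(sqrt(8)) - 16/(2*8)
  expect_equal(delay_score(4, 0, matrix(8, 1, 1), sigma2 = 2),
               -0.5 * log(8) - 1)

  lam <- matrix(c(3, 1, 1, 2), 2, 2)
  mu_s <- c(1, -1)
  phi_max <- delay_score(mu_s, mu_s, lam)
  expect_equal(phi_max, -0.5 * determinant(lam)$modulus[1])
  for (d in list(c(0, 0), c(2, 1), c(-3, 5))) {
    expect_lte(delay_score(d, mu_s, lam), phi_max)
  }

  expect_error(delay_score(c(1, 2), 0, matrix(8)), "dimension")
  expect_error(delay_score(Inf, 0, matrix(8)), "finite")
})

test_that("full scan equals per-candidate recomputation and ranks the source", {
  pm <- delay_moments(0.5)
  g <- largest_connected_component(generate_er(20, 3, seed = 5))
  nn <- igraph::vcount(g)
  real <- si_simulate(g, 3, 0.5, seed = 6)
  rep <- make_report(real, c(1, 4, 7, 10))
  scan <- ptva_li_scan(g, rep, pm)
  expect_equal(sort(scan$node), 1:nn)
  expect_equal(attr(scan, "score_evaluations"), nn)

  naive <- naive_scores(g, rep, pm)
  expect_equal(scan$score, naive[scan$node], tolerance = 1e-12)

  # noiseless tree: the true source attains the maximal score
  gt <- igraph::make_tree(15, children = 2, mode = "undirected")
  rep_t <- noiseless_report(gt, 4, c(1, 8, 11, 15), pm$mu)
  scan_t <- ptva_li_scan(gt, rep_t, pm)
  expect_equal(scan_t$node[1], 4)

  # path 1..5, observers at the ends tied at t = 2: middle node wins
  gp <- path_graph(5)
  scan_p <- ptva_li_scan(gp, observer_report(c(1, 5), c(2, 2)), pm)
  expect_equal(scan_p$node[1], 3)
  naive_p <- naive_scores(gp, observer_report(c(1, 5), c(2, 2)), pm)
  expect_equal(which.max(naive_p), 3L)
})

test_that("scores are translation invariant in the reported times", {
  pm <- delay_moments(0.4)
  g <- largest_connected_component(generate_ba(30, 2, seed = 8))
  real <- si_simulate(g, 2, 0.4, seed = 9)
  obs <- c(5, 9, 14, 20)
  rep <- make_report(real, obs)
  rep_shift <- observer_report(rep$node, rep$time + 11.5)
  for (form in c("gaussian", "linearized")) {
    expect_identical(score_candidates(g, rep, pm, form = form),
                     score_candidates(g, rep_shift, pm, form = form))
  }
})

test_that("candidates that cannot reach every observer score -Inf", {
  g <- igraph::graph_from_edgelist(
    cbind(c(1, 2, 4), c(2, 3, 5)), directed = FALSE) # path 1-2-3 and edge 4-5
  pm <- delay_moments(0.5)
  rep <- observer_report(c(1, 3), c(0, 2))
  sc <- score_candidates(g, rep, pm)
  expect_true(all(is.infinite(sc[c("4", "5")])))
  expect_true(all(is.finite(sc[c("1", "2", "3")])))
})
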