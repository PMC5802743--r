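test_that("observer placement: exact count, density metadata, K >= 2", {
  g <- generate_er(100, 4, seed = 1)
  expect_identical(sort(place_observers(g, 1, seed = 1)), 1:100)

  g2 <- generate_er(1000, 6, seed = 2)
  obs <- place_observers(g2, 0.2, seed = 3)
  expect_length(obs, 200)
  expect_false(anyDuplicated(obs) > 0)
  expect_equal(attr(obs, "rho"), 0.2)

  expect_error(place_observers(g, 0.001, seed = 1), "fewer than 2")
  expect_identical(place_observers(g2, 0.2, seed = 3),
                   place_observers(g2, 0.2, seed = 3))
})

test_that("source among observers implies P(source observed) = rho", {
  g <- generate_er(100, 4, seed = 1)
  hits <- vapply(1:2000, function(s) 17 %in% place_observers(g, 0.2, s), TRUE)
  se <- sqrt(0.2 * 0.8 / 2000)
  expect_lt(abs(mean(hits) - 0.2), 3 * se)
})

test_that("report assembly sorts by time then id and drops unreached", {
  real <- list(source = 9,
               arrival = c(3, 1, 2, NA, 0, 2, 2, 1, 0),
               beta = 0.5)
  class(real) <- "spread_realization"

  rep <- make_report(real, c(1, 2, 3))
  expect_equal(rep$node, c(2, 3, 1))
  expect_equal(rep$time, c(1, 2, 3))

  # source among the observers: first entry is (source, 0)
  rep2 <- make_report(real, c(9, 1, 2))
  expect_equal(rep2$node[1], 9)
  expect_equal(rep2$time[1], 0)

  # tie at t = 2 between ids 7 and 6 -> smaller id first
  rep3 <- make_report(real, c(7, 6, 2))
  expect_equal(rep3$node, c(2, 6, 7))

  expect_warning(rep4 <- make_report(real, c(1, 2, 4)), "never reached")
  expect_equal(nrow(rep4), 2)
  expect_error(suppressWarnings(make_report(real, c(1, 4))),
               "fewer than 2")
})

test_that("nearest-observer selection keeps the K0 quickest, id-breaking ties", {
  rep <- observer_report(c(3, 8, 9, 5, 2), c(0, 1, 2, 2, 3))
  sel <- select_nearest(rep, 3)
  expect_equal(sel$node, c(3, 8, 5)) # t in {0,1} plus the smaller tied id
  expect_equal(nrow(sel), 3)

  # K0 >= K returns the report unchanged; selection is idempotent
  expect_identical(select_nearest(rep, 10)$node, rep$node)
  expect_identical(select_nearest(select_nearest(rep, 3), 3)$node, sel$node)
  expect_error(select_nearest(rep, 1), "at least 2")
})

test_that("default K0 follows round(0.5 sqrt(N)) with a floor of 2", {
  expect_identical(default_k0(400), 10L)
  expect_identical(default_k0(10000), 50L)
  expect_identical(default_k0(4), 2L)
})

test_that("noisy-observer classification against path enumeration", {
  # star: center is the hub; leaf-to-leaf shortest path passes it
  gs <- star_graph(10)
  expect_true(classify_noisy(gs, source = 2, observer = 3))
  # hub observers are noisy by definition
  expect_true(classify_noisy(gs, source = 2, observer = 1))

  # adjacent pair with no hub in between: non-noisy
  gp <- path_graph(5)
  expect_false(classify_noisy(gp, source = 2, observer = 3))

  # brute-force oracle: enumerate all shortest paths and inspect intermediates
  for (i in 1:15) {
    g <- largest_connected_component(generate_ba(30, 2, seed = i))
    hubs <- hub_set(g)
    nn <- igraph::vcount(g)
    set.seed(i)
    src <- sample.int(nn, 1)
    others <- setdiff(seq_len(nn), src)
    for (obs in sample(others, 3)) {
      sp <- igraph::all_shortest_paths(g, from = src, to = obs)$vpaths
      has_hub <- vapply(sp, function(p) {
        mid <- setdiff(as.integer(p), c(src, obs))
        any(mid %in% hubs)
      }, TRUE)
      oracle_all <- (obs %in% hubs) || all(has_hub)
      oracle_any <- (obs %in% hubs) || any(has_hub)
      expect_identical(classify_noisy(g, src, obs, rule = "all"), oracle_all)
      expect_identical(classify_noisy(g, src, obs, rule = "any"), oracle_any)
    }
  }
})

test_that("reports serialize to TSV", {
  rep <- observer_report(c(4, 2), c(1.5, 0.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, f)
  tab <- utils::read.delim(f, comment.char = "#")
  expect_equal(tab$observer_id, c(2, 4))
  expect_equal(tab$time, c(0.5, 1.5))
})
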