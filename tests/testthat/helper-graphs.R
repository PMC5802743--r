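# Small graphs and an independent naive scoring oracle used across tests.

path_graph <- function(n) igraph::make_ring(n, circular = FALSE)

star_graph <- function(n) igraph::make_star(n, mode = "undirected", center = 1)

# scores every node through the exported per-candidate R operations
# (fresh BFS tree, literal delay/covariance construction, dense score) —
# independent of the compiled batch kernel used by ptva_li_scan/gmla
naive_scores <- function(g, report, params, form = "gaussian") {
  vapply(seq_len(igraph::vcount(g)), function(s) {
    tr <- bfs_tree(g, s)
    if (anyNA(tr$depth[report$node])) return(-Inf)
    delay_score(observed_delays(report),
                deterministic_delays(tr, report$node, params$mu),
                delay_covariance(tr, report$node, params$sigma2),
                form = form, sigma2 = params$sigma2)
  }, numeric(1))
}

# deterministic noiseless report: t(v) = mu * dist(source, v)
noiseless_report <- function(g, source, observers, mu) {
  d <- igraph::distances(g, v = source, to = observers)[1, ]
  observer_report(observers, mu * d)
}

edge_set <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "-"))
}
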