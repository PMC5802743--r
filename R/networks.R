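#' Generate an Erdős–Rényi random graph with a given mean degree
#'
#' Draws a G(n, p) graph with p = mean_degree / (n - 1), so the expected
#' average degree equals `mean_degree`. Parameterizing by mean degree rather
#' than p matches how benchmark network ensembles are usually reported
#' (e.g. "ER graphs with <k> = 6").
#'
#' @param n Number of nodes (>= 2).
#' @param mean_degree Target average degree, in [0, n - 1].
#' @param seed Integer seed; identical arguments give an identical graph.
#' @return An undirected simple [igraph::igraph] graph with nodes 1..n.
#' @export
generate_er <- function(n, mean_degree, seed) {
  stopifnot(n >= 2)
  if (mean_degree < 0 || mean_degree > n - 1) {
    stop("mean_degree must lie in [0, n - 1]", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  igraph::sample_gnp(n, p = mean_degree / (n - 1), directed = FALSE)
}

#' Generate a Barabási–Albert preferential-attachment graph
#'
#' Growth starts from a small connected core of `m` nodes; each subsequent
#' node attaches `m` edges preferentially by degree, so every node has
#' degree >= m and the average degree tends to 2m for large n. The choice of
#' seed core is a standard one (any connected core gives the same degree
#' statistics, which is all the downstream analysis uses).
#'
#' @param n Number of nodes (> m).
#' @param m Edges attached by each incoming node (>= 1).
#' @param seed Integer seed.
#' @return An undirected simple [igraph::igraph] graph.
#' @export
generate_ba <- function(n, m, seed) {
  if (m < 1 || n <= m) stop("require n > m >= 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  start <- igraph::make_full_graph(m, directed = FALSE)
  g <- igraph::sample_pa(n, m = m, directed = FALSE, start.graph = start)
  igraph::simplify(g)
}

#' Read an undirected graph from a whitespace-separated edge-list file
#'
#' Accepts the SNAP text dialect: lines starting with `#` are comments, every
#' other line holds two integer node ids separated by a tab or spaces.
#' Directed duplicates and repeated lines collapse to a single undirected
#' edge; self-loops are dropped (with a message giving the count). Node ids
#' are remapped to consecutive ids 1..N; the original file ids are kept in
#' the vertex attribute `orig_id`.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph::igraph] graph.
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (length(data_lines) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  parts <- strsplit(trimws(data_lines), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) > 0) {
    stop("malformed edge line ", line_no[bad[1]], " in ", path, call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.integer(unlist(parts))),
                ncol = 2, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- line_no[which(rowSums(is.na(mat)) > 0)[1]]
    stop("malformed edge line ", bad, " in ", path, call. = FALSE)
  }
  n_loops <- sum(mat[, 1] == mat[, 2])
  if (n_loops > 0) {
    message("load_edge_list: dropped ", n_loops, " self-loop(s)")
    mat <- mat[mat[, 1] != mat[, 2], , drop = FALSE]
  }
  ids <- sort(unique(as.vector(mat)))
  from <- match(mat[, 1], ids)
  to <- match(mat[, 2], ids)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$orig_id <- ids
  g
}

#' Write a graph as a tab-separated edge list
#'
#' One `from<TAB>to` line per edge, preceded by a `#` comment header.
#' Round-trips with [load_edge_list()] on canonicalized graphs.
#'
#' @param g An igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# Undirected edge list: %d nodes, %d edges",
                     igraph::vcount(g), igraph::ecount(g)), con)
  if (nrow(el) > 0) {
    writeLines(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected component, with vertex ids
#' remapped to 1..N. Ties between equally sized components are broken in
#' favor of the component containing the smallest original vertex id.
#'
#' @param g An igraph graph.
#' @return The LCC as an igraph graph (empty graph if `g` is empty).
#' @export
largest_connected_component <- function(g) {
  if (igraph::vcount(g) == 0) return(g)
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    # smallest contained original id wins
    first_id <- vapply(best, function(ci) min(which(comp$membership == ci)), 1)
    best <- best[which.min(first_id)]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Hub nodes: degree at least sqrt(N)
#'
#' Returns the vertex ids whose degree is >= sqrt(N) (real-valued threshold,
#' no rounding). On scale-free networks these high-degree nodes dominate the
#' fast spreading paths and degrade arrival-time information passing
#' through them.
#'
#' @param g An igraph graph with at least one node.
#' @return Integer vector of hub vertex ids (possibly empty).
#' @export
hub_set <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n >= 1)
  deg <- igraph::degree(g)
  which(deg >= sqrt(n))
}

#' Basic structural summary of a graph
#'
#' @param g An igraph graph.
#' @return A list with `n`, `e`, `mean_degree`, `clustering` (global average
#'   local clustering coefficient, isolated/degree-1 nodes counting 0) and
#'   `hub_fraction` (share of nodes with degree >= sqrt(N)).
#' @export
graph_stats <- function(g) {
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  list(
    n = n,
    e = e,
    mean_degree = if (n > 0) 2 * e / n else NA_real_,
    clustering = igraph::transitivity(g, type = "localaverageundirected",
                                      isolates = "zero"),
    hub_fraction = if (n > 0) length(hub_set(g)) / n else NA_real_
  )
}

# Save/restore of the global RNG state so seeded generators do not disturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
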