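#' Place observers uniformly at random
#'
#' Samples round(rho * N) distinct vertices without replacement. At least
#' two observers are required downstream (a single report time carries no
#' delay information).
#'
#' @param g An igraph graph.
#' @param rho Observer density in (0, 1].
#' @param seed Integer seed.
#' @return Integer vector of observer vertex ids.
#' @export
place_observers <- function(g, rho, seed) {
  n <- igraph::vcount(g)
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]", call. = FALSE)
  k <- round(rho * n)
  if (k < 2) stop("observer density too low: fewer than 2 observers",
                  call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  obs <- sort(sample.int(n, k))
  attr(obs, "rho") <- rho
  obs
}

#' Assemble the observer report from a spread realization
#'
#' The report lists (observer, arrival time) pairs sorted by ascending time,
#' ties broken by ascending vertex id. Entry one ("observer one") is the
#' earliest-reporting observer — the anchor for the observed delay vector
#' and the starting region of the gradient search. Observers the spread
#' never reached are dropped with a warning: the Gaussian delay likelihood
#' cannot consume infinite times.
#'
#' @param realization A `spread_realization` from [si_simulate()].
#' @param observers Vector of observer vertex ids.
#' @return An object of class `observer_report`: data.frame with columns
#'   `node` and `time`, plus attributes `k` (number of entries) and `rho`
#'   (if carried by `observers`).
#' @export
make_report <- function(realization, observers) {
  observers <- as.integer(observers)
  t_obs <- realization$arrival[observers]
  if (anyNA(t_obs)) {
    warning(sum(is.na(t_obs)), " observer(s) never reached; dropped",
            call. = FALSE)
    observers <- observers[!is.na(t_obs)]
    t_obs <- t_obs[!is.na(t_obs)]
  }
  if (length(observers) < 2) {
    stop("fewer than 2 reached observers: no delay vector can be formed",
         call. = FALSE)
  }
  ord <- order(t_obs, observers)
  rep <- data.frame(node = observers[ord], time = t_obs[ord])
  structure(rep,
            class = c("observer_report", "data.frame"),
            k = nrow(rep),
            rho = attr(observers, "rho"))
}

#' Build an observer report directly from (node, time) pairs
#'
#' For externally supplied reports. Applies the same ordering convention as
#' [make_report()].
#'
#' @param nodes Observer vertex ids (distinct).
#' @param times Non-negative arrival times, same length as `nodes`.
#' @return An `observer_report`.
#' @export
observer_report <- function(nodes, times) {
  nodes <- as.integer(nodes)
  stopifnot(length(nodes) == length(times), !anyDuplicated(nodes),
            all(times >= 0))
  if (length(nodes) < 2) stop("need at least 2 observers", call. = FALSE)
  ord <- order(times, nodes)
  structure(data.frame(node = nodes[ord], time = as.numeric(times[ord])),
            class = c("observer_report", "data.frame"),
            k = length(nodes))
}

#' Restrict a report to the K0 earliest-reporting observers
#'
#' GMLA scores candidates against only the K0 nearest (quickest) observers:
#' far observers contribute little to the likelihood but dominate its cost,
#' and on hub-rich networks their delay information is degraded. Ties at
#' the time cutoff are broken by ascending vertex id; if `k0 >= K` the
#' report is returned unchanged.
#'
#' @param report An `observer_report`.
#' @param k0 Number of observers to keep (>= 2).
#' @return An `observer_report` with at most `k0` entries.
#' @export
select_nearest <- function(report, k0) {
  if (k0 < 2) stop("k0 must be at least 2", call. = FALSE)
  k <- nrow(report)
  if (k0 >= k) return(report)
  out <- report[seq_len(k0), , drop = FALSE] # already sorted by (time, id)
  rownames(out) <- NULL
  structure(out,
            class = c("observer_report", "data.frame"),
            k = k0, rho = attr(report, "rho"))
}

#' Default number of nearest observers, K0 = 0.5 sqrt(N)
#'
#' The accuracy-optimal observer count grows roughly as a square root of the
#' network size; round(0.5 * sqrt(n)), floored at 2, is a good default for
#' random placement at moderate density.
#'
#' @param n Network size (number of nodes).
#' @return Integer K0 >= 2.
#' @export
default_k0 <- function(n) {
  stopifnot(n >= 2)
  max(2L, as.integer(round(0.5 * sqrt(n))))
}

#' Classify an observer as noisy ("behind a hub") with respect to a source
#'
#' Hubs (degree >= sqrt(N)) randomize arrival times passing through them. An
#' observer is noisy if it is itself a hub or if its shortest paths to the
#' source are blocked by hubs. With `rule = "all"` (default) the observer is
#' noisy when every shortest path from the source contains a hub as an
#' intermediate node — i.e. no hub-free shortest path exists. With
#' `rule = "any"` it is noisy as soon as some shortest path passes a hub.
#'
#' @param g An igraph graph.
#' @param source Source vertex id.
#' @param observer Observer vertex id (different from `source`).
#' @param rule `"all"` or `"any"` (see above).
#' @return `TRUE` if noisy, `FALSE` otherwise.
#' @export
classify_noisy <- function(g, source, observer, rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(source != observer)
  d_full <- igraph::distances(g, v = source, to = observer)[1, 1]
  if (is.infinite(d_full)) {
    stop("source and observer are disconnected", call. = FALSE)
  }
  hubs <- hub_set(g)
  if (observer %in% hubs) return(TRUE)
  # intermediate hubs only: keep the endpoints even if the source is a hub
  blocked <- setdiff(hubs, c(source, observer))
  if (length(blocked) == 0) return(FALSE)
  sub <- igraph::delete_vertices(g, blocked)
  remaining <- setdiff(seq_len(igraph::vcount(g)), blocked)
  s2 <- match(source, remaining)
  o2 <- match(observer, remaining)
  d_sub <- igraph::distances(sub, v = s2, to = o2)[1, 1]
  if (rule == "all") {
    # noisy iff no shortest path avoids the hubs
    return(d_sub > d_full)
  }
  # "any": noisy iff at least one shortest path passes a hub, i.e. the
  # hub-free subgraph carries strictly fewer shortest paths of length d_full
  if (d_sub > d_full) return(TRUE)
  n_full <- .count_shortest_paths(g, source, observer)
  n_sub <- .count_shortest_paths(sub, s2, o2)
  n_sub < n_full
}

# number of distinct shortest paths between two nodes (BFS path counting)
.count_shortest_paths <- function(g, s, t) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  dist <- rep(NA_integer_, n)
  cnt <- rep(0, n)
  dist[s] <- 0L
  cnt[s] <- 1
  frontier <- s
  while (length(frontier) > 0 && is.na(dist[t])) {
    nxt <- integer(0)
    for (u in frontier) {
      for (w in as.integer(adj[[u]])) {
        if (is.na(dist[w])) {
          dist[w] <- dist[u] + 1L
          nxt <- c(nxt, w)
          cnt[w] <- cnt[w] + cnt[u]
        } else if (dist[w] == dist[u] + 1L) {
          cnt[w] <- cnt[w] + cnt[u]
        }
      }
    }
    frontier <- unique(nxt)
  }
  cnt[t]
}

#' Write an observer report as TSV
#'
#' @param report An `observer_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  rho <- attr(report, "rho")
  writeLines(sprintf("# observers=%d rho=%s", nrow(report),
                     if (is.null(rho)) "NA" else format(rho)), con)
  writeLines("observer_id\ttime", con)
  writeLines(paste(report$node, report$time, sep = "\t"), con)
  invisible(path)
}
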