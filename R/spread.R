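#' Per-edge delay moments of the discrete SI model
#'
#' In the discrete-time Susceptible-Infected model each infected node tries
#' to infect each susceptible neighbor once per step, succeeding with
#' probability `beta`. The number of steps to pass an edge is therefore
#' Geometric(beta), with mean mu = 1/beta and variance
#' sigma2 = (1 - beta)/beta^2. The propagation ratio lambda = mu/sigma =
#' 1/sqrt(1 - beta) summarizes how deterministic the spread is; it is
#' infinite at beta = 1 (unit delays, no noise).
#'
#' @param beta Infection probability per neighbor per step, in (0, 1].
#' @return An object of class `propagation_model`: a list with `beta`, `mu`,
#'   `sigma2` and `lambda` (`Inf` at beta = 1).
#' @export
delay_moments <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1 || is.na(beta) ||
      beta <= 0 || beta > 1) {
    stop("beta must be a single number in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      beta = beta,
      mu = 1 / beta,
      sigma2 = (1 - beta) / beta^2,
      lambda = if (beta < 1) 1 / sqrt(1 - beta) else Inf
    ),
    class = "propagation_model"
  )
}

#' @export
print.propagation_model <- function(x, ...) {
  cat(sprintf(
    "SI propagation model: beta = %g (mu = %g, sigma2 = %g, lambda = %s)\n",
    x$beta, x$mu, x$sigma2,
    if (is.finite(x$lambda)) format(x$lambda) else "Inf"))
  invisible(x)
}

#' Simulate a discrete-time Susceptible-Infected spread
#'
#' Synchronous dynamics: at each step every infected node attempts each
#' currently susceptible neighbor independently with probability `beta`;
#' all attempts of a step are evaluated against the susceptible set at the
#' start of the step, so simultaneous first exposures share the same
#' arrival step. A node's arrival time is the index of the step of its
#' first successful exposure; the source has arrival time 0.
#'
#' @param g An igraph graph.
#' @param source Vertex id of the true source.
#' @param beta Infection probability per neighbor per step, in (0, 1].
#' @param seed Integer seed; identical arguments give identical arrivals.
#' @param stop_nodes Optional vector of vertex ids: the simulation stops as
#'   soon as all of them are infected. Default (`NULL`) runs until the whole
#'   component containing `source` is infected.
#' @return An object of class `spread_realization`: list with `source`,
#'   `arrival` (numeric vector over all vertices, `NA` = never reached) and
#'   `beta`.
#' @export
si_simulate <- function(g, source, beta, seed, stop_nodes = NULL) {
  n <- igraph::vcount(g)
  source <- as.integer(source)
  if (length(source) != 1 || is.na(source) || source < 1 || source > n) {
    stop("source must be a vertex of g", call. = FALSE)
  }
  if (beta <= 0 || beta > 1) stop("beta must be in (0, 1]", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  # directed view of each undirected edge so infection can cross either way
  el <- igraph::as_edgelist(g, names = FALSE)
  from <- c(el[, 1], el[, 2])
  to <- c(el[, 2], el[, 1])

  arrival <- rep(NA_real_, n)
  arrival[source] <- 0
  infected <- logical(n)
  infected[source] <- TRUE

  if (!is.null(stop_nodes)) {
    stop_nodes <- as.integer(stop_nodes)
    stopifnot(all(stop_nodes >= 1 & stop_nodes <= n))
  }
  target_met <- function() {
    if (is.null(stop_nodes)) FALSE else all(infected[stop_nodes])
  }

  # nodes in the source's component that can ever be reached
  reachable <- !is.infinite(igraph::distances(g, v = source)[1, ])
  total_reachable <- sum(reachable)

  step <- 0L
  while (!target_met() && sum(infected) < total_reachable) {
    step <- step + 1L
    active <- infected[from] & !infected[to]
    if (!any(active)) break # cannot happen on a connected component, but safe
    tries_to <- to[active]
    hit <- tries_to[stats::runif(length(tries_to)) < beta]
    if (length(hit) > 0) {
      new_nodes <- unique(hit)
      arrival[new_nodes] <- step
      infected[new_nodes] <- TRUE
    }
  }

  structure(
    list(source = source, arrival = arrival, beta = beta),
    class = "spread_realization"
  )
}

#' @export
print.spread_realization <- function(x, ...) {
  reached <- sum(!is.na(x$arrival))
  cat(sprintf(
    "SI realization: source %d, beta = %g, %d node(s) reached, max t = %g\n",
    x$source, x$beta, reached, max(x$arrival, na.rm = TRUE)))
  invisible(x)
}

#' Write a spread realization as TSV
#'
#' Header comment records the source and beta; body is `node<TAB>arrival`.
#' Unreached nodes are written with arrival `NA`.
#'
#' @param realization A `spread_realization`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_realization <- function(realization, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source=%d beta=%g",
                     realization$source, realization$beta), con)
  writeLines("node\tarrival", con)
  writeLines(paste(seq_along(realization$arrival), realization$arrival,
                   sep = "\t"), con)
  invisible(path)
}
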