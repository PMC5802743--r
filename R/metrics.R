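#' Single-realization accuracy
#'
#' a_i = 1/|V_top| if the true source is among the top scorers, else 0.
#' The reciprocal handles score ties: a locator that returns j tied top
#' scorers including the source gets credit 1/j.
#'
#' @param result A `source_estimate`.
#' @param true_source The true source vertex id.
#' @return A number in \{0\} or \{1/j\}.
#' @export
accuracy <- function(result, true_source) {
  v_top <- result$v_top
  if (length(v_top) == 0 || all(is.na(v_top))) {
    stop("result has no top scorer", call. = FALSE)
  }
  if (true_source %in% v_top) 1 / length(v_top) else 0
}

#' Rank of the true source in the score list
#'
#' Position of the true source on the descending score list, resolving ties
#' pessimistically: nodes tied with the source count as ranked above it.
#' A source absent from the suspected set (possible for GMLA) gets rank `n`.
#' The baseline method assigns no scores, so rank is undefined for it.
#'
#' @param result A `source_estimate` with scores.
#' @param true_source The true source vertex id.
#' @param n The network size.
#' @return Integer rank in [1, n].
#' @export
source_rank <- function(result, true_source, n) {
  if (is.null(result$scores)) {
    stop("rank is unsupported for the ", result$method,
         " method (no scores assigned)", call. = FALSE)
  }
  s <- result$scores[as.character(true_source)]
  if (is.na(s)) return(as.integer(n))
  # ties resolved below the peers: count every node scoring >= source
  as.integer(sum(result$scores >= as.numeric(s)))
}

#' Distance error of a localization
#'
#' Mean shortest-path (hop) distance between the true source and the top
#' scorers. Zero iff the unique top scorer is the true source.
#'
#' @param g The igraph graph the localization ran on.
#' @param result A `source_estimate`.
#' @param true_source The true source vertex id.
#' @return Non-negative mean hop count.
#' @export
distance_error <- function(g, result, true_source) {
  v_top <- result$v_top
  dists <- igraph::distances(g, v = true_source, to = v_top)[1, ]
  if (any(is.infinite(dists))) {
    stop("a top scorer is disconnected from the true source", call. = FALSE)
  }
  mean(dists)
}
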