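new_source_estimate <- function(scores, method, n0, score_evaluations,
                                k0 = NA_integer_) {
  if (is.null(scores)) {
    ranking <- NULL
    v_top <- NA_integer_
  } else {
    nodes <- as.integer(names(scores))
    ord <- order(-scores, nodes)
    ranking <- nodes[ord]
    finite_max <- max(scores)
    v_top <- sort(nodes[scores == finite_max])
  }
  structure(
    list(scores = scores, ranking = ranking, v_top = v_top,
         n0 = n0, method = method, score_evaluations = score_evaluations,
         k0 = k0),
    class = "source_estimate"
  )
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("Source estimate (%s): top scorer(s) {%s}",
              x$method, paste(x$v_top, collapse = ", ")))
  if (!is.null(x$scores)) {
    cat(sprintf(", N0 = %d suspected node(s), %d score evaluation(s)",
                x$n0, x$score_evaluations))
  }
  cat("\n")
  invisible(x)
}

#' Gradient Maximum Likelihood Algorithm (GMLA)
#'
#' Fast source localization. The report is first restricted to the `k0`
#' earliest-reporting observers. Scoring starts from the neighbors of
#' observer one (the earliest report, almost always close to the source) and
#' then follows the likelihood gradient: the search jumps to the
#' best-scoring neighbor and keeps expanding while some neighbor's score is
#' at least the running maximum. Every computed score is cached, each node
#' is expanded at most once (which guarantees termination on score
#' plateaus), and the suspected set V_s is exactly the set of scored nodes —
#' the true source is not guaranteed to be in it.
#'
#' @param g An igraph graph.
#' @param report An `observer_report`.
#' @param params A `propagation_model` from [delay_moments()].
#' @param k0 Number of nearest observers to use (default
#'   [default_k0()] of the graph size).
#' @param form Score form, `"gaussian"` (default) or `"linearized"`.
#' @return A `source_estimate` with the scored suspect set, descending
#'   `ranking`, top-scorer set `v_top`, `n0 = |V_s|` and the number of score
#'   evaluations.
#' @export
gmla <- function(g, report, params, k0 = default_k0(igraph::vcount(g)),
                 form = c("gaussian", "linearized")) {
  form <- match.arg(form)
  rep0 <- select_nearest(report, k0)
  csr <- graph_csr(g)
  d <- observed_delays(rep0)
  obs0 <- as.integer(rep0$node) - 1L
  adj <- lapply(igraph::as_adj_list(g), as.integer)

  score_batch <- function(nodes) {
    s <- score_candidates_cpp(csr$ptr, csr$idx, csr$n,
                              as.integer(nodes) - 1L, obs0,
                              as.numeric(d), params$mu, params$sigma2,
                              form == "gaussian")
    names(s) <- as.character(nodes)
    s
  }

  o1 <- rep0$node[1]
  nb1 <- sort(adj[[o1]])
  if (length(nb1) == 0) stop("observer one is isolated", call. = FALSE)

  scores <- score_batch(nb1)
  expanded <- integer(0)

  pick_best <- function(nodes, sc) {
    best <- max(sc)
    cand <- sort(nodes[sc == best])
    cand_open <- setdiff(cand, expanded)
    if (length(cand_open) == 0) NA_integer_ else cand_open[1]
  }

  current <- pick_best(nb1, scores)
  cur_max <- max(scores)

  while (!is.na(current)) {
    expanded <- c(expanded, current)
    nbs <- sort(adj[[current]])
    new <- nbs[!(as.character(nbs) %in% names(scores))]
    if (length(new) > 0) scores <- c(scores, score_batch(new))
    nb_scores <- scores[as.character(nbs)]
    best_nb <- max(nb_scores)
    if (best_nb < cur_max) break
    cur_max <- max(cur_max, best_nb)
    current <- pick_best(nbs, nb_scores)
  }

  nodes <- as.integer(names(scores))
  ord <- order(nodes)
  scores <- scores[ord]
  names(scores) <- as.character(nodes[ord])
  new_source_estimate(scores, method = "gmla", n0 = length(scores),
                      score_evaluations = length(scores), k0 = k0)
}

#' PTVA-LI locator (full scan)
#'
#' Scores every node of the graph as a candidate source using all reported
#' observers; the suspected set is the whole vertex set (N0 = N).
#'
#' @inheritParams gmla
#' @return A `source_estimate`.
#' @export
ptva_li <- function(g, report, params, form = c("gaussian", "linearized")) {
  form <- match.arg(form)
  n <- igraph::vcount(g)
  scores <- score_candidates(g, report, params, seq_len(n), form)
  new_source_estimate(scores, method = "ptva_li", n0 = n,
                      score_evaluations = n)
}

#' Baseline locator: the earliest-reporting observer is the source
#'
#' A no-cost benchmark. Its accuracy equals the observer density under
#' uniform random placement: whenever the true source happens to be an
#' observer, it necessarily reports first. It assigns no scores, so the
#' rank of the true source is undefined for this method.
#'
#' @param report An `observer_report` with at least one entry.
#' @return A `source_estimate` with `v_top` = observer one and no scores.
#' @export
baseline <- function(report) {
  if (nrow(report) < 1) stop("empty report", call. = FALSE)
  est <- new_source_estimate(NULL, method = "baseline", n0 = 0L,
                             score_evaluations = 0L)
  est$v_top <- as.integer(report$node[1])
  est
}
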