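#' Deterministic breadth-first search tree
#'
#' BFS from `root` with a fixed tie rule: the frontier is processed in
#' ascending vertex id, so each node's parent is its smallest-id neighbor at
#' the previous depth. The BFS tree stands in for the (unknown) propagation
#' tree under the shortest-path spreading assumption; since BFS trees are
#' not unique, fixing the tie rule makes the delay covariance deterministic.
#'
#' @param g An igraph graph.
#' @param root Root vertex id.
#' @return An object of class `bfs_tree`: list with `root`, `parent`
#'   (integer vector, `NA` at the root and at unreachable nodes) and `depth`
#'   (integer vector, `NA` at unreachable nodes).
#' @export
bfs_tree <- function(g, root) {
  n <- igraph::vcount(g)
  root <- as.integer(root)
  stopifnot(root >= 1, root <= n)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  parent <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  level <- root
  d <- 0L
  while (length(level) > 0) {
    level <- sort(level)
    nxt <- integer(0)
    for (u in level) {
      for (w in adj[[u]]) {
        if (is.na(depth[w])) {
          depth[w] <- d + 1L
          parent[w] <- u
          nxt <- c(nxt, w)
        }
      }
    }
    level <- nxt
    d <- d + 1L
  }
  structure(list(root = root, parent = parent, depth = depth),
            class = "bfs_tree")
}

#' Observed delay vector of a report
#'
#' Delays of observers 2..K relative to observer one (the earliest report):
#' d_k = t_{k+1} - t_1. Translation of all report times leaves d unchanged,
#' so no absolute clock is needed.
#'
#' @param report An `observer_report` with at least 2 entries.
#' @return Numeric vector of length K - 1, entries >= 0.
#' @export
observed_delays <- function(report) {
  if (nrow(report) < 2) stop("need at least 2 observers", call. = FALSE)
  report$time[-1] - report$time[1]
}

#' Deterministic (expected) delay vector for a candidate source
#'
#' If `s` were the source and spreading followed shortest paths with mean
#' per-edge delay mu, observer k would report mu * depth(o_k) where depth is
#' taken on the BFS tree rooted at s. Entry k of the deterministic delay
#' vector is mu * (depth(o_{k+1}) - depth(o_1)); entries can be negative
#' when observer one is not the closest observer to `s`.
#'
#' @param tree A `bfs_tree` rooted at the candidate source.
#' @param observers Ordered observer vertex ids (report order).
#' @param mu Mean per-edge delay.
#' @return Numeric vector of length K - 1.
#' @export
deterministic_delays <- function(tree, observers, mu) {
  dep <- tree$depth[observers]
  if (anyNA(dep)) stop("observer unreachable from candidate", call. = FALSE)
  mu * (dep[-1] - dep[1])
}

#' Delay covariance matrix for a candidate source
#'
#' Per-edge delays are i.i.d. with variance sigma2, so the covariance of the
#' observed delays (all taken relative to observer one) is sigma2 times the
#' number of tree edges shared between the paths o_1 -> o_{i+1} and
#' o_1 -> o_{k+1}, both within the BFS tree rooted at the candidate. The
#' diagonal is sigma2 times the tree-path length from o_1 to each observer.
#'
#' This reference implementation enumerates the tree paths explicitly and
#' intersects their edge sets.
#'
#' @param tree A `bfs_tree` rooted at the candidate source.
#' @param observers Ordered observer vertex ids (report order).
#' @param sigma2 Per-edge delay variance.
#' @return Symmetric positive semi-definite (K-1) x (K-1) matrix.
#' @export
delay_covariance <- function(tree, observers, sigma2) {
  k <- length(observers)
  if (k < 2) stop("need at least 2 observers", call. = FALSE)
  if (anyNA(tree$depth[observers])) {
    stop("observer unreachable from candidate", call. = FALSE)
  }
  o1 <- observers[1]
  paths <- lapply(observers[-1], function(ok) .tree_path_edges(tree, o1, ok))
  m <- k - 1
  lambda <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in i:m) {
      shared <- length(intersect(paths[[i]], paths[[j]]))
      lambda[i, j] <- sigma2 * shared
      lambda[j, i] <- lambda[i, j]
    }
  }
  lambda
}

# edges (as "lo-hi" strings) on the unique tree path between two nodes
.tree_path_edges <- function(tree, a, b) {
  anc <- function(v) {
    path <- v
    while (!is.na(tree$parent[v])) {
      v <- tree$parent[v]
      path <- c(path, v)
    }
    path # v .. root
  }
  pa <- anc(a)
  pb <- anc(b)
  # drop the common suffix (shared ancestors above the LCA)
  while (length(pa) > 1 && length(pb) > 1 &&
         pa[length(pa) - 1] == pb[length(pb) - 1]) {
    pa <- pa[-length(pa)]
    pb <- pb[-length(pb)]
  }
  nodes <- c(pa, rev(pb[-length(pb)])) # a .. lca .. b
  if (length(nodes) < 2) return(character(0))
  u <- nodes[-length(nodes)]
  v <- nodes[-1]
  paste(pmin(u, v), pmax(u, v), sep = "-")
}

#' Gaussian log-score of a candidate source
#'
#' The score phi of a candidate is the log-likelihood of the observed delay
#' vector under a multivariate Gaussian with mean `mu_s` and covariance
#' `lambda_s`, up to the additive constant -(K-1)/2 log(2 pi):
#' phi = -1/2 logdet(Lambda) - 1/2 (d - mu_s)' Lambda^{-1} (d - mu_s).
#' The alternative `form = "linearized"` scores
#' mu_s' Lambda^{-1} (d - mu_s / 2), the determinant-free estimator used
#' when candidates are compared under a common covariance normalization.
#' A singular covariance is regularized by adding eps * sigma2 * I with
#' eps = 1e-8 (sigma2 taken as the mean diagonal scale when not supplied).
#'
#' @param d Observed delay vector.
#' @param mu_s Deterministic delay vector of the candidate.
#' @param lambda_s Delay covariance matrix of the candidate.
#' @param form `"gaussian"` (default) or `"linearized"`.
#' @param sigma2 Optional per-edge variance used for the regularization
#'   scale; defaults to mean(diag(lambda_s)).
#' @return The log-score, a single number.
#' @export
delay_score <- function(d, mu_s, lambda_s, form = c("gaussian", "linearized"),
                        sigma2 = NULL) {
  form <- match.arg(form)
  m <- length(d)
  if (length(mu_s) != m || !all(dim(lambda_s) == c(m, m))) {
    stop("dimension mismatch between d, mu_s and lambda_s", call. = FALSE)
  }
  if (!all(is.finite(d)) || !all(is.finite(mu_s)) ||
      !all(is.finite(lambda_s))) {
    stop("non-finite entries in score inputs", call. = FALSE)
  }
  if (is.null(sigma2)) sigma2 <- mean(diag(lambda_s))
  ch <- tryCatch(chol(lambda_s), error = function(e) NULL)
  if (is.null(ch)) {
    reg <- lambda_s + diag(1e-8 * sigma2, m)
    ch <- tryCatch(chol(reg), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
  }
  if (form == "gaussian") {
    resid <- d - mu_s
    z <- backsolve(ch, resid, transpose = TRUE)
    -sum(log(diag(ch))) - 0.5 * sum(z^2)
  } else {
    rhs <- d - 0.5 * mu_s
    z1 <- backsolve(ch, mu_s, transpose = TRUE)
    z2 <- backsolve(ch, rhs, transpose = TRUE)
    sum(z1 * z2)
  }
}

# Compressed sparse row adjacency (0-based, neighbors ascending) for the
# compiled scoring kernel. Cached on the graph environment would invalidate
# poorly; recomputation is O(E) and cheap relative to a scan.
graph_csr <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  from <- c(el[, 1], el[, 2])
  to <- c(el[, 2], el[, 1])
  ord <- order(from, to)
  from <- from[ord]
  to <- to[ord]
  deg <- tabulate(from, nbins = n)
  list(ptr = c(0L, cumsum(deg)), idx = as.integer(to - 1L), n = n)
}

#' Score a set of candidate sources against an observer report
#'
#' Computes the log-score of each candidate using the compiled kernel:
#' a BFS tree per candidate, the deterministic delay vector and delay
#' covariance from that tree, then the Gaussian (or linearized) score.
#' Candidates from which some reporting observer is unreachable score -Inf.
#'
#' @param g An igraph graph.
#' @param report An `observer_report`.
#' @param params A `propagation_model` from [delay_moments()].
#' @param candidates Vertex ids to score (default: all).
#' @param form `"gaussian"` or `"linearized"`.
#' @return Numeric vector of log-scores named by candidate vertex id.
#' @export
score_candidates <- function(g, report, params,
                             candidates = seq_len(igraph::vcount(g)),
                             form = c("gaussian", "linearized")) {
  form <- match.arg(form)
  csr <- graph_csr(g)
  d <- observed_delays(report)
  scores <- score_candidates_cpp(
    csr$ptr, csr$idx, csr$n,
    as.integer(candidates) - 1L, as.integer(report$node) - 1L,
    as.numeric(d), params$mu, params$sigma2, form == "gaussian")
  names(scores) <- as.character(candidates)
  scores
}

#' Full maximum-likelihood scan (PTVA-LI)
#'
#' Scores every node of the graph as a candidate source using all reported
#' observers, the limited-information variant of the Pinto-Thiran-Vetterli
#' locator: observers report arrival times only, not the sending neighbor.
#'
#' @param g An igraph graph.
#' @param report An `observer_report`.
#' @param params A `propagation_model`.
#' @param form `"gaussian"` or `"linearized"`.
#' @return A data.frame `node`, `score` sorted by descending score (ties by
#'   ascending node id), with attribute `score_evaluations`.
#' @export
ptva_li_scan <- function(g, report, params,
                         form = c("gaussian", "linearized")) {
  form <- match.arg(form)
  n <- igraph::vcount(g)
  scores <- score_candidates(g, report, params, seq_len(n), form)
  ord <- order(-scores, seq_len(n))
  structure(data.frame(node = ord, score = scores[ord]),
            score_evaluations = n)
}

#' Write a score table as TSV
#'
#' @param scores A data.frame with `node` and `score` (e.g. from
#'   [ptva_li_scan()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
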