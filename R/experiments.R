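#' Deterministic child seeds for replicated experiments
#'
#' All harness randomness flows through seeds drawn once from a stream
#' seeded by `master_seed`, so every experiment is reproducible from a
#' single integer and replicates are independent.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds in [1, 2^31 - 2].
#' @export
child_seeds <- function(master_seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# one benchmark realization: graph -> source -> spread -> observers -> report
.make_instance <- function(topology, n, mean_degree, m, beta, rho, seeds,
                           graph = NULL) {
  g <- switch(topology,
    er = generate_er(n, mean_degree, seeds[1]),
    ba = generate_ba(n, m, seeds[1]),
    file = graph,
    stop("unknown topology: ", topology, call. = FALSE))
  g <- largest_connected_component(g)
  nn <- igraph::vcount(g)
  old <- .Random.seed_save()
  set.seed(seeds[2])
  src <- sample.int(nn, 1)
  .Random.seed_restore(old)
  obs <- place_observers(g, rho, seeds[3])
  real <- si_simulate(g, src, beta, seeds[4], stop_nodes = obs)
  list(g = g, source = src, observers = obs,
       report = make_report(real, obs), realization = real)
}

.run_method <- function(method, inst, params, k0_rule, form) {
  nn <- igraph::vcount(inst$g)
  k0 <- if (identical(k0_rule, "auto")) default_k0(nn) else as.integer(k0_rule)
  est <- switch(method,
    gmla = gmla(inst$g, inst$report, params, k0 = k0, form = form),
    ptva_li = ptva_li(inst$g, inst$report, params, form = form),
    baseline = baseline(inst$report),
    stop("unknown method: ", method, call. = FALSE))
  data.frame(
    method = method,
    a_i = accuracy(est, inst$source),
    rank = if (is.null(est$scores)) NA_integer_
           else source_rank(est, inst$source, nn),
    dist_err = distance_error(inst$g, est, inst$source),
    n0 = est$n0,
    score_evaluations = est$score_evaluations
  )
}

#' Quality-versus-size benchmark of the locators
#'
#' For each network size and replicate: generate the graph (or reuse a
#' supplied one), take its largest connected component, pick a uniform
#' random source, run the SI spread, place observers uniformly at random,
#' assemble the report and run each requested locator; record accuracy,
#' rank, distance error, suspect-set size and score-evaluation count.
#' Fully deterministic under `seed` (child seeds per replicate).
#'
#' @param topology `"er"`, `"ba"` or `"file"` (supply `graph`).
#' @param sizes Vector of network sizes (ignored for `"file"`).
#' @param mean_degree ER mean degree (default 6).
#' @param m BA attachment parameter (default 3, so <k> = 6).
#' @param beta SI infection rate (default 0.5).
#' @param rho Observer density (default 0.2).
#' @param k0 `"auto"` (0.5 sqrt(N)) or a fixed integer.
#' @param methods Subset of `c("gmla", "ptva_li", "baseline")`.
#' @param replicates Realizations per size.
#' @param seed Master seed.
#' @param graph igraph graph when `topology = "file"`.
#' @param form Score form for the likelihood-based methods.
#' @return data.frame of per-realization records with columns `n`,
#'   `replicate`, `method`, `a_i`, `rank`, `dist_err`, `n0`,
#'   `score_evaluations`.
#' @export
run_quality_benchmark <- function(topology, sizes, mean_degree = 6, m = 3,
                                  beta = 0.5, rho = 0.2, k0 = "auto",
                                  methods = c("gmla", "ptva_li", "baseline"),
                                  replicates = 300, seed = 1, graph = NULL,
                                  form = "gaussian") {
  params <- delay_moments(beta)
  if (topology == "file") sizes <- igraph::vcount(graph)
  seeds <- matrix(child_seeds(seed, 4 * replicates * length(sizes)),
                  ncol = 4)
  rows <- vector("list", replicates * length(sizes) * length(methods))
  ri <- 0L
  cell <- 0L
  for (n in sizes) {
    for (rep_i in seq_len(replicates)) {
      cell <- cell + 1L
      rec <- tryCatch({
        inst <- .make_instance(topology, n, mean_degree, m, beta, rho,
                               seeds[cell, ], graph)
        do.call(rbind, lapply(methods, .run_method, inst = inst,
                              params = params, k0_rule = k0, form = form))
      }, error = function(e) {
        warning("replicate ", rep_i, " at n = ", n, " failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(rec)) next
      rec$n <- n
      rec$replicate <- rep_i
      ri <- ri + 1L
      rows[[ri]] <- rec
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  out[, c("n", "replicate", "method", "a_i", "rank", "dist_err", "n0",
          "score_evaluations")]
}

#' Aggregate benchmark records per (size, method) cell
#'
#' Mean accuracy with its standard error, rank quartiles, mean distance
#' error, mean suspect-set size and mean score-evaluation count.
#'
#' @param records Output of [run_quality_benchmark()].
#' @return data.frame with one row per (n, method).
#' @export
summarize_benchmark <- function(records) {
  cells <- split(records, list(records$n, records$method), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(cc) {
    data.frame(
      n = cc$n[1],
      method = cc$method[1],
      replicates = nrow(cc),
      accuracy = mean(cc$a_i),
      accuracy_se = stats::sd(cc$a_i) / sqrt(nrow(cc)),
      rank_median = if (all(is.na(cc$rank))) NA_real_
                    else stats::median(cc$rank, na.rm = TRUE),
      rank_q1 = if (all(is.na(cc$rank))) NA_real_
                else unname(stats::quantile(cc$rank, 0.25, na.rm = TRUE)),
      rank_q3 = if (all(is.na(cc$rank))) NA_real_
                else unname(stats::quantile(cc$rank, 0.75, na.rm = TRUE)),
      dist_err = mean(cc$dist_err),
      n0 = mean(cc$n0),
      score_evaluations = mean(cc$score_evaluations)
    )
  }))
  out <- out[order(out$method, out$n), ]
  rownames(out) <- NULL
  out
}

#' Nonlinear least-squares power-law fit y = b x^a
#'
#' Gauss-Newton fit (stats::nls) started from the log-log linear fit; when
#' the log-log fit is already exact the closed form is returned directly
#' (zero-residual data breaks the Gauss-Newton step). 95% confidence
#' intervals come from the asymptotic covariance.
#'
#' @param x,y Positive numeric vectors, length >= 3.
#' @return List with `a`, `b`, `a_ci`, `b_ci` (95% CIs) and the `nls` fit
#'   object (`NULL` for an exact fit).
#' @export
fit_power_law <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    stop("need >= 3 (x, y) points", call. = FALSE)
  }
  if (any(x <= 0) || any(y <= 0)) {
    stop("power-law fit requires positive data", call. = FALSE)
  }
  ll <- stats::lm(log(y) ~ log(x))
  a0 <- unname(stats::coef(ll)[2])
  b0 <- exp(unname(stats::coef(ll)[1]))
  if (max(abs(stats::residuals(ll))) < 1e-10) {
    return(list(a = a0, b = b0, a_ci = c(a0, a0), b_ci = c(b0, b0),
                fit = NULL))
  }
  fit <- stats::nls(y ~ b * x^a, start = list(a = a0, b = b0))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qt(0.975, df = length(x) - 2)
  list(a = unname(est["a"]), b = unname(est["b"]),
       a_ci = unname(est["a"] + c(-1, 1) * z * se["a"]),
       b_ci = unname(est["b"] + c(-1, 1) * z * se["b"]),
       fit = fit)
}

#' Accuracy versus number of nearest observers, and the optimal K0
#'
#' Runs GMLA over a grid of K0 values for each network size and estimates
#' K0* — the smallest grid value whose mean accuracy is within one standard
#' error of the grid maximum (the minimal observer count achieving maximal
#' localization quality). With at least 3 sizes a power law K0* = b N^a is
#' fitted.
#'
#' @param sizes Vector of network sizes.
#' @param k0_grid Ascending grid of K0 values (>= 2).
#' @param topology `"er"` or `"ba"`.
#' @param mean_degree,m,beta,rho,form As in [run_quality_benchmark()].
#' @param replicates Realizations per (size, K0) cell.
#' @param seed Master seed.
#' @return List with `table` (per-cell mean accuracy and s.e.), `k0_star`
#'   (per size) and `fit` (power-law fit or `NULL`).
#' @export
sweep_k0 <- function(sizes, k0_grid, topology = "ba", mean_degree = 6, m = 3,
                     beta = 0.5, rho = 0.2, replicates = 100, seed = 1,
                     form = "gaussian") {
  stopifnot(!is.unsorted(k0_grid), all(k0_grid >= 2))
  params <- delay_moments(beta)
  seeds <- matrix(child_seeds(seed, 4 * replicates * length(sizes)),
                  ncol = 4)
  table_rows <- list()
  k0_star <- numeric(length(sizes))
  cell <- 0L
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    acc <- matrix(NA_real_, replicates, length(k0_grid))
    for (rep_i in seq_len(replicates)) {
      cell <- cell + 1L
      inst <- .make_instance(topology, n, mean_degree, m, beta, rho,
                             seeds[cell, ])
      k_available <- nrow(inst$report)
      grid <- k0_grid
      if (any(grid > k_available)) {
        warning("k0 grid truncated to the ", k_available,
                " available observers", call. = FALSE)
        grid <- pmin(grid, k_available)
      }
      for (gi in seq_along(grid)) {
        est <- gmla(inst$g, inst$report, params, k0 = grid[gi], form = form)
        acc[rep_i, gi] <- accuracy(est, inst$source)
      }
    }
    mean_acc <- colMeans(acc)
    se_acc <- apply(acc, 2, stats::sd) / sqrt(replicates)
    best <- which.max(mean_acc)
    # smallest K0 whose accuracy is within one standard error of the grid
    # maximum; the instances are shared across the grid, so the paired
    # difference se is the relevant yardstick
    within_one_se <- vapply(seq_along(k0_grid), function(gi) {
      dif <- acc[, gi] - acc[, best]
      mean(dif) >= -stats::sd(dif) / sqrt(replicates)
    }, TRUE)
    k0_star[si] <- k0_grid[which(within_one_se)[1]]
    table_rows[[si]] <- data.frame(n = n, k0 = k0_grid, accuracy = mean_acc,
                                   accuracy_se = se_acc)
  }
  fit <- if (length(sizes) >= 3 && all(k0_star > 0)) {
    tryCatch(fit_power_law(sizes, k0_star), error = function(e) NULL)
  } else {
    NULL
  }
  list(table = do.call(rbind, table_rows),
       k0_star = data.frame(n = sizes, k0_star = k0_star),
       fit = fit)
}

# noisy/non-noisy classification for nodes at distance exactly 2:
# the intermediates of every shortest path are the common neighbors
.noisy_2hop <- function(adj, hubs, source, node) {
  if (node %in% hubs) return(TRUE)
  mids <- intersect(adj[[source]], adj[[node]])
  all(mids %in% hubs)
}

#' Hub-noise experiment: PTVA-LI accuracy for curated observer sets
#'
#' Measures how observers "behind" hubs degrade localization on scale-free
#' networks. For each realization on a BA graph, a source whose
#' second-order neighborhood contains at least 15 eligible nodes of the
#' requested class is drawn (resampling up to `resample_budget` times),
#' a 15-observer set at exactly 2 hops is built, the SI spread is simulated
#' and PTVA-LI is run on the resulting report. Set types: `"noisy"` (all
#' observers behind hubs or hubs themselves), `"non_noisy"` (none),
#' `"mixed"` (each of the 15 slots drawn from either pool with equal
#' probability) and `"quickest"` (the 15 smallest arrival times among
#' 2-hop nodes, ties by id).
#'
#' @param sizes Vector of BA network sizes.
#' @param set_type One of `"noisy"`, `"non_noisy"`, `"mixed"`, `"quickest"`.
#' @param replicates Realizations per size.
#' @param seed Master seed.
#' @param m BA attachment parameter (default 3).
#' @param beta SI infection rate (default 0.5).
#' @param n_observers Observer-set size (default 15).
#' @param resample_budget Source redraws allowed per realization.
#' @param form Score form.
#' @return data.frame per size: mean accuracy, s.e., effective replicates
#'   and skipped count.
#' @export
hub_noise_experiment <- function(sizes, set_type = c("noisy", "non_noisy",
                                                     "mixed", "quickest"),
                                 replicates = 100, seed = 1, m = 3,
                                 beta = 0.5, n_observers = 15,
                                 resample_budget = 50, form = "gaussian") {
  set_type <- match.arg(set_type)
  params <- delay_moments(beta)
  seeds <- matrix(child_seeds(seed, 3 * replicates * length(sizes)),
                  ncol = 3)
  out <- vector("list", length(sizes))
  cell <- 0L
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    acc <- rep(NA_real_, replicates)
    skipped <- 0L
    for (rep_i in seq_len(replicates)) {
      cell <- cell + 1L
      g <- largest_connected_component(generate_ba(n, m, seeds[cell, 1]))
      nn <- igraph::vcount(g)
      adj <- lapply(igraph::as_adj_list(g), as.integer)
      hubs <- hub_set(g)
      old <- .Random.seed_save()
      set.seed(seeds[cell, 2])
      chosen <- NULL
      for (try_i in seq_len(resample_budget)) {
        src <- sample.int(nn, 1)
        two_hop <- which(igraph::distances(g, v = src)[1, ] == 2)
        if (length(two_hop) < n_observers) next
        if (set_type == "quickest") {
          chosen <- list(source = src, two_hop = two_hop)
          break
        }
        noisy <- vapply(two_hop, .noisy_2hop, TRUE,
                        adj = adj, hubs = hubs, source = src)
        pools <- list(noisy = two_hop[noisy], non_noisy = two_hop[!noisy])
        obs <- switch(set_type,
          noisy = if (length(pools$noisy) >= n_observers) {
            sample(pools$noisy, n_observers)
          },
          non_noisy = if (length(pools$non_noisy) >= n_observers) {
            sample(pools$non_noisy, n_observers)
          },
          mixed = if (length(two_hop) >= n_observers &&
                      length(pools$noisy) > 0 &&
                      length(pools$non_noisy) > 0) {
            .mixed_sample(pools, n_observers)
          })
        if (!is.null(obs)) {
          chosen <- list(source = src, observers = obs)
          break
        }
      }
      .Random.seed_restore(old)
      if (is.null(chosen)) {
        skipped <- skipped + 1L
        next
      }
      stop_at <- if (set_type == "quickest") chosen$two_hop
                 else chosen$observers
      real <- si_simulate(g, chosen$source, beta, seeds[cell, 3],
                          stop_nodes = stop_at)
      if (set_type == "quickest") {
        tt <- real$arrival[chosen$two_hop]
        ord <- order(tt, chosen$two_hop)
        chosen$observers <- chosen$two_hop[ord][seq_len(n_observers)]
      }
      report <- make_report(real, chosen$observers)
      est <- ptva_li(g, report, params, form = form)
      acc[rep_i] <- accuracy(est, chosen$source)
    }
    ok <- !is.na(acc)
    out[[si]] <- data.frame(
      n = n, set_type = set_type, replicates = sum(ok),
      skipped = skipped,
      accuracy = mean(acc[ok]),
      accuracy_se = stats::sd(acc[ok]) / sqrt(sum(ok))
    )
  }
  do.call(rbind, out)
}

# draw each slot from the noisy/non-noisy pool with equal probability,
# without replacement, falling back to the other pool when one empties
.mixed_sample <- function(pools, k) {
  picked <- integer(0)
  for (i in seq_len(k)) {
    use_noisy <- stats::runif(1) < 0.5
    pool <- if (use_noisy) "noisy" else "non_noisy"
    if (length(pools[[pool]]) == 0) {
      pool <- setdiff(c("noisy", "non_noisy"), pool)
    }
    if (length(pools[[pool]]) == 0) return(NULL)
    take <- if (length(pools[[pool]]) == 1) pools[[pool]]
            else sample(pools[[pool]], 1)
    picked <- c(picked, take)
    pools[[pool]] <- setdiff(pools[[pool]], take)
  }
  picked
}

#' Fraction of noisy observers among the K0 nearest
#'
#' Diagnostic for why gradient search with the quickest observers resists
#' hub noise: the share of noisy observers among the K0 earliest reports,
#' averaged over realizations on BA graphs with random observer placement.
#'
#' @param sizes Vector of BA network sizes.
#' @param replicates Realizations per size.
#' @param seed Master seed.
#' @param m,beta,rho As in [run_quality_benchmark()].
#' @return data.frame per size with the mean noisy fraction among the K0
#'   nearest observers and among all observers.
#' @export
noisy_fraction_nearest <- function(sizes, replicates = 100, seed = 1, m = 3,
                                   beta = 0.5, rho = 0.2) {
  seeds <- matrix(child_seeds(seed, 4 * replicates * length(sizes)),
                  ncol = 4)
  out <- vector("list", length(sizes))
  cell <- 0L
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    frac_nearest <- frac_all <- rep(NA_real_, replicates)
    for (rep_i in seq_len(replicates)) {
      cell <- cell + 1L
      inst <- .make_instance("ba", n, 6, m, beta, rho, seeds[cell, ])
      g <- inst$g
      hubs <- hub_set(g)
      k0 <- default_k0(igraph::vcount(g))
      nearest <- select_nearest(inst$report, k0)
      is_noisy <- function(o) {
        if (o == inst$source) return(FALSE)
        classify_noisy(g, inst$source, o)
      }
      frac_nearest[rep_i] <- mean(vapply(nearest$node, is_noisy, TRUE))
      frac_all[rep_i] <- mean(vapply(inst$report$node, is_noisy, TRUE))
    }
    out[[si]] <- data.frame(n = n,
                            noisy_frac_nearest = mean(frac_nearest),
                            noisy_frac_all = mean(frac_all))
  }
  do.call(rbind, out)
}
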