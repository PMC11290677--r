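#' Optimizer configuration
#'
#' @param runs Monte-Carlo repetitions per candidate combination (default 1000,
#'   the recommended minimum for stable protocol choice).
#' @param seed Master seed. Every candidate combination draws from its own
#'   substream derived deterministically from this seed and its sample counts,
#'   so adding or removing candidates never perturbs another candidate's draws.
#' @param max_combinations Cap on the exhaustive enumeration size; beyond it
#'   the exhaustive optimizer errors and the nested (greedy) mode is the
#'   documented alternative.
#' @param exact_threshold When the number of distinct sample subsets implied by
#'   a combination is at most this, the expectation is computed by exact
#'   enumeration instead of Monte-Carlo (standard error then 0).
#' @return Object of class \code{"optimizer_config"}.
#' @export
optimizer_config <- function(runs = 1000, seed = 1, max_combinations = 1e6,
                             exact_threshold = 1000) {
  if (!is.numeric(runs) || runs < 1) stop("'runs' must be >= 1")
  structure(list(runs = as.integer(runs), seed = as.integer(seed),
                 max_combinations = max_combinations,
                 exact_threshold = exact_threshold),
            class = "optimizer_config")
}

# deterministic per-combination substream seed: fold counts into master seed
combo_seed <- function(seed, n, salt = 0) {
  s <- (abs(as.numeric(seed)) + salt) %% 2147483647
  for (c in n) s <- (s * 131 + c + 17) %% 2147483647
  as.integer(max(1, floor(s)))
}

# precomputed scoring context shared by all candidate combinations
opt_context <- function(data, t) {
  stopifnot(inherits(data, "sample_matrix"))
  paths <- edge_paths(t)
  unknown <- setdiff(sm_species(data), names(paths))
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  sp_edges <- paths[sm_species(data)]
  sample_edges <- apply(data$abundance > 0, 1L, function(pres)
    unique(unlist(sp_edges[pres], use.names = FALSE)), simplify = FALSE)
  sites <- sm_sites(data)
  methods <- sm_methods(data)
  idx <- lapply(sites, function(s) {
    lapply(stats::setNames(methods, methods), function(m)
      which(data$site == s & data$method == m))
  })
  names(idx) <- sites
  avail <- vapply(idx, function(site) lengths(site), integer(length(methods)))
  if (length(methods) == 1L) avail <- matrix(avail, nrow = 1L)
  dimnames(avail) <- list(methods, sites)
  site_edges <- lapply(idx, function(site)
    unique(unlist(sample_edges[unlist(site)], use.names = FALSE)))
  len <- t$edge.length
  true_alpha <- vapply(site_edges, function(e) sum(len[e]), numeric(1))
  list(sites = sites, methods = methods, idx = idx, avail = avail,
       sample_edges = sample_edges, site_edges = site_edges,
       len = len, true_alpha = true_alpha)
}

#' True diversity of a site
#'
#' Alpha-diversity of the pooled community of all samples taken at a site —
#' the "true" value revealed by the intensive inventory, against which
#' subsampled protocols are standardized. An injection point for an externally
#' estimated true value is provided by the optimizers' \code{true} argument.
#'
#' @param data A \code{\link{sample_matrix}}.
#' @param site Site tag present in \code{data}.
#' @param t Tree of class \code{"phylo"}.
#' @return Non-negative branch-length diversity.
#' @export
true_alpha <- function(data, site, t) {
  stopifnot(inherits(data, "sample_matrix"))
  if (!site %in% data$site) stop("unknown site: ", site)
  alpha_div(pooled_species(data, which(data$site == site)), t)
}

# per-site list of all subsets (as vectors of sample rows) for counts n,
# or NULL when the enumeration exceeds `cap`
site_subsets <- function(site_idx, n, cap) {
  per_m <- lapply(names(n), function(m) {
    k <- n[[m]]
    if (k == 0L) return(list(integer(0)))
    pool <- site_idx[[m]]
    if (choose(length(pool), k) > cap) return(NULL)
    utils::combn(pool, k, simplify = FALSE)
  })
  if (any(vapply(per_m, is.null, logical(1)))) return(NULL)
  total <- prod(lengths(per_m))
  if (total > cap) return(NULL)
  grid <- expand.grid(lapply(per_m, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    unlist(lapply(seq_along(per_m), function(m) per_m[[m]][[grid[i, m]]]),
           use.names = FALSE))
}

check_feasible <- function(ctx, n) {
  for (s in ctx$sites) {
    short <- n > ctx$avail[names(n), s]
    if (any(short))
      stop("combination exceeds the available samples of method(s) ",
           paste(names(n)[short], collapse = ", "), " at site ", s)
  }
}

alpha_prop_of_draw <- function(ctx, rows_by_site) {
  props <- vapply(seq_along(ctx$sites), function(si) {
    e <- unique(unlist(ctx$sample_edges[rows_by_site[[si]]], use.names = FALSE))
    tr <- ctx$true_alpha[[si]]
    if (tr == 0) 1 else sum(ctx$len[e]) / tr
  }, numeric(1))
  mean(props)
}

# expected alpha proportion for counts n (named, all methods), given context
score_alpha <- function(ctx, n, cfg) {
  check_feasible(ctx, n)
  if (sum(n) == 0L) return(list(value = 0, se = 0, exact = TRUE))
  # exact per-site enumeration: alpha proportions are independent across sites
  subsets <- lapply(ctx$sites, function(s)
    site_subsets(ctx$idx[[s]], n, cfg$exact_threshold))
  if (!any(vapply(subsets, is.null, logical(1)))) {
    props <- vapply(seq_along(ctx$sites), function(si) {
      tr <- ctx$true_alpha[[si]]
      vals <- vapply(subsets[[si]], function(rows) {
        e <- unique(unlist(ctx$sample_edges[rows], use.names = FALSE))
        if (tr == 0) 1 else sum(ctx$len[e]) / tr
      }, numeric(1))
      mean(vals)
    }, numeric(1))
    return(list(value = mean(props), se = 0, exact = TRUE))
  }
  set.seed(combo_seed(cfg$seed, n))
  vals <- vapply(seq_len(cfg$runs), function(run) {
    rows <- lapply(ctx$sites, function(s) draw_rows(ctx$idx[[s]], n))
    alpha_prop_of_draw(ctx, rows)
  }, numeric(1))
  list(value = mean(vals), se = stats::sd(vals) / sqrt(cfg$runs), exact = FALSE)
}

draw_rows <- function(site_idx, n) {
  unlist(lapply(names(n), function(m) {
    pool <- site_idx[[m]]
    pool[sample.int(length(pool), n[[m]])]
  }), use.names = FALSE)
}

beta_bias_of_draw <- function(ctx, rows_by_site, true_mats) {
  edges <- lapply(rows_by_site, function(rows)
    unique(unlist(ctx$sample_edges[rows], use.names = FALSE)))
  mats <- beta_matrices_from_edges(edges, ctx$len)
  up <- upper.tri(true_mats$total)
  mean(c(abs(mats$total[up] - true_mats$total[up]),
         abs(mats$repl[up] - true_mats$repl[up]),
         abs(mats$rich[up] - true_mats$rich[up])))
}

score_beta <- function(ctx, n, cfg) {
  if (length(ctx$sites) < 2L) stop("beta-sampling needs at least 2 sites")
  check_feasible(ctx, n)
  true_mats <- beta_matrices_from_edges(ctx$site_edges, ctx$len)
  # exact joint enumeration across sites when small enough
  subsets <- lapply(ctx$sites, function(s)
    site_subsets(ctx$idx[[s]], n, cfg$exact_threshold))
  if (!any(vapply(subsets, is.null, logical(1))) &&
      prod(lengths(subsets)) <= cfg$exact_threshold) {
    grid <- expand.grid(lapply(subsets, seq_along), KEEP.OUT.ATTRS = FALSE)
    vals <- vapply(seq_len(nrow(grid)), function(i) {
      rows <- lapply(seq_along(subsets), function(si) subsets[[si]][[grid[i, si]]])
      beta_bias_of_draw(ctx, rows, true_mats)
    }, numeric(1))
    return(list(value = mean(vals), se = 0, exact = TRUE))
  }
  set.seed(combo_seed(cfg$seed, n, salt = 1))
  vals <- vapply(seq_len(cfg$runs), function(run) {
    rows <- lapply(ctx$sites, function(s) draw_rows(ctx$idx[[s]], n))
    beta_bias_of_draw(ctx, rows, true_mats)
  }, numeric(1))
  list(value = mean(vals), se = stats::sd(vals) / sqrt(cfg$runs), exact = FALSE)
}

#' Expected proportion of diversity captured by a combination
#'
#' For each site, samples are drawn uniformly without replacement (the given
#' number per method), pooled, and the sampled alpha-diversity is divided by
#' the site's true (pooled) diversity — the 0-1 standardization that gives
#' every site equal weight. Site proportions are averaged, then averaged over
#' Monte-Carlo runs; when the implied subset space is small (at most the
#' configured exact-expectation threshold) all subsets are enumerated exactly
#' instead.
#'
#' @param comb Named non-negative integer sample counts per method.
#' @param data A \code{\link{sample_matrix}}.
#' @param t Tree of class \code{"phylo"}.
#' @param cfg An \code{\link{optimizer_config}}.
#' @return Proportion in \[0, 1\] with attribute \code{"se"} (Monte-Carlo
#'   standard error; 0 under exact enumeration).
#' @export
expected_alpha_proportion <- function(comb, data, t, cfg = optimizer_config()) {
  ctx <- opt_context(data, t)
  n <- as_combination(comb, ctx$methods)
  sc <- score_alpha(ctx, n, cfg)
  structure(sc$value, se = sc$se, exact = sc$exact)
}

#' Expected beta-diversity bias of a combination
#'
#' True beta-diversity matrices (total, replacement, richness-difference) are
#' computed on the fully pooled sites; each run subsamples the combination at
#' every site, recomputes the three matrices, and the bias is the mean over
#' the three measures of the mean over site pairs of the absolute difference
#' from the true values. Efficiency of a monitoring protocol is 1 - bias.
#'
#' @inheritParams expected_alpha_proportion
#' @return Bias in \[0, 1\] with attribute \code{"se"}.
#' @export
beta_bias <- function(comb, data, t, cfg = optimizer_config()) {
  ctx <- opt_context(data, t)
  n <- as_combination(comb, ctx$methods)
  sc <- score_beta(ctx, n, cfg)
  structure(sc$value, se = sc$se, exact = sc$exact)
}

# shared optimizer machinery ------------------------------------------------

opt_result <- function(rows, methods, objective, mode, cfg) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  structure(df, objective = objective, mode = mode, methods = methods,
            seed = cfg$seed, class = c("opt_result", "data.frame"))
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("Protocol optimization (%s, %s): %d cost level(s)\n",
              attr(x, "objective"), attr(x, "mode"), nrow(x)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

result_row <- function(n, cost, sc) {
  df <- as.data.frame(as.list(n))
  names(df) <- paste0("n_", names(n))
  cbind(data.frame(cost = cost), df,
        data.frame(value = sc$value, se = sc$se))
}

optim_exhaustive <- function(ctx, cm, cfg, pool, budget, scorer, objective) {
  methods <- ctx$methods
  if (!all(methods %in% cm$methods))
    stop("cost model does not cover method(s): ",
         paste(setdiff(methods, cm$methods), collapse = ", "))
  maxn <- apply(ctx$avail, 1L, min)
  pool <- as_combination(pool, methods)
  if (any(pool > maxn)) stop("pool exceeds available samples")
  n_comb <- prod(maxn - pool + 1)
  if (n_comb > cfg$max_combinations)
    stop("enumeration of ", format(n_comb, big.mark = ","),
         " combinations exceeds the cap; use the nested (greedy) mode")
  grid <- expand.grid(lapply(methods, function(m) pool[[m]]:maxn[[m]]),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- methods
  costs <- vapply(seq_len(nrow(grid)), function(i)
    combination_cost(unlist(grid[i, , drop = FALSE]), cm), numeric(1))
  keep <- costs <= budget
  grid <- grid[keep, , drop = FALSE]; costs <- costs[keep]
  if (nrow(grid) == 0L) stop("no feasible combination within budget")
  scores <- lapply(seq_len(nrow(grid)), function(i)
    scorer(ctx, stats::setNames(as.integer(grid[i, ]), methods), cfg))
  values <- vapply(scores, `[[`, numeric(1), "value")
  obj <- if (objective == "alpha") values else 1 - values
  rows <- lapply(sort(unique(costs)), function(cv) {
    cand <- which(costs == cv)
    # best objective; ties -> lexicographically smallest counts
    ord <- do.call(order, c(list(-obj[cand]),
                            lapply(methods, function(m) grid[cand, m])))
    i <- cand[ord[1L]]
    sc <- scores[[i]]
    if (objective == "beta") sc$value <- 1 - sc$value  # report efficiency
    result_row(stats::setNames(as.integer(grid[i, ]), methods), costs[i], sc)
  })
  opt_result(rows, methods, objective, "exhaustive", cfg)
}

optim_nested <- function(ctx, cm, cfg, pool, budget, steps, scorer, objective) {
  methods <- ctx$methods
  if (!all(methods %in% cm$methods))
    stop("cost model does not cover method(s): ",
         paste(setdiff(methods, cm$methods), collapse = ", "))
  maxn <- apply(ctx$avail, 1L, min)
  n <- as_combination(pool, methods)
  if (any(n > maxn)) stop("pool exceeds available samples")
  if (is.null(steps)) steps <- sum(maxn) - sum(n)
  eff <- function(sc) if (objective == "beta") 1 - sc$value else sc$value
  cur_sc <- scorer(ctx, n, cfg)
  rows <- list()
  if (sum(n) > 0L) {
    sc <- cur_sc; sc$value <- eff(sc)
    rows[[1L]] <- result_row(n, combination_cost(n, cm), sc)
  }
  cur_val <- eff(cur_sc)
  cur_cost <- combination_cost(n, cm)
  taken <- 0L
  while (taken < steps) {
    cand <- methods[n < maxn]
    if (length(cand)) {
      costs <- vapply(cand, function(m) {
        n2 <- n; n2[m] <- n2[m] + 1L
        combination_cost(n2, cm)
      }, numeric(1))
      cand <- cand[costs <= budget]
      costs <- costs[costs <= budget]
    }
    if (length(cand) == 0L) {
      if (taken < steps && sum(n) < sum(maxn))
        warning("stopping early: no affordable samples remain")
      break
    }
    sc_cand <- lapply(cand, function(m) {
      n2 <- n; n2[m] <- n2[m] + 1L
      scorer(ctx, n2, cfg)
    })
    dval <- vapply(sc_cand, function(s) eff(s), numeric(1)) - cur_val
    dcost <- costs - cur_cost
    gain <- ifelse(dcost > 0, dval / dcost,
                   ifelse(dval > 0, Inf, ifelse(dval < 0, -Inf, 0)))
    best <- which.max(gain)  # ties: first method in sorted order
    m <- cand[best]
    n[m] <- n[m] + 1L
    cur_sc <- sc_cand[[best]]
    cur_val <- eff(cur_sc)
    cur_cost <- costs[best]
    sc <- cur_sc; sc$value <- cur_val
    rows[[length(rows) + 1L]] <- result_row(n, cur_cost, sc)
    taken <- taken + 1L
  }
  if (length(rows) == 0L) stop("no samples remain to add")
  opt_result(rows, methods, objective, "nested", cfg)
}

#' Optimize sample allocation for inventorying (alpha-sampling)
#'
#' Searches for the allocation of sample units across methods that maximizes
#' the expected proportion of true diversity captured, at every cost level.
#' \code{mode = "exhaustive"} enumerates all combinations containing the pool
#' (up to the configured cap), groups them by cost and keeps, per cost value,
#' the combination with the least bias (highest expected proportion).
#' \code{mode = "nested"} instead grows a nested sample sequence greedily,
#' adding at each step one sample of the method with the steepest accumulation
#' slope (highest expected gain per cost unit) — the flexible protocol family
#' of which any prefix is itself a recommended protocol.
#'
#' @param data A \code{\link{sample_matrix}} (the near-complete multi-method
#'   inventory of one or more sites).
#' @param t Tree of class \code{"phylo"} (unit star tree for TD, phylogeny
#'   for PD, functional tree for FD).
#' @param cm A \code{\link{cost_model}} covering the data's methods.
#' @param cfg An \code{\link{optimizer_config}}.
#' @param pool Optional named counts: a predefined pool of samples per method
#'   that every candidate combination must contain (constrained optimization,
#'   e.g. when extending an existing protocol).
#' @param mode \code{"exhaustive"} or \code{"nested"}.
#' @param steps Nested mode: number of greedy additions (default: until all
#'   samples are used).
#' @param budget Optional maximum cost.
#' @return An \code{"opt_result"} data frame: one row per cost level
#'   (exhaustive) or per greedy step (nested), with columns \code{cost},
#'   \code{n_<method>} counts, \code{value} (expected diversity proportion)
#'   and \code{se}.
#' @export
optim_alpha <- function(data, t, cm, cfg = optimizer_config(), pool = NULL,
                        mode = c("exhaustive", "nested"), steps = NULL,
                        budget = Inf) {
  mode <- match.arg(mode)
  ctx <- opt_context(data, t)
  if (mode == "exhaustive")
    optim_exhaustive(ctx, cm, cfg, pool, budget, score_alpha, "alpha")
  else
    optim_nested(ctx, cm, cfg, pool, budget, steps, score_alpha, "alpha")
}

#' Optimize sample allocation for monitoring (beta-sampling)
#'
#' Same search machinery as \code{\link{optim_alpha}}, but scoring candidate
#' combinations by monitoring efficiency \code{1 - bias}, where bias is the
#' expected absolute difference between subsampled and true beta-diversity
#' (total, replacement and richness-difference components averaged over all
#' site pairs; see \code{\link{beta_bias}}). The same combination is applied
#' at every site, as a monitoring protocol would be.
#'
#' @inheritParams optim_alpha
#' @return An \code{"opt_result"} data frame with \code{value} = efficiency
#'   (1 - bias).
#' @export
optim_beta <- function(data, t, cm, cfg = optimizer_config(), pool = NULL,
                       mode = c("exhaustive", "nested"), steps = NULL,
                       budget = Inf) {
  mode <- match.arg(mode)
  ctx <- opt_context(data, t)
  if (length(ctx$sites) < 2L) stop("beta-sampling needs at least 2 sites")
  if (mode == "exhaustive")
    optim_exhaustive(ctx, cm, cfg, pool, budget, score_beta, "beta")
  else
    optim_nested(ctx, cm, cfg, pool, budget, steps, score_beta, "beta")
}

#' Pick the best affordable row of an optimization result
#'
#' @param result An \code{"opt_result"}.
#' @param budget Maximum cost.
#' @return The row with the highest value among those with cost at most
#'   \code{budget} (ties: lowest cost).
#' @export
best_at_cost <- function(result, budget) {
  stopifnot(inherits(result, "opt_result"))
  ok <- which(result$cost <= budget)
  if (length(ok) == 0L) stop("no combination within budget")
  i <- ok[order(-result$value[ok], result$cost[ok])[1L]]
  result[i, , drop = FALSE]
}

#' Write a per-dimension protocol summary table
#'
#' One row per diversity dimension (e.g. TD, PD, FD), with the chosen number
#' of samples per method and the achieved expected proportion of diversity
#' (alpha) or efficiency 1 - bias (beta), formatted to 3 decimals.
#'
#' @param results Named list of single-row \code{"opt_result"} selections
#'   (see \code{\link{best_at_cost}}); may be empty.
#' @param path Output CSV path.
#' @param digits Decimals for the value column (default 3).
#' @return The assembled data frame, invisibly.
#' @export
report_table <- function(results, path, digits = 3) {
  if (length(results) == 0L) {
    df <- data.frame(dimension = character(0), value = character(0))
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("'results' must be a named list (dimension labels)")
  rows <- lapply(names(results), function(dim) {
    r <- as.data.frame(results[[dim]])
    if (nrow(r) != 1L) stop("each element must be a single selected row")
    r$value <- formatC(r$value, format = "f", digits = digits)
    cbind(data.frame(dimension = dim), r[c(setdiff(names(r), c("se")))])
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
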