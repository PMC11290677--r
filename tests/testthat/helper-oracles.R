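# Independent brute-force oracles, deliberately written with plain loops and
# direct subset enumeration rather than through the package's scoring paths.

# Gower distance computed directly from the definition
oracle_gower <- function(df, types, weights) {
  n <- nrow(df)
  rng <- lapply(seq_along(df), function(j)
    if (types[j] == "numeric") diff(range(df[[j]], na.rm = TRUE)) else NA)
  d <- matrix(0, n, n, dimnames = list(rownames(df), rownames(df)))
  for (i in seq_len(n - 1)) for (k in (i + 1):n) {
    num <- 0; den <- 0
    for (j in seq_along(df)) {
      xi <- df[[j]][i]; xk <- df[[j]][k]
      if (is.na(xi) || is.na(xk) || weights[j] == 0) next
      delta <- if (types[j] == "numeric") {
        if (rng[[j]] == 0) 0 else abs(xi - xk) / rng[[j]]
      } else as.numeric(xi != xk)
      num <- num + weights[j] * delta
      den <- den + weights[j]
    }
    d[i, k] <- d[k, i] <- num / den
  }
  d
}

# species pooled over a set of sample rows
pool_rows <- function(sm, rows) {
  if (length(rows) == 0) return(character(0))
  sub <- sm$abundance[rows, , drop = FALSE]
  colnames(sub)[colSums(sub) > 0]
}

# all subsets (lists of row indices) realizing counts n at one site
site_subset_list <- function(sm, site, n) {
  per_m <- lapply(names(n), function(m) {
    idx <- which(sm$site == site & sm$method == m)
    if (n[[m]] == 0) list(integer(0)) else utils::combn(idx, n[[m]], simplify = FALSE)
  })
  grid <- expand.grid(lapply(per_m, seq_along))
  lapply(seq_len(nrow(grid)), function(i)
    unlist(lapply(seq_along(per_m), function(m) per_m[[m]][[grid[i, m]]])))
}

# exact expected alpha proportion by full subset enumeration
oracle_expected_alpha <- function(sm, tree, n) {
  sites <- sort(unique(sm$site))
  site_means <- vapply(sites, function(s) {
    truev <- alpha_div(pool_rows(sm, which(sm$site == s)), tree)
    subs <- site_subset_list(sm, s, n)
    mean(vapply(subs, function(rows)
      alpha_div(pool_rows(sm, rows), tree) / truev, numeric(1)))
  }, numeric(1))
  mean(site_means)
}

# exact expected beta bias by joint subset enumeration across sites
oracle_beta_bias <- function(sm, tree, n) {
  sites <- sort(unique(sm$site))
  true_comms <- lapply(sites, function(s) pool_rows(sm, which(sm$site == s)))
  true_mats <- beta_matrices(stats::setNames(true_comms, sites), tree)
  subs <- lapply(sites, function(s) site_subset_list(sm, s, n))
  grid <- expand.grid(lapply(subs, seq_along))
  biases <- vapply(seq_len(nrow(grid)), function(i) {
    comms <- lapply(seq_along(sites), function(si)
      pool_rows(sm, subs[[si]][[grid[i, si]]]))
    mats <- beta_matrices(stats::setNames(comms, sites), tree)
    up <- upper.tri(true_mats$total)
    mean(c(abs(mats$total[up] - true_mats$total[up]),
           abs(mats$repl[up] - true_mats$repl[up]),
           abs(mats$rich[up] - true_mats$rich[up])))
  }, numeric(1))
  mean(biases)
}
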