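#' Simulation configuration for multi-method surveys
#'
#' Describes a virtual survey campaign: a species pool on a Yule phylogeny,
#' lognormal species abundances, several sites sharing the pool up to a
#' compositional turnover parameter, and several sampling methods with
#' method-specific, species-specific detection probabilities — the structure
#' (method complementarity, undersampling) that makes protocol optimization
#' non-trivial in real surveys where, e.g., mist-nets and acoustic recorders
#' each detect different bat families.
#'
#' Defaults describe a medium-sized campaign: 40 species, 4 sites, 3 methods,
#' 8 samples per site and method, lognormal(meanlog 2, sdlog 1) abundances and
#' turnover 0.25. When \code{detection} is \code{NULL} each species is
#' assigned one primary method (detection 0.8) and is hard to detect otherwise
#' (0.1), giving every method its own biased slice of the community.
#'
#' @param n_species Species pool size (>= 2).
#' @param n_sites Number of sites.
#' @param methods Character vector of method names.
#' @param samples_per_method Samples taken per (site, method).
#' @param detection Optional methods x species matrix of detection
#'   probabilities in \[0, 1\] (rows named by method); must not be all zero.
#' @param abundance_meanlog,abundance_sdlog Lognormal abundance parameters
#'   (log scale).
#' @param turnover In \[0, 1\]: probability that a species is exclusive to one
#'   random site rather than shared by all; 0 gives one common composition,
#'   1 disjoint site pools.
#' @param tree Optional tree of class \code{"phylo"} with
#'   \code{n_species} tips to use instead of simulating a Yule tree.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_species = 40, n_sites = 4, methods = c("A", "B", "C"),
                       samples_per_method = 8, detection = NULL,
                       abundance_meanlog = 2, abundance_sdlog = 1,
                       turnover = 0.25, tree = NULL, seed = 1) {
  if (n_species < 2) stop("'n_species' must be >= 2")
  if (n_sites < 1) stop("'n_sites' must be >= 1")
  if (length(methods) < 1 || anyDuplicated(methods)) stop("invalid 'methods'")
  if (samples_per_method < 1) stop("'samples_per_method' must be >= 1")
  if (turnover < 0 || turnover > 1) stop("'turnover' must be in [0, 1]")
  if (!is.null(detection)) {
    detection <- as.matrix(detection)
    if (nrow(detection) != length(methods) || ncol(detection) != n_species)
      stop("'detection' must be a methods x species matrix")
    if (any(detection < 0 | detection > 1)) stop("detection probabilities must be in [0, 1]")
    if (all(detection == 0)) stop("all detection probabilities are zero; nothing can be sampled")
    rownames(detection) <- methods
  }
  if (!is.null(tree)) {
    check_tree(tree)
    if (length(tree$tip.label) != n_species)
      stop("'tree' must have exactly 'n_species' tips")
  }
  structure(list(n_species = as.integer(n_species), n_sites = as.integer(n_sites),
                 methods = as.character(methods),
                 samples_per_method = as.integer(samples_per_method),
                 detection = detection, abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog, turnover = turnover,
                 tree = tree, seed = as.integer(seed)),
            class = "sim_config")
}

# zero-truncated Poisson draws via the inverse-CDF trick
rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Simulate a multi-method survey
#'
#' Generates a mutually label-consistent quadruple: a sample matrix, the
#' phylogeny, a trait table (two phylogenetically structured numeric traits,
#' one binary, one categorical, all weighted 1) and a taxonomy table (genera
#' and families grouping neighbouring tips). In each sample, a species from
#' the site's pool is detected with its (method, species) probability and, if
#' detected, recorded with a zero-truncated Poisson count of its abundance —
#' so empirical detection frequencies converge to the configured
#' probabilities.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with elements \code{samples} (a \code{\link{sample_matrix}}),
#'   \code{tree} (\code{"phylo"}), \code{traits} (\code{\link{trait_table}})
#'   and \code{taxonomy} (data frame: species, genus, family).
#' @export
simulate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  S <- cfg$n_species
  species <- sprintf("sp%03d", seq_len(S))
  tree <- cfg$tree
  if (is.null(tree)) {
    tree <- ape::rphylo(S, birth = 1, death = 0)
    tree$tip.label <- species
  } else {
    species <- tree$tip.label
  }
  detection <- cfg$detection
  if (is.null(detection)) {
    primary <- sample.int(length(cfg$methods), S, replace = TRUE)
    detection <- matrix(0.1, length(cfg$methods), S,
                        dimnames = list(cfg$methods, species))
    detection[cbind(primary, seq_len(S))] <- 0.8
  } else colnames(detection) <- species
  if (all(detection == 0)) stop("all detection probabilities are zero")
  abundance <- stats::rlnorm(S, cfg$abundance_meanlog, cfg$abundance_sdlog)

  # site pools: shared species vs species exclusive to one site
  exclusive <- stats::runif(S) < cfg$turnover
  owner <- sample.int(cfg$n_sites, S, replace = TRUE)
  pools <- lapply(seq_len(cfg$n_sites), function(s) which(!exclusive | owner == s))

  sites <- sprintf("site%02d", seq_len(cfg$n_sites))
  rows <- list(); site_tag <- character(0); method_tag <- character(0)
  for (s in seq_len(cfg$n_sites)) {
    pool <- pools[[s]]
    for (m in cfg$methods) {
      for (j in seq_len(cfg$samples_per_method)) {
        counts <- integer(S)
        if (length(pool)) {
          hit <- pool[stats::runif(length(pool)) < detection[m, pool]]
          if (length(hit)) counts[hit] <- rztpois(length(hit), abundance[hit])
        }
        rows[[length(rows) + 1L]] <- counts
        site_tag <- c(site_tag, sites[s])
        method_tag <- c(method_tag, m)
      }
    }
  }
  ab <- do.call(rbind, rows)
  colnames(ab) <- species
  rownames(ab) <- sprintf("%s_%s_%02d", site_tag, method_tag,
                          stats::ave(seq_along(site_tag),
                                     paste(site_tag, method_tag),
                                     FUN = seq_along))
  samples <- sample_matrix(ab, site = site_tag, method = method_tag)

  traits <- data.frame(
    size = ape::rTraitCont(tree, sigma = 0.5),
    shape = ape::rTraitCont(tree, sigma = 0.5),
    nocturnal = stats::rbinom(S, 1, 0.5),
    guild = sample(c("predator", "herbivore", "omnivore"), S, replace = TRUE),
    row.names = species
  )
  traits <- trait_table(traits,
                        types = c("numeric", "numeric", "binary", "categorical"))

  ord <- tree$tip.label  # group neighbouring tips into genera / families
  genus <- paste0("gen", sprintf("%02d", ceiling(match(species, ord) / 3)))
  family <- paste0("fam", sprintf("%02d", ceiling(match(species, ord) / 9)))
  taxonomy <- data.frame(species = species, genus = genus, family = family)

  list(samples = samples, tree = tree, traits = traits, taxonomy = taxonomy)
}

#' A survey scenario with an analytically known optimal allocation
#'
#' Two methods with equal unit costs and no fixed costs survey one site.
#' Method A detects (with probability 1) exactly the species of a clade
#' carrying 3/4 of the total tree length, method B exactly the complementary
#' clade (1/4 of the length). A single sample of a method therefore saturates
#' its clade, so the alpha-optimal allocation of any budget b >= 2 is one
#' sample of each method plus arbitrary extras — under the lowest-count
#' tie-break, (A = 1, B = b - 1) — and any optimal allocation must include
#' method A, whose clade carries most of the diversity.
#'
#' @param budget Total number of samples to allocate (>= 2).
#' @param seed Seed stored in the emitted configuration.
#' @return List: \code{config} (a \code{\link{sim_config}}), \code{cost_model},
#'   \code{best} (the expected optimal combination at cost \code{budget}),
#'   \code{budget}.
#' @export
planted_optimum_scenario <- function(budget, seed = 1) {
  if (budget < 2) stop("'budget' must be >= 2")
  budget <- as.integer(budget)
  species <- sprintf("sp%03d", 1:8)
  lens <- c(rep(0.75, 4), rep(0.25, 4))  # clade X: 3 units, clade Y: 1 unit
  tree <- star_tree(species)
  tree$edge.length <- lens
  detection <- rbind(A = c(rep(1, 4), rep(0, 4)),
                     B = c(rep(0, 4), rep(1, 4)))
  colnames(detection) <- species
  cfg <- sim_config(n_species = 8, n_sites = 1, methods = c("A", "B"),
                    samples_per_method = budget, detection = detection,
                    abundance_meanlog = 3, abundance_sdlog = 0.2,
                    turnover = 0, tree = tree, seed = seed)
  list(config = cfg,
       cost_model = cost_model(fixed = c(A = 0, B = 0),
                               variable = c(A = 1, B = 1)),
       best = c(A = 1L, B = budget - 1L),
       budget = budget)
}
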