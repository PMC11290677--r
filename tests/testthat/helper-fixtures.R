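# Shared fixtures: small trees and surveys built in code.

toy_tree <- function() ape::read.tree(text = "((a:1,b:1):1,c:2);")

# random rooted binary tree with strictly positive branch lengths
random_tree <- function(n, min_len = 0.1) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + min_len
  tr
}

bat_cost_model <- function() {
  cost_model(fixed = c(mistnet = 520, acoustic = 883.20),
             variable = c(mistnet = 384, acoustic = 1062))
}

# tiny two-site, two-method survey, small enough for subset enumeration
toy_survey <- function(seed = 42) {
  cfg <- sim_config(n_species = 12, n_sites = 2, methods = c("A", "B"),
                    samples_per_method = 3, turnover = 0.3, seed = seed)
  simulate_survey(cfg)
}
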