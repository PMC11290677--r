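#' @title Branch-length diversity on trees
#' @description Alpha-diversity of a community is the sum of branch lengths of
#'   the minimal subtree connecting the root and all present tips (the root
#'   path is included, so on a unit star tree alpha equals species richness and
#'   a single-species community has positive phylogenetic diversity).
#'   Beta-diversity between two communities partitions the total branch-length
#'   turnover into a replacement and a richness-difference component with
#'   beta_total = beta_repl + beta_rich.
#' @name diversity
NULL

# list, per tip label, of the edge indices on the root-to-tip path
edge_paths <- function(t) {
  check_tree(t)
  ntip <- length(t$tip.label)
  # edge index whose child is node v
  child_edge <- integer(ntip + t$Nnode)
  child_edge[t$edge[, 2L]] <- seq_len(nrow(t$edge))
  root <- ntip + 1L
  parent <- integer(ntip + t$Nnode)
  parent[t$edge[, 2L]] <- t$edge[, 1L]
  paths <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    v <- i
    p <- integer(0)
    while (v != root && parent[v] != 0L) {
      p <- c(p, child_edge[v])
      v <- parent[v]
    }
    paths[[i]] <- p
  }
  names(paths) <- t$tip.label
  paths
}

community_edges <- function(comm, paths) {
  comm <- unique(as.character(comm))
  if (length(comm) == 0L) return(integer(0))
  unknown <- setdiff(comm, names(paths))
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  unique(unlist(paths[comm], use.names = FALSE))
}

#' Alpha-diversity of a community on a tree
#'
#' @param comm Character vector of species present (incidence); may be empty.
#' @param t Tree of class \code{"phylo"} whose tips include all of \code{comm}.
#' @return Sum of branch lengths of the rooted spanning subtree of the present
#'   tips; 0 for an empty community.
#' @examples
#' tr <- star_tree(letters[1:5])
#' alpha_div(c("a", "c"), tr)  # 2: unit star tree, alpha = richness
#' @export
alpha_div <- function(comm, t) {
  paths <- edge_paths(t)
  e <- community_edges(comm, paths)
  sum(t$edge.length[e])
}

# beta partition from two edge-index sets; len = tree edge lengths
beta_from_edges <- function(e1, e2, len) {
  shared <- intersect(e1, e2)
  a <- sum(len[shared])
  b <- sum(len[setdiff(e1, shared)])
  cc <- sum(len[setdiff(e2, shared)])
  denom <- a + b + cc
  if (denom == 0)
    return(c(beta_total = 0, beta_repl = 0, beta_rich = 0))
  c(beta_total = (b + cc) / denom,
    beta_repl = 2 * min(b, cc) / denom,
    beta_rich = abs(b - cc) / denom)
}

#' Pairwise beta-diversity partition
#'
#' With A the branch length shared by the two communities' rooted spanning
#' subtrees, B the length unique to the first and C unique to the second:
#' \deqn{\beta_{total} = (B+C)/(A+B+C), \quad
#'       \beta_{repl} = 2\min(B,C)/(A+B+C), \quad
#'       \beta_{rich} = |B-C|/(A+B+C).}
#' On a unit star tree \eqn{\beta_{total}} reduces to the Jaccard dissimilarity
#' of the two species sets.
#'
#' @param c1,c2 Character vectors of species present in each community.
#' @param t Tree of class \code{"phylo"}.
#' @return Named numeric vector \code{(beta_total, beta_repl, beta_rich)},
#'   each in \[0, 1\], with \code{beta_total = beta_repl + beta_rich}. Two empty
#'   communities give (0, 0, 0).
#' @export
beta_pair <- function(c1, c2, t) {
  paths <- edge_paths(t)
  beta_from_edges(community_edges(c1, paths), community_edges(c2, paths),
                  t$edge.length)
}

#' Pairwise beta matrices across communities
#'
#' Applies \code{\link{beta_pair}} to every pair of communities.
#'
#' @param communities Named list of character vectors (species present).
#' @param t Tree of class \code{"phylo"}.
#' @return List of three symmetric zero-diagonal matrices: \code{total},
#'   \code{repl}, \code{rich}, with \code{total = repl + rich} elementwise.
#' @export
beta_matrices <- function(communities, t) {
  if (!is.list(communities) || length(communities) < 2L)
    stop("need a list of at least 2 communities")
  paths <- edge_paths(t)
  edges <- lapply(communities, community_edges, paths = paths)
  beta_matrices_from_edges(edges, t$edge.length, names(communities))
}

beta_matrices_from_edges <- function(edges, len, labels = NULL) {
  n <- length(edges)
  total <- repl <- rich <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      b <- beta_from_edges(edges[[i]], edges[[j]], len)
      total[i, j] <- total[j, i] <- b[["beta_total"]]
      repl[i, j] <- repl[j, i] <- b[["beta_repl"]]
      rich[i, j] <- rich[j, i] <- b[["beta_rich"]]
    }
  }
  list(total = total, repl = repl, rich = rich)
}
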