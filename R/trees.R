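#' Star tree
#'
#' Builds a tree in which every species is attached directly to the root by a
#' branch of the same length. With unit branches, branch-length diversity on
#' this tree equals species richness, which is how taxonomic diversity is
#' brought into the common tree-based currency shared with phylogenetic and
#' functional diversity.
#'
#' @param species Character vector of unique, non-empty species labels.
#' @param branch_length Positive branch length shared by all tips (default 1,
#'   i.e. "unit length").
#' @return A rooted tree of class \code{"phylo"}.
#' @examples
#' tr <- star_tree(c("a", "b", "c"))
#' total_length(tr)  # 3
#' @export
star_tree <- function(species, branch_length = 1) {
  species <- as.character(species)
  if (length(species) == 0L) stop("'species' must be non-empty")
  if (anyDuplicated(species)) stop("duplicate species labels")
  if (any(!nzchar(species)) || anyNA(species)) stop("species labels must be non-empty")
  if (!is.numeric(branch_length) || length(branch_length) != 1L ||
      !is.finite(branch_length) || branch_length <= 0)
    stop("'branch_length' must be a single positive number")
  n <- length(species)
  tr <- list(
    edge = cbind(rep.int(n + 1L, n), seq_len(n)),
    edge.length = rep.int(as.numeric(branch_length), n),
    tip.label = species,
    Nnode = 1L
  )
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Linnaean surrogate tree
#'
#' Builds an ultrametric tree from a taxonomic hierarchy, used as a surrogate
#' phylogeny when no molecular tree is available. Every distinct taxon at
#' every rank becomes an internal node, every root-to-tip path has length
#' \code{depth}, and each rank step is \code{depth / r} where \code{r} is the
#' number of rank columns above species.
#'
#' When the coarsest rank contains a single taxon that taxon is the root.
#' With several coarsest-rank taxa they are joined to the root by zero-length
#' branches so that all tip depths stay equal to \code{depth}; supplying a
#' constant top rank (e.g. an order or class column) avoids this degenerate
#' case and is the recommended usage.
#'
#' @param tax Data frame: rows are species, columns are Linnaean ranks ordered
#'   from finest (species, first column) to coarsest. No missing cells.
#' @param depth Positive root-to-tip depth of the output tree (default 1).
#' @return An ultrametric rooted tree of class \code{"phylo"}.
#' @examples
#' tax <- data.frame(species = c("s1", "s2", "s3", "s4"),
#'                   genus   = c("g1", "g1", "g2", "g2"),
#'                   family  = "f1")
#' tr <- linnaean_tree(tax)
#' is_ultrametric(tr)
#' @export
linnaean_tree <- function(tax, depth = 1) {
  tax <- as.data.frame(tax)
  if (ncol(tax) < 2L) stop("'tax' needs a species column plus at least one rank")
  tax[] <- lapply(tax, as.character)
  if (anyNA(tax) || any(!nzchar(as.matrix(tax)))) stop("'tax' has missing cells")
  if (anyDuplicated(tax[[1L]])) stop("duplicate species in taxonomy")
  if (!is.numeric(depth) || length(depth) != 1L || !is.finite(depth) || depth <= 0)
    stop("'depth' must be a single positive number")
  r <- ncol(tax) - 1L
  # nesting consistency: a taxon at rank j maps to exactly one taxon at rank j+1
  for (j in seq_len(ncol(tax) - 1L)) {
    parents <- tapply(tax[[j + 1L]], tax[[j]], function(v) length(unique(v)))
    if (any(parents > 1L))
      stop("inconsistent taxonomy: taxa in '", names(tax)[j],
           "' map to more than one '", names(tax)[j + 1L], "'")
  }
  step <- depth / r

  build <- function(col, members) {
    # newick subtree for each distinct taxon of column `col` among `members`
    vals <- unique(tax[[col]][members])
    vapply(vals, function(v) {
      sub <- members[tax[[col]][members] == v]
      if (col == 1L) {
        paste0(quote_label(v), ":", format(step, digits = 15))
      } else {
        paste0("(", paste(build(col - 1L, sub), collapse = ","), ")",
               quote_label(v), ":",
               format(if (col == ncol(tax)) 0 else step, digits = 15))
      }
    }, character(1))
  }

  members <- seq_len(nrow(tax))
  top <- unique(tax[[ncol(tax)]])
  if (length(top) == 1L) {
    inner <- build(ncol(tax) - 1L, members)
    nwk <- paste0("(", paste(inner, collapse = ","), ")", quote_label(top), ";")
  } else {
    nwk <- paste0("(", paste(build(ncol(tax), members), collapse = ","), ")root;")
  }
  tr <- ape::read.tree(text = nwk)
  tr
}

quote_label <- function(x) {
  ifelse(grepl("[ ,():;\\[\\]]", x), paste0("'", x, "'"), x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \code{\link[ape]{nj}}) with two
#' conventions needed downstream: negative branch-length estimates are clamped
#' to zero (with a warning), and the unrooted NJ result is rooted at its
#' midpoint so that output is deterministic and label-order independent.
#'
#' @param d Square symmetric matrix of non-negative distances with labelled
#'   rows/columns, or a \code{"dist"} object. At least 2 taxa.
#' @return A rooted tree of class \code{"phylo"}.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' total_length(neighbor_joining(d))  # 5
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) stop("'d' must be a numeric matrix or dist")
  if (nrow(d) != ncol(d)) stop("'d' must be square")
  if (is.null(rownames(d))) stop("'d' must have species labels")
  if (anyDuplicated(rownames(d))) stop("duplicate labels in 'd'")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8, check.attributes = FALSE)))
    stop("'d' must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("'d' must have a zero diagonal")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    tr <- star_tree(rownames(d), branch_length = 1)
    tr$edge.length <- rep.int(d[1L, 2L] / 2, 2L)
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch-length estimates clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  phangorn::midpoint(tr)
}

#' Total branch length of a tree
#'
#' @param t A tree of class \code{"phylo"}.
#' @return Sum of all branch lengths.
#' @export
total_length <- function(t) {
  check_tree(t)
  sum(t$edge.length)
}

#' Is a tree ultrametric?
#'
#' TRUE when all root-to-tip path lengths are equal within \code{tol}
#' (absolute tolerance on the range of tip depths).
#'
#' @param t A tree of class \code{"phylo"}.
#' @param tol Non-negative absolute tolerance.
#' @return Logical.
#' @export
is_ultrametric <- function(t, tol = 1e-8) {
  check_tree(t)
  if (length(t$tip.label) == 1L) return(TRUE)
  depths <- ape::node.depth.edgelength(t)[seq_along(t$tip.label)]
  diff(range(depths)) <= tol
}

#' Read / write Newick trees
#'
#' Thin wrappers around \pkg{ape}'s Newick parser/serializer; branch lengths
#' are always written, and both bifurcating and multifurcating rooted trees
#' are accepted on input.
#'
#' @param path File path.
#' @param t A tree of class \code{"phylo"}.
#' @return \code{read_newick}: a \code{"phylo"}; \code{write_newick}: the path,
#'   invisibly.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  check_tree(tr)
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(t, path) {
  check_tree(t)
  ape::write.tree(t, file = path, digits = 12)
  invisible(path)
}

# shared validation for tree arguments
check_tree <- function(t) {
  if (!inherits(t, "phylo")) stop("expected a tree of class 'phylo'")
  if (is.null(t$edge.length)) stop("tree has no branch lengths")
  if (any(t$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(t$tip.label)) stop("tree tip labels are not unique")
  if (any(!nzchar(t$tip.label))) stop("tree has empty tip labels")
  invisible(t)
}
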