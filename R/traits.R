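#' Trait table
#'
#' Bundles a species-by-trait data frame with per-trait types and weights,
#' the input for \code{\link{gower_distance}} and \code{\link{functional_tree}}.
#' Numeric traits enter Gower's formula range-scaled; binary and categorical
#' traits contribute 0 when equal and 1 otherwise. Weights rescale the
#' contribution of each trait (e.g. the common "1/n types" rule that downweights
#' a block of related binary columns is expressed by setting each column's
#' weight to 1/n).
#'
#' @param data Data frame with species as row names and one column per trait.
#'   Missing values are allowed and handled by pairwise trait deletion.
#' @param types Optional character vector (recycled/named by column) with values
#'   \code{"numeric"}, \code{"binary"} or \code{"categorical"}; by default
#'   numeric columns are numeric and everything else categorical.
#' @param weights Non-negative per-trait weights, at least one positive
#'   (default all 1).
#' @return The data frame with class \code{"trait_table"} and attributes
#'   \code{types} and \code{weights}.
#' @export
trait_table <- function(data, types = NULL, weights = NULL) {
  data <- as.data.frame(data)
  if (nrow(data) < 1L || ncol(data) < 1L) stop("'data' must have rows and columns")
  if (is.null(rownames(data)) || anyDuplicated(rownames(data)))
    stop("'data' must have unique species row names")
  if (is.null(types)) {
    types <- ifelse(vapply(data, is.numeric, logical(1)), "numeric", "categorical")
  } else {
    if (!is.null(names(types))) types <- types[names(data)]
    types <- rep_len(as.character(types), ncol(data))
  }
  if (!all(types %in% c("numeric", "binary", "categorical")))
    stop("trait types must be 'numeric', 'binary' or 'categorical'")
  for (j in seq_along(data)) {
    if (types[j] == "numeric") {
      if (!is.numeric(data[[j]])) stop("trait '", names(data)[j], "' is not numeric")
      if (any(!is.finite(data[[j]]) & !is.na(data[[j]])))
        stop("trait '", names(data)[j], "' has non-finite values")
    } else {
      data[[j]] <- factor(data[[j]])
    }
  }
  if (is.null(weights)) weights <- rep.int(1, ncol(data))
  if (!is.null(names(weights))) weights <- weights[names(data)]
  weights <- as.numeric(weights)
  if (length(weights) != ncol(data)) stop("one weight per trait required")
  if (anyNA(weights) || any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0)) stop("at least one trait weight must be positive")
  names(weights) <- names(types) <- names(data)
  structure(data, types = types, weights = weights,
            class = c("trait_table", "data.frame"))
}

#' Read a trait table from CSV plus a YAML column configuration
#'
#' The CSV holds one row per species (first column = species label); the YAML
#' sidecar declares, per trait column, its \code{type} and \code{weight}:
#' \preformatted{
#' traits:
#'   body_size: {type: numeric, weight: 1}
#'   web: {type: categorical, weight: 0.5}
#' }
#' Columns absent from the YAML default to inferred type and weight 1.
#'
#' @param path CSV file path.
#' @param config Optional YAML file path.
#' @return A \code{\link{trait_table}}.
#' @export
read_trait_table <- function(path, config = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- df[[1L]]
  df[[1L]] <- NULL
  types <- NULL
  weights <- NULL
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    decl <- cfg$traits
    if (is.null(decl)) stop("config YAML must have a top-level 'traits' map")
    types <- ifelse(vapply(df, is.numeric, logical(1)), "numeric", "categorical")
    names(types) <- names(df)
    weights <- stats::setNames(rep.int(1, ncol(df)), names(df))
    for (nm in names(decl)) {
      if (!nm %in% names(df)) stop("config declares unknown trait '", nm, "'")
      if (!is.null(decl[[nm]]$type)) types[nm] <- decl[[nm]]$type
      if (!is.null(decl[[nm]]$weight)) weights[nm] <- decl[[nm]]$weight
    }
  }
  trait_table(df, types = types, weights = weights)
}

#' Residuals against a size covariate
#'
#' Ordinary least-squares residuals of \code{y} on \code{x} (with intercept),
#' used to remove the size signal from morphological traits before computing
#' functional distances (e.g. regressing each body measurement on prosoma
#' width so that shape, not size, drives the distances).
#'
#' @param y,x Equal-length numeric vectors (n >= 3); \code{x} must vary.
#' @return Numeric vector of residuals (they sum to zero).
#' @export
residualize <- function(y, x) {
  if (!is.numeric(y) || !is.numeric(x)) stop("'y' and 'x' must be numeric")
  if (length(y) != length(x)) stop("'y' and 'x' must have equal length")
  if (length(y) < 3L) stop("need at least 3 observations")
  if (anyNA(y) || anyNA(x) || any(!is.finite(c(y, x)))) stop("inputs must be finite")
  if (stats::sd(x) == 0) stop("'x' is constant; cannot residualize")
  unname(stats::resid(stats::lm(y ~ x)))
}

#' Gower distance over weighted mixed traits
#'
#' Pairwise functional dissimilarity: for species i and k,
#' \eqn{d(i,k) = \sum_j w_j \delta_j(i,k) / \sum_j w_j}, summing over the
#' traits comparable for that pair. Numeric traits use
#' \eqn{\delta = |x_i - x_k|} / (observed range over the full table); binary
#' and categorical traits use 0/1 mismatch. A pair missing a value for trait j
#' drops that trait and renormalizes the weights. Distances lie in \[0, 1\].
#'
#' @param traits A \code{\link{trait_table}} with at least 2 species.
#' @return Square symmetric labelled distance matrix.
#' @export
gower_distance <- function(traits) {
  if (!inherits(traits, "trait_table")) traits <- trait_table(traits)
  if (nrow(traits) < 2L) stop("need at least 2 species")
  w <- attr(traits, "weights")
  df <- as.data.frame(traits)
  d <- cluster::daisy(df, metric = "gower", weights = w, warnBin = FALSE,
                      warnAsym = FALSE, warnConst = FALSE)
  m <- as.matrix(d)
  if (anyNA(m))
    stop("some species pair shares no comparable trait; distance undefined")
  diag(m) <- 0
  m
}

#' Functional tree from traits
#'
#' Neighbor-joining tree on the weighted Gower distance matrix, the tree-based
#' representation of functional diversity that makes FD commensurable with
#' taxonomic and phylogenetic branch-length diversity.
#'
#' @param traits A \code{\link{trait_table}} with at least 2 species.
#' @return A rooted tree of class \code{"phylo"} whose tips are the species.
#' @export
functional_tree <- function(traits) {
  neighbor_joining(gower_distance(traits))
}
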