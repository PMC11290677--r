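#' Survey cost model
#'
#' Per-method cost accounting: a fixed cost charged once if a method is used
#' at all (equipment purchase, travel) and a variable cost per sample unit
#' (person-hours, survey nights). For example, an Amazonian bat mist-net
#' survey has a fixed cost of $520 (18 nets at $20 plus 20 poles at $8) and a
#' variable cost of $384 per site (2 nights of 4 researchers at $48), so a
#' single site costs $904 and each extra site $384.
#'
#' @param fixed,variable Named non-negative numeric vectors over the same
#'   method names.
#' @return Object of class \code{"cost_model"}.
#' @examples
#' cm <- cost_model(fixed = c(mistnet = 520, acoustic = 883.2),
#'                  variable = c(mistnet = 384, acoustic = 1062))
#' combination_cost(c(mistnet = 1), cm)  # 904
#' @export
cost_model <- function(fixed, variable) {
  if (is.null(names(fixed)) || is.null(names(variable)))
    stop("'fixed' and 'variable' must be named by method")
  if (!setequal(names(fixed), names(variable)))
    stop("'fixed' and 'variable' must cover the same methods")
  variable <- variable[names(fixed)]
  if (anyNA(fixed) || anyNA(variable) || any(fixed < 0) || any(variable < 0))
    stop("costs must be non-negative")
  structure(list(fixed = fixed, variable = variable,
                 methods = names(fixed)), class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat("Cost model over", length(x$methods), "methods:\n")
  print(data.frame(fixed = x$fixed, variable = x$variable, row.names = x$methods))
  invisible(x)
}

#' Read a cost model from YAML
#'
#' Expected layout:
#' \preformatted{
#' methods:
#'   mistnet: {fixed: 520, variable: 384, unit: "site (2 nights x 4 people)"}
#'   acoustic: {fixed: 883.2, variable: 1062, unit: "site"}
#' }
#'
#' @param path YAML file path.
#' @return A \code{\link{cost_model}}.
#' @export
read_cost_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$methods)) stop("cost YAML must have a top-level 'methods' map")
  fixed <- vapply(cfg$methods, function(m) as.numeric(m$fixed %||% 0), numeric(1))
  variable <- vapply(cfg$methods, function(m) as.numeric(m$variable %||% 0), numeric(1))
  cost_model(fixed = fixed, variable = variable)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce/validate a combination (named non-negative integer counts) against
# a set of known methods; missing methods count as 0
as_combination <- function(comb, methods) {
  if (length(comb) == 0L)
    return(stats::setNames(integer(length(methods)), methods))
  if (is.null(names(comb))) stop("a combination must be named by method")
  unknown <- setdiff(names(comb), methods)
  if (length(unknown)) stop("unknown method(s): ", paste(unknown, collapse = ", "))
  if (anyNA(comb) || any(comb < 0) || any(comb != round(comb)))
    stop("sample counts must be non-negative integers")
  out <- stats::setNames(integer(length(methods)), methods)
  out[names(comb)] <- as.integer(comb)
  out
}

#' Cost of a combination of samples
#'
#' \eqn{\sum_m [fixed_m \cdot 1(n_m > 0) + variable_m \cdot n_m]}: a method's
#' fixed cost is charged once as soon as at least one of its samples is taken.
#'
#' @param comb Named non-negative integer vector of sample counts per method
#'   (methods omitted count as 0).
#' @param cm A \code{\link{cost_model}}.
#' @return Total cost.
#' @export
combination_cost <- function(comb, cm) {
  stopifnot(inherits(cm, "cost_model"))
  n <- as_combination(comb, cm$methods)
  sum(cm$fixed[n > 0]) + sum(cm$variable * n)
}

#' Cost of a combination as a fraction of a full scheme
#'
#' @param comb,full Combinations (named counts per method); \code{comb} must
#'   be componentwise within \code{full}.
#' @param cm A \code{\link{cost_model}}.
#' @return \code{combination_cost(comb, cm) / combination_cost(full, cm)},
#'   in \[0, 1\].
#' @examples
#' cm <- cost_model(fixed = c(mistnet = 520, acoustic = 883.2),
#'                  variable = c(mistnet = 384, acoustic = 1062))
#' full <- c(mistnet = 12, acoustic = 12)
#' cost_fraction(c(mistnet = 12, acoustic = 1), full, cm)  # 0.377
#' @export
cost_fraction <- function(comb, full, cm) {
  stopifnot(inherits(cm, "cost_model"))
  n <- as_combination(comb, cm$methods)
  nf <- as_combination(full, cm$methods)
  if (any(n > nf)) stop("'comb' exceeds the full scheme for some method")
  denom <- combination_cost(nf, cm)
  if (denom <= 0) stop("full scheme has zero cost")
  combination_cost(n, cm) / denom
}
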