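#' Multi-method survey sample matrix
#'
#' Samples-by-species abundance counts, with each sample tagged by the
#' sampling method that produced it and the site (or sampling event) it
#' belongs to. This is the raw input to protocol optimization: a
#' (near-)complete inventory of several sites obtained with several methods.
#'
#' @param abundance Integer matrix, samples in rows (unique row names),
#'   species in columns (unique column names), non-negative counts.
#' @param site,method Character vectors, one tag of each per sample.
#' @return Object of class \code{"sample_matrix"}: a list with elements
#'   \code{abundance}, \code{site}, \code{method}.
#' @export
sample_matrix <- function(abundance, site, method) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || anyDuplicated(rownames(abundance)))
    stop("'abundance' must have unique sample row names")
  if (is.null(colnames(abundance)) || anyDuplicated(colnames(abundance)))
    stop("'abundance' must have unique species column names")
  if (!is.numeric(abundance) || anyNA(abundance) || any(abundance < 0) ||
      any(abundance != round(abundance)))
    stop("abundances must be non-negative integers")
  site <- as.character(site); method <- as.character(method)
  if (length(site) != nrow(abundance) || length(method) != nrow(abundance))
    stop("'site' and 'method' must have one entry per sample")
  if (anyNA(site) || anyNA(method) || any(!nzchar(site)) || any(!nzchar(method)))
    stop("every sample needs a non-empty site and method tag")
  structure(list(abundance = abundance, site = site, method = method),
            class = "sample_matrix")
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat("Sample matrix:", nrow(x$abundance), "samples x",
      ncol(x$abundance), "species;",
      length(unique(x$site)), "site(s),",
      length(unique(x$method)), "method(s)\n")
  invisible(x)
}

#' Sites, methods and species of a sample matrix
#' @param x A \code{\link{sample_matrix}}.
#' @return Character vector.
#' @export
sm_sites <- function(x) sort(unique(x$site))

#' @rdname sm_sites
#' @export
sm_methods <- function(x) sort(unique(x$method))

#' @rdname sm_sites
#' @export
sm_species <- function(x) colnames(x$abundance)

# species present (incidence) in a set of sample rows
pooled_species <- function(x, rows) {
  if (length(rows) == 0L) return(character(0))
  sub <- x$abundance[rows, , drop = FALSE]
  colnames(sub)[colSums(sub) > 0]
}

#' Read / write survey data as CSV
#'
#' Two dialects are supported. Long format has columns
#' \code{sample_id, site, method, species, abundance} (one row per non-zero
#' count; zero-abundance rows are allowed and ignored). Wide format has
#' columns \code{sample_id, site, method} followed by one column per species.
#'
#' @param path CSV file path.
#' @param format \code{"long"} or \code{"wide"}.
#' @return \code{read_sample_matrix}: a \code{\link{sample_matrix}};
#'   \code{write_sample_matrix}: the path, invisibly.
#' @export
read_sample_matrix <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "long") {
    need <- c("sample_id", "site", "method", "species", "abundance")
    if (!all(need %in% names(df)))
      stop("long format needs columns: ", paste(need, collapse = ", "))
    if (anyNA(df[need]) || any(!nzchar(df$site)) || any(!nzchar(df$method)))
      stop("missing site/method/species tags")
    if (anyDuplicated(df[c("sample_id", "species")]))
      stop("duplicate (sample, species) rows")
    if (any(df$abundance < 0)) stop("negative abundance")
    tags <- unique(df[c("sample_id", "site", "method")])
    if (anyDuplicated(tags$sample_id))
      stop("a sample maps to more than one (site, method) tag")
    samples <- tags$sample_id
    species <- sort(unique(df$species))
    ab <- matrix(0L, length(samples), length(species),
                 dimnames = list(samples, species))
    ab[cbind(match(df$sample_id, samples), match(df$species, species))] <-
      as.integer(df$abundance)
    sample_matrix(ab, site = tags$site, method = tags$method)
  } else {
    need <- c("sample_id", "site", "method")
    if (!all(need %in% names(df)))
      stop("wide format needs leading columns: ", paste(need, collapse = ", "))
    sp <- setdiff(names(df), need)
    if (length(sp) == 0L) stop("wide format has no species columns")
    ab <- as.matrix(df[sp])
    rownames(ab) <- df$sample_id
    sample_matrix(ab, site = df$site, method = df$method)
  }
}

#' @rdname read_sample_matrix
#' @param x A \code{\link{sample_matrix}}.
#' @export
write_sample_matrix <- function(x, path, format = c("long", "wide")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "sample_matrix"))
  if (format == "long") {
    idx <- which(x$abundance > 0, arr.ind = TRUE)
    df <- data.frame(
      sample_id = rownames(x$abundance)[idx[, 1L]],
      site = x$site[idx[, 1L]],
      method = x$method[idx[, 1L]],
      species = colnames(x$abundance)[idx[, 2L]],
      abundance = x$abundance[idx]
    )
    df <- df[order(df$sample_id, df$species), ]
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    df <- data.frame(sample_id = rownames(x$abundance), site = x$site,
                     method = x$method, check.names = FALSE)
    df <- cbind(df, as.data.frame(x$abundance, check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
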