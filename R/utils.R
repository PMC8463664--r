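#' @useDynLib dendrocare, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimize runif rnorm rexp rbinom rlogis complete.cases
#'   pt sd quantile median p.adjust var acf setNames plogis
#' @importFrom utils read.csv write.csv
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

#' Normalize species names
#'
#' Trims surrounding whitespace and replaces internal spaces with
#' underscores. Matching between tree tip labels and trait tables is
#' case-sensitive after normalization.
#'
#' @param x Character vector of species names.
#' @return Character vector of normalized names.
#' @export
normalize_taxon_names <- function(x) {
  x <- trimws(as.character(x))
  gsub("[ ]+", "_", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dc <- function(...) stop(..., call. = FALSE)
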