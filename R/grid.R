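#' Histogram grid for test-statistic ensembles
#'
#' All null-density estimation in this package happens on a shared grid of
#' equispaced bins for the two-sample statistics.  The default grid spans
#' \[-6, 6\] with 120 bins (width 0.1), wide enough that essentially all
#' null mass is interior while keeping the Poisson regression
#' well-conditioned.
#'
#' @param from,to grid range.
#' @param bins number of equispaced bins.
#' @return numeric vector of `bins + 1` bin edges.
#' @export
#' @examples
#' e <- default_edges()
#' length(e)    # 121
default_edges <- function(from = -6, to = 6, bins = 120) {
  seq(from, to, length.out = bins + 1)
}

bin_mids <- function(edges) (edges[-length(edges)] + edges[-1]) / 2

bin_width <- function(edges) {
  w <- diff(edges)
  if (any(abs(w - w[1]) > 1e-8 * abs(w[1]))) {
    abort("histogram edges must be equispaced")
  }
  w[1]
}

check_edges <- function(edges) {
  if (length(edges) < 4) abort("need at least 3 bins")
  if (any(diff(edges) <= 0)) abort("edges must be strictly increasing")
  bin_width(edges)
  invisible(edges)
}

#' Bin a vector of statistics onto a shared grid
#'
#' Counts by half-open bins `[edge_k, edge_{k+1})`; values falling outside
#' the grid are clamped into the terminal bins so the total count is always
#' conserved (the Poisson fit relies on the `m * delta` scaling of a full
#' histogram).
#'
#' @param stats numeric vector of statistics.
#' @param edges equispaced bin edges (see [default_edges()]).
#' @return integer vector of counts, one per bin.
#' @export
#' @examples
#' histogram_counts(c(0.05, 0.15), edges = c(0, 0.1, 0.2))
histogram_counts <- function(stats, edges = default_edges()) {
  check_edges(edges)
  B <- length(edges) - 1L
  if (length(stats) == 0) return(integer(B))
  if (anyNA(stats)) abort("statistics contain NA")
  idx <- findInterval(stats, edges)
  idx[idx < 1L] <- 1L
  idx[idx > B] <- B
  tabulate(idx, nbins = B)
}

#' Expected null histogram counts under the standard Gaussian
#'
#' The expected count per bin for `m` statistics drawn from N(0, 1), with
#' the tail mass beyond the grid folded into the terminal bins (matching
#' the clamping of [histogram_counts()]).
#'
#' @param m number of statistics.
#' @param edges equispaced bin edges.
#' @return numeric vector of expected counts; sums to `m`.
#' @export
expected_null_counts <- function(m, edges = default_edges()) {
  check_edges(edges)
  p <- diff(pnorm(edges))
  p[1] <- p[1] + pnorm(edges[1])
  p[length(p)] <- p[length(p)] + pnorm(edges[length(edges)], lower.tail = FALSE)
  m * p
}

# Two-sided tail-mass function for a density given by values at bin
# midpoints (step density, hence piecewise-linear CDF at the edges).
# Returns a vectorised function c -> integral of f over {|z| > c}.
tail_mass_fun <- function(f, edges) {
  delta <- bin_width(edges)
  total <- sum(f) * delta
  if (total <= 0) abort("density has no mass on the grid")
  cdf_edges <- c(0, cumsum(f * delta)) / total
  Fc <- approxfun(edges, cdf_edges, yleft = 0, yright = 1)
  function(c) {
    c <- abs(c)
    pmin(1, pmax(0, 1 - Fc(c) + Fc(-c)))
  }
}
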