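#' Random Latin hypercube design
#'
#' Stratified random sampling of the unit cube: each of the `n` equal-width
#' bins of every dimension receives exactly one point, with the point jittered
#' uniformly inside its bin.
#'
#' @param n Number of design points (>= 1).
#' @param d Number of dimensions (>= 1).
#' @param seed Optional integer seed; given the same seed the design is
#'   reproduced exactly. The global RNG state is left untouched.
#'
#' @return A tibble of class `berry_design` with columns `x1 ... xd`, all
#'   entries in `[0, 1]`, satisfying exact Latin stratification.
#' @export
#' @examples
#' random_lhs(10, 3, seed = 1)
random_lhs <- function(n, d, seed = NULL) {
  stopifnot(n >= 1, d >= 1)
  m <- with_seed_if(seed, lhs::randomLHS(as.integer(n), as.integer(d)))
  new_design(m, seed = seed)
}

new_design <- function(m, seed = NULL) {
  colnames(m) <- paste0("x", seq_len(ncol(m)))
  out <- as_tibble(as.data.frame(m))
  class(out) <- c("berry_design", class(out))
  attr(out, "seed") <- seed
  out
}

design_matrix <- function(design) {
  m <- unit_columns(design, max(1L, sum(grepl("^x[0-9]+$", names(as.data.frame(design))))))
  m
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Check exact Latin stratification of a design
#'
#' A design is Latin-stratified when, per column, assigning each value to bin
#' `floor(value * n)` (bin `n - 1` for a value of exactly 1) uses every bin
#' `0 ... n-1` exactly once.
#'
#' @param design A design (tibble or matrix) with values in `[0, 1]`.
#' @return `TRUE`/`FALSE`.
#' @export
is_latin <- function(design) {
  m <- as.matrix(as.data.frame(design))
  n <- nrow(m)
  all(apply(m, 2, function(col) {
    bins <- pmin(floor(col * n), n - 1)
    identical(sort(as.integer(bins)), 0:(n - 1))
  }))
}

#' Latin hypercube sampling inside a neighborhood
#'
#' Generates `count` points by Latin hypercube sampling within the box
#' `[center - radius, center + radius]^d`, intersected with the unit cube
#' (the box is clipped at the boundary, so all points stay feasible and within
#' Chebyshev distance `radius` of `center`). This is the local-search move of
#' the design-optimization MOEA.
#'
#' @param center Numeric vector in `[0, 1]^d`.
#' @param radius Positive half-width of the search box.
#' @param count Number of points (>= 1).
#' @param seed Optional integer seed.
#' @return A `count x d` matrix of points.
#' @export
lhs_neighborhood <- function(center, radius, count, seed = NULL) {
  stopifnot(radius > 0, count >= 1, all(center >= 0 & center <= 1))
  d <- length(center)
  lo <- pmax(center - radius, 0)
  hi <- pmin(center + radius, 1)
  u <- with_seed_if(seed, lhs::randomLHS(as.integer(count), d))
  pts <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(pts) <- paste0("x", seq_len(d))
  pts
}

#' Space-filling diagnostics for a design
#'
#' Quantifies how uniformly a design covers the unit cube: the minimum
#' pairwise Euclidean distance (larger is better spread), the centered L2
#' discrepancy (smaller is more uniform), and the per-dimension Latin bin
#' occupancy counts (all ones for a valid Latin hypercube).
#'
#' @param design A design with values in `[0, 1]` (tibble or matrix), n >= 2.
#' @return A list of class `uniformity_report` with elements
#'   `min_pairwise_distance`, `centered_l2_discrepancy`, and `bin_occupancy`
#'   (an `n x d` matrix of counts).
#' @export
#' @examples
#' uniformity_report(random_lhs(10, 2, seed = 1))
uniformity_report <- function(design) {
  m <- as.matrix(as.data.frame(design))
  n <- nrow(m)
  if (n < 2) abort("minimum pairwise distance is undefined for fewer than 2 points.")
  occ <- apply(m, 2, function(col) {
    bins <- pmin(floor(col * n), n - 1)
    tabulate(bins + 1L, nbins = n)
  })
  out <- list(
    min_pairwise_distance = min_pairwise_distance(m),
    centered_l2_discrepancy = centered_l2_discrepancy(m),
    bin_occupancy = occ
  )
  class(out) <- "uniformity_report"
  out
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat("Design uniformity report\n")
  cat(sprintf("  min pairwise distance  : %.5f\n", x$min_pairwise_distance))
  cat(sprintf("  centered L2 discrepancy: %.5f\n", x$centered_l2_discrepancy))
  cat(sprintf("  Latin bins occupied once: %s\n",
              if (all(x$bin_occupancy == 1)) "yes" else "no"))
  invisible(x)
}

min_pairwise_distance <- function(m) {
  min(stats::dist(m))
}

# Hickernell's centered L2 discrepancy (closed form). Small values indicate a
# design close to the uniform distribution on the unit cube.
centered_l2_discrepancy <- function(m) {
  n <- nrow(m)
  d <- ncol(m)
  z <- abs(m - 0.5)
  term1 <- (13 / 12)^d
  prod_i <- apply(1 + 0.5 * z - 0.5 * z^2, 1, prod)
  term2 <- (2 / n) * sum(prod_i)
  # pairwise product over dimensions of (1 + |xi-.5|/2 + |xj-.5|/2 - |xi-xj|/2)
  term3 <- 0
  cross <- matrix(1, n, n)
  for (k in seq_len(d)) {
    zk <- z[, k]
    xk <- m[, k]
    cross <- cross * (1 + 0.5 * outer(zk, zk, "+") - 0.5 * abs(outer(xk, xk, "-")))
  }
  term3 <- sum(cross) / n^2
  sqrt(term1 - term2 + term3)
}
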