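# Halton low-discrepancy sequence (radical inverse in the first d primes).
# Deterministic background set for main-effect averaging.
halton_sequence <- function(n, d) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  if (d > length(primes)) abort("Halton background supports up to 10 dimensions.")
  radical_inverse <- function(i, base) {
    f <- 1 / base
    r <- 0
    while (i > 0) {
      r <- r + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    r
  }
  vapply(seq_len(d), function(j) {
    vapply(seq_len(n), radical_inverse, double(1), base = primes[j])
  }, double(n))
}

#' Main-effect curves of a quality predictor
#'
#' For each factor, sweeps `n_levels` equispaced levels across `[0, 1]` and
#' averages the model prediction over a fixed background of settings of the
#' remaining factors. The curve shows the mean change in each response caused
#' by moving one factor on its own -- monotone curves indicate simple trends,
#' interior extrema indicate an optimum within the range.
#'
#' @param model A trained surrogate (anything with a `predict` method over
#'   normalized inputs).
#' @param inputs Input column names swept (default `x1 ... x3`).
#' @param n_levels Number of equispaced levels per factor (>= 2).
#' @param n_background Background points averaged over at each level.
#' @param background `"halton"` (default, deterministic low-discrepancy set)
#'   or `"lhs"` (seeded Latin hypercube).
#' @param seed Seed for the `"lhs"` background (ignored for `"halton"`).
#' @return A tibble of class `main_effects`: `response`, `factor`, `level`,
#'   `mean` (mean predicted response).
#' @export
#' @examples
#' main_effects(eq15_surfaces(), n_levels = 5, n_background = 64)
main_effects <- function(model, inputs = c("x1", "x2", "x3"),
                         n_levels = 11, n_background = 256,
                         background = c("halton", "lhs"), seed = NULL) {
  background <- match.arg(background)
  stopifnot(n_levels >= 2, n_background >= 1)
  d <- length(inputs)
  bg <- switch(background,
    halton = halton_sequence(n_background, d),
    lhs = with_seed_if(seed, lhs::randomLHS(n_background, d))
  )
  levels <- seq(0, 1, length.out = n_levels)
  out <- list()
  for (i in seq_len(d)) {
    for (l in levels) {
      pts <- bg
      pts[, i] <- l
      colnames(pts) <- inputs
      pred <- as.data.frame(predict(model, as.data.frame(pts)))
      out[[length(out) + 1]] <- tibble(
        response = names(pred),
        factor = inputs[i],
        level = l,
        mean = unname(vapply(pred, mean, double(1)))
      )
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("main_effects", class(res))
  res
}

#' Signed Pareto term contributions of a quadratic response surface
#'
#' Attributes to each non-intercept polynomial term a percentage share of
#' influence, computed as the absolute coefficient share on normalized
#' inputs: `percent_t = |b_t| / sum(|b|) * 100`, with the sign of the
#' coefficient indicating the direction of the association (positive terms
#' raise the response, negative terms lower it). Because all inputs live on
#' the same `[0, 1]` scale, absolute coefficients are comparable across
#' terms. This coefficient-share decomposition is an approximation to
#' variance-based contribution measures; dominant-term identity and signs
#' are robust, exact percentages depend on the chosen formula.
#'
#' @param rsm A fitted `quadratic_rsm`.
#' @return A tibble of class `contribution_table`: `response`, `term`,
#'   `percent` (sums to 100 per response), `sign` (+1/-1).
#' @export
#' @examples
#' term_contributions(eq15_surfaces())
term_contributions <- function(rsm) {
  co <- rsm$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  out <- list()
  for (j in seq_len(ncol(co))) {
    b <- co[, j]
    tot <- sum(abs(b))
    if (tot == 0) {
      abort(sprintf(
        "all non-intercept coefficients are zero for response '%s': contributions undefined.",
        colnames(co)[j]))
    }
    out[[j]] <- tibble(
      response = colnames(co)[j],
      term = rownames(co),
      percent = unname(abs(b) / tot * 100),
      sign = unname(ifelse(b >= 0, 1, -1))
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("contribution_table", class(res))
  res
}
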