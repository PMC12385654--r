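#' Define a factor space
#'
#' A factor space is the ordered set of experimental factors (each with a
#' physical range) over which storage experiments are designed. All design and
#' optimization code in the package works on the normalized unit cube
#' `[0, 1]^d`; a factor space carries the affine map between raw factor units
#' and that cube.
#'
#' @param name Character vector of unique factor names.
#' @param lower,upper Numeric vectors of range endpoints, `lower < upper`
#'   elementwise.
#' @param unit Character vector of physical units (informational).
#'
#' @return A tibble of class `factor_space` with columns `name`, `unit`,
#'   `lower`, `upper`; one row per factor, in order.
#' @seealso [wolfberry_factors()] for the storage-experiment space used
#'   throughout the package.
#' @export
#' @examples
#' factor_space(c("temperature", "time"), c(-4, 0), c(24, 28), c("C", "d"))
factor_space <- function(name, lower, upper, unit = "") {
  name <- as.character(name)
  lower <- as.double(lower)
  upper <- as.double(upper)
  unit <- rep_len(as.character(unit), length(name))
  if (length(lower) != length(name) || length(upper) != length(name)) {
    abort("`name`, `lower` and `upper` must have the same length.")
  }
  if (anyDuplicated(name)) {
    abort("factor names must be unique.")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    abort("each factor needs finite bounds with `lower < upper`.")
  }
  out <- tibble(name = name, unit = unit, lower = lower, upper = upper)
  class(out) <- c("factor_space", class(out))
  out
}

#' The wolfberry storage factor space
#'
#' Storage temperature (-4 to 24 degrees C), storage time (0 to 28 days) and
#' initial maturity at harvest (20 to 90 percent): the three factors governing
#' post-harvest quality of fresh wolfberry, with the ranges used for the
#' 40-run storage experiment.
#'
#' @return A [factor_space()] with factors `temperature`, `time`, `maturity`.
#' @export
#' @examples
#' wolfberry_factors()
wolfberry_factors <- function() {
  factor_space(
    name  = c("temperature", "time", "maturity"),
    lower = c(-4, 0, 20),
    upper = c(24, 28, 90),
    unit  = c("degC", "days", "%")
  )
}

space_dim <- function(space) nrow(space)

#' Normalize raw factor values onto the unit cube
#'
#' Maps each factor linearly from its physical range `[lower, upper]` to
#' `[0, 1]`: `x = (raw - lower) / (upper - lower)`. Inputs outside a factor's
#' range are an error (silent clamping would hide data problems).
#'
#' @param data A data frame (or matrix) whose first `d` columns -- or columns
#'   named after the factors -- hold raw factor values; a bare numeric vector
#'   of length `d` is also accepted.
#' @param space A [factor_space()].
#'
#' @return A tibble with columns `x1 ... xd` of normalized coordinates.
#' @export
#' @examples
#' normalize_points(data.frame(temperature = 10, time = 14, maturity = 55),
#'                  wolfberry_factors())
normalize_points <- function(data, space) {
  raw <- factor_columns(data, space)
  d <- space_dim(space)
  for (i in seq_len(d)) {
    bad <- which(raw[, i] < space$lower[i] | raw[, i] > space$upper[i])
    if (length(bad) > 0) {
      abort(sprintf(
        "factor '%s' out of range [%g, %g] in row(s) %s",
        space$name[i], space$lower[i], space$upper[i],
        paste(head(bad, 5), collapse = ", ")
      ))
    }
  }
  unit <- sweep(sweep(raw, 2, space$lower, "-"), 2, space$upper - space$lower, "/")
  colnames(unit) <- paste0("x", seq_len(d))
  as_tibble(as.data.frame(unit))
}

#' Map unit-cube coordinates back to raw factor units
#'
#' Exact inverse of [normalize_points()]: `raw = lower + x * (upper - lower)`.
#'
#' @param data Data frame, matrix or numeric vector of coordinates in
#'   `[0, 1]^d` (columns `x1 ... xd` or positional).
#' @param space A [factor_space()].
#'
#' @return A tibble with one column per factor, named after the factors, in
#'   raw units.
#' @export
denormalize_points <- function(data, space) {
  unit <- unit_columns(data, space_dim(space))
  if (any(unit < 0 | unit > 1)) {
    abort("normalized coordinates must lie in [0, 1].")
  }
  raw <- sweep(sweep(unit, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  colnames(raw) <- space$name
  as_tibble(as.data.frame(raw))
}

#' Sample size rule for the quality-surrogate design
#'
#' The number of design points used to train the storage-quality surrogates
#' grows quadratically with the number of factors: `n = 2 (N + 1)(N + 2)`.
#' Three factors give the 40-run design used for the wolfberry experiment.
#'
#' @param n_factors Integer number of experimental factors, at least 1.
#' @return Integer sample size.
#' @export
#' @examples
#' required_sample_size(3) # 40
required_sample_size <- function(n_factors) {
  if (length(n_factors) != 1 || !is.finite(n_factors) ||
      n_factors < 1 || n_factors != round(n_factors)) {
    abort("`n_factors` must be a single integer >= 1.")
  }
  as.integer(2 * (n_factors + 1) * (n_factors + 2))
}

# Accept vectors, matrices, data frames; return an n x d numeric matrix with
# columns in factor order. Named data-frame columns win over position.
factor_columns <- function(data, space) {
  d <- space_dim(space)
  if (is.numeric(data) && is.null(dim(data))) {
    if (length(data) != d) abort(sprintf("expected %d factor values.", d))
    return(matrix(as.double(data), nrow = 1))
  }
  data <- as.data.frame(data)
  if (all(space$name %in% names(data))) {
    data <- data[space$name]
  } else if (ncol(data) >= d) {
    data <- data[seq_len(d)]
  } else {
    abort(sprintf("expected %d factor columns.", d))
  }
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("factor values must be numeric and non-missing.")
  m
}

unit_columns <- function(data, d) {
  if (is.numeric(data) && is.null(dim(data))) {
    if (length(data) != d) abort(sprintf("expected %d coordinates.", d))
    return(matrix(as.double(data), nrow = 1))
  }
  data <- as.data.frame(data)
  xn <- paste0("x", seq_len(d))
  if (all(xn %in% names(data))) {
    data <- data[xn]
  } else if (ncol(data) >= d) {
    data <- data[seq_len(d)]
  } else {
    abort(sprintf("expected %d coordinate columns.", d))
  }
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("coordinates must be numeric and non-missing.")
  m
}
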