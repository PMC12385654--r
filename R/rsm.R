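rsm_terms <- function(inputs) {
  d <- length(inputs)
  sq <- paste0(inputs, "^2")
  inter <- if (d >= 2) {
    cmb <- utils::combn(inputs, 2)
    paste0(cmb[1, ], ":", cmb[2, ])
  } else character(0)
  c("(Intercept)", inputs, sq, inter)
}

rsm_basis <- function(X) {
  d <- ncol(X)
  inter <- if (d >= 2) {
    cmb <- utils::combn(seq_len(d), 2)
    m <- matrix(NA_real_, nrow(X), ncol(cmb))
    for (k in seq_len(ncol(cmb))) m[, k] <- X[, cmb[1, k]] * X[, cmb[2, k]]
    m
  } else NULL
  B <- cbind(1, X, X^2, inter)
  B
}

#' Fit a full quadratic response surface
#'
#' Ordinary least squares, per response, over the complete second-order basis
#' `1, x_i, x_i^2, x_i x_j` (10 terms for three factors). This is the
#' polynomial model used for factor-sensitivity decomposition and as a
#' deterministic evaluator in optimization tests.
#'
#' @inheritParams rbf_train
#' @return Object of class `quadratic_rsm`: `coefficients` (terms x responses
#'   matrix), `r_squared` (named per-response), `n`.
#' @export
#' @examples
#' fit <- fit_quadratic_rsm(load_table2())
#' tidy(fit)
fit_quadratic_rsm <- function(data, inputs = c("x1", "x2", "x3"),
                              responses = quality_responses) {
  xy <- surrogate_xy(data, inputs, responses)
  X <- xy$X; Y <- xy$Y
  B <- rsm_basis(X)
  p <- ncol(B)
  if (nrow(X) < p) abort(sprintf("need at least %d rows for the %d-term basis.", p, p))
  fit <- lm(Y ~ B - 1)
  if (any(is.na(coef(fit)))) {
    abort("rank-deficient quadratic basis: design does not identify all terms.")
  }
  co <- coef(fit)
  if (is.null(dim(co))) co <- matrix(co, ncol = 1)
  rownames(co) <- rsm_terms(inputs)
  colnames(co) <- responses
  r2 <- vapply(seq_along(responses), function(j) {
    # constant responses fit perfectly via the intercept but have no SST
    tryCatch(r_squared(Y[, j], B %*% co[, j]), error = function(e) NA_real_)
  }, double(1))
  names(r2) <- responses
  new_quadratic_rsm(co, inputs, responses, r_squared = r2, n = nrow(X))
}

new_quadratic_rsm <- function(coefficients, inputs, responses,
                              r_squared = NULL, n = NA_integer_,
                              provenance = "fitted") {
  structure(
    list(coefficients = coefficients, r_squared = r_squared, n = n,
         provenance = provenance),
    class = "quadratic_rsm",
    inputs = inputs, responses = responses
  )
}

#' Construct a quadratic response surface from explicit coefficients
#'
#' @param coefficients A terms-by-responses numeric matrix in the canonical
#'   basis order `1, x1 ... xd, x1^2 ... xd^2, x1:x2, ...` (rows) with one
#'   column per response.
#' @param inputs Input names (default `x1`, `x2`, `x3`).
#' @param provenance Free-text note carried along (e.g. `"as printed"`).
#' @return A `quadratic_rsm`.
#' @export
quadratic_rsm <- function(coefficients, inputs = c("x1", "x2", "x3"),
                          provenance = "supplied") {
  co <- as.matrix(coefficients)
  terms <- rsm_terms(inputs)
  if (nrow(co) != length(terms)) {
    abort(sprintf("expected %d coefficients per response.", length(terms)))
  }
  if (any(!is.finite(co))) abort("coefficients must be finite.")
  rownames(co) <- terms
  new_quadratic_rsm(co, inputs, colnames(co), provenance = provenance)
}

#' The published wolfberry storage-quality response surfaces
#'
#' The four quadratic polynomials relating normalized storage temperature
#' (`x1`), storage time (`x2`) and initial maturity (`x3`) to hardness, SSC,
#' TA and vitamin C, with coefficients exactly as published. The three pure
#' quadratic terms are attached to `x1^2`, `x2^2`, `x3^2` in that order.
#' Note that the hardness surface is on the gram force scale (the 40-run
#' dataset's hardness column is in newtons); no unit conversion is applied
#' anywhere.
#'
#' @return A `quadratic_rsm` with responses `hardness`, `ssc`, `ta`, `vc`.
#' @export
#' @examples
#' rsm_evaluate(eq15_surfaces(), c(0, 0, 0))
eq15_surfaces <- function() {
  co <- cbind(
    hardness = c(2335.8, -2578, 816.4, -53.13, 1253.2, -864.08, 184.21,
                 344.77, 297.58, -533.94),
    ssc = c(11.157, 8.859, 9.233, -11.724, -5.8784, -6.5147, 12.646,
            0.57922, 5.3007, -6.2718),
    ta = c(1.8548, -1.7579, 0.3851, 2.1481, 2.4077, -1.9714, -1.5817,
           -0.10174, -3.2872, 2.1514),
    vc = c(12.415, 10.573, 9.0241, -4.5248, -3.0938, 6.1445, 4.0587,
           -16.788, -2.3267, -3.5507)
  )
  quadratic_rsm(co, provenance = "as printed (hardness on gram scale)")
}

#' Evaluate a quadratic response surface
#'
#' Polynomial evaluation over the full second-order basis. Points slightly
#' outside the unit cube are evaluated with a warning (the polynomial is
#' defined everywhere, but it was fitted on normalized data).
#'
#' @param rsm A `quadratic_rsm`.
#' @param x A d-vector, matrix or data frame of normalized input points.
#' @return A tibble with one column per response.
#' @export
rsm_evaluate <- function(rsm, x) {
  X <- new_input_matrix(
    if (is.numeric(x) && is.null(dim(x))) matrix(x, nrow = 1) else x,
    attr(rsm, "inputs")
  )
  if (any(X < -1e-8 | X > 1 + 1e-8)) {
    warning("evaluating the response surface outside [0, 1]^d.")
  }
  out <- rsm_basis(X) %*% rsm$coefficients
  as_tibble(as.data.frame(out))
}

#' @export
predict.quadratic_rsm <- function(object, newdata, ...) {
  rsm_evaluate(object, newdata)
}

#' @export
print.quadratic_rsm <- function(x, ...) {
  cat(sprintf("Quadratic response surface (%s): %d terms x %d responses\n",
              x$provenance, nrow(x$coefficients), ncol(x$coefficients)))
  if (!is.null(x$r_squared)) {
    cat("  training R^2:",
        paste(sprintf("%s %.3f", names(x$r_squared), x$r_squared), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
tidy.quadratic_rsm <- function(x, ...) {
  co <- x$coefficients
  tidyr::pivot_longer(
    dplyr::mutate(as_tibble(as.data.frame(co)), term = rownames(co)),
    -"term", names_to = "response", values_to = "estimate"
  )[, c("response", "term", "estimate")]
}

#' @export
glance.quadratic_rsm <- function(x, ...) {
  tibble(
    response = colnames(x$coefficients),
    r.squared = if (is.null(x$r_squared)) NA_real_ else unname(x$r_squared),
    nobs = x$n
  )
}
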