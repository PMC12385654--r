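#' Gaussian radial basis function
#'
#' `exp(-||x - c||^2 / (2 * width^2))`: the hidden-unit response of the RBF
#' network, 1 at the center and decaying with Euclidean distance.
#'
#' @param x,center Numeric vectors of equal length.
#' @param width Positive kernel width (sigma).
#' @return Value in `(0, 1]`.
#' @export
#' @examples
#' gaussian_basis(c(1, 0), c(0, 0), width = 1)
gaussian_basis <- function(x, center, width) {
  if (width <= 0) abort("`width` must be positive.")
  if (length(x) != length(center)) abort("`x` and `center` must have equal length.")
  exp(-sum((x - center)^2) / (2 * width^2))
}

# n x h matrix of Gaussian basis responses of rows of A to centers (rows of C)
rbf_basis_matrix <- function(A, C, width) {
  D2 <- outer(rowSums(A^2), rowSums(C^2), "+") - 2 * A %*% t(C)
  exp(-pmax(D2, 0) / (2 * width^2))
}

#' Train a Gaussian RBF network surrogate
#'
#' Exact-interpolation RBF regression: the hidden layer holds one Gaussian
#' unit per training point (centers = training inputs), and the linear output
#' weights are obtained analytically by solving the (ridge-regularized) basis
#' system -- no iterative training. The kernel width is selected by
#' leave-one-out cross-validation over `width_grid`, scoring the mean of the
#' per-response MSE scaled by the response variance so that responses with
#' different units weigh equally. At the regularization floor the network
#' interpolates the training data.
#'
#' @param data Data frame with normalized input columns and response columns.
#' @param inputs,responses Column names (defaults: `x1 ... x3` and the four
#'   quality indicators).
#' @param width Fixed kernel width; if `NULL` (default) selected by
#'   cross-validation over `width_grid`.
#' @param width_grid Candidate widths for cross-validation. The default grid
#'   spans 0.1 to 100 on normalized inputs (100 being far into the flat,
#'   heavily smoothed regime of the unit cube).
#' @param ridge Regularization floor added to the basis-matrix diagonal;
#'   raised automatically (with a warning) when duplicate training rows would
#'   make the system singular.
#'
#' @return An object of class `rbf_surrogate` with elements `centers`,
#'   `width`, `weights`, `cv` (tibble of widths and scores, when
#'   cross-validated).
#' @export
#' @examples
#' fit <- rbf_train(load_table2(), width = 0.5)
#' predict(fit, load_table2()[1:2, ])
rbf_train <- function(data, inputs = c("x1", "x2", "x3"),
                      responses = quality_responses,
                      width = NULL,
                      width_grid = c(0.1, 0.5, 1, 5, 10, 50, 100),
                      ridge = 1e-10) {
  xy <- surrogate_xy(data, inputs, responses)
  X <- xy$X; Y <- xy$Y
  n <- nrow(X)
  if (n < 2) abort("need at least 2 training rows.")
  if (anyDuplicated(as.data.frame(X))) {
    warning("duplicate training inputs: raising the regularization floor.")
    ridge <- max(ridge, 1e-6)
  }
  cv <- NULL
  if (is.null(width)) {
    scores <- vapply(width_grid, function(w) rbf_loo_score(X, Y, w, ridge), double(1))
    cv <- tibble(width = width_grid, loo_score = scores)
    width <- width_grid[which.min(scores)]
  }
  if (width <= 0) abort("`width` must be positive.")
  Phi <- rbf_basis_matrix(X, X, width)
  W <- solve(Phi + diag(ridge, n), Y)
  structure(
    list(centers = X, width = width, weights = W, ridge = ridge, cv = cv),
    class = "rbf_surrogate",
    inputs = inputs, responses = responses
  )
}

# LOO CV score: mean over responses of MSE / var(y). Lower is better.
rbf_loo_score <- function(X, Y, width, ridge) {
  n <- nrow(X)
  err2 <- matrix(NA_real_, n, ncol(Y))
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    Phi <- rbf_basis_matrix(Xi, Xi, width)
    W <- tryCatch(solve(Phi + diag(ridge, n - 1), Y[-i, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(W)) return(Inf)
    err2[i, ] <- (rbf_basis_matrix(X[i, , drop = FALSE], Xi, width) %*% W - Y[i, ])^2
  }
  vars <- apply(Y, 2, stats::var)
  mean(colMeans(err2) / vars)
}

#' @describeIn rbf_train Predict quality responses at new input points.
#' @param object A trained `rbf_surrogate`.
#' @param newdata Data frame (or matrix) of input coordinates.
#' @param ... Unused.
#' @export
predict.rbf_surrogate <- function(object, newdata, ...) {
  X <- new_input_matrix(newdata, attr(object, "inputs"))
  if (ncol(X) != ncol(object$centers)) abort("input dimension mismatch.")
  out <- rbf_basis_matrix(X, object$centers, object$width) %*% object$weights
  colnames(out) <- attr(object, "responses")
  as_tibble(as.data.frame(out))
}

#' @export
print.rbf_surrogate <- function(x, ...) {
  cat(sprintf("Gaussian RBF surrogate: %d centers, width %g, %d responses\n",
              nrow(x$centers), x$width, ncol(x$weights)))
  invisible(x)
}

#' @export
glance.rbf_surrogate <- function(x, ...) {
  tibble(
    n_centers = nrow(x$centers),
    width = x$width,
    ridge = x$ridge,
    cross_validated = !is.null(x$cv)
  )
}
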