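#' Forward pass of an Elman recurrent network
#'
#' Runs the Elman recursion over an ordered input sequence: at step k the
#' hidden state is `x(k) = f(W1 %*% xc(k) + W2 %*% u(k))` with context
#' `xc(k) = x(k - 1)` (zeros at the sequence start), and the output is
#' `y(k) = g(W3 %*% x(k))`. The context layer is what distinguishes the Elman
#' net from a plain feed-forward network: it replays the previous hidden
#' state as an extra input.
#'
#' @param model An `elman_surrogate` (see [elman_train()]) or a bare list with
#'   weight matrices `w_context` (h x h), `w_input` (h x d), `w_output`
#'   (m x h) and optional activations `f` (default `tanh`) and `g` (default
#'   identity).
#' @param inputs An `n x d` matrix (or data frame) of input vectors, one row
#'   per time step, in sequence order.
#' @return List with `outputs` (n x m matrix), `hidden` (n x h matrix of
#'   hidden states) and `context` (h-vector: the context after the last step,
#'   i.e. the final hidden state).
#' @export
#' @examples
#' net <- list(w_context = matrix(0.5), w_input = matrix(1),
#'             w_output = matrix(2))
#' elman_forward(net, matrix(c(1, 0)))$outputs
elman_forward <- function(model, inputs) {
  u <- as.matrix(as.data.frame(inputs))
  storage.mode(u) <- "double"
  W1 <- model$w_context; W2 <- model$w_input; W3 <- model$w_output
  f <- model$f %||% tanh
  g <- model$g %||% identity
  h <- nrow(W2)
  n <- nrow(u)
  outs <- matrix(NA_real_, n, nrow(W3))
  hid <- matrix(NA_real_, n, h)
  xc <- rep(0, h)
  for (k in seq_len(n)) {
    x <- f(as.vector(W1 %*% xc + W2 %*% u[k, ]))
    outs[k, ] <- g(as.vector(W3 %*% x))
    hid[k, ] <- x
    xc <- x
  }
  list(outputs = outs, hidden = hid, context = xc)
}

#' Train an Elman recurrent network surrogate
#'
#' Gradient training of all three weight matrices by dynamic backpropagation
#' with the standard one-step truncation of the context gradient (the context
#' is treated as a fixed extra input at each step). The static dataset is
#' presented as one ordered sequence per epoch, row order preserved, with the
#' context reset to zero at each epoch start; plain online gradient descent
#' with a fixed learning rate. Training stops at the epoch cap, when the
#' epoch mean squared error (on the internal standardized scale) falls below
#' `error_tol`, or when the gradient norm falls below `grad_tol` -- whichever
#' comes first.
#'
#' Responses are standardized internally (z-scored per response) before
#' training and mapped back at prediction; disable with
#' `standardize = FALSE`.
#'
#' @inheritParams rbf_train
#' @param hidden Number of hidden (and context) neurons.
#' @param max_epochs Epoch cap.
#' @param error_tol Stop when the epoch training MSE falls below this.
#' @param grad_tol Stop when the epoch mean gradient norm falls below this.
#' @param learn_rate Gradient-descent step size.
#' @param standardize Z-score the responses internally (default `TRUE`).
#' @param seed Integer seed for the uniform(-0.5, 0.5) weight initialization.
#'
#' @return An object of class `elman_surrogate` with the three weight
#'   matrices, the scaling, the per-epoch `trace` (tibble of `epoch`, `mse`,
#'   `grad_norm`), `epochs_run` and `stop_reason`.
#' @export
elman_train <- function(data, inputs = c("x1", "x2", "x3"),
                        responses = quality_responses,
                        hidden = 10, max_epochs = 1000,
                        error_tol = 1e-5, grad_tol = 1e-6,
                        learn_rate = 0.01, standardize = TRUE,
                        seed = NULL) {
  xy <- surrogate_xy(data, inputs, responses)
  X <- xy$X; Y <- xy$Y
  n <- nrow(X); d <- ncol(X); m <- ncol(Y)
  if (n < 2) abort("need at least 2 training rows.")
  stopifnot(hidden >= 1, max_epochs >= 1, error_tol > 0, grad_tol > 0, learn_rate > 0)

  if (standardize) {
    center <- colMeans(Y)
    scale <- apply(Y, 2, sd)
    scale[scale == 0] <- 1
  } else {
    center <- rep(0, m); scale <- rep(1, m)
  }
  Ys <- sweep(sweep(Y, 2, center, "-"), 2, scale, "/")

  W <- with_seed_if(seed, list(
    w1 = matrix(runif(hidden * hidden, -0.5, 0.5), hidden, hidden),
    w2 = matrix(runif(hidden * d, -0.5, 0.5), hidden, d),
    w3 = matrix(runif(m * hidden, -0.5, 0.5), m, hidden)
  ))

  trace <- matrix(NA_real_, max_epochs, 2)
  epochs <- 0L
  reason <- "max_epochs"
  for (e in seq_len(max_epochs)) {
    xc <- rep(0, hidden)
    se <- 0
    gn <- 0
    for (k in seq_len(n)) {
      uk <- X[k, ]
      a <- as.vector(W$w1 %*% xc + W$w2 %*% uk)
      x <- tanh(a)
      err <- as.vector(W$w3 %*% x) - Ys[k, ]
      se <- se + sum(err^2)
      g3 <- err %o% x
      da <- as.vector(t(W$w3) %*% err) * (1 - x^2)
      g1 <- da %o% xc
      g2 <- da %o% uk
      gn <- gn + sqrt(sum(g1^2) + sum(g2^2) + sum(g3^2))
      W$w3 <- W$w3 - learn_rate * g3
      W$w1 <- W$w1 - learn_rate * g1
      W$w2 <- W$w2 - learn_rate * g2
      xc <- x
    }
    mse <- se / (n * m)
    if (!is.finite(mse)) {
      abort(sprintf("Elman training diverged (non-finite loss) at epoch %d.", e))
    }
    trace[e, ] <- c(mse, gn / n)
    epochs <- e
    if (mse < error_tol) { reason <- "error_tol"; break }
    if (gn / n < grad_tol) { reason <- "grad_tol"; break }
  }

  structure(
    list(
      w_context = W$w1, w_input = W$w2, w_output = W$w3,
      f = tanh, g = identity,
      center = center, scale = scale,
      trace = tibble(epoch = seq_len(epochs),
                     mse = trace[seq_len(epochs), 1],
                     grad_norm = trace[seq_len(epochs), 2]),
      epochs_run = epochs, stop_reason = reason,
      hidden = hidden, seed = seed
    ),
    class = "elman_surrogate",
    inputs = inputs, responses = responses
  )
}

#' @describeIn elman_train Predict responses for new rows. Rows are run as one
#'   ordered sequence with the context reset at the start (`reset =
#'   "sequence"`, the same convention as training) or independently with a
#'   fresh zero context per row (`reset = "row"`).
#' @param object A trained `elman_surrogate`.
#' @param newdata Data frame of input coordinates.
#' @param reset Context handling, `"sequence"` (default) or `"row"`.
#' @param ... Unused.
#' @export
predict.elman_surrogate <- function(object, newdata,
                                    reset = c("sequence", "row"), ...) {
  reset <- match.arg(reset)
  X <- new_input_matrix(newdata, attr(object, "inputs"))
  outs <- if (reset == "sequence") {
    elman_forward(object, X)$outputs
  } else {
    do.call(rbind, lapply(seq_len(nrow(X)), function(i) {
      elman_forward(object, X[i, , drop = FALSE])$outputs
    }))
  }
  out <- sweep(sweep(outs, 2, object$scale, "*"), 2, object$center, "+")
  colnames(out) <- attr(object, "responses")
  as_tibble(as.data.frame(out))
}

#' @export
print.elman_surrogate <- function(x, ...) {
  cat(sprintf(
    "Elman surrogate: %d hidden neurons, %d epochs (stop: %s), final MSE %.3g\n",
    x$hidden, x$epochs_run, x$stop_reason, x$trace$mse[x$epochs_run]))
  invisible(x)
}

#' @export
glance.elman_surrogate <- function(x, ...) {
  tibble(
    hidden = x$hidden,
    epochs_run = x$epochs_run,
    stop_reason = x$stop_reason,
    initial_mse = x$trace$mse[1],
    final_mse = x$trace$mse[x$epochs_run]
  )
}
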