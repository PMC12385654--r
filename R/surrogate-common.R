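# Shared plumbing for the surrogate trainers: all take a data frame whose
# input columns are normalized factors (default x1..x3) and whose response
# columns are the four quality indicators.

quality_responses <- c("hardness", "ssc", "ta", "vc")

surrogate_xy <- function(data, inputs, responses) {
  data <- as.data.frame(data)
  missing_in <- setdiff(inputs, names(data))
  missing_out <- setdiff(responses, names(data))
  if (length(missing_in) > 0 || length(missing_out) > 0) {
    abort(paste0("missing column(s): ",
                 paste(c(missing_in, missing_out), collapse = ", ")))
  }
  X <- as.matrix(data[inputs]); storage.mode(X) <- "double"
  Y <- as.matrix(data[responses]); storage.mode(Y) <- "double"
  if (anyNA(X) || anyNA(Y)) abort("inputs and responses must be numeric and non-missing.")
  list(X = X, Y = Y)
}

new_input_matrix <- function(newdata, inputs) {
  nd <- as.data.frame(newdata)
  if (!all(inputs %in% names(nd))) {
    if (ncol(nd) >= length(inputs)) {
      nd <- nd[seq_along(inputs)]
      names(nd) <- inputs
    } else {
      abort(paste0("`newdata` must contain columns ", paste(inputs, collapse = ", ")))
    }
  }
  X <- as.matrix(nd[inputs]); storage.mode(X) <- "double"
  X
}

#' Split a dataset into training and test subsets
#'
#' Random row split, reproducible by seed; the 80/20 split used for surrogate
#' training and held-out evaluation.
#'
#' @param data A data frame.
#' @param train_fraction Fraction of rows in the training set (default 0.8).
#' @param seed Optional integer seed.
#' @return List with tibbles `train` and `test` and the integer `train_idx`.
#' @export
train_test_split <- function(data, train_fraction = 0.8, seed = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- nrow(data)
  n_train <- round(train_fraction * n)
  idx <- with_seed_if(seed, sample.int(n, n_train))
  list(
    train = as_tibble(as.data.frame(data)[idx, , drop = FALSE]),
    test = as_tibble(as.data.frame(data)[-idx, , drop = FALSE]),
    train_idx = sort(idx)
  )
}

#' Held-out fit metrics for a trained surrogate
#'
#' Predicts the test rows and computes [fit_metrics()] per response.
#'
#' @param model A trained surrogate (`rbf_surrogate`, `elman_surrogate` or
#'   `quadratic_rsm`), or any object with a `predict` method returning a data
#'   frame of response columns.
#' @param data Test data containing the model's input and response columns.
#' @return Tibble with one row per response: `response`, `r2`, `rmse`,
#'   `mape`, `nrmse`.
#' @export
evaluate_model <- function(model, data) {
  if (nrow(as.data.frame(data)) == 0) abort("test set is empty.")
  responses <- attr(model, "responses") %||% quality_responses
  pred <- as.data.frame(predict(model, data))
  obs <- as.data.frame(data)
  dplyr::bind_rows(lapply(responses, function(r) {
    dplyr::bind_cols(tibble(response = r), fit_metrics(obs[[r]], pred[[r]]))
  }))
}
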