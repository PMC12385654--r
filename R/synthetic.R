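#' Load the 40-run wolfberry storage dataset
#'
#' The packaged optimized-Latin-hypercube storage experiment: 40 design
#' points over normalized storage temperature (`x1`), storage time (`x2`)
#' and initial maturity (`x3`), with the measured quality indicators --
#' hardness (N, as printed), SSC (%), TA (%) and vitamin C (mg/100 g). The
#' file is validated against frozen column checksums on every load so a
#' corrupted installation fails loudly.
#'
#' @return A 40-row tibble of class `quality_dataset` with columns
#'   `x1, x2, x3, hardness, ssc, ta, vc`.
#' @export
#' @examples
#' load_table2()
load_table2 <- function() {
  path <- system.file("extdata", "table2_design.csv", package = "berrystore",
                      mustWork = TRUE)
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_double()))
  expected_cols <- c("x1", "x2", "x3", quality_responses)
  if (!identical(names(data), expected_cols) || nrow(data) != 40) {
    abort("packaged 40-run dataset is corrupted (schema).")
  }
  sums <- round(colSums(data), 6)
  frozen <- c(x1 = 22.12, x2 = 19.98, x3 = 19.98,
              hardness = 613.97, ssc = 591.44, ta = 57.84, vc = 675.70)
  if (!isTRUE(all.equal(unname(sums[expected_cols]), unname(frozen), tolerance = 1e-9))) {
    abort("packaged 40-run dataset is corrupted (checksum).")
  }
  new_quality_dataset(data, provenance = "in-study 40-run storage experiment")
}

new_quality_dataset <- function(data, provenance, seed = NULL) {
  out <- as_tibble(data)
  class(out) <- c("quality_dataset", class(out))
  attr(out, "provenance") <- provenance
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic quality dataset from a response surface
#'
#' Evaluates a quadratic response surface at the design points and adds
#' independent Gaussian measurement noise per response. With zero noise the
#' responses equal [rsm_evaluate()] exactly, which is the basis of the
#' parameter-recovery guarantees tested for [fit_quadratic_rsm()].
#'
#' @param design A design (tibble/matrix with columns `x1 ... x3`) in the
#'   unit cube.
#' @param truth A `quadratic_rsm` acting as the data-generating truth
#'   (default: the published surfaces, [eq15_surfaces()]).
#' @param noise_sd Per-response Gaussian standard deviations in response
#'   units, recycled to the four responses. Default 0 (noise-free).
#' @param seed Optional integer seed.
#' @return A `quality_dataset` tibble with the design columns and the four
#'   response columns.
#' @export
#' @examples
#' generate_from_rsm(random_lhs(20, 3, seed = 1), noise_sd = 2, seed = 2)
generate_from_rsm <- function(design, truth = eq15_surfaces(),
                              noise_sd = 0, seed = NULL) {
  X <- unit_columns(design, length(attr(truth, "inputs")))
  colnames(X) <- attr(truth, "inputs")
  responses <- attr(truth, "responses")
  sds <- rep_len(as.double(noise_sd), length(responses))
  if (any(sds < 0)) abort("`noise_sd` must be non-negative.")
  Y <- as.matrix(rsm_evaluate(truth, X))
  noise <- with_seed_if(seed, {
    matrix(rnorm(length(Y)), nrow(Y), ncol(Y)) %*% diag(sds, length(sds))
  })
  Y <- Y + noise
  out <- dplyr::bind_cols(as_tibble(as.data.frame(X)),
                          as_tibble(as.data.frame(Y)))
  new_quality_dataset(out, provenance = "synthetic (quadratic surface + Gaussian noise)",
                      seed = seed)
}

# Printed anchor values for the stage-wise kinetic profiles, one block per
# varied factor (the other two factors sit at the reference conditions of the
# corresponding single-factor experiment). Values without a printed source
# are package defaults, documented in the methods vignette. Hardness is on
# the gram scale here.
kinetic_anchors <- function() {
  list(
    temperature = list(
      held = c(time = 8, maturity = 70),
      ssc = list(kind = "peak_quadratic", peak_at = 8, peak_value = 24.95,
                 ref_at = -4, ref_value = 15.0),
      vc = list(kind = "peak_quadratic", peak_at = 8, peak_value = 28.37,
                ref_at = -4, ref_value = 20.0),
      hardness = list(kind = "linear", at = c(-4, 24), value = c(2135.96, 659.85)),
      ta = list(kind = "constant", value = 1.65)
    ),
    time = list(
      held = c(temperature = 4, maturity = 70),
      hardness = list(kind = "spline", at = c(0, 4, 28), value = c(1500, 1636.54, 659.85)),
      vc = list(kind = "spline", at = c(0, 4, 28), value = c(28.5, 35.16, 9.75)),
      ssc = list(kind = "spline", at = c(0, 8, 28), value = c(15.3, 23.54, 5.37)),
      ta = list(kind = "spline", at = c(0, 8, 28), value = c(1.0, 1.65, 0.295))
    ),
    maturity = list(
      held = c(temperature = 4, time = 8),
      hardness = list(kind = "linear", at = c(20, 90), value = c(1800, 1314)),
      ta = list(kind = "linear", at = c(20, 90), value = c(1.65, 0.297)),
      ssc = list(kind = "spline", at = c(20, 55, 90), value = c(5.37, 15, 23.56)),
      vc = list(kind = "spline", at = c(20, 60, 90), value = c(26.89, 12, 20))
    )
  )
}

eval_anchor_profile <- function(spec, grid) {
  switch(spec$kind,
    constant = rep(spec$value, length(grid)),
    linear = stats::approx(spec$at, spec$value, xout = grid)$y,
    spline = splinefun(spec$at, spec$value, method = "monoH.FC")(grid),
    peak_quadratic = {
      a <- (spec$ref_value - spec$peak_value) / (spec$ref_at - spec$peak_at)^2
      spec$peak_value + a * (grid - spec$peak_at)^2
    },
    abort("unknown profile kind.")
  )
}

#' Generate stage-wise kinetic quality profiles
#'
#' Smooth single-factor quality profiles reproducing the stage-wise kinetics
#' observed in storage: SSC and vitamin C parabolic in temperature with the
#' peak at 8 degrees C (24.95% and 28.37 mg/100 g); hardness strictly
#' decreasing in temperature; hardness and vitamin C peaking on day 4
#' (1636.54 g and 35.16 mg/100 g) and SSC and TA on day 8 (23.54% and
#' 1.65%); monotone or V-shaped trends in initial maturity. Profiles pass
#' through every anchor exactly (monotone Hermite interpolation between
#' anchors), and the held factors sit at the single-factor experiment's
#' reference conditions. Hardness is on the gram scale in this mode.
#'
#' @param variable Which factor to sweep: `"temperature"`, `"time"` or
#'   `"maturity"`.
#' @param grid Raw-unit grid over the factor's range (default 50 equispaced
#'   points).
#' @param anchors Anchor set (defaults to the built-in printed anchors plus
#'   documented package defaults).
#' @param space The factor space.
#' @return A `quality_dataset` tibble with the raw swept variable, the
#'   normalized coordinates `x1 ... x3`, and the four responses.
#' @export
#' @examples
#' generate_kinetic_profiles("temperature")
generate_kinetic_profiles <- function(variable = c("temperature", "time", "maturity"),
                                      grid = NULL,
                                      anchors = kinetic_anchors(),
                                      space = wolfberry_factors()) {
  variable <- match.arg(variable)
  block <- anchors[[variable]]
  i <- match(variable, space$name)
  if (is.null(grid)) {
    grid <- seq(space$lower[i], space$upper[i], length.out = 50)
  }
  if (any(grid < space$lower[i] | grid > space$upper[i])) {
    abort(sprintf("grid outside the '%s' range.", variable))
  }
  for (r in quality_responses) {
    sp <- block[[r]]
    if (!is.null(sp$at) && (any(sp$at < space$lower[i]) || any(sp$at > space$upper[i]))) {
      abort(sprintf("anchor for '%s' outside the '%s' range.", r, variable))
    }
    if (identical(sp$kind, "peak_quadratic") &&
        (sp$peak_at < space$lower[i] || sp$peak_at > space$upper[i])) {
      abort(sprintf("peak location for '%s' outside the '%s' range.", r, variable))
    }
  }
  raw <- matrix(NA_real_, length(grid), space_dim(space))
  colnames(raw) <- space$name
  raw[, variable] <- grid
  for (nm in names(block$held)) raw[, nm] <- block$held[[nm]]
  unit <- normalize_points(as.data.frame(raw), space)
  Y <- vapply(quality_responses, function(r) eval_anchor_profile(block[[r]], grid),
              double(length(grid)))
  out <- dplyr::bind_cols(
    tibble(!!variable := grid),
    unit,
    as_tibble(as.data.frame(Y))
  )
  new_quality_dataset(out, provenance = sprintf("synthetic kinetic profile (%s sweep)", variable))
}
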