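#' Configuration for the SMPSO optimizer
#'
#' Speed-constrained multi-objective particle swarm settings. Defaults follow
#' the storage-condition optimization runs (12 particles, 50 generations,
#' 600 objective-evaluation rounds in total) with standard SMPSO internals:
#' acceleration coefficients resampled uniformly from `c_range` each update,
#' a constriction factor limiting the velocity, polynomial mutation applied
#' to a fraction of the swarm, and a crowding-bounded leader archive.
#'
#' @param swarm_size Particles in the swarm.
#' @param generations Iterations of the swarm.
#' @param archive_capacity Maximum leaders retained (crowding eviction above).
#' @param c_range Range for the acceleration coefficients c1, c2.
#' @param mutation_prob Per-particle probability of polynomial mutation.
#' @param mutation_eta Distribution index of the polynomial mutation.
#' @param seed Optional integer seed; the whole run is reproducible given it.
#' @return List of class `smpso_config`.
#' @export
smpso_config <- function(swarm_size = 12, generations = 50,
                         archive_capacity = 100,
                         c_range = c(1.5, 2.5),
                         mutation_prob = 0.15, mutation_eta = 20,
                         seed = NULL) {
  stopifnot(swarm_size >= 1, generations >= 1, archive_capacity >= 1,
            length(c_range) == 2, c_range[1] <= c_range[2],
            mutation_prob >= 0, mutation_prob <= 1, mutation_eta > 0)
  structure(
    list(swarm_size = as.integer(swarm_size),
         generations = as.integer(generations),
         archive_capacity = as.integer(archive_capacity),
         c_range = c_range, mutation_prob = mutation_prob,
         mutation_eta = mutation_eta, seed = seed),
    class = "smpso_config"
  )
}

#' SMPSO velocity constriction factor
#'
#' The speed constraint that prevents swarm explosion: with
#' `phi = c1 + c2`, returns 1 when `phi <= 4` and
#' `2 / |2 - phi - sqrt(phi^2 - 4 phi)|` otherwise. Always in `(0, 1]`.
#'
#' @param c1,c2 Non-negative acceleration coefficients.
#' @return The constriction factor.
#' @export
#' @examples
#' constriction_factor(1.5, 1.5) # 1
#' constriction_factor(2.05, 2.05)
constriction_factor <- function(c1, c2) {
  stopifnot(c1 >= 0, c2 >= 0)
  phi <- c1 + c2
  if (phi <= 4) return(1)
  2 / abs(2 - phi - sqrt(phi^2 - 4 * phi))
}

#' Define a multi-objective maximization problem
#'
#' @param evaluate Function mapping a point of the unit cube `[0, 1]^d` to a
#'   numeric vector of objective values, all maximized.
#' @param n_var Number of decision variables.
#' @param objective_names Optional names for the objectives.
#' @return List of class `moo_problem`.
#' @export
moo_problem <- function(evaluate, n_var, objective_names = NULL) {
  stopifnot(is.function(evaluate), n_var >= 1)
  structure(
    list(evaluate = evaluate, n_var = as.integer(n_var),
         objective_names = objective_names),
    class = "moo_problem"
  )
}

#' Storage-condition optimization problem for wolfberry quality
#'
#' Builds the four-objective maximization problem over normalized storage
#' conditions: maximize predicted hardness, SSC, TA and vitamin C subject to
#' the box bounds of the factor space (temperature -4 to 24 degrees C, time 0
#' to 28 days, maturity 20 to 90 percent). Predictions come either from one
#' multi-response model or from a named list pairing each response with its
#' own surrogate (the default study pairing uses the RBF network for
#' hardness, TA and Vc and the Elman network for SSC). Factors may be frozen
#' at raw values (e.g. a fixed storage time) so the swarm searches only the
#' remaining conditions.
#'
#' @param models A single model with a multi-response `predict`, or a named
#'   list `list(hardness = ..., ssc = ..., ta = ..., vc = ...)`.
#' @param space The [factor_space()] (defaults to [wolfberry_factors()]).
#' @param frozen Named numeric vector of raw factor values to hold fixed,
#'   e.g. `c(time = 10)`.
#' @return A `moo_problem` over the free factors, carrying the space and the
#'   frozen assignment as attributes.
#' @export
storage_problem <- function(models, space = wolfberry_factors(), frozen = NULL) {
  d <- space_dim(space)
  frozen_unit <- rep(NA_real_, d)
  if (!is.null(frozen)) {
    if (is.null(names(frozen)) || !all(names(frozen) %in% space$name)) {
      abort("`frozen` must be a named vector of factor names.")
    }
    for (nm in names(frozen)) {
      i <- match(nm, space$name)
      if (frozen[[nm]] < space$lower[i] || frozen[[nm]] > space$upper[i]) {
        abort(sprintf("frozen value for '%s' outside its range.", nm))
      }
      frozen_unit[i] <- (frozen[[nm]] - space$lower[i]) / (space$upper[i] - space$lower[i])
    }
  }
  free <- which(is.na(frozen_unit))
  if (length(free) == 0) abort("at least one factor must remain free.")

  predict_all <- make_multi_predictor(models)

  evaluate <- function(z) {
    full <- frozen_unit
    full[free] <- z
    pt <- as.data.frame(matrix(full, nrow = 1))
    names(pt) <- paste0("x", seq_len(d))
    as.double(predict_all(pt))
  }
  prob <- moo_problem(evaluate, n_var = length(free),
                      objective_names = quality_responses)
  attr(prob, "space") <- space
  attr(prob, "free") <- free
  attr(prob, "frozen_unit") <- frozen_unit
  prob
}

make_multi_predictor <- function(models) {
  if (!is.list(models) || !is.null(attr(models, "class"))) {
    # single multi-response model
    return(function(pt) unlist(as.data.frame(predict(models, pt))[1, quality_responses]))
  }
  if (!all(quality_responses %in% names(models))) {
    abort("`models` list must name all of: hardness, ssc, ta, vc.")
  }
  function(pt) {
    vapply(quality_responses, function(r) {
      as.data.frame(predict(models[[r]], pt))[[r]][1]
    }, double(1))
  }
}

#' Insert a candidate into a Pareto archive
#'
#' The candidate enters only if no archived member dominates it; members it
#' dominates are removed; if the archive then exceeds capacity, the member
#' with the smallest crowding distance is evicted.
#'
#' @param archive List with matrices `positions` and `objectives`.
#' @param position,objective Candidate decision vector and objective vector.
#' @param capacity Maximum archive size.
#' @return The updated archive list.
#' @export
archive_insert <- function(archive, position, objective, capacity = 100) {
  if (any(!is.finite(objective))) abort("candidate objectives must be finite.")
  obj <- archive$objectives
  if (!is.null(obj) && nrow(obj) > 0) {
    dominated_by_member <- apply(obj, 1, function(o) all(o >= objective) && any(o > objective))
    if (any(dominated_by_member)) return(archive)
    equal_member <- apply(obj, 1, function(o) all(o == objective))
    if (any(equal_member)) return(archive)
    beats <- apply(obj, 1, function(o) all(objective >= o) && any(objective > o))
    archive$positions <- archive$positions[!beats, , drop = FALSE]
    archive$objectives <- obj[!beats, , drop = FALSE]
  }
  archive$positions <- rbind(archive$positions, position)
  archive$objectives <- rbind(archive$objectives, objective)
  if (nrow(archive$objectives) > capacity) {
    cd <- crowding_distance(archive$objectives)
    evict <- which.min(cd)
    archive$positions <- archive$positions[-evict, , drop = FALSE]
    archive$objectives <- archive$objectives[-evict, , drop = FALSE]
  }
  archive
}

#' Run the SMPSO optimizer
#'
#' Speed-constrained multi-objective PSO: particles fly through the unit
#' cube guided by their personal best and a leader drawn from the external
#' non-dominated archive by binary crowding tournament; velocities are scaled
#' by the constriction factor and clamped to half the variable range;
#' positions leaving a bound are clamped with the velocity component
#' reversed; polynomial mutation perturbs a fraction of the swarm each
#' generation.
#'
#' @param problem A [moo_problem()] (or [storage_problem()]).
#' @param config An [smpso_config()].
#' @return Object of class `pareto_archive`: list with `positions` (k x d,
#'   unit scale), `objectives` (k x m), `crowding` (k-vector), plus the
#'   problem attributes for denormalization when available.
#' @export
#' @examples
#' front <- run_smpso(moo_problem(function(x) c(x, 1 - x^2), 1),
#'                    smpso_config(10, 10, seed = 1))
run_smpso <- function(problem, config = smpso_config()) {
  with_seed_if(config$seed, run_smpso_impl(problem, config))
}

run_smpso_impl <- function(problem, config) {
  d <- problem$n_var
  n <- config$swarm_size
  eval1 <- function(x) {
    v <- as.double(problem$evaluate(x))
    if (any(!is.finite(v))) {
      abort(paste0("non-finite objective at point: ",
                   paste(signif(x, 4), collapse = ", ")))
    }
    v
  }
  pos <- lhs::randomLHS(n, d)
  vel <- matrix(0, n, d)
  obj <- do.call(rbind, lapply(seq_len(n), function(i) eval1(pos[i, ])))
  pbest_pos <- pos
  pbest_obj <- obj
  archive <- list(positions = NULL, objectives = NULL)
  for (i in seq_len(n)) {
    archive <- archive_insert(archive, pos[i, ], obj[i, ], config$archive_capacity)
  }
  vmax <- 0.5 # half the unit range, per dimension

  for (g in seq_len(config$generations)) {
    for (i in seq_len(n)) {
      # crowding refreshed per pick: inserts can reshape the archive mid-sweep
      cd <- crowding_distance(archive$objectives)
      leader <- archive$positions[pick_leader(cd), ]
      c1 <- runif(1, config$c_range[1], config$c_range[2])
      c2 <- runif(1, config$c_range[1], config$c_range[2])
      chi <- constriction_factor(c1, c2)
      r1 <- runif(d); r2 <- runif(d)
      v <- chi * (vel[i, ] + c1 * r1 * (pbest_pos[i, ] - pos[i, ]) +
                    c2 * r2 * (leader - pos[i, ]))
      v <- pmin(pmax(v, -vmax), vmax)
      x <- pos[i, ] + v
      low <- x < 0; high <- x > 1
      x[low] <- 0; x[high] <- 1
      v[low | high] <- -v[low | high]
      if (runif(1) < config$mutation_prob) {
        x <- polynomial_mutation(x, config$mutation_eta)
      }
      pos[i, ] <- x
      vel[i, ] <- v
      obj[i, ] <- eval1(x)
      # personal best: replace when the new point dominates; coin flip when
      # mutually non-dominated (standard SMPSO convention)
      if (dominates(obj[i, ], pbest_obj[i, ]) ||
          (!dominates(pbest_obj[i, ], obj[i, ]) && runif(1) < 0.5)) {
        pbest_pos[i, ] <- x
        pbest_obj[i, ] <- obj[i, ]
      }
      archive <- archive_insert(archive, x, obj[i, ], config$archive_capacity)
    }
  }

  out <- list(
    positions = unname(archive$positions),
    objectives = unname(archive$objectives),
    crowding = crowding_distance(archive$objectives)
  )
  colnames(out$objectives) <- problem$objective_names %||%
    paste0("f", seq_len(ncol(out$objectives)))
  class(out) <- "pareto_archive"
  attr(out, "space") <- attr(problem, "space")
  attr(out, "free") <- attr(problem, "free")
  attr(out, "frozen_unit") <- attr(problem, "frozen_unit")
  out
}

# binary crowding tournament among archive members
pick_leader <- function(cd) {
  k <- length(cd)
  if (k == 1) return(1L)
  ij <- sample.int(k, 2, replace = TRUE)
  if (cd[ij[1]] >= cd[ij[2]]) ij[1] else ij[2]
}

# polynomial mutation, per-variable probability 1/d, reflected at bounds
polynomial_mutation <- function(x, eta) {
  d <- length(x)
  for (j in seq_len(d)) {
    if (runif(1) < 1 / d) {
      u <- runif(1)
      delta <- if (u < 0.5) {
        (2 * u + (1 - 2 * u) * (1 - x[j])^(eta + 1))^(1 / (eta + 1)) - 1
      } else {
        1 - (2 * (1 - u) + 2 * (u - 0.5) * x[j]^(eta + 1))^(1 / (eta + 1))
      }
      x[j] <- min(max(x[j] + delta, 0), 1)
    }
  }
  x
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat(sprintf("Pareto archive: %d non-dominated solutions, %d objectives\n",
              nrow(x$objectives), ncol(x$objectives)))
  invisible(x)
}

#' @export
tidy.pareto_archive <- function(x, ...) {
  pos <- as.data.frame(x$positions)
  names(pos) <- paste0("x", seq_len(ncol(pos)))
  dplyr::bind_cols(as_tibble(pos),
                   as_tibble(as.data.frame(x$objectives)),
                   tibble(crowding = x$crowding))
}

#' Pick the single preferred solution from a Pareto archive
#'
#' Min-max normalizes each objective across the archive and returns the
#' member closest (Euclidean distance) to the ideal point -- the usual
#' automatic knee-point choice. Ties break by larger crowding distance, then
#' by lower index.
#'
#' @param archive A `pareto_archive`.
#' @return One-row tibble with the position (unit scale), objectives and the
#'   achieved distance to the ideal.
#' @export
select_optimal <- function(archive) {
  obj <- archive$objectives
  if (is.null(obj) || nrow(obj) == 0) abort("empty archive.")
  k <- nrow(obj)
  rng <- apply(obj, 2, function(o) {
    r <- max(o) - min(o)
    if (r == 0) 1 else r
  })
  norm <- sweep(sweep(obj, 2, apply(obj, 2, min), "-"), 2, rng, "/")
  dist <- sqrt(rowSums((1 - norm)^2))
  cd <- archive$crowding
  ord <- order(dist, -cd, seq_len(k))
  best <- ord[1]
  pos <- as.data.frame(archive$positions[best, , drop = FALSE])
  names(pos) <- paste0("x", seq_len(ncol(pos)))
  dplyr::bind_cols(
    as_tibble(pos),
    as_tibble(as.data.frame(obj[best, , drop = FALSE])),
    tibble(ideal_distance = dist[best])
  )
}

#' Optimal storage conditions for a fixed storage time
#'
#' Freezes storage time at `time_days`, optimizes the remaining conditions
#' (temperature, initial maturity) with SMPSO, and returns the automatically
#' selected optimum in raw units together with the four predicted quality
#' responses.
#'
#' @param models Model(s) accepted by [storage_problem()].
#' @param time_days Storage time in days, within the factor range.
#' @param config An [smpso_config()].
#' @param space The factor space (default [wolfberry_factors()]).
#' @return One-row tibble: `temperature`, `time`, `maturity` (raw units),
#'   `hardness`, `ssc`, `ta`, `vc` (predicted), plus `ideal_distance`.
#' @export
#' @examples
#' scenario_query(eq15_surfaces(), time_days = 10,
#'                config = smpso_config(8, 10, seed = 1))
scenario_query <- function(models, time_days, config = smpso_config(),
                           space = wolfberry_factors()) {
  prob <- storage_problem(models, space = space, frozen = c(time = time_days))
  archive <- run_smpso(prob, config)
  best <- select_optimal(archive)
  free <- attr(prob, "free")
  full <- attr(prob, "frozen_unit")
  full[free] <- as.double(best[1, seq_along(free)])
  raw <- denormalize_points(matrix(full, nrow = 1), space)
  dplyr::bind_cols(raw, best[, c(quality_responses, "ideal_distance")])
}
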