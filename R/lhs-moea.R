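#' Configuration for the individual-based LHS-MOEA
#'
#' Parameters of the multi-objective evolutionary algorithm that mixes Latin
#' hypercube local search with selection/crossover/mutation. Each generation,
#' a fraction `p` of the offspring budget is spent on LHS local search around
#' tournament-selected parents (search radius `delta` for non-dominated
#' parents, `2 * delta` otherwise, `H` samples per parent); the remainder is
#' produced by evolutionary operators. Parents and offspring are merged,
#' ranked, and the best `N` retained (elitism).
#'
#' @param population_size N, individuals per generation.
#' @param generations G, number of generations run.
#' @param local_search_fraction p in `[0, 1]`, share of the offspring budget
#'   routed through LHS local search (the loop bound `ceiling(p * N)` is used).
#' @param neighborhood_radius delta, half-width of the local-search box.
#' @param local_sample_count H, LHS samples per local search.
#' @param crossover_prob,mutation_prob Pc and Pm for the evolutionary part.
#' @param seed Optional integer seed making the run reproducible.
#' @return A list of class `moea_config`.
#' @export
moea_config <- function(population_size = 20,
                        generations = 30,
                        local_search_fraction = 0.3,
                        neighborhood_radius = 0.1,
                        local_sample_count = 3,
                        crossover_prob = 0.9,
                        mutation_prob = 0.2,
                        seed = NULL) {
  stopifnot(
    population_size >= 1, generations >= 1, local_sample_count >= 1,
    local_search_fraction >= 0, local_search_fraction <= 1,
    crossover_prob >= 0, crossover_prob <= 1,
    mutation_prob >= 0, mutation_prob <= 1,
    neighborhood_radius > 0
  )
  structure(
    list(
      population_size = as.integer(population_size),
      generations = as.integer(generations),
      local_search_fraction = local_search_fraction,
      neighborhood_radius = neighborhood_radius,
      local_sample_count = as.integer(local_sample_count),
      crossover_prob = crossover_prob,
      mutation_prob = mutation_prob,
      seed = seed
    ),
    class = "moea_config"
  )
}

#' Run the individual-based LHS-MOEA
#'
#' Generic engine over a pluggable genome representation. The default
#' representation is a real vector in the unit cube with LHS-box local search,
#' blend crossover and uniform-reset mutation; [optimize_design()] supplies a
#' permutation representation that preserves Latin stratification by
#' construction.
#'
#' @param evaluate Function mapping a decoded individual (numeric vector or
#'   matrix, depending on representation) to a numeric vector of objective
#'   values, all maximized. Non-finite objective values are an error.
#' @param n_var Dimension of the decision space (unit-cube representation).
#' @param config A [moea_config()].
#' @param ops Representation operators, see [real_vector_ops()]. Defaults to
#'   the unit-cube real-vector representation of dimension `n_var`.
#'
#' @return A list of class `moea_result` with `individuals` (list of genomes),
#'   `decoded` (list), `objectives` (matrix), `rank` (integer vector).
#' @export
#' @examples
#' res <- run_lhs_moea(function(x) -sum(x^2), n_var = 2,
#'                     config = moea_config(10, 5, seed = 1))
#' min(-res$objectives)
run_lhs_moea <- function(evaluate, n_var = NULL, config = moea_config(),
                         ops = real_vector_ops(n_var)) {
  with_seed_if(config$seed, run_lhs_moea_impl(evaluate, config, ops))
}

run_lhs_moea_impl <- function(evaluate, config, ops) {
  N <- config$population_size
  eval1 <- function(ind) {
    v <- as.double(evaluate(ops$decode(ind)))
    if (any(!is.finite(v))) {
      abort(paste0("non-finite objective value at individual: ",
                   paste(signif(unlist(ops$decode(ind)), 4), collapse = ", ")))
    }
    v
  }
  pop <- ops$init(N)
  obj <- do.call(rbind, lapply(pop, eval1))
  rank <- nondominated_rank(obj)

  n_local <- ceiling(config$local_search_fraction * N)
  n_evo <- N - n_local
  # per-generation best of each objective (row 1 = initial population);
  # non-decreasing columns certify elite retention
  trace <- matrix(NA_real_, config$generations + 1, ncol(obj))
  trace[1, ] <- apply(obj, 2, max)

  for (t in seq_len(config$generations)) {
    cd <- crowding_distance(obj)
    offspring <- list()
    # LHS local-search share: Steps 5-8
    if (n_local > 0) {
      for (k in seq_len(n_local)) {
        pi <- tournament_pick(rank, cd)
        radius <- if (rank[pi] == 1L) config$neighborhood_radius else 2 * config$neighborhood_radius
        offspring <- c(offspring, ops$local_search(pop[[pi]], radius, config$local_sample_count))
      }
    }
    # evolutionary share: Step 9
    if (n_evo > 0) {
      for (k in seq_len(n_evo)) {
        a <- pop[[tournament_pick(rank, cd)]]
        child <- if (runif(1) < config$crossover_prob) {
          b <- pop[[tournament_pick(rank, cd)]]
          ops$crossover(a, b)
        } else {
          a
        }
        offspring <- c(offspring, list(ops$mutate(child, config$mutation_prob)))
      }
    }
    off_obj <- do.call(rbind, lapply(offspring, eval1))
    # elite retention: merge parents, rank, keep best N
    merged <- c(pop, offspring)
    merged_obj <- rbind(obj, off_obj)
    keep <- truncate_by_rank(merged_obj, N)
    pop <- merged[keep]
    obj <- merged_obj[keep, , drop = FALSE]
    rank <- nondominated_rank(obj)
    trace[t + 1, ] <- apply(obj, 2, max)
  }

  structure(
    list(
      individuals = pop,
      decoded = lapply(pop, ops$decode),
      objectives = obj,
      rank = rank,
      trace = trace
    ),
    class = "moea_result"
  )
}

# binary tournament on (rank, crowding distance)
tournament_pick <- function(rank, cd) {
  ij <- sample.int(length(rank), 2, replace = TRUE)
  i <- ij[1]; j <- ij[2]
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (cd[i] >= cd[j]) i else j
}

#' Real-vector representation for [run_lhs_moea()]
#'
#' Individuals are points of the unit cube; initialization is a random Latin
#' hypercube, local search is [lhs_neighborhood()], crossover a random blend,
#' and mutation a per-gene uniform reset.
#'
#' @param d Dimension.
#' @return A list of operator functions (`init`, `decode`, `local_search`,
#'   `crossover`, `mutate`).
#' @export
real_vector_ops <- function(d) {
  stopifnot(d >= 1)
  list(
    init = function(N) {
      m <- lhs::randomLHS(N, d)
      lapply(seq_len(N), function(i) m[i, ])
    },
    decode = function(ind) ind,
    local_search = function(ind, radius, H) {
      pts <- lhs_neighborhood(ind, radius, H)
      lapply(seq_len(nrow(pts)), function(i) pts[i, ])
    },
    crossover = function(a, b) {
      w <- runif(length(a))
      w * a + (1 - w) * b
    },
    mutate = function(ind, pm) {
      hit <- runif(length(ind)) < pm
      ind[hit] <- runif(sum(hit))
      ind
    }
  )
}

# Permutation-encoded Latin hypercube representation: per-column bin
# permutations plus in-bin jitter. Every decoded individual is a valid LHS by
# construction, so the Latin invariant survives all operators.
latin_perm_ops <- function(n, d) {
  decode <- function(ind) (ind$bins + ind$u) / n
  list(
    init = function(N) {
      lapply(seq_len(N), function(i) {
        list(
          bins = vapply(seq_len(d), function(j) sample.int(n) - 1L, integer(n)),
          u = matrix(runif(n * d, min = 1e-9, max = 1 - 1e-9), n, d)
        )
      })
    },
    decode = decode,
    # stochastic swap neighborhood: the number of in-column bin swaps scales
    # with the search radius, mirroring LHS local search in permutation space
    local_search = function(ind, radius, H) {
      n_swaps <- max(1L, ceiling(radius * n))
      lapply(seq_len(H), function(h) {
        out <- ind
        for (j in seq_len(d)) {
          for (s in seq_len(n_swaps)) {
            ij <- sample.int(n, 2)
            out$bins[ij, j] <- out$bins[rev(ij), j]
          }
        }
        out$u <- matrix(runif(n * d, min = 1e-9, max = 1 - 1e-9), n, d)
        out
      })
    },
    # column-wise partial permutation exchange
    crossover = function(a, b) {
      from_b <- runif(d) < 0.5
      child <- a
      child$bins[, from_b] <- b$bins[, from_b]
      child$u[, from_b] <- b$u[, from_b]
      child
    },
    # swap two bins in one random column
    mutate = function(ind, pm) {
      if (runif(1) < pm) {
        j <- sample.int(d, 1)
        ij <- sample.int(n, 2)
        ind$bins[ij, j] <- ind$bins[rev(ij), j]
        ind$u[ij, j] <- runif(2, min = 1e-9, max = 1 - 1e-9)
      }
      ind
    }
  )
}

#' Optimize a Latin hypercube design for space-filling uniformity
#'
#' Evolves permutation-encoded Latin hypercubes under two objectives --
#' maximize the minimum pairwise Euclidean distance (maximin) and minimize the
#' centered L2 discrepancy -- using [run_lhs_moea()]. The returned design is
#' the non-dominated member with the largest maximin distance; thanks to elite
#' retention it is never worse, in maximin distance, than the best design of
#' the initial population.
#'
#' @param n Number of design points (>= 2).
#' @param d Number of dimensions.
#' @param config A [moea_config()]; supply `seed` for reproducibility.
#' @return A `berry_design` tibble (columns `x1 ... xd`) satisfying exact
#'   Latin stratification, with the final [uniformity_report()] attached as
#'   attribute `uniformity`.
#' @export
#' @examples
#' d <- optimize_design(12, 2, moea_config(10, 5, seed = 1))
#' is_latin(d)
optimize_design <- function(n, d, config = moea_config()) {
  stopifnot(n >= 2, d >= 1)
  evaluate <- function(m) {
    c(min_pairwise_distance(m), -centered_l2_discrepancy(m))
  }
  res <- run_lhs_moea(evaluate, config = config, ops = latin_perm_ops(n, d))
  front <- which(res$rank == 1L)
  best <- front[which.max(res$objectives[front, 1])]
  design <- new_design(res$decoded[[best]], seed = config$seed)
  attr(design, "uniformity") <- uniformity_report(design)
  design
}
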