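#' Non-dominated sorting of objective vectors
#'
#' Ranks points by Pareto dominance under maximization of every objective.
#' Rank 1 is the non-dominated set; rank k the set that becomes non-dominated
#' once ranks below k are removed (the hierarchical ranking used by both the
#' design MOEA and the dominance checks of the SMPSO archive).
#'
#' @param objectives An `n x m` matrix (or data frame) of objective values,
#'   all objectives to be maximized.
#' @return Integer vector of ranks (length `n`); `integer(0)` for empty input.
#' @export
#' @examples
#' nondominated_rank(rbind(c(2, 2), c(1, 1), c(0, 3)))
nondominated_rank <- function(objectives) {
  obj <- as.matrix(as.data.frame(objectives))
  n <- nrow(obj)
  if (n == 0) return(integer(0))
  if (anyNA(obj) || any(!is.finite(obj))) abort("objective values must be finite.")
  rank <- integer(n)
  remaining <- seq_len(n)
  r <- 1L
  while (length(remaining) > 0) {
    sub <- obj[remaining, , drop = FALSE]
    nd <- !dominated_mask(sub)
    rank[remaining[nd]] <- r
    remaining <- remaining[!nd]
    r <- r + 1L
  }
  rank
}

# TRUE for rows dominated by some other row (maximization).
dominated_mask <- function(obj) {
  n <- nrow(obj)
  dom <- logical(n)
  for (i in seq_len(n)) {
    if (dom[i]) next
    oi <- obj[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      oj <- obj[j, ]
      if (all(oj >= oi) && any(oj > oi)) {
        dom[i] <- TRUE
        break
      }
    }
  }
  dom
}

dominates <- function(a, b) all(a >= b) && any(a > b)

#' Crowding distance of a set of objective vectors
#'
#' The NSGA-II spread measure: for each point, the sum over objectives of the
#' normalized gap between its neighbours when sorted by that objective.
#' Boundary points get `Inf`. Used for archive truncation and tournament
#' tie-breaks.
#'
#' @param objectives An `n x m` matrix of objective values.
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(objectives) {
  obj <- as.matrix(as.data.frame(objectives))
  n <- nrow(obj)
  if (n == 0) return(numeric(0))
  if (n <= 2) return(rep(Inf, n))
  cd <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    ord <- order(obj[, k])
    rng <- obj[ord[n], k] - obj[ord[1], k]
    cd[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        cd[ord[i]] <- cd[ord[i]] + (obj[ord[i + 1], k] - obj[ord[i - 1], k]) / rng
      }
    }
  }
  cd
}

# Select the best `n` indices by (rank, crowding distance within rank,
# insertion order). Standard elitist truncation.
truncate_by_rank <- function(objectives, n_keep) {
  obj <- as.matrix(as.data.frame(objectives))
  rank <- nondominated_rank(obj)
  keep <- integer(0)
  for (r in sort(unique(rank))) {
    idx <- which(rank == r)
    if (length(keep) + length(idx) <= n_keep) {
      keep <- c(keep, idx)
    } else {
      cd <- crowding_distance(obj[idx, , drop = FALSE])
      ord <- order(-cd, idx) # larger crowding first, then insertion order
      keep <- c(keep, idx[ord[seq_len(n_keep - length(keep))]])
      break
    }
  }
  sort(keep)
}
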