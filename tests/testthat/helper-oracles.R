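# Independent brute-force oracles used across the suite.

# Pareto ranks by explicit pairwise dominance counting (maximization),
# written independently of the package's peeling implementation.
oracle_ranks <- function(obj) {
  n <- nrow(obj)
  rank <- rep(NA_integer_, n)
  r <- 0L
  while (anyNA(rank)) {
    r <- r + 1L
    alive <- which(is.na(rank))
    for (i in alive) {
      dominated <- FALSE
      for (j in alive) {
        if (i != j &&
            all(obj[j, ] >= obj[i, ]) &&
            sum(obj[j, ] > obj[i, ]) > 0) {
          dominated <- TRUE
          break
        }
      }
      if (!dominated) rank[i] <- r
    }
  }
  rank
}

# TRUE when no member of the set dominates another (maximization)
oracle_mutually_nondominated <- function(obj) {
  n <- nrow(obj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(obj[i, ] >= obj[j, ]) && any(obj[i, ] > obj[j, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

resp_cols <- c("hardness", "ssc", "ta", "vc")

# relative residual used by the interpolation checks
rel_resid <- function(pred, obs) {
  max(abs(as.matrix(pred) - as.matrix(obs)) / pmax(abs(as.matrix(obs)), 1))
}
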