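# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. With seed = NULL the expression runs on the current
# stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a replicate-specific sub-seed from a master seed. Kept below 2^31;
# depends only on (seed, i) so runs with different configurations but the
# same master seed share replicate streams (common random numbers).
derive_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 99991) * 100003 + i) %% 2147483647)
}

# Apportion `total` into integer counts proportional to `props` using the
# largest-remainder rule; ties broken by position. Always sums to `total`.
largest_remainder <- function(total, props) {
  stopifnot(total >= 0, all(props >= 0))
  s <- sum(props)
  if (s == 0) stop("cannot apportion over all-zero proportions")
  quota <- total * props / s
  counts <- floor(quota)
  left <- total - sum(counts)
  if (left > 0) {
    rem <- quota - counts
    top <- order(rem, decreasing = TRUE)[seq_len(left)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

# Apportion `total` into integer counts proportional to `props`, assigning
# the leftover units multinomially in proportion to the fractional parts.
# Sums exactly to `total` and is unbiased (E[counts] = total * props), which
# deterministic largest-remainder rounding is not: its fixed assignment of
# remainders creates a per-state allele drift that breaks neutrality in
# small populations. Consumes RNG draws.
stochastic_remainder <- function(total, props) {
  stopifnot(total >= 0, all(props >= 0))
  s <- sum(props)
  if (s == 0) stop("cannot apportion over all-zero proportions")
  quota <- total * props / s
  counts <- floor(quota)
  left <- total - sum(counts)
  if (left > 0) {
    rem <- pmax(quota - counts, 0)
    counts <- counts + drop(stats::rmultinom(1L, left, rem))
  }
  as.integer(counts)
}

# Clamp probabilities away from 0/1 for use inside log-likelihoods.
clamp_prob <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)
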