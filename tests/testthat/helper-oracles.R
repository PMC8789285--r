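# Independent oracles used to cross-check the implementation.

# Brute-force one-generation recursion: explicit spore bookkeeping.
# Each mating class contributes four spores weighted by its fitness; a
# heterozygote's surviving spores carry the driver with probability k.
oracle_next_freq <- function(p, k, w11, w12, w22, F) {
  f11 <- p^2 + F * p * (1 - p)
  f12 <- 2 * p * (1 - p) * (1 - F)
  f22 <- (1 - p)^2 + F * p * (1 - p)
  driver_spores <- 4 * f11 * w11 + 4 * f12 * w12 * k
  nondriver_spores <- 4 * f22 * w22 + 4 * f12 * w12 * (1 - k)
  driver_spores / (driver_spores + nondriver_spores)
}

# Exact one-generation transition pmf of the finite-population model at
# F = 0, built by exhaustive enumeration over every stochastic layer:
# binomial resampling, multinomial remainder assignment, binomial spore
# thinning of heterozygous matings, and the final hypergeometric (or
# binomial fallback) draw. Small N only.
wf_exact_pmf <- function(d0, N, het_fitness = 0.5,
                         drive_mode = c("complete", "neutral")) {
  drive_mode <- match.arg(drive_mode)
  pmf <- numeric(N + 1)
  enumerate_leftover <- function(left, rem) {
    if (left == 0) return(list(list(a = c(0L, 0L, 0L), pr = 1)))
    out <- list()
    for (a1 in 0:left) for (a2 in 0:(left - a1)) {
      a <- c(a1, a2, left - a1 - a2)
      pr <- stats::dmultinom(a, prob = rem)
      if (pr > 0) out[[length(out) + 1]] <- list(a = a, pr = pr)
    }
    out
  }
  for (d in 0:N) {
    pd <- stats::dbinom(d, N, d0 / N)
    if (pd == 0) next
    q <- d / N
    quota <- N * c(q^2, 2 * q * (1 - q), (1 - q)^2)
    base <- floor(quota)
    left <- N - sum(base)
    rem <- pmax(quota - base, 0)
    if (left > 0 && sum(rem) == 0) rem <- rep(1, 3)
    for (cfg in enumerate_leftover(left, rem)) {
      counts <- base + cfg$a
      p_counts <- pd * cfg$pr
      if (p_counts == 0) next
      n11 <- counts[1]; n12 <- counts[2]; n22 <- counts[3]
      for (s in 0:(4 * n12)) {
        ps <- stats::dbinom(s, 4 * n12, het_fitness)
        if (ps == 0) next
        if (drive_mode == "complete") {
          splits <- list(list(sd = s, pr = 1))
        } else {
          splits <- lapply(0:s, function(sd)
            list(sd = sd, pr = stats::dbinom(sd, s, 0.5)))
        }
        for (sp in splits) {
          drv <- 4 * n11 + sp$sd
          non <- 4 * n22 + (s - sp$sd)
          w <- p_counts * ps * sp$pr
          if (w == 0) next
          pool <- drv + non
          if (pool == 0) next # extinction; negligible and excluded
          probs <- if (pool >= N) {
            stats::dhyper(0:N, drv, non, N)
          } else {
            stats::dbinom(0:N, N, drv / pool)
          }
          pmf <- pmf + w * probs
        }
      }
    }
  }
  pmf / sum(pmf)
}

# Chi-squared goodness of fit of observed category counts against a
# theoretical pmf, merging bins until every expected count is >= 5.
gof_pvalue <- function(obs_counts, pmf) {
  n <- sum(obs_counts)
  expected <- n * pmf
  ord <- order(expected)
  merged_obs <- c(); merged_exp <- c()
  acc_o <- 0; acc_e <- 0
  for (i in ord) {
    acc_o <- acc_o + obs_counts[i]; acc_e <- acc_e + expected[i]
    if (acc_e >= 5) {
      merged_obs <- c(merged_obs, acc_o); merged_exp <- c(merged_exp, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0) {
    merged_obs[length(merged_obs)] <- merged_obs[length(merged_obs)] + acc_o
    merged_exp[length(merged_exp)] <- merged_exp[length(merged_exp)] + acc_e
  }
  stat <- sum((merged_obs - merged_exp)^2 / merged_exp)
  stats::pchisq(stat, df = length(merged_obs) - 1, lower.tail = FALSE)
}

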