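#' Predicted marker-frequency trajectory under a linked cost
#'
#' Deterministic forward model used by the cost fit: the drive recursion
#' ([drive_trajectory()]) with genotype fitnesses built from the linked cost
#' `c`, its dominance `h`, and the transmission bias `k`
#' ([fitness_from_costs()]). For no-drive control crosses `k = 0.5`, so the
#' focal (costly) allele declines purely through selection against the cost.
#'
#' @param p0 Initial focal-allele frequency, in `[0, 1]`.
#' @param c,h Linked homozygous cost and dominance, each in `[0, 1]`.
#' @param F Inbreeding coefficient.
#' @param k Transmission bias; default 0.5 (no drive).
#' @param G Number of generations.
#' @param driver_linked_to_costly Passed to [fitness_from_costs()]; default
#'   `TRUE` (the focal allele carries the cost).
#' @return A `drive_trajectory` data frame (`generation`, `p`).
#' @examples
#' predict_marker_trajectory(0.5, c = 0.234, h = 0.083, F = 0.5, G = 6)
#' @export
predict_marker_trajectory <- function(p0, c, h, F = 0, k = 0.5, G = 6L,
                                      driver_linked_to_costly = TRUE) {
  w <- fitness_from_costs(c, h, k = k,
                          driver_linked_to_costly = driver_linked_to_costly)
  pars <- drive_params(k = k, w11 = w[["w11"]], w12 = w[["w12"]],
                       w22 = w[["w22"]], F = F)
  drive_trajectory(p0, pars, G)
}

#' Negative log-likelihood of observed trajectories given (c, h)
#'
#' Sums, over replicates and generations 1..`window`, the per-observation
#' negative log-likelihood of the observed marker frequencies given the
#' deterministic prediction of [predict_marker_trajectory()] started from
#' each replicate's generation-0 observation.
#'
#' Two observation models are available. `"binomial"` (default) treats each
#' observation as `round(freq * effective_n)` successes in `effective_n`
#' cytometry events; predicted frequencies are floored to `[1e-9, 1-1e-9]`
#' so boundary predictions never produce infinite likelihoods.
#' `"gaussian"` uses homoscedastic Gaussian residuals with the variance
#' profiled out (concentrated likelihood).
#'
#' @param c,h Candidate cost and dominance, each in `[0, 1]`.
#' @param data A data frame with columns `replicate`, `generation`, `freq`,
#'   `effective_n` — e.g. from [sim_evolution_trajectories()] or
#'   [read_trajectories()]. Each replicate must include a generation-0
#'   observation.
#' @param F,k Inbreeding coefficient and transmission bias of the forward
#'   model.
#' @param window Last generation entering the likelihood (default 6).
#' @param obs_model `"binomial"` or `"gaussian"`.
#' @return The negative log-likelihood (scalar).
#' @export
cost_nll <- function(c, h, data, F = 0, k = 0.5, window = 6L,
                     obs_model = c("binomial", "gaussian")) {
  obs_model <- match.arg(obs_model)
  stopifnot(is.data.frame(data), nrow(data) > 0,
            all(c("replicate", "generation", "freq", "effective_n") %in%
                  names(data)))
  if (window < 1) stop("empty generation window")
  if (any(data$effective_n <= 0)) stop("'effective_n' must be positive")
  w <- fitness_from_costs(c, h, k = k)
  pars <- drive_params(k = k, w11 = w[["w11"]], w12 = w[["w12"]],
                       w22 = w[["w22"]], F = F)
  reps <- unique(data$replicate)
  is0 <- data$generation == 0
  p0 <- data$freq[is0][match(reps, data$replicate[is0])]
  if (anyNA(p0)) {
    stop("replicate ", reps[which(is.na(p0))[1L]],
         " has no generation-0 observation")
  }
  d_use <- data[data$generation >= 1 & data$generation <= window, ,
                drop = FALSE]
  if (!all(reps %in% d_use$replicate)) {
    stop("replicate ", setdiff(reps, d_use$replicate)[1L],
         " has no observations in generations 1..", window)
  }
  # recursion vectorised over replicates (shared parameters, distinct p0);
  # this sits in the optimiser's inner loop
  G <- max(d_use$generation)
  P <- matrix(0, nrow = G + 1L, ncol = length(reps))
  P[1L, ] <- p0
  for (g in seq_len(G)) P[g + 1L, ] <- next_freq(P[g, ], pars)
  mu <- clamp_prob(P[cbind(d_use$generation + 1L,
                           match(d_use$replicate, reps))])
  if (obs_model == "binomial") {
    x <- round(d_use$freq * d_use$effective_n)
    -sum(stats::dbinom(x, d_use$effective_n, mu, log = TRUE))
  } else {
    resid <- d_use$freq - mu
    n <- length(resid)
    s2 <- max(mean(resid^2), 1e-12)
    n / 2 * log(2 * pi * s2) + n / 2
  }
}

#' Maximum-likelihood fit of a linked fitness cost and its dominance
#'
#' Estimates the homozygous cost `c` and dominance `h` of an allele linked
#' to a fluorescent marker from control experimental-evolution trajectories,
#' by bounded (L-BFGS-B) minimisation of [cost_nll()] over `[0, 1]^2`.
#' A seeded Latin-hypercube of starting points guards against boundary
#' optima; the best converged optimum wins, ties going to the smaller `c`.
#'
#' @inheritParams cost_nll
#' @param data Observed trajectories (see [cost_nll()]).
#' @param n_starts Number of Latin-hypercube starting points (default 8).
#' @param seed Seed for the start set (default 1); fits are bit-for-bit
#'   reproducible given the seed and data.
#' @return An object of class `cost_fit`: a list with `c_hat`, `h_hat`,
#'   `loglik`, `converged`, `window`, `obs_model`, `F`, `k`, `n_starts`,
#'   `seed`, and `starts` (per-start diagnostics).
#' @examples
#' d <- sim_evolution_trajectories(0.5, c = 0.234, h = 0.083, k = 0.5,
#'                                 F = 0.5, G = 6, replicates = 3, seed = 2)
#' fit_linked_cost(d, F = 0.5)
#' @export
fit_linked_cost <- function(data, F = 0, k = 0.5, window = 6L,
                            obs_model = c("binomial", "gaussian"),
                            n_starts = 8L, seed = 1L) {
  obs_model <- match.arg(obs_model)
  stopifnot(window >= 2, n_starts >= 1)
  fn <- function(par) cost_nll(par[1L], par[2L], data, F = F, k = k,
                               window = window, obs_model = obs_model)
  starts <- with_seed(seed, lhs::randomLHS(as.integer(n_starts), 2L))
  colnames(starts) <- c("c", "h")
  rows <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(starts[i, ], fn, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(1, 1)),
      error = function(e) NULL)
    rows[[i]] <- if (is.null(res)) {
      data.frame(start_c = starts[i, 1L], start_h = starts[i, 2L],
                 c = NA_real_, h = NA_real_, nll = NA_real_,
                 converged = FALSE)
    } else {
      data.frame(start_c = starts[i, 1L], start_h = starts[i, 2L],
                 c = res$par[1L], h = res$par[2L], nll = res$value,
                 converged = res$convergence == 0L)
    }
  }
  diag <- do.call(rbind, rows)
  ok <- diag[diag$converged & is.finite(diag$nll), , drop = FALSE]
  if (nrow(ok) == 0L) {
    out <- list(c_hat = NA_real_, h_hat = NA_real_, loglik = NA_real_,
                converged = FALSE, window = as.integer(window),
                obs_model = obs_model, F = F, k = k,
                n_starts = as.integer(n_starts), seed = seed, starts = diag)
    class(out) <- "cost_fit"
    return(out)
  }
  ok <- ok[order(ok$nll, ok$c), , drop = FALSE]  # ties -> smaller c
  best <- ok[1L, ]
  out <- list(c_hat = best$c, h_hat = best$h, loglik = -best$nll,
              converged = TRUE, window = as.integer(window),
              obs_model = obs_model, F = F, k = k,
              n_starts = as.integer(n_starts), seed = seed, starts = diag)
  class(out) <- "cost_fit"
  out
}

#' @export
print.cost_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Linked-cost ML fit (%s, generations 1-%d): c = %.4f, h = %.4f\n",
                x$obs_model, x$window, x$c_hat, x$h_hat))
    cat(sprintf("  log-likelihood %.3f; %d/%d starts converged\n",
                x$loglik, sum(x$starts$converged), x$n_starts))
  } else {
    cat("Linked-cost ML fit: no start converged; see $starts for diagnostics\n")
  }
  invisible(x)
}
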