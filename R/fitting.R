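#' Half-normal prior for the action precision
#'
#' The prior used for the group-level action precision: a normal with
#' location 0 and the given scale, truncated to the non-negative half-line
#' (mode at 0). The default scale is 4, a deliberately wide prior whose
#' median is `qnorm(0.75) * scale = 2.698` at the default.
#'
#' @param scale positive scale (SD of the untruncated normal).
#' @return An object of class `half_normal_prior`.
#' @export
half_normal_prior <- function(scale = 4) {
  stopifnot(scale > 0)
  structure(list(scale = scale), class = "half_normal_prior")
}

#' Half-normal prior density
#'
#' @param alpha evaluation point(s).
#' @param prior a [half_normal_prior()].
#' @return density values; 0 for `alpha < 0`.
#' @export
prior_density <- function(alpha, prior = half_normal_prior()) {
  ifelse(alpha < 0, 0, 2 * stats::dnorm(alpha, 0, prior$scale))
}

#' Sample from the half-normal prior
#'
#' @param n number of draws.
#' @param prior a [half_normal_prior()].
#' @return numeric vector of non-negative draws.
#' @export
prior_sample <- function(n, prior = half_normal_prior()) {
  abs(stats::rnorm(n, 0, prior$scale))
}

#' Per-trial action marginals along a recorded trajectory
#'
#' Replays the blanket-state record through a single group-level POMDP
#' agent: starting from the model's state prior, each trial's marginal
#' next-action distribution `q_t(a)` is computed from the current belief,
#' after which the belief is conditioned on the recorded group action and
#' outcome (propagated through `B` under `a_t`, updated on `o_t`). The
#' result does not involve the action precision: `alpha` enters the
#' likelihood only through the final softmax, which is applied afterwards.
#'
#' @param trajectory a [group_trajectory()] (only `trials` is used; the
#'   Markov-blanket contract).
#' @param model the group-level [generative_model()].
#' @return numeric matrix, `n_trials x n_actions`, row `t` the marginal
#'   `q_t`.
#' @export
trajectory_action_marginals <- function(trajectory, model) {
  trials <- trajectory$trials
  n_trials <- nrow(trials)
  Q <- matrix(0, n_trials, model$n_actions)
  if (n_trials == 0) return(Q)
  if (max(trials$group_action) > model$n_actions ||
      max(trials$observation) > model$n_obs)
    stop("trajectory action/observation indices exceed the model's spaces")
  cache <- new.env(parent = emptyenv())
  belief <- model$D
  for (t in seq_len(n_trials)) {
    Q[t, ] <- action_marginal_given_belief(model, belief, cache)
    prior <- drop(model$B[, , trials$group_action[t]] %*% belief)
    belief <- infer_states(model, trials$observation[t], prior)$posterior
  }
  Q
}

# Compile the trajectory into a fast log-likelihood function of alpha.
# ll(alpha) = sum_t [ alpha * log q_t(a_t) - logsumexp_a(alpha * log q_t(a)) ];
# identical rows of Q are collapsed with multiplicity, which is exact.
make_alpha_loglik <- function(trajectory, model) {
  n_trials <- nrow(trajectory$trials)
  if (n_trials == 0) return(function(alpha) 0)
  Q <- trajectory_action_marginals(trajectory, model)
  LQ <- logsafe(Q)
  a_t <- trajectory$trials$group_action
  chosen_sum <- sum(LQ[cbind(seq_len(n_trials), a_t)])
  keys <- apply(round(LQ, 12), 1, paste, collapse = ",")
  uniq <- !duplicated(keys)
  LU <- LQ[uniq, , drop = FALSE]
  mult <- as.vector(table(keys)[keys[uniq]])
  function(alpha) {
    lw <- alpha * LU
    m <- apply(lw, 1, max)
    alpha * chosen_sum - sum(mult * (m + log(rowSums(exp(lw - m)))))
  }
}

#' Log likelihood of a blanket-state trajectory under a given alpha
#'
#' Treats the group as a single POMDP active-inference agent: for each
#' trial the action-precision softmax of the model's current marginal
#' action distribution scores the recorded group action, and the belief is
#' then conditioned on the recorded (action, outcome) pair. Returns the
#' summed log likelihood.
#'
#' @inheritParams trajectory_action_marginals
#' @param alpha non-negative action precision at which to evaluate.
#' @return scalar log likelihood (0 for an empty trajectory).
#' @export
replay_log_likelihood <- function(trajectory, model, alpha) {
  if (alpha < 0) stop("alpha must be non-negative")
  make_alpha_loglik(trajectory, model)(alpha)
}

#' Fit the group-level action precision by MCMC
#'
#' Samples the posterior over `alpha` proportional to
#' `prior_density(alpha) * exp(replay_log_likelihood(alpha))` with an
#' adaptive random-walk Metropolis sampler (Gaussian proposals; the step
#' size is tuned toward a 0.44 acceptance rate during warmup and then
#' frozen; proposals below 0 are rejected through the prior's truncation,
#' which leaves the stationary distribution correct). All other model
#' parameters are fixed; only `alpha` is estimated.
#'
#' Convergence is summarised by split R-hat over all chains and a crude
#' effective sample size; if split R-hat exceeds 1.01 the fit is flagged
#' (`converged = FALSE`) and a warning is raised -- never a silent pass.
#'
#' @inheritParams trajectory_action_marginals
#' @param prior a [half_normal_prior()].
#' @param n_chains number of independent chains.
#' @param n_draws post-warmup draws per chain.
#' @param warmup warmup (adaptation) iterations per chain, discarded.
#' @param seed optional integer seed.
#' @return An object of class `posterior_fit`: pooled `draws`, per-chain
#'   matrix `chains`, `point_estimate` (posterior median), `quantiles`
#'   (5/25/50/75/95%), `rhat`, `ess`, `accept_rate`, `converged`.
#' @export
fit_alpha <- function(trajectory, model, prior = half_normal_prior(4),
                      n_chains = 4, n_draws = 1000, warmup = 1000,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loglik <- make_alpha_loglik(trajectory, model)
  log_post <- function(a) {
    if (a < 0) return(-Inf)
    stats::dnorm(a, 0, prior$scale, log = TRUE) + log(2) + loglik(a)
  }
  chains <- matrix(NA_real_, n_draws, n_chains)
  accept_rate <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    a <- prior_sample(1, prior) / 2 + 0.05  # overdispersed but sane starts
    cur <- log_post(a)
    step <- 0.5
    n_acc <- 0L
    for (it in seq_len(warmup + n_draws)) {
      prop <- a + stats::rnorm(1, 0, step)
      lp <- log_post(prop)
      acc <- log(stats::runif(1)) < lp - cur
      if (acc) {
        a <- prop
        cur <- lp
      }
      if (it <= warmup) {
        step <- exp(log(step) + (as.numeric(acc) - 0.44) / sqrt(it))
        step <- min(max(step, 1e-4), 50)
      } else {
        chains[it - warmup, ch] <- a
        n_acc <- n_acc + acc
      }
    }
    accept_rate[ch] <- n_acc / n_draws
  }
  draws <- as.vector(chains)
  rhat <- split_rhat(chains)
  converged <- is.finite(rhat) && rhat <= 1.01
  if (!converged)
    warning(sprintf("fit_alpha: split R-hat = %.4f exceeds 1.01; chains may not have converged",
                    rhat))
  structure(
    list(draws = draws, chains = chains, n_chains = n_chains,
         n_draws = n_draws, warmup = warmup,
         point_estimate = stats::median(draws),
         quantiles = stats::quantile(draws, c(0.05, 0.25, 0.5, 0.75, 0.95)),
         rhat = rhat, ess = ess_draws(chains), accept_rate = accept_rate,
         converged = converged),
    class = "posterior_fit"
  )
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("Posterior fit of alpha (%d chains x %d draws, %d warmup)\n",
              x$n_chains, x$n_draws, x$warmup))
  cat(sprintf("  median = %.3f  [5%%, 95%%] = [%.3f, %.3f]\n",
              x$point_estimate, x$quantiles[["5%"]], x$quantiles[["95%"]]))
  cat(sprintf("  split R-hat = %.4f, ESS ~ %.0f, converged: %s\n",
              x$rhat, x$ess, x$converged))
  invisible(x)
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so within-chain trends register as between-chain variance).
#'
#' @param chains numeric matrix, one column per chain.
#' @return scalar R-hat (`NA` if the draws are degenerate).
#' @export
split_rhat <- function(chains) {
  n <- floor(nrow(chains) / 2)
  if (n < 2) return(NA_real_)
  halves <- cbind(chains[seq_len(n), , drop = FALSE],
                  chains[nrow(chains) - n + seq_len(n), , drop = FALSE])
  w <- mean(apply(halves, 2, stats::var))
  b <- n * stats::var(colMeans(halves))
  if (!is.finite(w) || w <= 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Effective sample size of MCMC draws
#'
#' Per-chain initial-positive-sequence estimator (autocorrelations summed
#' until the first negative lag pair), summed over chains. Deliberately
#' simple; used for reporting, not for gating.
#'
#' @param chains numeric matrix, one column per chain.
#' @return scalar effective sample size.
#' @export
ess_draws <- function(chains) {
  ess_one <- function(x) {
    n <- length(x)
    if (stats::var(x) == 0) return(n)
    rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    s <- 0
    k <- 1
    while (k + 1 <= length(rho)) {
      pair <- rho[k] + rho[k + 1]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2
    }
    n / (1 + 2 * s)
  }
  sum(apply(chains, 2, ess_one))
}
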