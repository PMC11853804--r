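# Derive a bounded sub-seed for a cell of a seeded pipeline. Keeps every
# derived seed a valid 32-bit integer regardless of the master seed.
cell_seed <- function(master, i, j = 0L) {
  as.integer((as.numeric(master) * 100003 + i * 1009 + j * 7 + 12345) %% 2147483647)
}

#' Heterogeneous action precisions with an exact mean
#'
#' Draws a weight vector from a symmetric Dirichlet (concentration 1.5 per
#' component, via normalised Gamma draws) and scales it by `n * desired_mean`,
#' so the returned precisions are non-negative and their arithmetic mean is
#' `desired_mean` exactly (the weights sum to 1 by construction).
#'
#' @param n number of internal agents.
#' @param desired_mean non-negative target mean of the returned vector.
#' @param concentration Dirichlet concentration per component.
#' @return numeric vector of `n` action precisions.
#' @export
construct_alphas_dirichlet <- function(n, desired_mean, concentration = 1.5) {
  stopifnot(n >= 1)
  if (desired_mean < 0) stop("desired_mean must be non-negative")
  g <- stats::rgamma(n, shape = concentration, rate = 1)
  w <- g / sum(g)
  w * n * desired_mean
}

#' Heterogeneous preference weights from a Beta distribution
#'
#' Draws each internal agent's relative preference for outcome 1 i.i.d.
#' from `Beta(a, b)`. The default `Beta(0.8, 0.8)` is U-shaped and
#' symmetric about 0.5, so roughly half the agents end up preferring
#' outcome 2 (and hence the low-yield arms), which makes their votes
#' contradict each other.
#'
#' @param n number of internal agents.
#' @param a,b positive Beta shape parameters.
#' @return numeric vector of `n` preference weights in (0, 1); agent `i`'s
#'   preference prior is `(c_i, 1 - c_i)`.
#' @export
construct_preferences_beta <- function(n, a = 0.8, b = 0.8) {
  stopifnot(n >= 1, a > 0, b > 0)
  stats::rbeta(n, a, b)
}

#' Parameter-recovery study for the action precision
#'
#' For each (true alpha, seed) cell a single agent is simulated on the
#' bandit for `n_trials` trials and `alpha` is re-estimated from the
#' resulting trajectory by [fit_alpha()]. Mirrors the identity-line
#' recovery plot: estimates track the truth on roughly `[0, 1]` and
#' saturate above it, where behaviour is already near-deterministic.
#'
#' @param alpha_grid true alpha values (non-negative).
#' @param n_seeds independent repetitions per grid value.
#' @param n_trials trials per simulation.
#' @param model group/agent [generative_model()] (its `alpha` slot is
#'   overridden per cell for simulation and free during fitting).
#' @param bandit a [bandit_config()].
#' @param prior a [half_normal_prior()].
#' @param n_chains,n_draws,warmup sampler settings passed to [fit_alpha()].
#' @param seed master seed; every cell derives its own sub-seed from it.
#' @return data.frame (one row per cell): `true_alpha, seed, n_trials,
#'   estimate, q05, q25, q75, q95, rhat, converged`.
#' @export
run_parameter_recovery <- function(alpha_grid = c(seq(0.1, 1, by = 0.1), 1.5, 2),
                                   n_seeds = 3, n_trials = 500,
                                   model = mab_generative_model(),
                                   bandit = mab_bandit(),
                                   prior = half_normal_prior(4),
                                   n_chains = 4, n_draws = 1000, warmup = 1000,
                                   seed = 1) {
  if (any(alpha_grid < 0)) stop("alpha_grid values must be non-negative")
  rows <- vector("list", length(alpha_grid) * n_seeds)
  k <- 0L
  for (i in seq_along(alpha_grid)) {
    sim_model <- model
    sim_model$alpha <- alpha_grid[i]
    for (s in seq_len(n_seeds)) {
      k <- k + 1L
      cs <- cell_seed(seed, i, s)
      traj <- simulate_agent(sim_model, bandit, n_trials, seed = cs)
      fit <- fit_alpha(traj, model, prior, n_chains, n_draws, warmup,
                       seed = cs + 1L)
      rows[[k]] <- data.frame(
        true_alpha = alpha_grid[i], seed = s, n_trials = n_trials,
        estimate = fit$point_estimate,
        q05 = fit$quantiles[["5%"]], q25 = fit$quantiles[["25%"]],
        q75 = fit$quantiles[["75%"]], q95 = fit$quantiles[["95%"]],
        rhat = fit$rhat, converged = fit$converged
      )
    }
  }
  do.call(rbind, rows)
}

#' Run one of the four group-level simulation experiments
#'
#' All experiments share the same bandit and group structure and vary one
#' ingredient each:
#' \describe{
#'   \item{1}{all internal agents identical (shared alpha), probabilistic
#'     vote aggregation;}
#'   \item{2}{heterogeneous alphas from the Dirichlet construction
#'     ([construct_alphas_dirichlet()]) with the cell's mean;}
#'   \item{3}{identical agents but deterministic (plurality) aggregation;}
#'   \item{4}{identical alphas but heterogeneous preference priors from
#'     [construct_preferences_beta()].}
#' }
#' For each (mean alpha, N, seed) cell the group is simulated for
#' `n_trials` trials and the group-level action precision is estimated
#' from its blanket states with [fit_alpha()] under the fixed default
#' group model.
#'
#' @param id experiment id, 1-4.
#' @param n_internal vector of group sizes to run.
#' @param mean_alpha vector of internal mean action precisions (in `[0,1]`
#'   in the reference setup).
#' @param n_seeds repetitions per cell.
#' @param n_trials trials per simulation.
#' @param base_model template [generative_model()] for internal agents and
#'   for the group-level fit.
#' @param bandit a [bandit_config()].
#' @param prior,n_chains,n_draws,warmup fitting settings.
#' @param dirichlet_alpha if `TRUE`, experiment 3 also uses the Dirichlet
#'   alpha construction (default: identical alphas).
#' @param seed master seed.
#' @return data.frame, one row per cell: `experiment, n_internal,
#'   mean_alpha, realized_mean_alpha, aggregation, seed, estimate,
#'   q05, q25, q75, q95, rhat, converged`.
#' @export
run_experiment <- function(id, n_internal = c(4, 8, 16, 100),
                           mean_alpha = c(0.25, 0.5, 0.75),
                           n_seeds = 1, n_trials = 500,
                           base_model = mab_generative_model(),
                           bandit = mab_bandit(),
                           prior = half_normal_prior(4),
                           n_chains = 4, n_draws = 1000, warmup = 1000,
                           dirichlet_alpha = FALSE,
                           seed = 1) {
  if (!id %in% 1:4) stop("experiment id must be 1, 2, 3 or 4")
  aggregation <- if (id == 3) "deterministic" else "probabilistic"
  rows <- list()
  k <- 0L
  cell <- 0L
  for (N in n_internal) for (m in mean_alpha) {
    cell <- cell + 1L
    for (s in seq_len(n_seeds)) {
      cs <- cell_seed(seed, cell, s)
      set.seed(cs)
      alphas <- if (id == 2 || (id == 3 && dirichlet_alpha))
        construct_alphas_dirichlet(N, m) else rep(m, N)
      prefs <- if (id == 4) construct_preferences_beta(N) else NULL
      models <- lapply(seq_len(N), function(i) {
        mod <- if (is.null(prefs)) base_model else
          mab_generative_model(outcome1_probs = bandit$outcome1_probs,
                               preference = prefs[i],
                               gamma = base_model$gamma,
                               policy_len = base_model$policy_len)
        mod$alpha <- alphas[i]
        mod
      })
      traj <- run_group_simulation(
        group_config(models, aggregation, n_trials), bandit, seed = cs + 1L)
      fit <- fit_alpha(traj, base_model, prior, n_chains, n_draws, warmup,
                       seed = cs + 2L)
      k <- k + 1L
      rows[[k]] <- data.frame(
        experiment = id, n_internal = N, mean_alpha = m,
        realized_mean_alpha = mean(alphas), aggregation = aggregation,
        seed = s, estimate = fit$point_estimate,
        q05 = fit$quantiles[["5%"]], q25 = fit$quantiles[["25%"]],
        q75 = fit$quantiles[["75%"]], q95 = fit$quantiles[["95%"]],
        rhat = fit$rhat, converged = fit$converged
      )
    }
  }
  do.call(rbind, rows)
}

#' Identity-line plot of a parameter-recovery study
#'
#' @param results output of [run_parameter_recovery()].
#' @param file optional PNG path; plotted to the active device if `NULL`.
#' @return `results`, invisibly.
#' @export
plot_recovery <- function(results, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  lim <- range(0, results$true_alpha, results$estimate)
  graphics::plot(results$true_alpha, results$estimate, xlim = lim, ylim = lim,
                 pch = 19, col = grDevices::adjustcolor("steelblue", 0.7),
                 xlab = "generative alpha", ylab = "inferred alpha (posterior median)",
                 main = "Action-precision parameter recovery")
  graphics::abline(0, 1, col = "grey50")
  invisible(results)
}

#' Plot group-level estimates against the internal mean
#'
#' @param results output of [run_experiment()], possibly several row-bound
#'   experiments (facets are not drawn; colour encodes group size).
#' @param file optional PNG path.
#' @return `results`, invisibly.
#' @export
plot_experiment <- function(results, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  sizes <- sort(unique(results$n_internal))
  pal <- grDevices::hcl.colors(max(length(sizes), 2), "Dark 3")
  lim <- range(0, results$mean_alpha, results$estimate)
  graphics::plot(results$mean_alpha, results$estimate, xlim = lim, ylim = lim,
                 pch = 19, col = pal[match(results$n_internal, sizes)],
                 xlab = "mean internal alpha",
                 ylab = "inferred group alpha (posterior median)",
                 main = sprintf("Experiment %s", paste(unique(results$experiment),
                                                       collapse = ",")))
  graphics::abline(0, 1, col = "grey50")
  graphics::legend("topleft", legend = paste("N =", sizes), col = pal[seq_along(sizes)],
                   pch = 19, bty = "n")
  invisible(results)
}
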