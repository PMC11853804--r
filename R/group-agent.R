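#' Group-agent configuration
#'
#' Describes a group-level agent with an explicit Markov blanket: a sensory
#' agent that copies the environment outcome to all internal agents, `N`
#' internal POMDP active-inference agents that each vote for an arm, and an
#' active agent that aggregates the votes into the group action. The group's
#' blanket states are the per-trial (observation, group action) pairs.
#'
#' @param internal_models list of [generative_model()] objects, one per
#'   internal agent (possibly heterogeneous in `alpha` and `C`).
#' @param aggregation `"probabilistic"` (group action sampled with
#'   probability proportional to vote counts) or `"deterministic"` (the
#'   plurality option always wins; ties broken uniformly at random).
#' @param n_trials number of trials to simulate.
#' @return An object of class `group_config`.
#' @export
group_config <- function(internal_models,
                         aggregation = c("probabilistic", "deterministic"),
                         n_trials = 120) {
  aggregation <- match.arg(aggregation)
  if (!is.list(internal_models) || length(internal_models) < 1 ||
      !all(vapply(internal_models, inherits, TRUE, "generative_model")))
    stop("internal_models must be a non-empty list of generative_model objects")
  if (n_trials < 1 || n_trials != round(n_trials))
    stop("n_trials must be a positive integer")
  n_actions <- unique(vapply(internal_models, `[[`, 0L, "n_actions"))
  if (length(n_actions) != 1)
    stop("all internal agents must share the same action space")
  structure(list(internal_models = internal_models,
                 n_internal = length(internal_models),
                 aggregation = aggregation,
                 n_trials = as.integer(n_trials),
                 n_actions = n_actions),
            class = "group_config")
}

#' Sensory relay
#'
#' The group's sensory agent is a pure copier: it broadcasts the
#' environment outcome unchanged to every internal agent.
#'
#' @param observation outcome index.
#' @param n_internal number of internal agents.
#' @return integer vector of length `n_internal`, all equal to
#'   `observation` (length 0 when `n_internal = 0`).
#' @export
sensory_relay <- function(observation, n_internal) {
  rep(as.integer(observation), n_internal)
}

#' Aggregate internal votes into a group action
#'
#' The active agent of the group. In probabilistic mode the group action is
#' sampled with probability `count(a) / N`; in deterministic mode the
#' action with the most votes is returned, ties broken uniformly at random.
#'
#' @param votes integer vector of internal agents' action indices.
#' @param mode `"probabilistic"` or `"deterministic"`.
#' @param n_actions size of the action space (defaults to `max(votes)`).
#' @return a single group action index.
#' @export
aggregate_votes <- function(votes, mode = c("probabilistic", "deterministic"),
                            n_actions = max(votes)) {
  mode <- match.arg(mode)
  if (length(votes) == 0) stop("cannot aggregate an empty vote vector")
  if (any(votes < 1) || any(votes > n_actions))
    stop("votes contain invalid action indices")
  counts <- tabulate(votes, nbins = n_actions)
  if (mode == "probabilistic") {
    sample.int(n_actions, 1L, prob = counts)
  } else {
    top <- which(counts == max(counts))
    if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
  }
}

#' Simulate the group agent on the bandit
#'
#' Per trial: every internal agent emits a vote via [agent_step()] (on the
#' first trial from its state prior, thereafter after updating its belief
#' on the relayed previous outcome under its own previous vote); the active
#' agent aggregates the votes into the group action; the bandit is pulled;
#' and the outcome is relayed to all internal agents for the next trial.
#' The trial micro-order is therefore: votes, aggregation, outcome, relay,
#' belief update.
#'
#' @param group a [group_config()].
#' @param bandit a [bandit_config()].
#' @param seed optional integer seed (`set.seed()` is called when given);
#'   the whole trajectory is reproducible from it.
#' @return An object of class `group_trajectory`: list with `trials`
#'   (data.frame `trial, group_action, observation`), `votes`
#'   (`n_trials x N` integer matrix), and metadata (`aggregation`,
#'   `n_internal`, `bandit`, `internal_models`, `seed`).
#' @export
run_group_simulation <- function(group, bandit, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (group$n_actions != bandit$n_arms)
    stop("group action space and bandit arm count differ")
  N <- group$n_internal
  n_trials <- group$n_trials
  models <- group$internal_models

  states <- lapply(models, function(m) agent_state(m$D, NULL))
  caches <- lapply(seq_len(N), function(i) new.env(parent = emptyenv()))
  votes <- matrix(0L, n_trials, N)
  group_action <- integer(n_trials)
  observation <- integer(n_trials)

  relayed <- NULL  # first trial: no preceding outcome
  for (t in seq_len(n_trials)) {
    for (i in seq_len(N)) {
      step <- agent_step(models[[i]], states[[i]],
                         observation = if (is.null(relayed)) NULL else relayed[i],
                         cache = caches[[i]])
      votes[t, i] <- step$action
      states[[i]] <- step$state
    }
    group_action[t] <- aggregate_votes(votes[t, ], group$aggregation,
                                       group$n_actions)
    observation[t] <- pull(bandit, group_action[t])
    relayed <- sensory_relay(observation[t], N)
  }

  group_trajectory(
    trials = data.frame(trial = seq_len(n_trials),
                        group_action = group_action,
                        observation = observation),
    votes = votes,
    aggregation = group$aggregation,
    n_internal = N,
    bandit = bandit,
    internal_models = models,
    seed = seed
  )
}

#' Construct a group trajectory object
#'
#' The blanket-state record of a group simulation: per-trial (group action,
#' observation) pairs plus the internal votes for diagnostics. The `trials`
#' data frame alone suffices to recompute the fitting likelihood (the
#' Markov-blanket contract); votes and models are metadata.
#'
#' @param trials data.frame with columns `trial`, `group_action`,
#'   `observation` (may have zero rows).
#' @param votes integer matrix, one row per trial, or `NULL`.
#' @param aggregation,n_internal,bandit,internal_models,seed metadata.
#' @return An object of class `group_trajectory`.
#' @export
group_trajectory <- function(trials, votes = NULL,
                             aggregation = "probabilistic",
                             n_internal = if (is.null(votes)) 1L else ncol(votes),
                             bandit = NULL, internal_models = NULL,
                             seed = NULL) {
  stopifnot(is.data.frame(trials),
            all(c("trial", "group_action", "observation") %in% names(trials)))
  if (!is.null(votes) && nrow(trials) > 0 && nrow(votes) != nrow(trials))
    stop("votes must have one row per trial")
  structure(list(trials = trials, votes = votes, aggregation = aggregation,
                 n_internal = as.integer(n_internal), bandit = bandit,
                 internal_models = internal_models, seed = seed),
            class = "group_trajectory")
}

#' @export
print.group_trajectory <- function(x, ...) {
  cat(sprintf("Group trajectory: %d trials, %d internal agents, %s aggregation\n",
              nrow(x$trials), x$n_internal, x$aggregation))
  if (nrow(x$trials) > 0) {
    tab <- table(factor(x$trials$group_action))
    cat("  group action counts:",
        paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Exact group-action law
#'
#' Analytic distribution of the group action given the internal agents'
#' per-trial action distributions. In probabilistic mode this is exactly
#' the arithmetic mean of the internal distributions (law of total
#' expectation over vote counts). In deterministic mode it is the
#' distribution of the tie-broken plurality winner, computed by exhaustive
#' enumeration (over multinomial count vectors when all agents share one
#' distribution, over all `n_actions^N` vote profiles otherwise, for
#' `N <= 8`) and by Monte Carlo above that.
#'
#' @param dists numeric matrix, one row per internal agent, columns the
#'   shared action space (a single vector is recycled to one agent).
#' @param mode `"probabilistic"` or `"deterministic"`.
#' @param n_mc Monte Carlo sample size for the large-`N` heterogeneous
#'   deterministic case.
#' @return probability vector over group actions.
#' @export
group_action_law <- function(dists, mode = c("probabilistic", "deterministic"),
                             n_mc = 1e5) {
  mode <- match.arg(mode)
  if (is.vector(dists)) dists <- matrix(dists, nrow = 1)
  N <- nrow(dists)
  K <- ncol(dists)
  if (mode == "probabilistic") return(colMeans(dists))

  winner_share <- function(counts) {
    top <- which(counts == max(counts))
    share <- numeric(K)
    share[top] <- 1 / length(top)
    share
  }

  identical_rows <- all(abs(sweep(dists, 2, dists[1, ])) < 1e-12)
  if (identical_rows) {
    # enumerate multinomial count vectors recursively (cheap for small K)
    p <- dists[1, ]
    out <- numeric(K)
    recurse <- function(k, remaining, counts) {
      if (k == K) {
        counts[K] <- remaining
        out <<- out + stats::dmultinom(counts, prob = p) * winner_share(counts)
        return(invisible())
      }
      for (n_k in 0:remaining) {
        counts[k] <- n_k
        recurse(k + 1, remaining - n_k, counts)
      }
    }
    recurse(1, N, integer(K))
    return(out)
  }

  if (N <= 8) {
    profiles <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
    out <- numeric(K)
    for (r in seq_len(nrow(profiles))) {
      votes <- profiles[r, ]
      pr <- prod(dists[cbind(seq_len(N), votes)])
      out <- out + pr * winner_share(tabulate(votes, nbins = K))
    }
    return(out)
  }

  # heterogeneous, large N: Monte Carlo
  out <- numeric(K)
  for (rep in seq_len(n_mc)) {
    votes <- vapply(seq_len(N), function(i)
      sample.int(K, 1L, prob = dists[i, ]), 0L)
    out <- out + winner_share(tabulate(votes, nbins = K))
  }
  out / n_mc
}

#' Simulate a single agent on the bandit
#'
#' Convenience wrapper: a "group" of one internal agent with probabilistic
#' aggregation, which is exactly the single agent's action-perception loop
#' (used by the parameter-recovery study).
#'
#' @param model a [generative_model()].
#' @param bandit a [bandit_config()].
#' @param n_trials number of trials.
#' @param seed optional integer seed.
#' @return a `group_trajectory` with `n_internal = 1`.
#' @export
simulate_agent <- function(model, bandit, n_trials, seed = NULL) {
  run_group_simulation(group_config(list(model), "probabilistic", n_trials),
                       bandit, seed = seed)
}
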