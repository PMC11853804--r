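# Guard used inside logarithms so that (near-)zero preferences or beliefs
# leave the expected free energy finite. For the strictly positive
# distributions used throughout the package it changes nothing.
.log_guard <- 1e-16

logsafe <- function(x) log(pmax(x, .log_guard))

#' State inference for a categorical hidden state
#'
#' Perception under the model: given an observation and a prior belief over
#' hidden states, returns the belief with minimal variational free energy
#' \eqn{F[q(s), o] = KL(q(s) || p(o, s))}. For a single unconstrained
#' categorical factor the variational minimum is the exact Bayes posterior
#' \eqn{q(s) \propto A[o, s] \, prior(s)}, so that is what is computed; the
#' decomposition \eqn{F = KL(q || p(s|o)) + surprise} then gives
#' `free_energy == surprise` at the returned posterior, which is kept as a
#' numerical contract (and tested).
#'
#' @param model a [generative_model()].
#' @param observation observation index (row of `A`).
#' @param prior_belief probability vector over hidden states.
#' @return An object of class `perception_result`: list with `posterior`,
#'   `free_energy` (F evaluated at the posterior) and `surprise`
#'   (\eqn{-\log p(o)}).
#' @export
infer_states <- function(model, observation, prior_belief) {
  stopifnot(observation >= 1, observation <= model$n_obs)
  lik <- model$A[observation, ]
  joint <- lik * prior_belief
  p_o <- sum(joint)
  if (p_o <= 0)
    stop(sprintf("observation %d is impossible under the prior belief (p(o) = 0)",
                 observation))
  posterior <- joint / p_o
  structure(
    list(posterior = posterior,
         free_energy = variational_free_energy(posterior, model, observation,
                                               prior_belief),
         surprise = -log(p_o)),
    class = "perception_result"
  )
}

#' Variational free energy of an arbitrary belief
#'
#' Evaluates \eqn{F[q(s), o] = KL(q(s) || p(o, s)) =
#' \sum_s q(s) (\log q(s) - \log(A[o,s] D(s)))} for any candidate belief
#' `q`, with `prior_belief` playing the role of the state prior. `F` is
#' minimised (and equals the surprise) exactly when `q` is the Bayes
#' posterior returned by [infer_states()].
#'
#' @param q candidate probability vector over hidden states.
#' @inheritParams infer_states
#' @return scalar free energy.
#' @export
variational_free_energy <- function(q, model, observation, prior_belief) {
  lj <- logsafe(model$A[observation, ] * prior_belief)
  nz <- q > 0
  sum(q[nz] * (log(q[nz]) - lj[nz]))
}

#' Predicted state and observation trajectory under a policy
#'
#' Forward pass through the transition and observation models: starting from
#' the current belief, each action of the policy propagates the predicted
#' state distribution through its `B` slice, and `A` maps it to a predicted
#' observation distribution.
#'
#' @param model a [generative_model()].
#' @param belief probability vector over hidden states.
#' @param policy integer vector of action indices (one row of
#'   `model$policies`).
#' @return list with `states` and `observations`: matrices with one row per
#'   policy step, rows summing to 1.
#' @export
predict_under_policy <- function(model, belief, policy) {
  len <- length(policy)
  states <- matrix(0, len, model$n_states)
  observations <- matrix(0, len, model$n_obs)
  s <- belief
  for (tau in seq_len(len)) {
    s <- drop(model$B[, , policy[tau]] %*% s)
    states[tau, ] <- s
    observations[tau, ] <- drop(model$A %*% s)
  }
  list(states = states, observations = observations)
}

#' Expected free energy of a policy
#'
#' For each step of the policy the predicted outcome distribution is scored
#' against the preference prior (pragmatic value,
#' \eqn{\sum_o \tilde o(o) \log C(o)}) and the expected belief update is
#' scored as information gain (the expected KL divergence between the
#' posterior and prior state beliefs under predicted observations, i.e. the
#' mutual information between predicted states and outcomes). The expected
#' free energy is the negative sum of the two, accumulated over policy
#' steps: \eqn{G = -\sum_\tau (info\_gain_\tau + pragmatic_\tau)}.
#'
#' With a deterministic transition model and accurate `A` (the bandit
#' default) predicted states are delta distributions, information gain is
#' identically zero, and policies are ranked by pragmatic value alone.
#'
#' @inheritParams predict_under_policy
#' @return An object of class `policy_evaluation`: list with `G`,
#'   `info_gain` and `pragmatic_value`.
#' @export
expected_free_energy <- function(model, belief, policy) {
  pred <- predict_under_policy(model, belief, policy)
  logC <- logsafe(model$C)
  info_gain <- 0
  pragmatic <- 0
  for (tau in seq_along(policy)) {
    s_pred <- pred$states[tau, ]
    o_pred <- pred$observations[tau, ]
    pragmatic <- pragmatic + sum(o_pred * logC)
    for (o in seq_len(model$n_obs)) {
      if (o_pred[o] <= 0) next
      post <- model$A[o, ] * s_pred / o_pred[o]
      nz <- post > 0
      info_gain <- info_gain +
        o_pred[o] * sum(post[nz] * (log(post[nz]) - logsafe(s_pred[nz])))
    }
  }
  structure(
    list(G = -(info_gain + pragmatic),
         info_gain = info_gain,
         pragmatic_value = pragmatic),
    class = "policy_evaluation"
  )
}

#' Evaluate every policy of a model from a given belief
#'
#' @inheritParams predict_under_policy
#' @return data.frame with one row per policy (in `model$policies` order)
#'   and columns `G`, `info_gain`, `pragmatic_value`.
#' @export
evaluate_policies <- function(model, belief) {
  ev <- lapply(seq_len(model$n_policies), function(i)
    expected_free_energy(model, belief, model$policies[i, ]))
  data.frame(
    G = vapply(ev, `[[`, 0, "G"),
    info_gain = vapply(ev, `[[`, 0, "info_gain"),
    pragmatic_value = vapply(ev, `[[`, 0, "pragmatic_value")
  )
}

#' Posterior over policies
#'
#' A softmax (precision `gamma`) is applied to the negative expected free
#' energies and multiplied with the habit prior `E`:
#' `normalize(E * softmax(-gamma * G))`.
#'
#' @param G_values numeric vector of expected free energies, one per policy.
#' @param gamma non-negative precision.
#' @param E probability vector over policies.
#' @return probability vector over policies.
#' @export
policy_posterior <- function(G_values, gamma, E) {
  stopifnot(length(G_values) == length(E), all(is.finite(G_values)))
  lw <- -gamma * G_values
  sm <- exp(lw - max(lw))
  p <- E * sm
  p / sum(p)
}

#' Marginalize a policy posterior onto the next action
#'
#' @param policy_post probability vector over policies.
#' @param policies integer policy matrix (rows are policies).
#' @param n_actions number of actions.
#' @return probability vector `q(a)` over next actions: the summed posterior
#'   mass of all policies whose first action is `a`.
#' @export
action_marginal <- function(policy_post, policies, n_actions) {
  stopifnot(length(policy_post) == nrow(policies))
  q <- numeric(n_actions)
  first <- policies[, 1L]
  for (a in seq_len(n_actions)) q[a] <- sum(policy_post[first == a])
  q
}

#' Action-precision softmax
#'
#' Final action selection probabilities \eqn{p(a) \propto q(a)^\alpha}
#' (a softmax over \eqn{\alpha \log q(a)}). `alpha = 1` reproduces `q`
#' exactly (probability matching); `alpha = 0` is uniform; `alpha -> Inf`
#' concentrates on the modal action. Actions with `q(a) = 0` keep
#' probability 0 for `alpha > 0`.
#'
#' @param q_actions probability vector over actions.
#' @param alpha non-negative action precision.
#' @return probability vector over actions.
#' @export
action_probabilities <- function(q_actions, alpha) {
  if (alpha < 0) stop("alpha must be non-negative")
  if (alpha == 0) return(rep(1 / length(q_actions), length(q_actions)))
  p <- numeric(length(q_actions))
  sup <- q_actions > 0
  lw <- alpha * log(q_actions[sup])
  w <- exp(lw - max(lw))
  p[sup] <- w / sum(w)
  p
}

#' Agent state carried between trials
#'
#' @param belief probability vector over hidden states.
#' @param last_action previously selected action index, or `NULL` before the
#'   first trial.
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(belief, last_action = NULL) {
  if (abs(sum(belief) - 1) > 1e-12 || any(belief < 0))
    stop("belief must be a probability distribution")
  structure(list(belief = belief, last_action = last_action),
            class = "agent_state")
}

# Marginal next-action distribution from a belief, with optional memoisation.
# The cache (an environment) is keyed on the belief vector; entries are exact
# recomputations, so caching never changes results -- it only avoids
# re-evaluating policies for beliefs already seen (in the bandit task beliefs
# take at most n_states + 1 distinct values).
action_marginal_given_belief <- function(model, belief, cache = NULL) {
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(format(belief, digits = 15), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  ev <- evaluate_policies(model, belief)
  post <- policy_posterior(ev$G, model$gamma, model$E)
  qa <- action_marginal(post, model$policies, model$n_actions)
  if (!is.null(cache)) cache[[key]] <- qa
  qa
}

#' One action-perception cycle of an agent
#'
#' If an observation is supplied, the belief is first propagated through the
#' transition model under the agent's last action and updated by
#' [infer_states()]; on the first trial (`observation = NULL`) the agent
#' acts from its state prior. All policies are then evaluated, the policy
#' posterior formed and marginalized onto the next action, the
#' action-precision softmax applied, and an action sampled from the
#' resulting distribution using R's global RNG (deterministic under
#' `set.seed()`).
#'
#' @param model a [generative_model()].
#' @param state an [agent_state()].
#' @param observation observation index, or `NULL` on the first trial.
#' @param cache optional environment memoising policy evaluations per
#'   belief (exact; used by the group simulator for speed).
#' @return list with `action` (sampled index), `probs` (the action
#'   distribution it was sampled from) and `state` (updated `agent_state`).
#' @export
agent_step <- function(model, state, observation = NULL, cache = NULL) {
  belief <- state$belief
  if (!is.null(observation)) {
    prior <- if (is.null(state$last_action)) belief
             else drop(model$B[, , state$last_action] %*% belief)
    belief <- infer_states(model, observation, prior)$posterior
  }
  qa <- action_marginal_given_belief(model, belief, cache)
  p <- action_probabilities(qa, model$alpha)
  a <- sample.int(model$n_actions, 1L, prob = p)
  list(action = a, probs = p, state = agent_state(belief, a))
}
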