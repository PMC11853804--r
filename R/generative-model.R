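#' Construct a discrete POMDP generative model
#'
#' Bundles the five matrices of a discrete-state, discrete-time POMDP
#' generative model together with the policy-selection precisions. The model
#' is the standard active-inference parameterisation: an observation
#' likelihood `A`, per-action transition matrices `B`, a preference prior `C`
#' over observations, a state prior `D`, and a habit prior `E` over policies.
#'
#' Policies are all ordered sequences of `policy_len` actions, enumerated
#' lexicographically (see [enumerate_policies()]); `E` is indexed in that
#' order.
#'
#' @param A numeric matrix, `n_obs x n_states`; column `s` is the
#'   distribution over observations given hidden state `s`.
#' @param B numeric array, `n_states x n_states x n_actions`;
#'   `B[s2, s1, u]` is the probability of moving to state `s2` from `s1`
#'   under action `u`. Every `B[, s1, u]` must be a distribution.
#' @param C numeric probability vector over observations (prior preferences).
#' @param D numeric probability vector over hidden states (state prior).
#' @param E numeric probability vector over policies (habits); default
#'   uniform over all `n_actions^policy_len` policies.
#' @param policy_len positive integer, number of future actions per policy.
#' @param gamma non-negative policy-posterior precision (inverse temperature
#'   of the softmax over negative expected free energies).
#' @param alpha non-negative action precision (inverse temperature of the
#'   final softmax over marginal action probabilities; `alpha = 1` is
#'   probability matching).
#'
#' @return An object of class `generative_model`.
#' @seealso [mab_generative_model()] for the three-armed-bandit default.
#' @export
generative_model <- function(A, B, C, D, E = NULL, policy_len = 2,
                             gamma = 16, alpha = 1) {
  A <- as.matrix(A)
  dimnames(A) <- NULL
  if (!is.array(B) || length(dim(B)) != 3L)
    stop("B must be a 3-d array [s', s, u]")
  dimnames(B) <- NULL
  n_obs <- nrow(A)
  n_states <- ncol(A)
  n_actions <- dim(B)[3L]
  if (dim(B)[1L] != n_states || dim(B)[2L] != n_states)
    stop("B state dimensions must match ncol(A)")
  if (length(C) != n_obs) stop("C must have one entry per observation")
  if (length(D) != n_states) stop("D must have one entry per hidden state")
  if (policy_len < 1 || policy_len != round(policy_len))
    stop("policy_len must be a positive integer")
  if (gamma < 0) stop("gamma must be non-negative")
  if (alpha < 0) stop("alpha must be non-negative")

  check_dist <- function(x, what) {
    if (any(x < 0) || any(x > 1) || abs(sum(x) - 1) > 1e-12)
      stop(sprintf("%s must be a probability distribution (sums to 1 within 1e-12)", what))
  }
  for (s in seq_len(n_states)) check_dist(A[, s], sprintf("A[, %d]", s))
  for (u in seq_len(n_actions)) for (s in seq_len(n_states))
    check_dist(B[, s, u], sprintf("B[, %d, %d]", s, u))
  check_dist(C, "C")
  check_dist(D, "D")

  policies <- enumerate_policies(n_actions, policy_len)
  n_policies <- nrow(policies)
  if (is.null(E)) E <- rep(1 / n_policies, n_policies)
  if (length(E) != n_policies)
    stop(sprintf("E must have length n_actions^policy_len = %d", n_policies))
  check_dist(E, "E")

  structure(
    list(A = A, B = B, C = as.numeric(C), D = as.numeric(D), E = as.numeric(E),
         policy_len = as.integer(policy_len), gamma = gamma, alpha = alpha,
         n_obs = n_obs, n_states = n_states, n_actions = n_actions,
         policies = policies, n_policies = n_policies),
    class = "generative_model"
  )
}

#' @export
print.generative_model <- function(x, ...) {
  cat(sprintf(
    "POMDP generative model: %d states, %d observations, %d actions\n",
    x$n_states, x$n_obs, x$n_actions))
  cat(sprintf("  %d policies of length %d; gamma = %g, alpha = %g\n",
              x$n_policies, x$policy_len, x$gamma, x$alpha))
  invisible(x)
}

#' Enumerate all fixed-length policies
#'
#' Returns every ordered sequence of `policy_len` actions, in lexicographic
#' order of action indices: `(1,1), (1,2), ..., (n,n)`. The habit prior `E`
#' of a [generative_model()] is indexed in this order.
#'
#' @param n_actions positive integer.
#' @param policy_len positive integer.
#' @return Integer matrix with `n_actions^policy_len` rows and `policy_len`
#'   columns; row `i` is the i-th policy.
#' @export
enumerate_policies <- function(n_actions, policy_len) {
  stopifnot(n_actions >= 1, policy_len >= 1)
  idx <- 0:(n_actions^policy_len - 1)
  out <- matrix(0L, length(idx), policy_len)
  for (j in policy_len:1) {
    out[, j] <- as.integer(idx %% n_actions + 1)
    idx <- idx %/% n_actions
  }
  out
}

#' Default generative model for the three-armed bandit task
#'
#' One hidden state per bandit arm, binary outcomes, and deterministic
#' "motor" transitions: action `u` moves the hidden state to arm `u` with
#' certainty. The agent is equipped with accurate beliefs about the outcome
#' probabilities (column `s` of `A` equals the environment's outcome
#' distribution for arm `s`), modelling behaviour after learning has
#' converged; consequently information gain is identically zero and action
#' selection is driven by pragmatic value alone.
#'
#' The preference prior is `C = (preference, 1 - preference)` over outcomes
#' 1 and 2. The default `preference = 0.625` is calibrated analytically so
#' that, under `gamma = 16` and policy length 2, the marginal action
#' distribution has a best-vs-other-arm log-odds of
#' `gamma * 0.6 * logit(preference) = 4.90`, which makes action precision
#' `alpha` behaviourally discriminable on `[0, 1]` and unidentifiable above
#' about 1 (see the package vignette).
#'
#' @param outcome1_probs per-arm probability of outcome 1 (defines `A`).
#' @param preference preferred probability of outcome 1 in `C`.
#' @param gamma,alpha,policy_len as in [generative_model()].
#' @return A `generative_model` with uniform `D` and `E`.
#' @export
mab_generative_model <- function(outcome1_probs = c(0.8, 0.2, 0.2),
                                 preference = 0.625,
                                 gamma = 16, alpha = 1, policy_len = 2) {
  n_arms <- length(outcome1_probs)
  if (any(outcome1_probs < 0) || any(outcome1_probs > 1))
    stop("outcome1_probs must lie in [0, 1]")
  if (preference <= 0 || preference >= 1)
    stop("preference must lie in (0, 1)")
  A <- rbind(outcome1_probs, 1 - outcome1_probs)
  rownames(A) <- NULL
  B <- array(0, dim = c(n_arms, n_arms, n_arms))
  for (u in seq_len(n_arms)) B[u, , u] <- 1  # action u selects arm u exactly
  generative_model(
    A = A, B = B,
    C = c(preference, 1 - preference),
    D = rep(1 / n_arms, n_arms),
    policy_len = policy_len, gamma = gamma, alpha = alpha
  )
}
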