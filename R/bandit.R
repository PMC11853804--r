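#' Multi-armed bandit configuration
#'
#' A stationary bandit with binary outcomes: pulling arm `k` yields
#' outcome 1 with probability `outcome1_probs[k]`, otherwise outcome 2.
#' The default is the three-armed task with probabilities 0.8, 0.2, 0.2
#' for the (generally preferred) outcome 1.
#'
#' @param outcome1_probs numeric vector of per-arm probabilities of
#'   outcome 1, each in `[0, 1]`.
#' @return An object of class `bandit_config`.
#' @export
bandit_config <- function(outcome1_probs = c(0.8, 0.2, 0.2)) {
  if (length(outcome1_probs) < 1 ||
      any(outcome1_probs < 0) || any(outcome1_probs > 1))
    stop("outcome1_probs must be probabilities in [0, 1]")
  structure(list(outcome1_probs = as.numeric(outcome1_probs),
                 n_arms = length(outcome1_probs)),
            class = "bandit_config")
}

#' Default three-armed bandit
#'
#' @return `bandit_config(c(0.8, 0.2, 0.2))`.
#' @export
mab_bandit <- function() bandit_config(c(0.8, 0.2, 0.2))

#' Pull a bandit arm
#'
#' Samples one binary outcome from the configured arm using R's global RNG
#' (reproducible under `set.seed()`).
#'
#' @param config a [bandit_config()].
#' @param arm arm index.
#' @return integer outcome: `1L` with probability `outcome1_probs[arm]`,
#'   else `2L`.
#' @export
pull <- function(config, arm) {
  if (length(arm) != 1 || is.na(arm) || arm < 1 || arm > config$n_arms ||
      arm != round(arm))
    stop(sprintf("invalid arm index: %s (bandit has %d arms)",
                 paste(arm, collapse = ","), config$n_arms))
  if (stats::runif(1) < config$outcome1_probs[arm]) 1L else 2L
}
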