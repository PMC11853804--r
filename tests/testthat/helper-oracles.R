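# Independent test-side oracles. These deliberately re-derive quantities from
# first principles (closed forms, exhaustive enumeration) without touching the
# package's own computational paths.

# Action distribution of the default bandit agent, derived from scratch:
# with a deterministic transition model the predicted outcome distribution of
# a policy depends only on its arms, information gain is zero, and the policy
# posterior factorises over steps. Valid for the accurate-beliefs bandit model
# with uniform D and E only.
oracle_action_dist <- function(outcome1_probs = c(0.8, 0.2, 0.2),
                               preference = 0.625, gamma = 16, alpha = 1,
                               policy_len = 2) {
  n <- length(outcome1_probs)
  pv_arm <- outcome1_probs * log(preference) +
    (1 - outcome1_probs) * log(1 - preference)
  pols <- as.matrix(expand.grid(rep(list(seq_len(n)), policy_len)))
  pv <- rowSums(matrix(pv_arm[pols], nrow(pols)))
  w <- exp(gamma * (pv - max(pv)))
  post <- w / sum(w)
  q <- vapply(seq_len(n), function(a) sum(post[pols[, 1] == a]), 0)
  pw <- q^alpha
  pw / sum(pw)
}

# Exact tie-broken plurality law by exhaustive enumeration of all vote
# profiles (use only for a handful of voters).
oracle_majority_law <- function(dists) {
  N <- nrow(dists)
  K <- ncol(dists)
  profiles <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  out <- numeric(K)
  for (r in seq_len(nrow(profiles))) {
    v <- profiles[r, ]
    counts <- tabulate(v, nbins = K)
    top <- which(counts == max(counts))
    out[top] <- out[top] +
      prod(dists[cbind(seq_len(N), v)]) / length(top)
  }
  out
}

random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# Small random POMDP for brute-force inference checks.
random_small_model <- function() {
  n_s <- sample(2:4, 1)
  n_o <- sample(2:3, 1)
  n_u <- sample(1:3, 1)
  A <- vapply(seq_len(n_s), function(s) random_simplex(n_o), numeric(n_o))
  B <- array(0, c(n_s, n_s, n_u))
  for (u in seq_len(n_u)) for (s in seq_len(n_s)) B[, s, u] <- random_simplex(n_s)
  generative_model(A = A, B = B, C = random_simplex(n_o),
                   D = random_simplex(n_s), policy_len = 1, gamma = 4,
                   alpha = 1)
}

# 3-sigma binomial envelope check for empirical frequencies.
expect_freq_within_3sigma <- function(freq, prob, n) {
  for (k in seq_along(prob)) {
    tol <- 3 * sqrt(max(prob[k] * (1 - prob[k]), 1e-12) / n) + 1e-12
    expect_lt(abs(freq[k] - prob[k]), tol + 1e-9)
  }
}

make_empty_trajectory <- function() {
  group_trajectory(data.frame(trial = integer(0), group_action = integer(0),
                              observation = integer(0)))
}
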