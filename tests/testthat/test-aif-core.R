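test_that("enumerate_policies is exhaustive and lexicographic", {
  p32 <- enumerate_policies(3, 2)
  expect_equal(nrow(p32), 9L)
  expect_equal(p32[1, ], c(1L, 1L))
  expect_equal(p32[9, ], c(3L, 3L))
  expect_equal(nrow(unique(p32)), 9L)
  expect_equal(enumerate_policies(2, 1), matrix(c(1L, 2L), 2, 1))
  expect_equal(enumerate_policies(1, 3), matrix(c(1L, 1L, 1L), 1, 3))
})

test_that("infer_states returns the exact categorical posterior", {
  m <- mab_generative_model()
  # informative likelihood, uniform prior: hand Bayes-rule oracle
  pr <- infer_states(m, 1, rep(1 / 3, 3))
  expect_equal(pr$posterior, c(2 / 3, 1 / 6, 1 / 6), tolerance = 1e-12)
  expect_equal(pr$surprise, -log(0.4), tolerance = 1e-12)
  expect_equal(pr$free_energy, pr$surprise, tolerance = 1e-10)
  # uninformative likelihood leaves the prior untouched
  mu <- mab_generative_model(outcome1_probs = c(0.4, 0.4, 0.4))
  expect_equal(infer_states(mu, 1, rep(1 / 3, 3))$posterior, rep(1 / 3, 3))
  # delta prior is preserved
  expect_equal(infer_states(m, 2, c(0, 1, 0))$posterior, c(0, 1, 0))
  # impossible observation fails loudly, naming the observation
  mz <- mab_generative_model(outcome1_probs = c(1, 0.2, 0.2))
  expect_error(infer_states(mz, 2, c(1, 0, 0)), "observation 2")
})

test_that("posterior matches brute-force joint normalization on random models", {
  set.seed(11)
  for (rep in 1:50) {
    m <- random_small_model()
    prior <- random_simplex(m$n_states)
    o <- sample.int(m$n_obs, 1)
    joint <- m$A[o, ] * prior          # brute-force p(o, s) table row
    pr <- infer_states(m, o, prior)
    expect_equal(pr$posterior, joint / sum(joint), tolerance = 1e-10)
    expect_equal(pr$free_energy, -log(sum(joint)), tolerance = 1e-10)
  }
})

test_that("free energy is minimized at the returned posterior", {
  set.seed(12)
  m <- random_small_model()
  prior <- random_simplex(m$n_states)
  pr <- infer_states(m, 1, prior)
  f_star <- pr$free_energy
  for (rep in 1:100) {
    q <- random_simplex(m$n_states)
    expect_gte(variational_free_energy(q, m, 1, prior), f_star - 1e-12)
  }
  # and a genuinely perturbed belief is strictly worse
  q <- pr$posterior * c(1.3, rep(1, m$n_states - 1))
  q <- q / sum(q)
  expect_gt(variational_free_energy(q, m, 1, prior), f_star)
})

test_that("predict_under_policy propagates beliefs through B and A", {
  m <- mab_generative_model()
  # deterministic B: delta belief stays delta, following the actions
  pred <- predict_under_policy(m, c(1, 0, 0), c(2L, 3L))
  expect_equal(pred$states[1, ], c(0, 1, 0))
  expect_equal(pred$states[2, ], c(0, 0, 1))
  expect_equal(pred$observations[1, ], c(0.2, 0.8))
  expect_equal(rowSums(pred$states), c(1, 1))
  expect_equal(rowSums(pred$observations), c(1, 1))
  # identity B keeps the belief fixed
  B <- array(0, c(2, 2, 2))
  B[, , 1] <- diag(2)
  B[, , 2] <- diag(2)
  mi <- generative_model(A = matrix(c(0.7, 0.3, 0.4, 0.6), 2),
                         B = B, C = c(0.5, 0.5), D = c(0.5, 0.5),
                         policy_len = 2)
  b <- c(0.3, 0.7)
  pred <- predict_under_policy(mi, b, c(1L, 2L))
  expect_equal(pred$states[1, ], b)
  expect_equal(pred$states[2, ], b)
})

test_that("expected free energy decomposes into info gain and pragmatic value", {
  m <- mab_generative_model()
  ev <- evaluate_policies(m, m$D)
  # deterministic B + accurate A: zero information gain for every policy
  expect_equal(ev$info_gain, rep(0, 9), tolerance = 1e-12)
  expect_equal(ev$G, -(ev$info_gain + ev$pragmatic_value), tolerance = 1e-10)
  # single-step policy, predicted o = (0.8, 0.2) against C = (0.8, 0.2)
  m2 <- mab_generative_model(preference = 0.8, policy_len = 1)
  e <- expected_free_energy(m2, m2$D, 1L)
  expect_equal(e$pragmatic_value, 0.8 * log(0.8) + 0.2 * log(0.2),
               tolerance = 1e-12)
  # uniform C: all policies equal, so the policy posterior collapses to E
  mu <- mab_generative_model(preference = 0.5)
  evu <- evaluate_policies(mu, mu$D)
  expect_equal(diff(range(evu$G)), 0, tolerance = 1e-12)
  post <- policy_posterior(evu$G, mu$gamma, mu$E)
  expect_equal(post, mu$E, tolerance = 1e-12)
})

test_that("policy posterior is normalize(E * softmax(-gamma G))", {
  E <- c(0.5, 0.5)
  expect_equal(policy_posterior(c(0.3, 1.2), 0, E), E)
  expect_equal(policy_posterior(c(0.7, 0.7), 16, E), E)
  gamma <- 3.5
  expect_equal(policy_posterior(c(0, log(2) / gamma), gamma, E),
               c(2 / 3, 1 / 3), tolerance = 1e-12)
  # a non-uniform habit prior reweights multiplicatively
  expect_equal(policy_posterior(c(1, 1), 16, c(0.9, 0.1)), c(0.9, 0.1))
})

test_that("action_marginal sums policy mass by first action", {
  pols <- enumerate_policies(3, 2)
  expect_equal(action_marginal(rep(1 / 9, 9), pols, 3), rep(1 / 3, 3))
  delta <- numeric(9)
  delta[which(pols[, 1] == 2 & pols[, 2] == 1)] <- 1
  expect_equal(action_marginal(delta, pols, 3), c(0, 1, 0))
  pols3 <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L))
  expect_equal(action_marginal(c(0.5, 0.3, 0.2), pols3, 2), c(0.8, 0.2))
})

test_that("action precision softmax behaves across the alpha range", {
  q <- c(0.5, 0.25, 0.25)
  expect_equal(action_probabilities(q, 1), q, tolerance = 1e-12)
  expect_equal(action_probabilities(q, 0), rep(1 / 3, 3))
  expect_equal(action_probabilities(q, 2), c(2 / 3, 1 / 6, 1 / 6),
               tolerance = 1e-12)
  expect_error(action_probabilities(q, -0.1), "non-negative")
  # zero-probability actions stay at zero for alpha > 0
  expect_equal(action_probabilities(c(0.6, 0.4, 0), 0.5)[3], 0)
  # modal-action probability is non-decreasing in alpha, with the right limits
  qm <- c(0.45, 0.35, 0.2)
  modal <- vapply(seq(0, 8, by = 0.25),
                  function(a) action_probabilities(qm, a)[1], 0)
  expect_true(all(diff(modal) >= -1e-12))
  expect_equal(modal[1], 1 / 3)
  expect_equal(action_probabilities(qm, 1e6), c(1, 0, 0))
  # all outputs are distributions
  for (a in c(0, 0.3, 1, 5)) {
    p <- action_probabilities(qm, a)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(all(p >= 0))
  }
})

test_that("agent_step composes the loop and is seed-deterministic", {
  # uniform preferences and habits: uniform action distribution always
  mu <- mab_generative_model(preference = 0.5)
  st <- agent_state(mu$D)
  set.seed(1)
  s1 <- agent_step(mu, st)
  expect_equal(s1$probs, rep(1 / 3, 3), tolerance = 1e-12)
  s2 <- agent_step(mu, s1$state, observation = 2)
  expect_equal(s2$probs, rep(1 / 3, 3), tolerance = 1e-12)

  # same seed, same inputs -> identical action and updated state
  m <- mab_generative_model(alpha = 0.7)
  set.seed(99)
  a1 <- agent_step(m, agent_state(m$D))
  set.seed(99)
  a2 <- agent_step(m, agent_state(m$D))
  expect_identical(a1$action, a2$action)
  expect_equal(a1$state$belief, a2$state$belief)

  # huge alpha: sampled action is the argmax essentially always
  mh <- mab_generative_model(alpha = 1e6)
  set.seed(5)
  st <- agent_state(mh$D)
  acts <- integer(1e4)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(1e4)) {
    s <- agent_step(mh, st, cache = cache)
    acts[i] <- s$action
  }
  expect_gte(mean(acts == 1L), 0.999)
})
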