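test_that("sensory relay copies the outcome to every internal agent", {
  expect_equal(sensory_relay(1, 5), rep(1L, 5))
  expect_equal(sensory_relay(2, 3), rep(2L, 3))
  expect_equal(sensory_relay(1, 0), integer(0))
})

test_that("aggregate_votes implements both voting mechanisms", {
  expect_error(aggregate_votes(integer(0)), "empty")
  expect_equal(aggregate_votes(c(1L, 1L, 2L), "deterministic", 3), 1L)
  set.seed(3)
  # probabilistic: sampling frequencies match counts/N
  draws <- replicate(1e4, aggregate_votes(c(1L, 1L, 2L, 3L), "probabilistic", 3))
  expect_freq_within_3sigma(tabulate(draws, 3) / 1e4, c(0.5, 0.25, 0.25), 1e4)
  # deterministic tie: uniform among tied maxima
  ties <- replicate(1e4, aggregate_votes(c(1L, 2L), "deterministic", 3))
  expect_freq_within_3sigma(tabulate(ties, 3) / 1e4, c(0.5, 0.5, 0), 1e4)
})

test_that("group_action_law gives exact aggregator laws", {
  # probabilistic: arithmetic mean of the internal distributions
  p <- c(0.6, 0.3, 0.1)
  expect_equal(group_action_law(p, "probabilistic"), p)
  two <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(group_action_law(two, "probabilistic"), c(0.5, 0.5, 0))
  # deterministic N = 2 with opposed delta voters: pure tie-break
  expect_equal(group_action_law(two, "deterministic"), c(0.5, 0.5, 0))
  # identical-agent multinomial enumeration agrees with the exhaustive
  # profile-level oracle
  p3 <- matrix(rep(c(0.5, 0.3, 0.2), 3), 3, byrow = TRUE)
  expect_equal(group_action_law(p3, "deterministic"), oracle_majority_law(p3),
               tolerance = 1e-12)
  # heterogeneous route too
  het <- rbind(c(0.7, 0.2, 0.1), c(0.2, 0.5, 0.3), c(0.1, 0.1, 0.8))
  expect_equal(group_action_law(het, "deterministic"),
               oracle_majority_law(het), tolerance = 1e-12)
})

test_that("deterministic aggregation sharpens the modal action with N", {
  p <- c(0.6, 0.25, 0.15)
  modal_prob <- vapply(c(1, 3, 5, 9), function(N) {
    group_action_law(matrix(rep(p, N), N, byrow = TRUE), "deterministic")[1]
  }, 0)
  expect_gt(modal_prob[2], p[1])       # sharper than probabilistic voting
  expect_true(all(diff(modal_prob) > 0))  # and increasingly so with N
})

test_that("a group of one behaves exactly like its internal agent", {
  m <- mab_generative_model(alpha = 0.6)
  traj <- run_group_simulation(group_config(list(m), "probabilistic", 50),
                               mab_bandit(), seed = 21)
  expect_identical(traj$trials$group_action, as.integer(traj$votes[, 1]))
  trajd <- run_group_simulation(group_config(list(m), "deterministic", 50),
                                mab_bandit(), seed = 21)
  expect_identical(trajd$trials$group_action, as.integer(trajd$votes[, 1]))
})

test_that("group simulation is reproducible and well-formed", {
  m <- mab_generative_model(alpha = 0.4)
  g <- group_config(rep(list(m), 4), "probabilistic", 30)
  t1 <- run_group_simulation(g, mab_bandit(), seed = 8)
  t2 <- run_group_simulation(g, mab_bandit(), seed = 8)
  expect_identical(t1$trials, t2$trials)
  expect_identical(t1$votes, t2$votes)
  expect_equal(nrow(t1$trials), 30)
  expect_true(all(t1$trials$group_action %in% 1:3))
  expect_true(all(t1$trials$observation %in% 1:2))
  # deterministic mode: the group action is always among the votes
  gd <- group_config(rep(list(m), 5), "deterministic", 30)
  td <- run_group_simulation(gd, mab_bandit(), seed = 9)
  expect_true(all(vapply(seq_len(30), function(t)
    td$trials$group_action[t] %in% td$votes[t, ], TRUE)))
})

test_that("blanket states alone determine the fitting likelihood", {
  m <- mab_generative_model(alpha = 0.5)
  traj <- run_group_simulation(group_config(rep(list(m), 3), "probabilistic", 40),
                               mab_bandit(), seed = 13)
  stripped <- group_trajectory(traj$trials)  # no votes, models, or bandit
  expect_equal(replay_log_likelihood(stripped, m, 0.7),
               replay_log_likelihood(traj, m, 0.7), tolerance = 1e-12)
})
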