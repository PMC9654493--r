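test_that("policy forward pass: symmetric head, determinism, hand network", {
  set.seed(1)
  pol <- mlp(c(4, 8, 8, 3), head = "sigmoid")
  # zero weights and biases: all probabilities 0.5
  z <- pol
  z$W <- lapply(z$W, function(w) w * 0)
  z$b <- lapply(z$b, function(b) b * 0)
  expect_equal(policy_forward(z, rnorm(4)), rep(0.5, 3))
  # identical observations give identical outputs
  obs <- rnorm(4)
  expect_identical(policy_forward(pol, obs), policy_forward(pol, obs))
  # hand-set single-hidden-unit network traced through tanh and sigmoid
  hand <- mlp(c(1, 1, 1), head = "sigmoid")
  hand$W[[1]][1, 1] <- 2; hand$b[[1]][1] <- 0.5
  hand$W[[2]][1, 1] <- -1.5; hand$b[[2]][1] <- 0.25
  x <- 0.3
  expected <- 1 / (1 + exp(-(0.25 - 1.5 * tanh(2 * 0.3 + 0.5))))
  expect_equal(policy_forward(hand, x), expected, tolerance = 1e-12)
  # dimension mismatch rejected
  expect_error(policy_forward(pol, rnorm(5)), "dimension")
})

test_that("action sampling: Bernoulli statistics and joint log-probability", {
  set.seed(2)
  # empirical mean over many draws matches the probability
  p <- rep(0.3, 5)
  draws <- replicate(20000, sample_action(p)$action)
  expect_equal(mean(draws), 0.3, tolerance = 0.005)
  # log-probability is the sum of the per-muscle Bernoulli terms
  probs <- c(0.2, 0.9, 0.5)
  sa <- sample_action(probs)
  manual <- sum(sa$action * log(probs) + (1 - sa$action) * log(1 - probs))
  expect_equal(sa$logp, manual, tolerance = 1e-12)
  # fixed seed reproduces the sample
  set.seed(77); a1 <- sample_action(probs)$action
  set.seed(77); a2 <- sample_action(probs)$action
  expect_identical(a1, a2)
})

test_that("probability ratio identities", {
  expect_equal(prob_ratio(-1.3, -1.3), 1)
  expect_equal(prob_ratio(log(2) - 0.7, -0.7), 2, tolerance = 1e-12)
  # ratio of explicit Bernoulli products equals exp of the log difference
  set.seed(4)
  for (i in 1:30) {
    n <- sample(2:10, 1)
    p_new <- runif(n, 0.05, 0.95); p_old <- runif(n, 0.05, 0.95)
    a <- rbinom(n, 1, 0.5)
    lp_new <- sum(a * log(p_new) + (1 - a) * log(1 - p_new))
    lp_old <- sum(a * log(p_old) + (1 - a) * log(1 - p_old))
    direct <- prod(ifelse(a == 1, p_new, 1 - p_new)) /
      prod(ifelse(a == 1, p_old, 1 - p_old))
    expect_equal(prob_ratio(lp_new, lp_old), direct, tolerance = 1e-12)
  }
  expect_error(prob_ratio(Inf, 0), "finite")
})

test_that("clipped surrogate: identities and worked clip examples", {
  # all ratios 1: mean advantage, exactly
  set.seed(5)
  A <- rnorm(50)
  expect_equal(clipped_objective(rep(1, 50), A, 0.2), mean(A))
  # positive-advantage clip: r = 1.5, A = 1, eps = 0.2 -> 1.2
  expect_equal(clipped_objective(1.5, 1, 0.2), 1.2)
  # negative-advantage clip: r = 0.5, A = -1, eps = 0.2 -> -0.8
  expect_equal(clipped_objective(0.5, -1, 0.2), -0.8)
  # pessimism: clipped objective never exceeds the unclipped one when the
  # positive-advantage branch clips
  for (i in 1:50) {
    r <- runif(1, 0, 3); a <- rnorm(1)
    expect_lte(clipped_objective(r, a, 0.2), r * a + 1e-12)
  }
  expect_error(clipped_objective(c(1, 2), 1, 0.2), "length")
})

test_that("generalized advantage estimation against brute force", {
  # trivial: zero rewards and values give zero advantages
  z <- compute_advantages(rep(0, 5), rep(0, 5), rep(FALSE, 5))
  expect_equal(z$advantages, rep(0, 5))
  # single-step, gamma = 1: r + V(s') - V(s)
  one <- compute_advantages(2, 0.5, FALSE, gamma = 1, lambda = 0.95,
                            last_value = 1.5)
  expect_equal(one$advantages, 2 + 1.5 - 0.5)
  # lambda = 1 equals discounted-return-minus-value (brute force)
  set.seed(6)
  r <- rnorm(3); v <- rnorm(3); gamma <- 0.9
  ga <- compute_advantages(r, v, c(FALSE, FALSE, TRUE), gamma, 1, 0)
  brute <- c(r[1] + gamma * r[2] + gamma^2 * r[3] - v[1],
             r[2] + gamma * r[3] - v[2],
             r[3] - v[3])
  expect_equal(ga$advantages, brute, tolerance = 1e-12)
  # returns are advantages plus values
  expect_equal(ga$returns, ga$advantages + v)
  # episode boundaries stop the bootstrap: both halves independent
  r2 <- c(1, 2, 3, 4); v2 <- c(0, 0, 0, 0)
  ga2 <- compute_advantages(r2, v2, c(FALSE, TRUE, FALSE, TRUE), 0.5, 1, 0)
  expect_equal(ga2$advantages, c(1 + 0.5 * 2, 2, 3 + 0.5 * 4, 4))
})

test_that("training is deterministic and frozen at zero learning rate", {
  env <- bandit_env()
  cfg0 <- ppo_config(learning_rate = 0, rollout_length = 32,
                     total_iterations = 3, minibatch_size = 16, seed = 5)
  set.seed(99)
  out <- train_ppo(env, policy_spec(2, 1, 8), cfg0)
  # zero learning rate: parameters bit-identical to a fresh init
  set.seed(99)
  fresh <- {
    set.seed(cfg0$seed)
    mlp(c(2, 8, 1), head = "sigmoid")
  }
  expect_identical(out$policy$W, fresh$W)
  expect_identical(out$policy$b, fresh$b)
  # same seed twice: identical learning curves
  cfg <- ppo_config(learning_rate = 0.01, rollout_length = 64,
                    total_iterations = 4, minibatch_size = 32, seed = 11)
  h1 <- train_ppo(bandit_env(), policy_spec(2, 1, 8), cfg)$history
  h2 <- train_ppo(bandit_env(), policy_spec(2, 1, 8), cfg)$history
  expect_identical(h1, h2)
})

test_that("PPO solves the two-context bandit within 200 updates", {
  cfg <- ppo_config(learning_rate = 0.01, rollout_length = 64,
                    total_iterations = 200, minibatch_size = 64,
                    epochs_per_update = 2, entropy_coef = 0.001, seed = 3)
  out <- train_ppo(bandit_env(), policy_spec(2, 1, c(16, 16)), cfg)
  p_ctx1 <- policy_forward(out$policy, c(1, 0))   # rewarded action: 1
  p_ctx2 <- policy_forward(out$policy, c(0, 1))   # rewarded action: 0
  expect_gt(p_ctx1, 0.9)
  expect_gt(1 - p_ctx2, 0.9)
  # the learning curve reaches near-perfect mean reward
  expect_gt(tail(out$history$mean_step_reward, 1), 0.9)
})
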