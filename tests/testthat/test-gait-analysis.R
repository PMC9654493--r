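test_that("joint correlation: anchors, tail exclusion, affine invariance", {
  dt <- 0.01
  t <- seq(0, 2, by = dt)
  x <- sin(2 * pi * t)
  expect_equal(joint_correlation(x, x, dt), 1)
  expect_equal(joint_correlation(x, -x, dt), -1)
  # hand 4-point pair against the textbook formula (no tail exclusion)
  a <- c(1, 2, 4, 3); b <- c(2, 1, 5, 4)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(joint_correlation(a, b, dt = 1, exclude_tail = 0), manual)
  # the excluded tail does not influence the result
  y <- x; y[t > 1.5] <- 9     # corrupt the tail
  expect_equal(joint_correlation(x, y, dt), 1)
  # constant series: flagged NA, not NaN
  r <- joint_correlation(rep(1, 100), x[1:100], dt)
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
  expect_false(is.nan(unclass(r)))
  # affine invariance under positive rescaling of either series
  set.seed(8)
  for (i in 1:20) {
    s1 <- cumsum(rnorm(120)); s2 <- cumsum(rnorm(120))
    base <- joint_correlation(s1, s2, dt)
    scaled <- joint_correlation(runif(1, 0.1, 5) * s1 + rnorm(1),
                                s2 * runif(1, 0.1, 5) + rnorm(1), dt)
    expect_equal(scaled, base, tolerance = 1e-12)
  }
  expect_error(joint_correlation(x[1:10], x[1:10], dt = 0.01,
                                 exclude_tail = 0.5), "3 samples")
})

test_that("reward fraction semantics", {
  expect_equal(reward_fraction(1), 100)
  expect_equal(reward_fraction(0.5), 50)
  expect_equal(reward_fraction(0.716), 71.6)
  expect_equal(reward_fraction(0.571), 57.1)
  expect_equal(reward_fraction(30, max_per_step = 60), 50)
  expect_error(reward_fraction(-0.1), ">= 0")
})

test_that("muscle summary: mean, peak and exceedance", {
  cm <- compile_model(planar_model("ramp"))
  n <- 500
  forces <- matrix(0, n, cm$nm)
  colnames(forces) <- cm$muscles$names
  forces[, 1] <- 100                          # constant trace
  # half-sine with peak F on muscle 2: mean = 2 F / pi
  Fpk <- 800
  forces[, 2] <- Fpk * sin(pi * (seq_len(n) - 0.5) / n)
  ms <- muscle_summary(forces, cm)
  expect_equal(ms$mean[1], 100)
  expect_equal(ms$peak[1], 100)
  expect_equal(ms$mean[2], 2 * Fpk / pi, tolerance = 1e-3)
  expect_false(ms$exceeds[1])
  # zero trace: no exceedance
  expect_equal(ms$mean[3], 0)
  expect_false(ms$exceeds[3])
  # a trace above the scaled isometric maximum is flagged
  forces[, 4] <- cm$muscles$f_max[4] * 1.1
  expect_true(muscle_summary(forces, cm)$exceeds[4])
})

test_that("GRF report: episodes, nonzero mean, sign convention", {
  log1 <- data.frame(time = seq(0, 0.9, by = 0.1),
                     foot_l_fy = c(0, 0, 5, 5, 0, 0, 7, 7, 7, 0),
                     foot_r_fy = rep(0, 10))
  rep <- grf_report(log1)
  # two pulses separated by zeros: 2 episodes
  expect_equal(rep$foot_l$episodes, 2)
  expect_equal(rep$foot_l$nonzero_mean, mean(c(5, 5, 7, 7, 7)))
  expect_equal(rep$foot_l$peak, 7)
  # signed series follows the negative-up convention
  expect_equal(rep$foot_l$series_signed, -abs(log1$foot_l_fy))
  # never-loaded foot: zero episodes, undefined mean flagged
  expect_equal(rep$foot_r$episodes, 0)
  expect_true(is.na(rep$foot_r$nonzero_mean))
  expect_true(attr(rep$foot_r$nonzero_mean, "undefined"))
  # square pulse of height F: nonzero mean F, one episode
  log2 <- data.frame(time = 1:8 / 10, foot_l_fy = c(0, 4, 4, 4, 0, 0, 0, 0))
  expect_equal(grf_report(log2)$foot_l$nonzero_mean, 4)
  expect_equal(grf_report(log2)$foot_l$episodes, 1)
  # episode count equals zero->nonzero transitions (explicit-scan oracle)
  set.seed(10)
  for (i in 1:20) {
    fy <- rbinom(60, 1, 0.4) * runif(60, 1, 9)
    lg <- data.frame(time = seq_along(fy), f_fy = fy)
    nz <- fy != 0
    oracle <- sum(vapply(seq_along(nz), function(j) {
      nz[j] && (j == 1 || !nz[j - 1])
    }, TRUE))
    expect_equal(grf_report(lg)$f$episodes, oracle)
  }
})

test_that("gait_metrics summarizes a rollout trace end to end", {
  model <- planar_model("stairs")
  ref <- short_stair_ref()
  env <- gait_env(model, ascent_terrain("stairs"), ref)
  set.seed(6)
  ev <- evaluate_policy(env, NULL, n_episodes = 1, mode = "sample",
                        collect_trace = TRUE)
  gm <- gait_metrics(ev$trace, ref, model, exclude_tail = 0)
  expect_equal(names(gm$correlations),
               c("knee_l", "knee_r", "ankle_l", "ankle_r"))
  expect_true(all(abs(gm$correlations) <= 1, na.rm = TRUE))
  expect_gte(gm$reward_fraction, 0)
  expect_lte(gm$reward_fraction, 100)
  expect_equal(nrow(gm$muscles), 14)
  expect_true(all(gm$muscles$peak >= gm$muscles$mean - 1e-9))
  expect_true(all(c("foot_l", "foot_r") %in% names(gm$grf)))
  expect_gte(gm$grf$foot_l$episodes, 0)
})

test_that("a perfect imitation rollout scores a 100% reward fraction", {
  # idealized actuator: the state replays the reference exactly; push the
  # resulting per-step rewards through the reward pipeline
  cm <- compile_model(planar_model("stairs"))
  ref <- short_stair_ref()
  w <- reward_weights()
  rewards <- vapply(seq_along(ref$times), function(i) {
    q <- standing_q(cm$spec); u <- stats::setNames(numeric(cm$nq),
                                                   cm$dof_names)
    q[colnames(ref$joint_pos)] <- ref$joint_pos[i, ]
    u[colnames(ref$joint_pos)] <- ref$joint_vel[i, ]
    s <- model_state(cm, q = q, u = u, t = ref$times[i])
    sr <- step_reward(s, ref, ref$times[i], w)
    sr$reward
  }, 0)
  expect_equal(reward_fraction(mean(rewards)), 100, tolerance = 1e-6)
})
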