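# Proximal policy optimization with a clipped surrogate objective over a
# factored-Bernoulli (binary muscle excitation) policy.

#' Policy network specification
#'
#' @param n_obs Observation length (input layer size).
#' @param n_act Number of muscles (output layer size).
#' @param hidden Hidden layer sizes; the full-scale configuration uses
#'   `c(312, 312)`.
#' @return Named list used by [train_ppo()].
#' @export
policy_spec <- function(n_obs, n_act, hidden = c(312, 312)) {
  stopifnot(length(hidden) >= 1)
  list(n_obs = n_obs, n_act = n_act, hidden = hidden)
}

#' PPO configuration
#'
#' Clipped-surrogate hyperparameters. Defaults: clip 0.2, discount 0.99,
#' GAE lambda 0.95, learning rate 3e-4, 4 epochs per update, minibatch
#' 256, rollout 2048 steps.
#'
#' @param clip_epsilon Clip range, in (0, 1).
#' @param gamma Discount factor, in (0, 1].
#' @param gae_lambda Generalized-advantage-estimation lambda, in [0, 1].
#' @param learning_rate Adam step size.
#' @param epochs_per_update Optimization epochs per rollout.
#' @param minibatch_size Minibatch size.
#' @param rollout_length Environment steps collected per iteration.
#' @param total_iterations Number of rollout/update iterations.
#' @param value_coef Value-loss coefficient.
#' @param entropy_coef Entropy-bonus coefficient.
#' @param normalize_advantages Normalize advantages per batch.
#' @param seed RNG seed controlling every source of randomness in
#'   training.
#' @return Object of class `ppo_config`.
#' @export
ppo_config <- function(clip_epsilon = 0.2, gamma = 0.99, gae_lambda = 0.95,
                       learning_rate = 3e-4, epochs_per_update = 4,
                       minibatch_size = 256, rollout_length = 2048,
                       total_iterations = 50, value_coef = 0.5,
                       entropy_coef = 0.01, normalize_advantages = TRUE,
                       seed = 1) {
  stopifnot(clip_epsilon > 0, clip_epsilon < 1, gamma > 0, gamma <= 1,
            gae_lambda >= 0, gae_lambda <= 1, learning_rate >= 0)
  structure(list(clip_epsilon = clip_epsilon, gamma = gamma,
                 gae_lambda = gae_lambda, learning_rate = learning_rate,
                 epochs_per_update = epochs_per_update,
                 minibatch_size = minibatch_size,
                 rollout_length = rollout_length,
                 total_iterations = total_iterations,
                 value_coef = value_coef, entropy_coef = entropy_coef,
                 normalize_advantages = normalize_advantages,
                 seed = as.integer(seed)),
            class = "ppo_config")
}

#' Policy forward pass
#'
#' Maps observations to per-muscle excitation probabilities through the
#' tanh-hidden network and the sigmoid output head.
#'
#' @param policy An [mlp()] with sigmoid head.
#' @param obs Observation vector, or matrix with one row per observation.
#' @return Probability vector in `(0, 1)` (or matrix of them).
#' @export
policy_forward <- function(policy, obs) {
  out <- mlp_forward(policy, obs)$out
  if (nrow(out) == 1 && !is.matrix(obs)) out <- drop(out)
  out
}

#' Sample a binary excitation action
#'
#' Independent Bernoulli draws, one per muscle, with the joint
#' log-probability of the sampled vector.
#'
#' @param probs Per-muscle probabilities in `(0, 1)`.
#' @return List with `action` (0/1 vector) and `logp`.
#' @export
sample_action <- function(probs) {
  a <- as.numeric(stats::runif(length(probs)) < probs)
  list(action = a, logp = bernoulli_logp(probs, a))
}

bernoulli_logp <- function(probs, action) {
  p <- pmin(pmax(probs, 1e-10), 1 - 1e-10)
  sum(action * log(p) + (1 - action) * log(1 - p))
}

#' Probability ratio between new and old policy
#'
#' @param new_logp Log-probability of the action under the current
#'   policy.
#' @param old_logp Log-probability under the policy that collected the
#'   sample.
#' @return `exp(new_logp - old_logp)`; 1 when the parameters are
#'   unchanged.
#' @export
prob_ratio <- function(new_logp, old_logp) {
  if (any(!is.finite(new_logp)) || any(!is.finite(old_logp))) {
    stop("log-probabilities must be finite")
  }
  exp(new_logp - old_logp)
}

#' Clipped surrogate objective
#'
#' Mean over samples of `min(r * A, clip(r, 1 - eps, 1 + eps) * A)`. At
#' unchanged parameters (all ratios 1) it equals the mean advantage; the
#' clipped branch removes the incentive for the ratio to leave the clip
#' band.
#'
#' @param ratios Probability ratios.
#' @param advantages Advantage estimates, same length.
#' @param clip_epsilon Clip range.
#' @return Scalar objective (to be maximized).
#' @export
clipped_objective <- function(ratios, advantages, clip_epsilon = 0.2) {
  if (length(ratios) != length(advantages)) stop("length mismatch")
  mean(pmin(ratios * advantages,
            pmin(pmax(ratios, 1 - clip_epsilon), 1 + clip_epsilon) *
              advantages))
}

#' Generalized advantage estimation
#'
#' Backward recursion
#' `A_t = delta_t + gamma * lambda * (1 - done_t) * A_{t+1}` with
#' `delta_t = r_t + gamma * (1 - done_t) * V_{t+1} - V_t`; returns are
#' `A + V`. With `lambda = 1` the advantage reduces to the discounted
#' return minus the value baseline.
#'
#' @param rewards Reward series.
#' @param values Value estimates `V(s_t)`, same length.
#' @param dones Logical/0-1 episode-termination flags per step.
#' @param gamma Discount factor.
#' @param lambda GAE lambda.
#' @param last_value Bootstrap value of the state after the final step
#'   (0 if that state was terminal).
#' @return List with `advantages` and `returns`.
#' @export
compute_advantages <- function(rewards, values, dones, gamma = 0.99,
                               lambda = 0.95, last_value = 0) {
  n <- length(rewards)
  stopifnot(length(values) == n, length(dones) == n)
  adv <- numeric(n)
  gae <- 0
  for (t in n:1) {
    v_next <- if (t == n) last_value else values[t + 1]
    nonterm <- 1 - as.numeric(dones[t])
    delta <- rewards[t] + gamma * v_next * nonterm - values[t]
    gae <- delta + gamma * lambda * nonterm * gae
    adv[t] <- gae
  }
  list(advantages = adv, returns = adv + values)
}

# Collect one rollout batch from the environment.
collect_rollout <- function(env, policy, value_net, n_steps) {
  n_obs <- env$n_obs; n_act <- env$n_act
  obs_mat <- matrix(0, n_steps, n_obs)
  act_mat <- matrix(0, n_steps, n_act)
  rewards <- numeric(n_steps); dones <- logical(n_steps)
  logps <- numeric(n_steps)
  ep_returns <- numeric(0); ep_lengths <- integer(0)
  cur_ret <- 0; cur_len <- 0L
  obs <- env$state_obs()
  for (t in seq_len(n_steps)) {
    probs <- policy_forward(policy, obs)
    sa <- sample_action(probs)
    res <- env$step(sa$action)
    obs_mat[t, ] <- obs
    act_mat[t, ] <- sa$action
    logps[t] <- sa$logp
    rewards[t] <- res$reward
    dones[t] <- res$done
    cur_ret <- cur_ret + res$reward; cur_len <- cur_len + 1L
    if (res$done) {
      ep_returns <- c(ep_returns, cur_ret)
      ep_lengths <- c(ep_lengths, cur_len)
      cur_ret <- 0; cur_len <- 0L
      obs <- env$reset()
    } else {
      obs <- res$obs
    }
  }
  last_value <- if (dones[n_steps]) 0 else
    drop(mlp_forward(value_net, obs)$out)
  values <- drop(mlp_forward(value_net, obs_mat)$out)
  list(obs = obs_mat, actions = act_mat, rewards = rewards, dones = dones,
       logps = logps, values = values, last_value = last_value,
       ep_returns = ep_returns, ep_lengths = ep_lengths)
}

# One PPO update over a collected batch; returns updated nets and
# diagnostics. Binary-action policy: d logp / d z = a - p per output.
ppo_update <- function(policy, value_net, opt_p, opt_v, batch, cfg) {
  n <- nrow(batch$obs)
  ga <- compute_advantages(batch$rewards, batch$values, batch$dones,
                           cfg$gamma, cfg$gae_lambda, batch$last_value)
  adv <- ga$advantages
  if (cfg$normalize_advantages && stats::sd(adv) > 0) {
    adv <- (adv - mean(adv)) / stats::sd(adv)
  }
  rets <- ga$returns
  idx_all <- seq_len(n)
  pl <- vl <- 0; nb <- 0
  for (ep in seq_len(cfg$epochs_per_update)) {
    perm <- sample(idx_all)
    splits <- split(perm, ceiling(seq_along(perm) / cfg$minibatch_size))
    for (mb in splits) {
      X <- batch$obs[mb, , drop = FALSE]
      A <- batch$actions[mb, , drop = FALSE]
      advb <- adv[mb]
      fw <- mlp_forward(policy, X)
      P <- pmin(pmax(fw$out, 1e-10), 1 - 1e-10)
      logp_new <- rowSums(A * log(P) + (1 - A) * log(1 - P))
      ratio <- exp(logp_new - batch$logps[mb])
      clipped <- (advb > 0 & ratio > 1 + cfg$clip_epsilon) |
        (advb < 0 & ratio < 1 - cfg$clip_epsilon)
      coef <- ifelse(clipped, 0, ratio * advb) / length(mb)
      # maximize surrogate + entropy: gradient on output pre-activations
      dZ <- -(coef * (A - P))
      if (cfg$entropy_coef > 0) {
        dH <- P * (1 - P) * log((1 - P) / P)    # d entropy / d z
        dZ <- dZ - cfg$entropy_coef * dH / length(mb)
      }
      gp <- mlp_backward(policy, fw$cache, dZ)
      up <- adam_step(policy, gp, opt_p, cfg$learning_rate)
      policy <- up$net; opt_p <- up$state

      fv <- mlp_forward(value_net, X)
      verr <- drop(fv$out) - rets[mb]
      dZv <- matrix(cfg$value_coef * verr / length(mb), ncol = 1)
      gv <- mlp_backward(value_net, fv$cache, dZv)
      uv <- adam_step(value_net, gv, opt_v, cfg$learning_rate)
      value_net <- uv$net; opt_v <- uv$state

      pl <- pl - sum(coef * advb)   # running surrogate diagnostic
      vl <- vl + 0.5 * mean(verr^2)
      nb <- nb + 1
    }
  }
  list(policy = policy, value_net = value_net, opt_p = opt_p, opt_v = opt_v,
       policy_loss = pl / nb, value_loss = vl / nb)
}

#' Train a policy with PPO
#'
#' Alternates rollout collection and clipped-surrogate/value updates.
#' Each iteration records the mean per-step reward of the collected
#' batch and the mean horizon-normalized episode return (episode return
#' divided by the environment horizon, unreached steps scoring zero) —
#' the learning-curve metric. Metrics are flushed to
#' `<out>/metrics.csv` every 5 iterations when an output directory is
#' given, and the best policy (by normalized return) is retained as a
#' checkpoint. Fully reproducible for a given seed. A non-finite loss
#' aborts with diagnostics, retaining the last checkpoint.
#'
#' @param env An environment as returned by [gait_env()] or
#'   [bandit_env()].
#' @param spec A [policy_spec()]; defaults to the environment's
#'   dimensions with 64-unit hidden layers.
#' @param config A [ppo_config()].
#' @param out Optional output directory for metrics/checkpoints.
#' @param verbose Print per-iteration progress.
#' @return List with `policy`, `value_net`, `history` (one row per
#'   iteration), and `best` (checkpoint with the highest normalized
#'   return).
#' @export
train_ppo <- function(env, spec = NULL, config = ppo_config(), out = NULL,
                      verbose = FALSE) {
  set.seed(config$seed)
  if (is.null(spec)) spec <- policy_spec(env$n_obs, env$n_act, c(64, 64))
  policy <- mlp(c(spec$n_obs, spec$hidden, spec$n_act), head = "sigmoid")
  value_net <- mlp(c(spec$n_obs, spec$hidden, 1), head = "linear")
  opt_p <- adam_state(policy); opt_v <- adam_state(value_net)
  history <- data.frame()
  best <- list(norm_return = -Inf, policy = policy, iteration = 0L)
  env$reset()
  for (it in seq_len(config$total_iterations)) {
    batch <- collect_rollout(env, policy, value_net, config$rollout_length)
    upd <- ppo_update(policy, value_net, opt_p, opt_v, batch, config)
    if (!is.finite(upd$policy_loss) || !is.finite(upd$value_loss)) {
      warning("non-finite loss at iteration ", it,
              "; aborting and retaining the last checkpoint")
      break
    }
    policy <- upd$policy; value_net <- upd$value_net
    opt_p <- upd$opt_p; opt_v <- upd$opt_v
    horizon <- env$horizon %||% NA_real_
    nret <- if (length(batch$ep_returns) > 0 && is.finite(horizon)) {
      mean(batch$ep_returns / horizon)
    } else {
      mean(batch$rewards)
    }
    row <- data.frame(iteration = it,
                      mean_step_reward = mean(batch$rewards),
                      norm_return = nret,
                      n_episodes = length(batch$ep_returns),
                      mean_ep_length = if (length(batch$ep_lengths) > 0)
                        mean(batch$ep_lengths) else NA_real_,
                      policy_loss = upd$policy_loss,
                      value_loss = upd$value_loss)
    history <- rbind(history, row)
    if (is.finite(nret) && nret > best$norm_return) {
      best <- list(norm_return = nret, policy = policy, iteration = it)
    }
    if (verbose) {
      message(sprintf("iter %3d  mean reward %.4f  norm return %.4f  eps %d",
                      it, row$mean_step_reward, nret, row$n_episodes))
    }
    if (!is.null(out) && (it %% 5 == 0 || it == config$total_iterations)) {
      if (!dir.exists(out)) dir.create(out, recursive = TRUE)
      utils::write.csv(history, file.path(out, "metrics.csv"),
                       row.names = FALSE)
    }
  }
  list(policy = policy, value_net = value_net, history = history,
       best = best)
}
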