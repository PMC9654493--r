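# Reinforcement-learning environment wrappers: the muscle-driven ascent
# task and a small contextual bandit used as a trainer sanity check.

#' Muscle-driven ascent environment
#'
#' Wraps the planar model, terrain and reference trajectory as an
#' episodic environment. Each control step holds the binary muscle
#' excitation constant for `ctrl_dt` while the physics advances in
#' `physics_dt` substeps; the reward is the imitation+goal reward against
#' the reference at the new time. Episodes start from the reference's
#' initial state and end on a fall, on divergence, on leaving the
#' terrain, or at the end of the reference.
#'
#' Observations are the [observation()] vector rescaled by fixed
#' per-component characteristic scales (velocities 10 m/s, accelerations
#' 100 m/s^2, forces 2000 N, limit torques 100 N m) so all policy inputs
#' are of order one.
#'
#' @param model A planar `model_spec`.
#' @param terrain A terrain `tri_mesh` (e.g. [ascent_terrain()]).
#' @param ref A `reference_trajectory` for the model's DOFs.
#' @param contact A [contact_params()].
#' @param weights A [reward_weights()].
#' @param ctrl_dt Control (excitation hold) interval (s). Default 0.01 s.
#' @param physics_dt Physics step (s). Default 0.002 s.
#' @param tracked Tracked DOF names for the penalties; defaults to all
#'   reference DOFs.
#' @return An environment: a list with `reset()`, `step(action)`,
#'   `state_obs()`, `n_obs`, `n_act`, `horizon` (control steps to the
#'   reference end), and `last_state()`.
#' @export
gait_env <- function(model, terrain, ref, contact = contact_params(),
                     weights = reward_weights(), ctrl_dt = 0.01,
                     physics_dt = 0.002, tracked = NULL) {
  cm <- compile_model(model)
  hf <- if (inherits(terrain, "height_field")) terrain else
    height_field(terrain)
  n_sub <- max(1L, round(ctrl_dt / physics_dt))
  layout <- default_layout(cm)
  nb <- cm$nb; nq <- cm$nq; nm <- cm$nm
  scale <- c(rep(1, 2 * nb), rep(1, nb),        # seg pos, rot
             rep(0.1, 2 * nb), rep(0.1, nb),    # seg vel
             rep(0.01, 2 * nb), rep(0.01, nb),  # seg acc
             rep(1, nq), rep(0.1, nq), rep(0.01, nq),
             rep(5e-4, nm), rep(0.01, nq))
  horizon <- floor((ref$times[length(ref$times)] - ref$times[1]) / ctrl_dt)

  state <- NULL
  make_obs <- function(st) observation(st, cm, layout) * scale

  init_state <- function() {
    q <- standing_q(cm$spec)
    u <- stats::setNames(numeric(nq), cm$dof_names)
    common <- intersect(cm$dof_names, colnames(ref$joint_pos))
    q[common] <- ref$joint_pos[1, common]
    u[common] <- ref$joint_vel[1, common]
    model_state(cm, q = q, u = u, act = numeric(nm), t = ref$times[1])
  }

  reset <- function() {
    state <<- init_state()
    make_obs(state)
  }
  step <- function(action) {
    if (is.null(state)) reset()
    for (s in seq_len(n_sub)) {
      state <<- forward_step(state, action, cm, hf, contact, physics_dt)
      if (state$terminated) break
    }
    if (state$terminated) {
      return(list(obs = make_obs(state), reward = 0, done = TRUE,
                  info = list(reason = state$reason, grf = state$grf,
                              t = state$t)))
    }
    sr <- step_reward(state, ref, state$t, weights)
    if (sr$end) {
      return(list(obs = make_obs(state), reward = 0, done = TRUE,
                  info = list(reason = "end_of_reference", grf = state$grf,
                              t = state$t)))
    }
    list(obs = make_obs(state), reward = sr$reward, done = FALSE,
         info = list(grf = state$grf, penalties = sr$penalties,
                     muscle_forces = state$muscle_forces, t = state$t))
  }
  list(reset = reset, step = step,
       state_obs = function() {
         if (is.null(state)) reset() else make_obs(state)
       },
       last_state = function() state,
       n_obs = sum(layout), n_act = nm, horizon = horizon,
       ctrl_dt = ctrl_dt, model = cm, ref = ref)
}

#' Two-context bandit environment
#'
#' A minimal sanity-check task for the PPO trainer: the observation is
#' one of two one-hot contexts, the single binary action is rewarded
#' (reward 1) when it matches the context and not otherwise (reward 0);
#' every step ends the episode.
#'
#' @return An environment compatible with [train_ppo()].
#' @export
bandit_env <- function() {
  ctx <- 1L
  obs_of <- function() as.numeric(ctx == c(1L, 2L))
  reset <- function() {
    ctx <<- sample(1:2, 1)
    obs_of()
  }
  step <- function(action) {
    correct <- if (ctx == 1L) 1 else 0
    r <- as.numeric(action[1] == correct)
    old <- obs_of()
    ctx <<- sample(1:2, 1)
    list(obs = obs_of(), reward = r, done = TRUE, info = list())
  }
  list(reset = reset, step = step, state_obs = function() obs_of(),
       n_obs = 2L, n_act = 1L, horizon = 1L)
}

#' Evaluate a policy on an environment
#'
#' Runs full episodes with either a trained policy (excitation
#' probabilities thresholded at 0.5 by default, or sampled) or, when
#' `policy` is `NULL`, the random baseline policy (each muscle excited
#' with probability 0.5). Reports the mean per-step reward over achieved
#' steps and the horizon-normalized return (episode return divided by
#' the environment horizon; steps not reached score zero).
#'
#' @param env An environment.
#' @param policy An [mlp()] policy, or `NULL` for the random baseline.
#' @param n_episodes Number of evaluation episodes.
#' @param mode `"threshold"` (deterministic, probabilities >= 0.5 excite)
#'   or `"sample"`.
#' @param collect_trace Keep the full per-step trace of the first
#'   episode (time, coordinates, reward, muscle forces, per-foot ground
#'   reactions).
#' @return List with `mean_step_reward`, `norm_return`, `returns`,
#'   `lengths`, and optionally `trace`.
#' @export
evaluate_policy <- function(env, policy = NULL, n_episodes = 1,
                            mode = c("threshold", "sample"),
                            collect_trace = FALSE) {
  mode <- match.arg(mode)
  returns <- numeric(n_episodes); lengths <- integer(n_episodes)
  all_rewards <- numeric(0)
  trace <- NULL
  for (e in seq_len(n_episodes)) {
    obs <- env$reset()
    done <- FALSE; ret <- 0; len <- 0L
    rows <- list()
    while (!done && len < env$horizon + 5L) {
      action <- if (is.null(policy)) {
        as.numeric(stats::runif(env$n_act) < 0.5)
      } else {
        probs <- policy_forward(policy, obs)
        if (mode == "threshold") as.numeric(probs >= 0.5) else
          sample_action(probs)$action
      }
      res <- env$step(action)
      ret <- ret + res$reward; len <- len + 1L
      all_rewards <- c(all_rewards, res$reward)
      if (collect_trace && e == 1L) {
        st <- env$last_state()
        if (!is.null(st)) {
          row <- c(time = st$t, reward = res$reward, st$q,
                   mf = unname(st$muscle_forces))
          for (ft in names(st$grf)) {
            g <- st$grf[[ft]]
            row[paste0(ft, "_fy")] <- g$force[2]
            row[paste0(ft, "_contact")] <- as.numeric(g$n_points > 0)
          }
          rows[[len]] <- row
        }
      }
      done <- res$done
      obs <- res$obs
    }
    returns[e] <- ret; lengths[e] <- len
    if (collect_trace && e == 1L && length(rows) > 0) {
      trace <- as.data.frame(do.call(rbind, rows))
    }
  }
  out <- list(mean_step_reward = mean(all_rewards),
              norm_return = mean(returns / env$horizon),
              returns = returns, lengths = lengths)
  if (collect_trace) out$trace <- trace
  out
}
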