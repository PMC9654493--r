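#' Reward weights and exponent gains
#'
#' The per-step reward is a convex combination of a goal term and an
#' imitation term, `J_t = w_goal * Jgoal_t + w_imitation * Jimitation_t`
#' with `Jgoal = exp(-k_goal * p_vel_pelvis)` and
#' `Jimitation = w_imit_pos * exp(-k_pos * p_pos) +
#' w_imit_vel * exp(-k_vel * p_vel)`. The defaults (0.1/0.9 outer
#' weights, 0.9/0.1 imitation weights, gains 8, 4 and 0.1) are the fixed
#' task values.
#'
#' @param w_goal,w_imitation Outer weights; must sum to 1.
#' @param w_imit_pos,w_imit_vel Imitation weights; must sum to 1.
#' @param k_goal,k_pos,k_vel Positive exponent gains.
#' @return Object of class `reward_weights`.
#' @export
reward_weights <- function(w_goal = 0.1, w_imitation = 0.9,
                           w_imit_pos = 0.9, w_imit_vel = 0.1,
                           k_goal = 8, k_pos = 4, k_vel = 0.1) {
  if (abs(w_goal + w_imitation - 1) > 1e-12) {
    stop("w_goal + w_imitation must equal 1")
  }
  if (abs(w_imit_pos + w_imit_vel - 1) > 1e-12) {
    stop("w_imit_pos + w_imit_vel must equal 1")
  }
  if (k_goal <= 0 || k_pos <= 0 || k_vel <= 0) {
    stop("exponent gains must be positive")
  }
  structure(list(w_goal = w_goal, w_imitation = w_imitation,
                 w_imit_pos = w_imit_pos, w_imit_vel = w_imit_vel,
                 k_goal = k_goal, k_pos = k_pos, k_vel = k_vel),
            class = "reward_weights")
}

#' Tracking penalties against the reference
#'
#' Sums of squared errors between the observed and reference joint
#' positions and velocities over the tracked DOFs, the reference sampled
#' at its nearest grid point. A query past the end of the reference
#' returns an episode-end marker instead of raising.
#'
#' @param state A [model_state()] (named `q`/`u`).
#' @param ref A `reference_trajectory`.
#' @param t Query time (s).
#' @param tracked Character vector of tracked DOF names; defaults to all
#'   DOFs shared by the state and the reference.
#' @return List with `p_pos` (rad^2, m^2), `p_vel`, `p_vel_pelvis`
#'   (pelvis translational velocity error for the goal reward), and
#'   `end` (`TRUE` past the reference).
#' @export
penalties <- function(state, ref, t, tracked = NULL) {
  i <- ref_index(ref, t)
  if (is.na(i)) {
    return(list(p_pos = NA_real_, p_vel = NA_real_,
                p_vel_pelvis = NA_real_, end = TRUE))
  }
  if (is.null(tracked)) {
    tracked <- intersect(names(state$q), colnames(ref$joint_pos))
  }
  dq <- state$q[tracked] - ref$joint_pos[i, tracked]
  du <- state$u[tracked] - ref$joint_vel[i, tracked]
  pv_cols <- colnames(ref$pelvis_vel)
  dpv <- state$u[pv_cols] - ref$pelvis_vel[i, ]
  list(p_pos = sum(dq^2), p_vel = sum(du^2),
       p_vel_pelvis = sum(dpv^2), end = FALSE)
}

#' Goal reward
#'
#' `exp(-k_goal * p_vel)` where `p_vel` is the squared deviation of the
#' pelvis translational velocity from the reference. In `(0, 1]`, equal
#' to 1 only at zero deviation.
#'
#' @param p_vel_pelvis Pelvis velocity penalty, >= 0.
#' @param weights A [reward_weights()].
#' @return Scalar in `(0, 1]`.
#' @export
goal_reward <- function(p_vel_pelvis, weights = reward_weights()) {
  if (p_vel_pelvis < 0) stop("p_vel must be >= 0")
  exp(-weights$k_goal * p_vel_pelvis)
}

#' Imitation reward
#'
#' `w_imit_pos * exp(-k_pos * p_pos) + w_imit_vel * exp(-k_vel * p_vel)`
#' over the tracked joints' position and velocity penalties.
#'
#' @param pair List with `p_pos` and `p_vel`, both >= 0.
#' @param weights A [reward_weights()].
#' @return Scalar in `(0, 1]`.
#' @export
imitation_reward <- function(pair, weights = reward_weights()) {
  if (pair$p_pos < 0 || pair$p_vel < 0) stop("penalties must be >= 0")
  weights$w_imit_pos * exp(-weights$k_pos * pair$p_pos) +
    weights$w_imit_vel * exp(-weights$k_vel * pair$p_vel)
}

#' Total per-step reward
#'
#' Convex combination of the goal and imitation rewards.
#'
#' @param goal Goal reward in `(0, 1]`.
#' @param imitation Imitation reward in `(0, 1]`.
#' @param weights A [reward_weights()].
#' @return Scalar in `(0, 1]`; equals 1 iff both components equal 1.
#' @export
total_reward <- function(goal, imitation, weights = reward_weights()) {
  weights$w_goal * goal + weights$w_imitation * imitation
}

# Full reward evaluation for a state against the reference.
step_reward <- function(state, ref, t, weights, tracked = NULL) {
  p <- penalties(state, ref, t, tracked)
  if (p$end) return(list(reward = NA_real_, end = TRUE, penalties = p))
  g <- goal_reward(p$p_vel_pelvis, weights)
  im <- imitation_reward(p, weights)
  list(reward = total_reward(g, im, weights), end = FALSE, penalties = p,
       goal = g, imitation = im)
}
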