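#' Hill-type muscle parameters
#'
#' Bundles the properties that determine the force a Hill-type muscle can
#' produce: maximum isometric force, optimal fiber length, tendon slack
#' length, maximum contraction velocity, pennation angle, and the time
#' constants of the first-order excitation-to-activation dynamics.
#'
#' @param name Muscle label.
#' @param f_max Maximum isometric force (N), > 0.
#' @param l_opt Optimal fiber length (m), > 0.
#' @param l_slack Tendon slack length (m), >= 0.
#' @param v_max Maximum contraction velocity (optimal fiber lengths per
#'   second), > 0.
#' @param penn Pennation angle (rad) in `[0, pi/2)`.
#' @param tau_act Activation time constant (s), > 0. Default 0.01 s.
#' @param tau_deact Deactivation time constant (s), > 0. Default 0.04 s.
#' @param path Optional data frame of path points (columns `body`, `x`, `y`;
#'   body-local coordinates in m, ordered origin to insertion).
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(name, f_max, l_opt, l_slack, v_max = 10,
                          penn = 0, tau_act = 0.01, tau_deact = 0.04,
                          path = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(f_max) || f_max <= 0) stop("f_max must be a positive number")
  if (!is.finite(l_opt) || l_opt <= 0) stop("l_opt must be a positive number")
  if (!is.finite(l_slack) || l_slack < 0) stop("l_slack must be >= 0")
  if (!is.finite(v_max) || v_max <= 0) stop("v_max must be a positive number")
  if (!is.finite(penn) || penn < 0 || penn >= pi / 2) {
    stop("penn must lie in [0, pi/2)")
  }
  if (!is.finite(tau_act) || tau_act <= 0 || !is.finite(tau_deact) ||
      tau_deact <= 0) {
    stop("activation time constants must be positive")
  }
  structure(
    list(name = name, f_max = f_max, l_opt = l_opt, l_slack = l_slack,
         v_max = v_max, penn = penn, tau_act = tau_act,
         tau_deact = tau_deact, path = path),
    class = "muscle_params"
  )
}

#' Advance the excitation-activation dynamics by one step
#'
#' Muscle activation follows the neural excitation through a first-order
#' linear filter whose time constant differs between activation
#' (excitation above the current activation) and deactivation. The update
#' uses the exact exponential solution of the linear ODE over the step, so
#' it is unconditionally stable and lands on the closed-form trajectory for
#' constant excitation.
#'
#' @param excitation Neural excitation in `[0, 1]`.
#' @param activation Current activation in `[0, 1]`.
#' @param dt Time step (s), > 0.
#' @param params A [muscle_params()] object supplying `tau_act`/`tau_deact`.
#' @return The activation after `dt`, guaranteed to stay in `[0, 1]`.
#' @export
activation_step <- function(excitation, activation, dt, params) {
  if (!is.finite(excitation) || !is.finite(activation) || !is.finite(dt)) {
    stop("activation_step: non-finite input")
  }
  if (dt <= 0) stop("activation_step: dt must be > 0")
  if (excitation < 0 || excitation > 1) stop("excitation outside [0, 1]")
  if (activation < 0 || activation > 1) stop("activation outside [0, 1]")
  tau <- if (excitation > activation) params$tau_act else params$tau_deact
  a <- excitation + (activation - excitation) * exp(-dt / tau)
  min(max(a, 0), 1)
}

# Vectorized exact update used in the simulation inner loop.
act_step_vec <- function(u, a, dt, tau_act, tau_deact) {
  tau <- ifelse(u > a, tau_act, tau_deact)
  pmin(pmax(u + (a - u) * exp(-dt / tau), 0), 1)
}

#' Active force-length curve
#'
#' Gaussian bell centered at the optimal fiber length, `exp(-(l-1)^2/0.45)`
#' on the normalized length.
#'
#' @param lnorm Fiber length normalized by the optimal fiber length.
#' @return Multiplier in `(0, 1]`.
#' @export
force_length_active <- function(lnorm) exp(-((lnorm - 1)^2) / 0.45)

#' Force-velocity curve
#'
#' Hyperbolic (Hill) branch for shortening, reaching zero at the maximum
#' contraction velocity, and a saturating branch for lengthening that tends
#' to 1.8 at large stretch velocity. `vnorm` is the fiber velocity
#' normalized by `v_max * l_opt` (negative = shortening).
#'
#' @param vnorm Normalized fiber velocity.
#' @return Multiplier >= 0, equal to 1 at `vnorm = 0`.
#' @export
force_velocity <- function(vnorm) {
  ifelse(vnorm < 0,
         pmax(1 + vnorm, 0) / (1 - vnorm / 0.25),
         (1.8 * vnorm + 0.13) / (vnorm + 0.13))
}

#' Passive force-length curve
#'
#' Exponential passive stretch response, zero at or below the optimal
#' fiber length and reaching 1 at a passive strain of 0.6.
#'
#' @param lnorm Normalized fiber length.
#' @return Passive force multiplier >= 0.
#' @export
force_passive <- function(lnorm) {
  kpe <- 4
  e0 <- 0.6
  ifelse(lnorm > 1,
         (exp(kpe * (lnorm - 1) / e0) - 1) / (exp(kpe) - 1),
         0)
}

#' Hill-type muscle fiber force
#'
#' Computes `f_max * (a * fL * fV + fP) * cos(penn)`: activation times the
#' active force-length and force-velocity multipliers, plus the passive
#' elastic term, projected along the tendon by the pennation angle. The
#' result is clamped at zero (muscles pull, never push).
#'
#' @param params A [muscle_params()] object.
#' @param activation Activation level in `[0, 1]`.
#' @param fiber_len Fiber length (m), > 0.
#' @param fiber_vel Fiber velocity (m/s), negative while shortening.
#' @return Force along the tendon (N), >= 0.
#' @export
muscle_force <- function(params, activation, fiber_len, fiber_vel = 0) {
  if (!is.finite(activation) || activation < 0 || activation > 1) {
    stop("activation outside [0, 1]")
  }
  if (!is.finite(fiber_len) || fiber_len <= 0) {
    stop("fiber_len must be positive")
  }
  lnorm <- fiber_len / params$l_opt
  vnorm <- fiber_vel / (params$v_max * params$l_opt)
  f <- params$f_max *
    (activation * force_length_active(lnorm) * force_velocity(vnorm) +
       force_passive(lnorm)) * cos(params$penn)
  max(f, 0)
}

# Vectorized fiber force over all muscles of a compiled model.
muscle_force_vec <- function(f_max, l_opt, v_max, cospenn, act, lnorm, vnorm) {
  fl <- exp(-((lnorm - 1)^2) / 0.45)
  fv <- ifelse(vnorm < 0,
               pmax(1 + vnorm, 0) / (1 - vnorm / 0.25),
               (1.8 * vnorm + 0.13) / (vnorm + 0.13))
  fp <- ifelse(lnorm > 1, (exp(4 * (lnorm - 1) / 0.6) - 1) / (exp(4) - 1), 0)
  pmax(f_max * (act * fl * fv + fp) * cospenn, 0)
}

#' Scale the maximum isometric force of every muscle
#'
#' Multiplies `f_max` of all muscles in a model by a common factor, leaving
#' every other field untouched. A factor of 1.8 reproduces the 80% strength
#' increase used for the stair-ascent task; 1.0 leaves the ramp-task model
#' at its default strength.
#'
#' @param spec A [model_spec()].
#' @param factor Positive multiplier.
#' @return The model specification with scaled muscle strengths.
#' @export
apply_isometric_scaling <- function(spec, factor) {
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0")
  spec$muscles <- lapply(spec$muscles, function(m) {
    m$f_max <- m$f_max * factor
    m
  })
  spec$isometric_scale <- spec$isometric_scale * factor
  spec
}
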