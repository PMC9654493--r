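# Gait-evaluation metrics computed from rollout traces and reference
# trajectories.

#' Joint-angle correlation with tail exclusion
#'
#' Pearson correlation between a simulated and a reference joint series
#' over their common length, excluding the final `exclude_tail` seconds
#' (the part of a simulation where the model falls because the object
#' ends). A constant series has no defined correlation; the result is
#' then `NA` with attribute `undefined = TRUE` rather than `NaN`.
#'
#' @param sim_series,ref_series Numeric series on the same time grid.
#' @param dt Sampling interval (s).
#' @param exclude_tail Tail duration to drop (s). Default 0.5 s.
#' @return Pearson correlation in `[-1, 1]`, or flagged `NA`.
#' @export
joint_correlation <- function(sim_series, ref_series, dt,
                              exclude_tail = 0.5) {
  n <- min(length(sim_series), length(ref_series))
  drop_n <- round(exclude_tail / dt)
  keep <- n - drop_n
  if (keep < 3) stop("fewer than 3 samples remain after tail exclusion")
  x <- sim_series[seq_len(keep)]
  y <- ref_series[seq_len(keep)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  stats::cor(x, y)
}

#' Reward fraction
#'
#' The fraction of the maximum achievable reward, as a percentage:
#' `100 * achieved / max_per_step`. With the per-step maximum of 1 this
#' is the mean per-step reward expressed in percent (a mean reward of
#' 0.716 is a 71.6% reward fraction).
#'
#' @param achieved_mean_reward Mean per-step reward, >= 0.
#' @param max_per_step Maximum attainable per-step reward.
#' @return Percentage in `[0, 100]` (for rewards within the bound).
#' @export
reward_fraction <- function(achieved_mean_reward, max_per_step = 1) {
  if (achieved_mean_reward < 0) stop("achieved reward must be >= 0")
  100 * achieved_mean_reward / max_per_step
}

#' Per-muscle force summary
#'
#' Mean and peak fiber force over the active simulation for each muscle,
#' with the (scaled) maximum isometric force and an exceedance flag.
#'
#' @param forces Matrix of fiber-force traces (N), one named column per
#'   muscle.
#' @param model A `model_spec` or `compiled_model` supplying `f_max`.
#' @return Data frame with columns `muscle`, `mean`, `peak`, `f_max`,
#'   `exceeds`.
#' @export
muscle_summary <- function(forces, model) {
  cm <- compile_model(model)
  forces <- as.matrix(forces)
  if (is.null(colnames(forces))) colnames(forces) <- cm$muscles$names
  f_max <- stats::setNames(cm$muscles$f_max, cm$muscles$names)
  data.frame(
    muscle = colnames(forces),
    mean = colMeans(forces),
    peak = apply(forces, 2, max),
    f_max = unname(f_max[colnames(forces)]),
    exceeds = apply(forces, 2, max) > unname(f_max[colnames(forces)]),
    row.names = NULL
  )
}

#' Ground-reaction-force report
#'
#' Per-foot summary of the vertical (Y) ground reaction: the signed
#' series (negative-up sign convention preserved in `series_signed` for
#' comparability with force-plate style reporting, magnitudes in
#' `series`), the peak, the mean over contact samples only (zeros
#' excluded), and the number of contact episodes (maximal runs of
#' nonzero force).
#'
#' @param contact_log Data frame with a `time` column and one `<foot>_fy`
#'   column per foot (vertical GRF, N, upward positive as produced by the
#'   simulation).
#' @return Named list per foot: `series`, `series_signed`, `peak`,
#'   `nonzero_mean` (`NA` with `undefined = TRUE` when the foot never
#'   touches), `episodes`.
#' @export
grf_report <- function(contact_log) {
  fy_cols <- grep("_fy$", names(contact_log), value = TRUE)
  if (length(fy_cols) == 0) stop("contact log has no *_fy columns")
  out <- list()
  for (col in fy_cols) {
    foot <- sub("_fy$", "", col)
    fy <- contact_log[[col]]
    mag <- abs(fy)
    nz <- mag > 0
    episodes <- sum(diff(c(FALSE, nz)) == 1)
    nonzero_mean <- if (any(nz)) mean(mag[nz]) else
      structure(NA_real_, undefined = TRUE)
    out[[foot]] <- list(series = mag, series_signed = -mag,
                        peak = if (any(nz)) max(mag) else 0,
                        nonzero_mean = nonzero_mean,
                        episodes = episodes)
  }
  out
}

#' Full gait metrics from an evaluation trace
#'
#' Convenience wrapper computing the joint correlations (knee and ankle
#' joints by default), their mean, the reward fraction, the muscle force
#' summary and the GRF report from an [evaluate_policy()] trace.
#'
#' @param trace Trace data frame from `evaluate_policy(collect_trace =
#'   TRUE)`.
#' @param ref The `reference_trajectory` the rollout imitated.
#' @param model The model.
#' @param joints Joint columns to correlate.
#' @param exclude_tail Tail exclusion for the correlations (s).
#' @return List with `correlations`, `mean_correlation`,
#'   `reward_fraction`, `muscles`, `grf`.
#' @export
gait_metrics <- function(trace, ref, model,
                         joints = c("knee_l", "knee_r", "ankle_l",
                                    "ankle_r"),
                         exclude_tail = 0.5) {
  cm <- compile_model(model)
  dt <- stats::median(diff(trace$time))
  nref <- length(ref$times)
  idx <- vapply(trace$time, function(t) {
    i <- ref_index(ref, t)
    if (is.na(i)) nref else i     # clamp samples past the reference end
  }, 1L)
  cors <- sapply(joints, function(j) {
    joint_correlation(trace[[j]], ref$joint_pos[idx, j], dt, exclude_tail)
  })
  mf_cols <- grep("^mf", names(trace))
  forces <- as.matrix(trace[, mf_cols, drop = FALSE])
  colnames(forces) <- cm$muscles$names
  list(correlations = cors,
       mean_correlation = mean(cors, na.rm = TRUE),
       reward_fraction = reward_fraction(mean(trace$reward)),
       muscles = muscle_summary(forces, cm),
       grf = grf_report(trace))
}
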