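#' Force-matching errors
#'
#' Three complementary scores of how well the produced force `FM(t)` tracks
#' the desired force `Fd(t)` over a task of duration `T` (rectangle-rule
#' integrals on the grid):
#' * `erms = sqrt( (1/T) integral (FM - Fd)^2 dt )` \[N\] - average match;
#' * `emax = max |FM - Fd| / max Fd` (dimensionless) - worst instantaneous
#'   match, normalized by the task's peak force;
#' * `etot = | integral (FM - Fd) dt |` \[N s\] - net impulse error, which
#'   does not penalize compensation (undershoot in one phase balanced by
#'   overshoot in another).
#'
#' @param FM Produced force \[N\] on the grid, or a `mu_sim` object.
#' @param Fd Desired force \[N\] (ignored when `FM` is a `mu_sim`).
#' @param dt Grid step \[s\] (ignored when `FM` is a `mu_sim`).
#' @return One-row data frame with columns `erms`, `emax`, `etot`.
#' @export
match_errors <- function(FM, Fd = NULL, dt = NULL) {
  if (inherits(FM, "mu_sim")) {
    sim <- FM
    Fd <- sim$task$Fd
    dt <- sim$task$dt
    FM <- sim$FM
  }
  stopifnot(length(FM) == length(Fd), dt > 0)
  e <- FM - Fd
  if (max(Fd) <= 0) stop("emax undefined: desired force is identically zero")
  data.frame(erms = sqrt(mean(e^2)),
             emax = max(abs(e)) / max(Fd),
             etot = abs(sum(e) * dt))
}

#' Mean absolute plateau deviation for a trapezoidal task
#'
#' Mean of `|FM - Fd|` over the task's plateau window, excluding an initial
#' settling interval (the protocol papers report sustained-contraction
#' averages without defining the window; the settling exclusion keeps the
#' ramp-to-plateau transient out of the statistic).
#'
#' @param sim A [simulate_pool()] result on a [trapezoid_task()].
#' @param settle Settling time excluded at the start of the plateau \[s\].
#' @return Mean absolute deviation \[N\].
#' @export
plateau_error <- function(sim, settle = 1) {
  stopifnot(inherits(sim, "mu_sim"))
  win <- sim$task$plateau_window
  if (is.null(win)) stop("task has no plateau window")
  keep <- sim$t >= win[1] + settle & sim$t <= win[2]
  mean(abs(sim$FM[keep] - sim$task$Fd[keep]))
}

#' Steady-state drive-to-force map
#'
#' For each drive level `I`, holds the drive constant for `horizon` seconds
#' under isometric conditions and reports the mean (tetanic) force over the
#' final `avg_window` seconds. The horizon exceeds twenty twitch durations,
#' so the average is taken in the fused steady state.
#'
#' @param pool A [pool_model()].
#' @param twitch A [calibrate_twitch()] model.
#' @param I_grid Drive levels \[N\].
#' @param g Constant gain (1 = optimal isometric).
#' @param horizon,avg_window Simulation and averaging durations \[s\].
#' @param amax Optional precomputed [pool_amax()] vector.
#' @return Data frame with columns `I` and `FM` (nondecreasing in `I`).
#' @export
steady_state_map <- function(pool, twitch, I_grid, g = 1, horizon = 4,
                             avg_window = 1, amax = NULL) {
  stopifnot(inherits(pool, "mu_pool"), inherits(twitch, "twitch_model"))
  if (is.null(amax)) amax <- pool_amax(pool, twitch)
  dt <- twitch$dt
  n <- floor(horizon / dt) + 1L
  keep <- (seq_len(n) - 1) * dt >= horizon - avg_window
  Delta <- if (pool$rate_family == "linear") pool$Delta else rep(1, pool$spec$N)
  fam <- if (pool$rate_family == "linear") 0L else 1L
  FM <- vapply(I_grid, function(I) {
    res <- sim_pool_cpp(rep(I, n), rep(0, n), rep(g, n), 0,
                        pool$delta, Delta, pool$strengths, pool$rmax,
                        fam, pool$kr, twitch$Ad, twitch$gain, amax, dt, FALSE)
    mean(res$FM[keep])
  }, numeric(1))
  data.frame(I = I_grid, FM = FM)
}

#' Consolidated error report across pools and tasks
#'
#' One row per (pool, task) with the three matching errors, the plateau
#' deviation where the task defines a plateau, and the control mode.
#'
#' @param pools Named list of [pool_model()] objects.
#' @param twitch A [calibrate_twitch()] model.
#' @param tasks Named list of `mu_task` objects.
#' @param drives Either a single [drive_params()] used for every pool or a
#'   named list parallel to `pools`.
#' @return Data frame with columns `pool`, `task`, `gamma`, `erms`, `emax`,
#'   `etot`, `plateau`.
#' @export
pool_error_report <- function(pools, twitch, tasks, drives) {
  if (inherits(drives, "drive_params"))
    drives <- setNames(rep(list(drives), length(pools)), names(pools))
  rows <- list()
  for (pn in names(pools)) {
    amax <- pool_amax(pools[[pn]], twitch)
    for (tn in names(tasks)) {
      sim <- simulate_pool(pools[[pn]], twitch, tasks[[tn]], drives[[pn]],
                           amax = amax, full_output = FALSE)
      err <- match_errors(sim)
      err$plateau <- if (!is.null(tasks[[tn]]$plateau_window))
        plateau_error(sim) else NA_real_
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(pool = pn, task = tn, gamma = drives[[pn]]$gamma),
              err)
    }
  }
  do.call(rbind, rows)
}
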