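#' Feedforward neural-drive parameters
#'
#' Parameters of the feedforward mapping
#' `Iff(t) = alpha0 + alpha1 * (Fd(t + tau*dt) / g(t + tau*dt))^beta`:
#' a baseline muscle tone `alpha0` \[N\], a scale `alpha1` \[N\], a shape
#' exponent `beta` and an integer look-ahead delay `tau` in samples.
#'
#' @param alpha0,alpha1 Baseline and scale \[N\].
#' @param beta Shape exponent (dimensionless).
#' @param tau Look-ahead in samples (integer `>= 0`).
#' @return Object of class `ff_params`.
#' @export
feedforward_params <- function(alpha0 = 0, alpha1 = 1, beta = 1, tau = 0L) {
  tau <- as.integer(round(tau))
  if (tau < 0) stop("tau must be a nonnegative integer (samples)")
  structure(list(alpha0 = alpha0, alpha1 = alpha1, beta = beta, tau = tau),
            class = "ff_params")
}

#' Neural-drive parameters (feedforward + feedback gain)
#'
#' @param ff A [feedforward_params()] object.
#' @param gamma Feedback gain on the idealized force error
#'   `Ifb(t) = Fd(t) - FM(t)`; `gamma = 0` disables feedback.
#' @return Object of class `drive_params`.
#' @export
drive_params <- function(ff = feedforward_params(), gamma = 0) {
  stopifnot(inherits(ff, "ff_params"))
  structure(list(ff = ff, gamma = gamma), class = "drive_params")
}

#' Feedforward neural drive for a task
#'
#' Evaluates `Iff(t) = alpha0 + alpha1 * x(t)^beta` with
#' `x(t) = Fd(t + tau*dt) / g(t + tau*dt)`. The look-ahead holds the final
#' sample beyond the task end; for negative exponents `x` is floored at
#' `1e-9 * Fmax` before exponentiation so the mapping stays finite. With
#' `Fd = 0` and `beta > 0` the drive reduces to the baseline `alpha0`.
#'
#' @param task A `mu_task`.
#' @param ff A [feedforward_params()] object.
#' @param Fmax Muscle strength \[N\] setting the flooring scale; defaults to
#'   the task's peak desired force.
#' @return Numeric vector `Iff(t)` \[N\] on the task grid.
#' @export
feedforward_drive <- function(task, ff, Fmax = max(task$Fd)) {
  stopifnot(inherits(task, "mu_task"), inherits(ff, "ff_params"))
  n <- length(task$t)
  idx <- pmin(seq_len(n) + ff$tau, n)
  x <- task$Fd[idx] / task$g[idx]
  if (ff$beta < 0) {
    # flooring keeps negative exponents finite; with beta >= 0 the mapping
    # is already total and Fd = 0 yields exactly alpha0
    eps <- 1e-9 * max(Fmax, .Machine$double.eps)
    x <- pmax(x, eps)
  }
  ff$alpha0 + ff$alpha1 * x^ff$beta
}

#' Simulate a motor-unit pool on a task
#'
#' Runs the full pipeline on the task grid: neural drive
#' `I = Iff + gamma * Ifb` (the feedback error `Fd(t_k) - FM(t_{k-1})` uses
#' a one-step delay to break the algebraic loop), per-MU rate coding,
#' excitation impulse trains with discrete-time correction, third-order
#' activation dynamics with tetanic normalization, and force summation
#' `FM = sum_i fmax_i g a_bar_i`. With `gamma = 0` the result is identical
#' to running the open-loop pipeline end-to-end.
#'
#' @param pool A [pool_model()].
#' @param twitch A [calibrate_twitch()] model on the same `dt` as the task.
#' @param task A `mu_task`.
#' @param drive A [drive_params()] object.
#' @param amax Optional precomputed [pool_amax()] vector (computed on the
#'   fly when `NULL`).
#' @param full_output Keep per-MU rate and activation matrices and impulse
#'   trains (`TRUE`) or only the aggregate signals (`FALSE`, cheaper).
#' @return Object of class `mu_sim`: `t`, `FM`, `I`, `Iff`, `Ifb`,
#'   `n_impulses`, the `task` and labels; plus `rates`, `abar` (time x MU)
#'   and `trains` when `full_output`.
#' @export
simulate_pool <- function(pool, twitch, task, drive = drive_params(),
                          amax = NULL, full_output = TRUE) {
  stopifnot(inherits(pool, "mu_pool"), inherits(twitch, "twitch_model"),
            inherits(task, "mu_task"), inherits(drive, "drive_params"))
  if (abs(twitch$dt - task$dt) > 1e-12)
    stop("twitch model and task must share one time step")
  if (is.null(amax)) amax <- pool_amax(pool, twitch)
  Iff <- feedforward_drive(task, drive$ff, pool$spec$Fmax)
  Delta <- if (pool$rate_family == "linear") pool$Delta else rep(1, pool$spec$N)
  res <- sim_pool_cpp(Iff, task$Fd, task$g, drive$gamma,
                      pool$delta, Delta, pool$strengths, pool$rmax,
                      if (pool$rate_family == "linear") 0L else 1L,
                      pool$kr, twitch$Ad, twitch$gain, amax,
                      task$dt, isTRUE(full_output))
  out <- list(t = task$t, FM = res$FM, I = res$I, Iff = Iff, Ifb = res$Ifb,
              n_impulses = res$n_impulses, task = task,
              pool_label = pool$label, gamma = drive$gamma,
              strengths = pool$strengths)
  if (isTRUE(full_output)) {
    out$rates <- res$rates
    out$abar <- res$abar
    out$trains <- lapply(seq_along(res$trains), function(i)
      structure(list(phi = res$trains[[i]], n = length(res$trains[[i]]),
                     dt = task$dt, T_end = task$T_end, mu_index = i),
                class = "impulse_train"))
  }
  structure(out, class = "mu_sim")
}

#' Per-MU forces of a simulation
#'
#' @param sim A [simulate_pool()] result with `full_output = TRUE`.
#' @return Matrix (time x MU) of forces `f_i(t) = fmax_i g(t) a_bar_i(t)`.
#' @export
sim_mu_forces <- function(sim) {
  stopifnot(inherits(sim, "mu_sim"))
  if (is.null(sim$abar)) stop("simulation was run with full_output = FALSE")
  muscle_force(sim$abar, sim$strengths, sim$task$g)$f
}

#' @export
print.mu_sim <- function(x, ...) {
  cat(sprintf("<mu_sim %s on %s> gamma=%g, peak FM=%.2f N, %d impulses total\n",
              x$pool_label, x$task$label, x$gamma, max(x$FM),
              sum(x$n_impulses)))
  invisible(x)
}

#' Write a simulation result as delimited tables
#'
#' Writes the signal table `(t, Fd, g, Iff, Ifb, I, FM)` to `file` and,
#' when impulse trains are present, an event list next to it
#' (`<file>_events.tsv`).
#'
#' @param sim A [simulate_pool()] result.
#' @param file Output path for the signal table.
#' @export
write_sim_result <- function(sim, file) {
  stopifnot(inherits(sim, "mu_sim"))
  d <- data.frame(t = sim$t, Fd = sim$task$Fd, g = sim$task$g,
                  Iff = sim$Iff, Ifb = sim$Ifb, I = sim$I, FM = sim$FM)
  write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(sim$trains))
    write_event_list(sim$trains, sub("(\\.[^.]*)?$", "_events.tsv", file))
  invisible(file)
}
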