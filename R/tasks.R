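#' Minimum-jerk trajectory
#'
#' The standard quintic minimum-jerk profile
#' `s(u) = 10 u^3 - 15 u^4 + 6 u^5`, `u = t/T`, moving from `start` to
#' `start + delta` with zero velocity and acceleration at both ends.
#'
#' @param start Initial position.
#' @param delta Total displacement.
#' @param T_move Movement duration \[s\].
#' @param t Time points \[s\] at which to evaluate (clamped to `[0, T_move]`).
#' @return List with `position` and `velocity` vectors.
#' @export
minimum_jerk <- function(start, delta, T_move, t) {
  stopifnot(T_move > 0)
  u <- pmin(pmax(t / T_move, 0), 1)
  s <- 10 * u^3 - 15 * u^4 + 6 * u^5
  ds <- (30 * u^2 - 60 * u^3 + 30 * u^4) / T_move
  list(position = start + delta * s, velocity = delta * ds)
}

new_task <- function(t, Fd, g, label, length = NULL, velocity = NULL,
                     extra = list()) {
  dt <- t[2] - t[1]
  stopifnot(all(abs(diff(t) - dt) < 1e-9), all(Fd >= -1e-12), all(g > 0))
  structure(c(list(t = t, dt = dt, T_end = t[length(t)], Fd = pmax(Fd, 0),
                   g = g, label = label, length = length,
                   velocity = velocity), extra),
            class = "mu_task")
}

#' @export
print.mu_task <- function(x, ...) {
  cat(sprintf("<mu_task %s> T=%g s, dt=%g s, peak Fd=%.2f N, g in [%.2f, %.2f]\n",
              x$label, x$T_end, x$dt, max(x$Fd), min(x$g), max(x$g)))
  invisible(x)
}

# parabolic force pulse: zero at window ends, `peak` at the midpoint,
# zero-clamped outside the window
parabolic_pulse <- function(t, t0, t1, peak) {
  tc <- (t0 + t1) / 2
  w <- (t1 - t0) / 2
  pmax(peak * (1 - ((t - tc) / w)^2), 0)
}

#' Elementary task suite for neural-drive optimization
#'
#' Three contraction shapes at each force amplitude: an isometric
#' contraction and concentric and eccentric contractions in which the
#' muscle length follows a minimum-jerk excursion of +/-20% over the full
#' task. Every task lasts 2 s with a parabolic desired-force pulse spanning
#' 1 s: the first half of the movement for the concentric and isometric
#' tasks, the second half for the eccentric task. All contractions start at
#' optimal length; the isometric task has `g == 1`.
#'
#' @param spec A [muscle_spec()].
#' @param fvl An [fvl_params()] object for the gain computation.
#' @param amplitudes Peak desired forces as fractions of `Fmax`; the presets
#'   used for fitting are `c(0.3, 0.5)` for the TA and `c(0.05, 0.2)` for
#'   the SF.
#' @param T_task Task duration \[s\].
#' @param dt Grid step \[s\].
#' @param length_change Relative length excursion for the dynamic shapes.
#' @return Named list of `3 * length(amplitudes)` tasks (class `mu_task`).
#' @export
elementary_tasks <- function(spec, fvl = fvl_params(),
                             amplitudes = if (identical(spec$label, "SF"))
                               c(0.05, 0.2) else c(0.3, 0.5),
                             T_task = 2, dt = 0.002, length_change = 0.2) {
  validate_muscle_spec(spec)
  if (any(amplitudes <= 0 | amplitudes > 1))
    stop("amplitudes must be fractions of Fmax in (0, 1]")
  t <- seq(0, T_task, by = dt)
  out <- list()
  for (amp in amplitudes) {
    peak <- amp * spec$Fmax
    for (shape in c("concentric", "isometric", "eccentric")) {
      if (shape == "isometric") {
        len <- rep(1, length(t)); vel <- rep(0, length(t)); g <- rep(1, length(t))
      } else {
        dl <- if (shape == "concentric") -length_change else length_change
        mj <- minimum_jerk(1, dl, T_task, t)
        len <- mj$position; vel <- mj$velocity
        g <- fvl_gain(len, vel, fvl)
      }
      win <- if (shape == "eccentric") c(T_task / 2, T_task) else c(0, T_task / 2)
      Fd <- parabolic_pulse(t, win[1], win[2], peak)
      lbl <- sprintf("%s-%s-%.2fFmax", spec$label, shape, amp)
      out[[lbl]] <- new_task(t, Fd, g, lbl, len, vel,
                             extra = list(amplitude = amp, shape = shape))
    }
  }
  out
}

#' Isometric trapezoidal force task
#'
#' Ramp-hold-ramp desired-force profile at optimal length (`g == 1`):
#' a zero lead-in, a linear ramp at `ramp_rate` (fraction of `Fmax` per
#' second) up to `level_fraction * Fmax`, a plateau, a symmetric ramp down
#' and a zero tail. The plateau window is carried in the task for plateau
#' error scoring.
#'
#' @param spec A [muscle_spec()].
#' @param level_fraction Plateau level as a fraction of `Fmax` (the test
#'   protocols use 0.3 and 0.5).
#' @param ramp_rate Ramp slope \[fraction of Fmax per s\].
#' @param plateau_s Plateau duration \[s\].
#' @param lead_s Zero-force lead-in and tail \[s\].
#' @param dt Grid step \[s\].
#' @return A `mu_task` with `plateau_window = c(start, end)` \[s\].
#' @export
trapezoid_task <- function(spec, level_fraction, ramp_rate = 0.05,
                           plateau_s = 10, lead_s = 1, dt = 0.002) {
  validate_muscle_spec(spec)
  stopifnot(level_fraction > 0, level_fraction <= 1, ramp_rate > 0)
  ramp_s <- level_fraction / ramp_rate
  T_task <- 2 * lead_s + 2 * ramp_s + plateau_s
  t <- seq(0, T_task, by = dt)
  lvl <- level_fraction * spec$Fmax
  up0 <- lead_s; up1 <- lead_s + ramp_s
  dn0 <- up1 + plateau_s; dn1 <- dn0 + ramp_s
  Fd <- ifelse(t < up0, 0,
        ifelse(t < up1, lvl * (t - up0) / ramp_s,
        ifelse(t < dn0, lvl,
        ifelse(t < dn1, lvl * (dn1 - t) / ramp_s, 0))))
  lbl <- sprintf("%s-trapezoid-%.2fFmax", spec$label, level_fraction)
  new_task(t, Fd, rep(1, length(t)), lbl,
           length = rep(1, length(t)), velocity = rep(0, length(t)),
           extra = list(level_fraction = level_fraction,
                        plateau_window = c(up1, dn0)))
}

#' Seeded synthetic reaching-style tasks
#'
#' Generates reproducible low-amplitude multi-peaked force tasks with
#' nonmonotonic gain trajectories, emulating the force demands a shoulder
#' flexor sees during reaching while undergoing prescribed length changes.
#' These are synthetic fixtures: desired force is a sum of 1-3 smooth
#' raised-cosine pulses with the overall peak drawn in
#' `[0.05, 0.2] * Fmax` (the first task always has two peaks separated by a
#' deep minimum), and the gain derives from a minimum-jerk length excursion
#' within +/-20% of optimal and its velocity.
#'
#' @param spec A [muscle_spec()].
#' @param fvl An [fvl_params()] object.
#' @param n Number of tasks.
#' @param seed Integer seed; identical seeds give identical suites.
#' @param dt Grid step \[s\].
#' @return Named list of `mu_task` objects.
#' @export
synthetic_reach_tasks <- function(spec, fvl = fvl_params(), n = 4,
                                  seed = 1, dt = 0.002) {
  validate_muscle_spec(spec)
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- list()
  for (k in seq_len(n)) {
    T_task <- round(runif(1, 1, 2) / dt) * dt
    t <- seq(0, T_task, by = dt)
    npulse <- if (k == 1) 2L else sample(1:3, 1)
    if (k == 1) {
      # two well-separated pulses -> deep inter-peak minimum
      centers <- c(0.25, 0.75) * T_task
      widths <- c(0.12, 0.12) * T_task
      amps <- c(1, runif(1, 0.6, 1))
    } else {
      centers <- sort(runif(npulse, 0.2, 0.8)) * T_task
      widths <- runif(npulse, 0.08, 0.2) * T_task
      amps <- runif(npulse, 0.4, 1)
    }
    Fd <- rep(0, length(t))
    for (p in seq_len(npulse)) {
      u <- (t - centers[p]) / widths[p]
      Fd <- Fd + amps[p] * ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)
    }
    peak <- runif(1, 0.05, 0.2) * spec$Fmax
    Fd <- Fd / max(Fd) * peak
    dl <- runif(1, -0.2, 0.2)
    mj <- minimum_jerk(1, dl, T_task, t)
    g <- fvl_gain(mj$position, mj$velocity, fvl)
    lbl <- sprintf("%s-reach-%02d", spec$label, k)
    out[[lbl]] <- new_task(t, Fd, g, lbl, mj$position, mj$velocity,
                           extra = list(seed = seed, synthetic = TRUE))
  }
  out
}

#' Write a task as a delimited table
#'
#' Tab-separated columns `t`, `Fd`, `g` and, when present, `length`,
#' `velocity`.
#'
#' @param task A `mu_task`.
#' @param file Output path.
#' @export
write_task <- function(task, file) {
  stopifnot(inherits(task, "mu_task"))
  d <- data.frame(t = task$t, Fd = task$Fd, g = task$g)
  if (!is.null(task$length)) {
    d$length <- task$length
    d$velocity <- task$velocity
  }
  write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a task table
#'
#' Accepts either a precomputed `g` column or `length`/`velocity` columns
#' from which the gain is computed with [fvl_gain()].
#'
#' @param file Path to a table written by [write_task()] (or assembled by
#'   hand with the same header).
#' @param fvl An [fvl_params()] object used when `g` is absent.
#' @param label Task label; defaults to the file name.
#' @return A `mu_task`.
#' @export
read_task <- function(file, fvl = fvl_params(), label = NULL) {
  d <- read.table(file, header = TRUE, sep = "\t")
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(file))
  if (!"g" %in% names(d)) {
    if (!all(c("length", "velocity") %in% names(d)))
      stop("task file needs a g column or length + velocity columns")
    d$g <- fvl_gain(d$length, d$velocity, fvl)
  }
  new_task(d$t, d$Fd, d$g, label,
           length = d$length, velocity = d$velocity)
}

#' Write a task suite with a provenance manifest
#'
#' @param suite Named list of `mu_task` objects.
#' @param dir Output directory (created if missing).
#' @param manifest Extra provenance fields (generator parameters, seed)
#'   stored alongside the task list in `manifest.yaml`.
#' @return The directory, invisibly.
#' @export
write_task_suite <- function(suite, dir, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(suite)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    write_task(suite[[nm]], f)
    files[nm] <- basename(f)
  }
  yaml::write_yaml(c(list(tasks = as.list(files)), manifest),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
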