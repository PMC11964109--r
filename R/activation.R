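# Third-order twitch activation dynamics: a cascade of three first-order
# stages with time constants (tau, tau, tau_c). The analytic unit-jump
# impulse response (state x1 jumped to 1, output x3) is, with a = 1/tau,
# b = 1/tau_c, c = b - a:
#   x3(t) = a*b * [ (t/c) e^{-a t} - (e^{-a t} - e^{-b t}) / c^2 ]
# The response is nonnegative and single-peaked; `gain` rescales it to unit
# peak so one excitation impulse yields one unit-amplitude twitch.

cascade_response <- function(t, tau, tau_c) {
  a <- 1 / tau
  b <- 1 / tau_c
  c <- b - a
  if (abs(c) < 1e-8 * a) {
    # equal-constant limit: x3 = a^2 t^2 / 2 * exp(-a t)
    a^2 * t^2 / 2 * exp(-a * t)
  } else {
    a * b * ((t / c) * exp(-a * t) - (exp(-a * t) - exp(-b * t)) / c^2)
  }
}

# exact one-step state transition exp(A * dt) of the lower-triangular
# cascade, in closed form (series limit when the constants nearly coincide)
cascade_transition <- function(tau, tau_c, dt) {
  a <- 1 / tau
  b <- 1 / tau_c
  cc <- b - a
  E1 <- exp(-a * dt)
  E3 <- exp(-b * dt)
  if (abs(cc) < 1e-6 * a) {
    m31 <- (a * dt)^2 / 2 * E1
    m32 <- a * dt * E1
  } else {
    m31 <- a * b * ((dt / cc) * E1 - (E1 - E3) / cc^2)
    m32 <- b * (E1 - E3) / cc
  }
  matrix(c(E1, 0, 0,
           a * dt * E1, E1, 0,
           m31, m32, E3), 3, 3, byrow = TRUE)
}

cascade_shape <- function(tau, tau_c, t_fine) {
  h <- cascade_response(t_fine, tau, tau_c)
  ip <- which.max(h)
  tp <- t_fine[ip]
  half <- h[ip] / 2
  post <- h[seq(ip, length(h))]
  ih <- which(post <= half)[1]
  th <- if (is.na(ih)) NA_real_ else t_fine[ip + ih - 1] - tp
  list(tp = tp, thr = th, peak = h[ip])
}

#' Calibrate third-order twitch dynamics to time-to-peak and half-relaxation
#'
#' Finds the two free time constants of a third-order linear cascade
#' (`tau`, `tau`, `tau_c`) so that the unit-impulse response peaks at `Tp`
#' and decays to half its peak `Thr` after the peak. The response is
#' normalized to unit peak; the exact one-step transition matrix for the
#' simulation grid `dt` is precomputed so impulses can be integrated as
#' state jumps without discretization error in the linear stages.
#'
#' @param Tp Twitch time-to-peak \[s\].
#' @param Thr Twitch half-relaxation time (peak to half-peak) \[s\].
#' @param dt Simulation time step \[s\].
#' @param tol Calibration tolerance on each timing residual \[s\]; defaults
#'   to half a grid step.
#' @return An object of class `twitch_model` with fields `tau` (length-3
#'   vector), `gain`, `Ad` (3 x 3 one-step transition matrix), `Tp`, `Thr`,
#'   `dt`, and `integral` (time integral of the unit-peak twitch \[s\]).
#' @examples
#' tw <- calibrate_twitch(0.060, 0.070, dt = 0.002)
#' tw$Tp
#' @export
calibrate_twitch <- function(Tp, Thr, dt = 0.002, tol = dt / 2) {
  stopifnot(Tp > 0, Thr > 0, dt > 0)
  t_fine <- seq(0, max(20 * Tp, 20 * Thr, 1), by = 1e-5)
  resid <- function(p) {
    s <- cascade_shape(exp(p[1]), exp(p[2]), t_fine)
    if (is.na(s$thr)) return(1e6)
    (s$tp - Tp)^2 + (s$thr - Thr)^2
  }
  best <- NULL
  for (start in list(c(Tp / 2, Thr / 2), c(Tp / 3, Thr), c(Tp / 2, Thr / 5))) {
    fit <- optim(log(start), resid, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  tau <- exp(best$par[1])
  tau_c <- exp(best$par[2])
  s <- cascade_shape(tau, tau_c, t_fine)
  if (is.na(s$thr) || abs(s$tp - Tp) > tol || abs(s$thr - Thr) > tol)
    stop(sprintf(paste0("twitch calibration failed: requested Tp=%.1f ms, Thr=%.1f ms; ",
                        "achieved Tp=%.2f ms, Thr=%.2f ms (third-order cascade ",
                        "cannot realize this shape)"),
                 1000 * Tp, 1000 * Thr, 1000 * s$tp, 1000 * s$thr))
  gain <- 1 / s$peak
  Ad <- cascade_transition(tau, tau_c, dt)
  structure(list(tau = c(tau, tau, tau_c), gain = gain, Ad = Ad,
                 Tp = Tp, Thr = Thr, dt = dt,
                 integral = gain * tau),
            class = "twitch_model")
}

#' Unit-impulse twitch response on the simulation grid
#'
#' @param twitch A [calibrate_twitch()] model.
#' @param T_end Duration \[s\].
#' @return Data frame with columns `t` and `a`: the unit-peak twitch sampled
#'   at the model's `dt`.
#' @export
twitch_response <- function(twitch, T_end = 0.5) {
  stopifnot(inherits(twitch, "twitch_model"))
  n <- floor(T_end / twitch$dt) + 1L
  a <- twitch_filter_cpp(0L, n, twitch$Ad, twitch$gain)
  data.frame(t = (seq_len(n) - 1) * twitch$dt, a = a)
}

#' @export
print.twitch_model <- function(x, ...) {
  cat(sprintf("<twitch_model> tau = (%.2f, %.2f, %.2f) ms, Tp=%g ms, Thr=%g ms, dt=%g ms\n",
              1000 * x$tau[1], 1000 * x$tau[2], 1000 * x$tau[3],
              1000 * x$Tp, 1000 * x$Thr, 1000 * x$dt))
  invisible(x)
}

#' Unnormalized activation driven by an impulse train
#'
#' Integrates the calibrated third-order cascade over the simulation grid
#' with each excitation impulse entering as a unit state jump at its grid
#' time; by linearity the response to a train is the superposition of
#' unit-peak twitches.
#'
#' @param train An [build_impulse_train()] object (or a numeric vector of
#'   firing times on the grid).
#' @param twitch A [calibrate_twitch()] model.
#' @param T_end Duration \[s\]; defaults to the train's horizon.
#' @return Numeric vector `a(t)` on the grid, `a >= 0`.
#' @export
unnormalized_activation <- function(train, twitch, T_end = NULL) {
  stopifnot(inherits(twitch, "twitch_model"))
  phi <- if (inherits(train, "impulse_train")) train$phi else as.numeric(train)
  if (is.null(T_end))
    T_end <- if (inherits(train, "impulse_train")) train$T_end else
      (if (length(phi)) max(phi) + 1 else 1)
  n <- floor(T_end / twitch$dt) + 1L
  steps <- as.integer(round(phi / twitch$dt))
  twitch_filter_cpp(steps, n, twitch$Ad, twitch$gain)
}

#' Tetanic normalization constant for a maximum firing rate
#'
#' Simulates sustained firing at rate `rmax_i` (impulse train built with the
#' same discrete-time rules as the simulator) for `horizon` seconds and
#' returns the mean unnormalized activation over the final `avg_window`
#' seconds. Dividing by this constant makes the steady-state mean activation
#' at maximal rate equal one.
#'
#' @param rmax_i Maximum firing rate \[Hz\], > 0.
#' @param twitch A [calibrate_twitch()] model.
#' @param horizon Simulated duration \[s\].
#' @param avg_window Averaging window at the end of the horizon \[s\].
#' @return Scalar `amax_i` > 0.
#' @export
tetanic_norm <- function(rmax_i, twitch, horizon = 4, avg_window = 1) {
  stopifnot(rmax_i > 0, inherits(twitch, "twitch_model"))
  dt <- twitch$dt
  n <- floor(horizon / dt) + 1L
  phi <- build_train_cpp(rep(rmax_i, n), dt)
  a <- twitch_filter_cpp(as.integer(round(phi / dt)), n, twitch$Ad, twitch$gain)
  keep <- (seq_len(n) - 1) * dt >= horizon - avg_window
  mean(a[keep])
}

#' Per-MU tetanic normalization constants for a pool
#'
#' Computes [tetanic_norm()] for each MU's maximum firing rate, caching by
#' distinct rate value (the constant-rmax scheme needs a single evaluation).
#'
#' @param pool A [pool_model()].
#' @param twitch A [calibrate_twitch()] model.
#' @return Numeric vector `amax` of length `N`.
#' @export
pool_amax <- function(pool, twitch) {
  stopifnot(inherits(pool, "mu_pool"))
  key <- round(pool$rmax, 10)
  uq <- unique(key)
  vals <- vapply(uq, tetanic_norm, numeric(1), twitch = twitch)
  vals[match(key, uq)]
}

#' Normalized activation
#'
#' `a_bar(t) = min(a(t) / amax_i, 1)`: activation normalized by the tetanic
#' constant and clipped at one to absorb the ripple of the periodic tetanic
#' response above its mean.
#'
#' @inheritParams unnormalized_activation
#' @param amax_i Tetanic normalization constant from [tetanic_norm()].
#' @return Numeric vector in \[0, 1\].
#' @export
normalized_activation <- function(train, twitch, amax_i, T_end = NULL) {
  stopifnot(amax_i > 0)
  a <- unnormalized_activation(train, twitch, T_end)
  pmin(pmax(a / amax_i, 0), 1)
}
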