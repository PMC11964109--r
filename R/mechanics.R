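#' Hill-type force-velocity-length gain parameters
#'
#' Parameters of the default gain model used when a task supplies length and
#' velocity trajectories instead of a precomputed gain: a Gaussian
#' force-length bell on normalized length and a Hill hyperbola on normalized
#' shortening velocity with a saturating eccentric branch.
#'
#' @param fl_width Width of the force-length bell on normalized length
#'   (dimensionless).
#' @param v_max Maximum normalized shortening speed \[optimal lengths / s\].
#' @param hill_a Force-velocity curvature (dimensionless); smaller is more
#'   curved.
#' @param ecc_plateau Eccentric force ceiling (dimensionless, `>= 1`).
#' @return Object of class `fvl_params`.
#' @export
fvl_params <- function(fl_width = 0.45, v_max = 5, hill_a = 0.25,
                       ecc_plateau = 1.5) {
  stopifnot(fl_width > 0, v_max > 0, hill_a > 0, ecc_plateau >= 1)
  structure(list(fl_width = fl_width, v_max = v_max, hill_a = hill_a,
                 ecc_plateau = ecc_plateau), class = "fvl_params")
}

fl_gain <- function(length, params) {
  exp(-((length - 1) / params$fl_width)^2)
}

# velocity convention: v = d(length)/dt, so shortening has v < 0
fv_gain <- function(velocity, params) {
  s <- -velocity / params$v_max          # normalized shortening speed
  out <- numeric(length(s))
  con <- s >= 0                          # shortening (or isometric)
  a <- params$hill_a
  out[con] <- pmax(0, (1 - pmin(s[con], 1)) / (1 + s[con] / a))
  ecc <- !con
  w <- -s[ecc]                           # normalized lengthening speed, > 0
  out[ecc] <- 1 + (params$ecc_plateau - 1) * w / (w + 0.15)
  out
}

#' Force-velocity-length gain trajectory
#'
#' `g(t) = fL(length(t)) * fV(velocity(t))`, the multiplicative scaling of
#' the muscle's force capacity by its instantaneous length and contraction
#' velocity. `fL` is a Gaussian bell equal to 1 at optimal length; `fV` is 1
#' at zero velocity, decreases hyperbolically with shortening speed reaching
#' 0 at `v_max`, and saturates at `ecc_plateau` for lengthening.
#'
#' @param length Normalized length trajectory (1 = optimal).
#' @param velocity Normalized velocity trajectory
#'   \[optimal lengths / s\], positive = lengthening.
#' @param params An [fvl_params()] object.
#' @return Numeric vector `g(t) >= 0`.
#' @export
fvl_gain <- function(length, velocity, params = fvl_params()) {
  stopifnot(inherits(params, "fvl_params"))
  if (length(length) != length(velocity))
    stop("length and velocity trajectories must share one grid")
  fl_gain(length, params) * fv_gain(velocity, params)
}

#' Muscle force from per-MU activations
#'
#' `f_i(t) = fmax_i * g(t) * a_bar_i(t)` and `FM(t) = sum_i f_i(t)`.
#'
#' @param a_bar Matrix of normalized activations (time steps x MUs) or a
#'   vector for a single MU.
#' @param strengths Per-MU isometric strengths \[N\].
#' @param g Gain trajectory `g(t)` (recycled if scalar).
#' @return List with `FM` (total force \[N\]) and `f` (per-MU force matrix).
#' @export
muscle_force <- function(a_bar, strengths, g = 1) {
  if (is.vector(a_bar)) a_bar <- matrix(a_bar, ncol = 1)
  if (ncol(a_bar) != length(strengths))
    stop("a_bar columns must match the number of MU strengths")
  if (length(g) == 1L) g <- rep(g, nrow(a_bar))
  if (length(g) != nrow(a_bar))
    stop("g(t) must match the activation time grid")
  f <- sweep(a_bar, 2, strengths, `*`) * g
  list(FM = rowSums(f), f = f)
}
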