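#' Muscle-level parameter set for a motor-unit pool
#'
#' Bundles the muscle-level quantities from which every pool variant is
#' derived: pool size, muscle strength, the range of MU strengths, the first
#' and last recruitment thresholds, the maximum firing rate of the first MU,
#' twitch timing, and the constants of the maximum-firing-rate schemes and of
#' the logarithmic rate function.
#'
#' Two presets are built in: `"TA"`, a tibialis anterior modelled as a full
#' pool of 400 MUs (Fmax = 400 N, Rf = 100, thresholds 0.5 N to 0.5 Fmax,
#' rmax1 = 25 Hz, twitch 60/70 ms), and `"SF"`, a generic shoulder flexor
#' represented by its 200 smallest MUs (Fmax = 200 N, Rf = 10, thresholds
#' 0.5 N to 0.95 Fmax, rmax1 = 50 Hz, twitch 70/80 ms).
#'
#' @param muscle Preset name, `"TA"` or `"SF"`, or `NULL` to build a spec
#'   purely from the named arguments.
#' @param ... Overrides for any field of the preset: `N`, `Fmax`, `Rf`,
#'   `delta1`, `deltaN`, `rmax1`, `Tp`, `Thr`, `rho1`, `rho2`, `d1`, `d2`,
#'   `Rr`, `c1`, `c2`, `rmin`, `label`.
#'
#' @return An object of class `muscle_spec` (a named list).
#' @examples
#' ta <- muscle_spec("TA")
#' ta$Fmax
#' small <- muscle_spec("TA", N = 25)
#' @export
muscle_spec <- function(muscle = "TA", ...) {
  presets <- list(
    TA = list(N = 400L, Fmax = 400, Rf = 100, delta1 = 0.5, deltaN = 0.5 * 400,
              rmax1 = 25, Tp = 0.060, Thr = 0.070, label = "TA"),
    SF = list(N = 200L, Fmax = 200, Rf = 10, delta1 = 0.5, deltaN = 0.95 * 200,
              rmax1 = 50, Tp = 0.070, Thr = 0.080, label = "SF")
  )
  common <- list(rho1 = 0.25, rho2 = 0.05, d1 = 0.1, d2 = 1.47, Rr = 2.4,
                 c1 = 29.195, c2 = 1.833, rmin = 0)
  if (is.null(muscle)) {
    spec <- c(list(label = "custom"), common)
  } else {
    muscle <- match.arg(muscle, names(presets))
    spec <- c(presets[[muscle]], common)
  }
  dots <- list(...)
  # deltaN given as a fraction of an overridden Fmax must be recomputed by the
  # caller; overrides are taken literally.
  spec <- modifyList(spec, dots)
  spec$N <- as.integer(spec$N)
  structure(spec, class = "muscle_spec")
}

validate_muscle_spec <- function(spec) {
  stopifnot(inherits(spec, "muscle_spec"))
  if (spec$N < 2L) stop("muscle_spec: N must be >= 2")
  if (spec$Fmax <= 0) stop("muscle_spec: Fmax must be positive")
  if (spec$Rf <= 0) stop("muscle_spec: Rf must be positive")
  if (!(spec$delta1 > 0 && spec$delta1 < spec$deltaN && spec$deltaN < spec$Fmax))
    stop("muscle_spec: need 0 < delta1 < deltaN < Fmax")
  if (spec$rmax1 <= 0) stop("muscle_spec: rmax1 must be positive")
  if (spec$Tp <= 0 || spec$Thr <= 0) stop("muscle_spec: twitch times must be positive")
  invisible(spec)
}

#' @export
print.muscle_spec <- function(x, ...) {
  cat(sprintf("<muscle_spec %s> N=%d Fmax=%g N, Rf=%g, thresholds [%g, %g] N, rmax1=%g Hz, twitch %g/%g ms\n",
              x$label, x$N, x$Fmax, x$Rf, x$delta1, x$deltaN, x$rmax1,
              1000 * x$Tp, 1000 * x$Thr))
  invisible(x)
}
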