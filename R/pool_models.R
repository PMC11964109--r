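#' Per-MU isometric strengths
#'
#' Distributes the muscle strength `Fmax` over `N` motor units so that
#' strengths grow geometrically from smallest to largest with range
#' `Rf = fmax_N / fmax_1`:
#' `fmax_i = Rf^((i-1)/(N-1)) / sum_j Rf^((j-1)/(N-1)) * Fmax`.
#'
#' @param spec A [muscle_spec()].
#' @return Numeric vector of length `N`, strictly increasing, summing to
#'   `Fmax`.
#' @examples
#' f <- mu_strengths(muscle_spec("TA"))
#' sum(f)          # 400
#' f[400] / f[1]   # 100
#' @export
mu_strengths <- function(spec) {
  validate_muscle_spec(spec)
  w <- spec$Rf^((seq_len(spec$N) - 1) / (spec$N - 1))
  w / sum(w) * spec$Fmax
}

#' Derived recruitment-threshold parameter for a threshold family
#'
#' Each threshold family carries one derived parameter fixed by the first and
#' last recruitment thresholds so that all pool variants for one muscle share
#' the same threshold range: the exponential family's threshold range
#' `Rd = deltaN / delta1`; the strength-matched family's band overlap
#' `b1 = 1 - (deltaN - delta1) / (Fmax - fmax_N)`; the mixed family's
#' `Rc = (deltaN - c1) / delta1`.
#'
#' @param spec A [muscle_spec()].
#' @param family `"exponential"`, `"matched"` or `"mixed"`.
#' @return A single numeric value (`Rd`, `b1` or `Rc`).
#' @examples
#' derive_threshold_params(muscle_spec("TA"), "exponential") # 400
#' derive_threshold_params(muscle_spec("SF"), "mixed")       # 321.61
#' @export
derive_threshold_params <- function(spec,
                                    family = c("exponential", "matched", "mixed")) {
  validate_muscle_spec(spec)
  family <- match.arg(family)
  switch(family,
    exponential = spec$deltaN / spec$delta1,
    matched = {
      fmaxN <- mu_strengths(spec)[spec$N]
      b1 <- 1 - (spec$deltaN - spec$delta1) / (spec$Fmax - fmaxN)
      if (b1 < 0 || b1 > 1)
        stop(sprintf("matched-threshold overlap b1 = %.4f outside [0, 1]", b1))
      b1
    },
    mixed = {
      if (spec$deltaN <= spec$c1)
        stop("mixed thresholds need deltaN > c1")
      (spec$deltaN - spec$c1) / spec$delta1
    }
  )
}

#' Recruitment thresholds and bandwidths
#'
#' Builds the per-MU recruitment thresholds `delta_i` and, where applicable,
#' recruitment bandwidths `Delta_i` for one of three families:
#'
#' * `exponential`: `delta_i = delta1 * Rd^((i-1)/(N-1))` with a constant
#'   bandwidth `Delta = Fmax - delta1 * Rd` shared by all MUs.
#' * `matched`: bandwidth matched to MU strength, `Delta_i = fmax_i`, with
#'   thresholds advancing by `Delta_{i-1} * (1 - b1)` so adjacent bands
#'   overlap by the fraction `b1`.
#' * `mixed`: `delta_i = delta1 * Rc^(((i-1)/(N-1))^c2) + c1 * (i-1)/(N-1)`;
#'   saturation is supplied implicitly by the logarithmic rate function, so
#'   no bandwidth is defined (`Delta` is `NA`).
#'
#' @inheritParams derive_threshold_params
#' @return List with `delta` (length `N`), `Delta` (length `N`, `NA` for the
#'   mixed family) and the derived parameter under its own name.
#' @export
recruitment_thresholds <- function(spec,
                                   family = c("exponential", "matched", "mixed")) {
  validate_muscle_spec(spec)
  family <- match.arg(family)
  N <- spec$N
  u <- (seq_len(N) - 1) / (N - 1)
  par <- derive_threshold_params(spec, family)
  out <- switch(family,
    exponential = {
      delta <- spec$delta1 * par^u
      list(delta = delta,
           Delta = rep(spec$Fmax - spec$delta1 * par, N),
           Rd = par)
    },
    matched = {
      f <- mu_strengths(spec)
      delta <- numeric(N)
      delta[1] <- spec$delta1
      for (i in 2:N) delta[i] <- delta[i - 1] + f[i - 1] * (1 - par)
      list(delta = delta, Delta = f, b1 = par)
    },
    mixed = {
      delta <- spec$delta1 * par^(u^spec$c2) + spec$c1 * u
      list(delta = delta, Delta = rep(NA_real_, N), Rc = par)
    }
  )
  if (any(diff(out$delta) <= 0))
    stop("recruitment thresholds are not strictly increasing")
  if (abs(out$delta[N] - spec$deltaN) > 0.005 * spec$deltaN)
    stop(sprintf("last threshold %.3f deviates from deltaN %.3f by > 0.5%%",
                 out$delta[N], spec$deltaN))
  out
}

#' Maximum firing-rate profile across the pool
#'
#' Three schemes for the per-MU maximum firing rate: `constant`
#' (`rmax_i = rmax1`), `linear` (`rmax_i = rmax1 * (1 - rho1 (i-1)/(N-1))`)
#' and `exponential` (`rmax_i = rmax1 * i^-rho2`). The decreasing schemes
#' enforce onion-skin behaviour (later-recruited MUs sustain lower rates).
#'
#' @param spec A [muscle_spec()].
#' @param scheme `"constant"`, `"linear"` or `"exponential"`.
#' @return Numeric vector of length `N`, non-increasing, first element
#'   `rmax1`.
#' @export
rmax_profile <- function(spec, scheme = c("constant", "linear", "exponential")) {
  validate_muscle_spec(spec)
  scheme <- match.arg(scheme)
  N <- spec$N
  out <- switch(scheme,
    constant = rep(spec$rmax1, N),
    linear = {
      if (spec$rho1 >= 1) stop("rho1 >= 1 gives nonpositive maximum rates")
      spec$rmax1 * (1 - spec$rho1 * (seq_len(N) - 1) / (N - 1))
    },
    exponential = spec$rmax1 * seq_len(N)^(-spec$rho2)
  )
  out
}

#' Construct one of the nine motor-unit pool variants
#'
#' A pool variant pairs a recruitment-threshold family with its rate-coding
#' function (linear for exponential and strength-matched thresholds,
#' logarithmic for mixed thresholds) and one of three maximum-firing-rate
#' schemes, giving nine variants in total.
#'
#' @inheritParams derive_threshold_params
#' @param rmax_scheme Passed to [rmax_profile()].
#' @return An object of class `mu_pool` with the per-MU vectors `delta`,
#'   `Delta`, `strengths`, `rmax`, the `rate_family`, the derived threshold
#'   parameter and the originating `spec`.
#' @examples
#' pool <- pool_model(muscle_spec("TA"), "matched", "constant")
#' pool
#' @export
pool_model <- function(spec,
                       threshold_family = c("exponential", "matched", "mixed"),
                       rmax_scheme = c("constant", "linear", "exponential")) {
  threshold_family <- match.arg(threshold_family)
  rmax_scheme <- match.arg(rmax_scheme)
  thr <- recruitment_thresholds(spec, threshold_family)
  rate_family <- if (threshold_family == "mixed") "logarithmic" else "linear"
  rmax <- rmax_profile(spec, rmax_scheme)
  pool <- structure(list(
    spec = spec,
    threshold_family = threshold_family,
    rate_family = rate_family,
    rmax_scheme = rmax_scheme,
    delta = thr$delta,
    Delta = thr$Delta,
    strengths = mu_strengths(spec),
    rmax = rmax,
    derived = thr[[length(thr)]],
    label = paste0(c(exponential = "exp-lin", matched = "matched-lin",
                     mixed = "mixed-log")[threshold_family], " ",
                   c(constant = "const", linear = "lin",
                     exponential = "exp")[rmax_scheme])
  ), class = "mu_pool")
  # kr_i = d1 * Rr^((i/N)^d2) / delta_i, the LIF time-scale constant of the
  # logarithmic rate function (only used by the mixed family)
  i <- seq_len(spec$N)
  pool$kr <- spec$d1 * spec$Rr^((i / spec$N)^spec$d2) / pool$delta
  pool
}

#' All nine pool variants for one muscle
#'
#' @param spec A [muscle_spec()].
#' @return Named list of nine `mu_pool` objects (threshold family crossed
#'   with rmax scheme), names matching their `label`s.
#' @export
all_pool_variants <- function(spec) {
  out <- list()
  for (tf in c("exponential", "matched", "mixed"))
    for (rs in c("constant", "linear", "exponential")) {
      p <- pool_model(spec, tf, rs)
      out[[p$label]] <- p
    }
  out
}

#' Instantaneous firing rates of all MUs at a drive level
#'
#' Evaluates the pool's rate-coding function at neural drive `I`. The linear
#' family rises from 0 at the recruitment threshold to `rmax_i` over the
#' bandwidth `Delta_i` (minimum rate 0); the logarithmic family is the
#' steady-state rate of a leaky integrate-and-fire motor neuron, 0 at and
#' below threshold and saturating towards `rmax_i` as drive grows.
#'
#' @param pool A [pool_model()].
#' @param I Neural drive value(s) \[N\]; any real value is admissible
#'   (sub-threshold or negative drive recruits nothing).
#' @return If `I` is scalar, a length-`N` vector of rates \[Hz\]; otherwise a
#'   `length(I) x N` matrix.
#' @export
firing_rates <- function(pool, I) {
  stopifnot(inherits(pool, "mu_pool"))
  one <- function(Ival) {
    if (pool$rate_family == "linear") {
      r <- pool$rmax * (Ival - pool$delta) / pool$Delta
      r[Ival <= pool$delta] <- 0
      pmin(pmax(r, 0), pool$rmax)
    } else {
      r <- numeric(pool$spec$N)
      on <- Ival > pool$delta * (1 + 1e-12)
      if (any(on)) {
        inv <- 1 / pool$rmax[on] -
          pool$kr[on] * log(1 - pool$delta[on] / Ival)
        r[on] <- pmin(1 / inv, pool$rmax[on])
      }
      r
    }
  }
  if (length(I) == 1L) one(I) else t(vapply(I, one, numeric(pool$spec$N)))
}

#' Export a pool as a per-MU table
#'
#' @param pool A [pool_model()].
#' @param file Optional path; when given, the table is written as
#'   tab-separated text.
#' @return Data frame with columns `i`, `delta`, `Delta`, `fmax`, `rmax`
#'   (invisibly when writing to file).
#' @export
pool_table <- function(pool, file = NULL) {
  stopifnot(inherits(pool, "mu_pool"))
  d <- data.frame(i = seq_len(pool$spec$N), delta = pool$delta,
                  Delta = pool$Delta, fmax = pool$strengths,
                  rmax = pool$rmax)
  if (!is.null(file)) {
    write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(d))
  }
  d
}

#' @export
print.mu_pool <- function(x, ...) {
  cat(sprintf("<mu_pool %s> %s muscle, N=%d, thresholds [%.3g, %.3g] N, %s rate coding\n",
              x$label, x$spec$label, x$spec$N, x$delta[1],
              x$delta[x$spec$N], x$rate_family))
  invisible(x)
}
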