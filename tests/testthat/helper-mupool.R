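# Shared fixtures (built once per test run) and independent oracles.

ta_spec <- muscle_spec("TA")
sf_spec <- muscle_spec("SF")
tw_ta <- calibrate_twitch(ta_spec$Tp, ta_spec$Thr, 0.002)

# small muscle for cheap end-to-end runs; same twitch-shape ratio as the TA
toy_spec <- muscle_spec(NULL, N = 5L, Fmax = 10, Rf = 5, delta1 = 0.2,
                        deltaN = 5, rmax1 = 20, Tp = 0.030, Thr = 0.035,
                        c1 = 1, label = "toy")
tw_toy <- calibrate_twitch(toy_spec$Tp, toy_spec$Thr, 0.002)

# plain-R re-implementation of the impulse-train rules (first fire at first
# r > 0; then fire at the first grid time t with t >= phi + 1/r(t) - C, C by
# linear interpolation of the continuous firing time), used as the
# step-by-step oracle for the compiled path
oracle_train <- function(rates, dt) {
  phi <- numeric(0)
  C <- 0; fired <- FALSE; r_prev <- 0; phi_prev <- 0
  for (k in seq_along(rates)) {
    t <- (k - 1) * dt
    r <- rates[k]
    if (r > 0) {
      if (!fired) {
        fired <- TRUE; phi_prev <- t; C <- 0; phi <- c(phi, t)
      } else if (t >= phi_prev + 1 / r - C - 1e-9) {
        Cn <- 0
        if (r_prev > 0) {
          den <- 1 / r_prev - 1 / r + dt
          if (den > 1e-12) {
            num <- 1 / r_prev + phi_prev - t + dt
            Cn <- max(min(dt * (1 - num / den), dt), -dt)
          }
        }
        phi_prev <- t; C <- Cn; phi <- c(phi, t)
      }
    }
    r_prev <- r
  }
  phi
}

# random admissible rate trajectory for property tests
random_rates <- function(n, rmax = 30) {
  r <- pmax(0, cumsum(rnorm(n, 0, rmax / 20)))
  r[r > rmax] <- rmax
  # random silent stretch
  if (runif(1) < 0.5) {
    i0 <- sample.int(n - 10, 1)
    r[i0:(i0 + 9)] <- 0
  }
  r
}
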