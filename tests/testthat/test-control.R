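make_ramp_task <- function(T_end = 1, dt = 0.002, peak = 5) {
  t <- seq(0, T_end, by = dt)
  new_task(t, peak * t / T_end, rep(1, length(t)), "ramp")
}

test_that("feedforward drive reduces to identity and baseline in edge cases", {
  tk <- make_ramp_task()
  ident <- feedforward_params(0, 1, 1, 0)
  expect_equal(feedforward_drive(tk, ident, Fmax = 10), tk$Fd, tolerance = 1e-8)
  # zero desired force with positive exponent leaves only the baseline
  t <- seq(0, 1, by = 0.002)
  zero <- new_task(t, rep(0, length(t)), rep(1, length(t)), "zero")
  expect_equal(feedforward_drive(zero, feedforward_params(0.7, 2, 1.3, 0),
                                 Fmax = 10),
               rep(0.7, length(t)), tolerance = 1e-6)
  # look-ahead of tau samples reads Fd at t + tau*dt, holding the last sample
  ff <- feedforward_params(0, 1, 1, 25)
  drv <- feedforward_drive(tk, ff, Fmax = 10)
  n <- length(tk$t)
  expect_equal(drv[1:(n - 25)], tk$Fd[26:n], tolerance = 1e-8)
  expect_equal(drv[(n - 24):n], rep(tk$Fd[n], 25), tolerance = 1e-8)
  # gain divides the desired force before exponentiation
  g2 <- new_task(tk$t, tk$Fd, rep(2, n), "g2")
  expect_equal(feedforward_drive(g2, ident, Fmax = 10), tk$Fd / 2,
               tolerance = 1e-8)
})

test_that("closed loop with zero gain equals the open-loop pipeline", {
  pool <- pool_model(toy_spec, "matched", "constant")
  amax <- pool_amax(pool, tw_toy)
  tk <- elementary_tasks(toy_spec, amplitudes = 0.4)[[2]]
  drive <- drive_params(feedforward_params(0.2, 1, 1, 10), gamma = 0)
  sim <- simulate_pool(pool, tw_toy, tk, drive, amax = amax)
  # open-loop recomputation: rates from Iff alone, then trains, activation,
  # forces, assembled module by module
  Iff <- feedforward_drive(tk, drive$ff, toy_spec$Fmax)
  R <- firing_rates(pool, Iff)
  FM_open <- rowSums(vapply(1:5, function(i) {
    tr <- build_impulse_train(R[, i], tk$dt)
    pool$strengths[i] * tk$g *
      normalized_activation(tr, tw_toy, amax[i], T_end = tk$T_end)
  }, numeric(length(tk$t))))
  expect_equal(sim$FM, FM_open, tolerance = 1e-12)
  expect_equal(sim$I, Iff)
})

test_that("feedback error is the one-step-lagged force mismatch", {
  pool <- pool_model(toy_spec, "exponential", "constant")
  amax <- pool_amax(pool, tw_toy)
  tk <- elementary_tasks(toy_spec, amplitudes = 0.4)[[1]]
  drive <- drive_params(feedforward_params(0.1, 0.8, 1, 5), gamma = 0.9)
  sim <- simulate_pool(pool, tw_toy, tk, drive, amax = amax)
  n <- length(tk$t)
  expect_equal(sim$Ifb, tk$Fd - c(0, sim$FM[-n]))
  expect_equal(sim$I, sim$Iff + 0.9 * sim$Ifb)
})

test_that("closed-loop trace matches a hand-stepped three-MU oracle", {
  spec3 <- muscle_spec(NULL, N = 3L, Fmax = 6, Rf = 4, delta1 = 0.3,
                       deltaN = 2.5, rmax1 = 20, Tp = 0.030, Thr = 0.035,
                       label = "tiny")
  pool <- pool_model(spec3, "matched", "linear")
  amax <- pool_amax(pool, tw_toy)
  n <- 20
  t <- (seq_len(n) - 1) * 0.002
  tk <- new_task(t, seq(0, 4, length.out = n), rep(1, n), "steps")
  drive <- drive_params(feedforward_params(0.3, 1, 1, 2), gamma = 0.5)
  sim <- simulate_pool(pool, tw_toy, tk, drive, amax = amax)

  # independent step-by-step recomputation of the same update order
  Iff <- feedforward_drive(tk, drive$ff, spec3$Fmax)
  x <- matrix(0, 3, 3)                   # cascade states per MU
  st <- lapply(1:3, function(i) list(fired = FALSE, phi = 0, C = 0, rp = 0))
  FM_prev <- 0
  FM_oracle <- numeric(n)
  for (k in seq_len(n)) {
    I <- Iff[k] + 0.5 * (tk$Fd[k] - FM_prev)
    F <- 0
    for (i in 1:3) {
      r <- firing_rates(pool, I)[i]
      s <- st[[i]]
      fire <- FALSE
      if (r > 0) {
        if (!s$fired) {
          fire <- TRUE; s$fired <- TRUE; s$phi <- t[k]; s$C <- 0
        } else if (t[k] >= s$phi + 1 / r - s$C - 1e-9) {
          fire <- TRUE
          Cn <- 0
          if (s$rp > 0) {
            den <- 1 / s$rp - 1 / r + 0.002
            if (den > 1e-12)
              Cn <- max(min(0.002 * (1 - (1 / s$rp + s$phi - t[k] + 0.002) / den),
                            0.002), -0.002)
          }
          s$phi <- t[k]; s$C <- Cn
        }
      }
      s$rp <- r
      st[[i]] <- s
      x[, i] <- tw_toy$Ad %*% x[, i]
      if (fire) x[1, i] <- x[1, i] + 1
      abar <- min(max(tw_toy$gain * x[3, i] / amax[i], 0), 1)
      F <- F + pool$strengths[i] * tk$g[k] * abar
    }
    FM_oracle[k] <- F
    FM_prev <- F
  }
  expect_equal(sim$FM, FM_oracle, tolerance = 1e-12)
})

test_that("simulation results serialize with their event lists", {
  pool <- pool_model(toy_spec, "matched", "constant")
  tk <- elementary_tasks(toy_spec, amplitudes = 0.4)[[2]]
  sim <- simulate_pool(pool, tw_toy, tk, drive_params(feedforward_params(0.2, 1, 1, 0)))
  f <- tempfile(fileext = ".tsv")
  write_sim_result(sim, f)
  d <- read.table(f, header = TRUE, sep = "\t")
  expect_named(d, c("t", "Fd", "g", "Iff", "Ifb", "I", "FM"))
  expect_equal(d$FM, sim$FM, tolerance = 1e-6)
  ev <- read.table(sub("\\.tsv$", "_events.tsv", f), header = TRUE, sep = "\t")
  expect_equal(nrow(ev), sum(sim$n_impulses))
  # per-MU forces reassemble the total
  expect_equal(rowSums(sim_mu_forces(sim)), sim$FM, tolerance = 1e-9)
})
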