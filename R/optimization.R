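#' Force-matching objective over a task suite
#'
#' The two-stage fitting objective: the sum over tasks of the time-averaged
#' squared force error, `sum_k (1/T_k) integral (Fd_k - FM_k)^2 dt`
#' (rectangle rule on the simulation grid), in N^2.
#'
#' @param pool A [pool_model()].
#' @param twitch A [calibrate_twitch()] model.
#' @param tasks List of `mu_task` objects.
#' @param drive A [drive_params()] object.
#' @param amax Optional precomputed [pool_amax()] vector.
#' @return Scalar objective \[N^2\].
#' @export
drive_objective <- function(pool, twitch, tasks, drive, amax = NULL) {
  if (is.null(amax)) amax <- pool_amax(pool, twitch)
  tot <- 0
  for (task in tasks) {
    sim <- simulate_pool(pool, twitch, task, drive, amax = amax,
                         full_output = FALSE)
    tot <- tot + mean((task$Fd - sim$FM)^2)
  }
  tot
}

clip_chrom <- function(x, lo, hi) {
  x <- pmin(pmax(x, lo), hi)
  x[4] <- round(x[4])
  x
}

#' Fit feedforward drive parameters with a mixed-integer genetic algorithm
#'
#' Stage one of the two-stage controller fit: with feedback disabled
#' (`gamma = 0`), searches `alpha0, alpha1 in [-1, 5]`, `beta in [-2, 2]`
#' and integer `tau in [0, 50]` samples for the parameter set minimizing
#' [drive_objective()] over the elementary task suite. The search is a
#' real-coded genetic algorithm (tournament selection, blend crossover,
#' Gaussian mutation, elitism; `tau` handled by rounding within bounds),
#' restarted from independent seeded populations; each restart's best is
#' polished by a bounded Nelder-Mead search over the three continuous
#' parameters at fixed `tau` (the hybrid local step customary for genetic
#' searches), and the best solution across restarts is returned.
#'
#' @inheritParams drive_objective
#' @param bounds Named list of `c(lower, upper)` for `alpha0`, `alpha1`,
#'   `beta`, `tau`.
#' @param pop Population size.
#' @param generations Generations per restart.
#' @param restarts Independent restarts.
#' @param polish Run the Nelder-Mead hybrid step after each restart.
#' @param seed Integer seed (restart `r` uses `seed + r - 1`).
#' @return List with `ff` (a [feedforward_params()]) and `report`: best
#'   objective, per-restart bests, per-generation best trace (non-increasing
#'   within each restart), bounds, seeds and evaluation count.
#' @export
optimize_feedforward <- function(pool, twitch, tasks,
                                 bounds = list(alpha0 = c(-1, 5),
                                               alpha1 = c(-1, 5),
                                               beta = c(-2, 2),
                                               tau = c(0, 50)),
                                 pop = 40, generations = 60, restarts = 3,
                                 polish = TRUE, seed = 1, amax = NULL) {
  stopifnot(length(tasks) >= 1, pop >= 4, generations >= 1, restarts >= 1)
  if (is.null(amax)) amax <- pool_amax(pool, twitch)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  evaln <- 0L
  fitness <- function(x) {
    evaln <<- evaln + 1L
    ff <- feedforward_params(x[1], x[2], x[3], x[4])
    obj <- drive_objective(pool, twitch, tasks, drive_params(ff, 0), amax)
    if (!is.finite(obj)) 1e12 else obj
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  best_overall <- NULL
  restart_best <- numeric(restarts)
  traces <- vector("list", restarts)
  seeds <- seed + seq_len(restarts) - 1L
  for (r in seq_len(restarts)) {
    set.seed(seeds[r])
    P <- t(replicate(pop, clip_chrom(runif(4, lo, hi), lo, hi)))
    f <- apply(P, 1, fitness)
    trace <- numeric(generations)
    for (gen in seq_len(generations)) {
      ord <- order(f)
      elite <- P[ord[1:2], , drop = FALSE]
      elite_f <- f[ord[1:2]]
      newP <- matrix(0, pop, 4)
      newP[1:2, ] <- elite
      for (j in 3:pop) {
        # tournament selection (size 2) for two parents
        pick <- function() {
          c2 <- sample.int(pop, 2)
          P[c2[which.min(f[c2])], ]
        }
        p1 <- pick(); p2 <- pick()
        child <- if (runif(1) < 0.9) {
          # blend (BLX-0.5) crossover
          lo_c <- pmin(p1, p2); hi_c <- pmax(p1, p2); d <- hi_c - lo_c
          runif(4, lo_c - 0.5 * d, hi_c + 0.5 * d)
        } else p1
        mut <- runif(4) < 0.2
        child[mut] <- child[mut] + rnorm(sum(mut), 0, 0.1 * (hi - lo)[mut])
        newP[j, ] <- clip_chrom(child, lo, hi)
      }
      newf <- c(elite_f, apply(newP[3:pop, , drop = FALSE], 1, fitness))
      P <- newP
      f <- newf
      trace[gen] <- min(f)
    }
    traces[[r]] <- cummin(trace)
    i <- which.min(f)
    par_r <- P[i, ]
    obj_r <- f[i]
    if (isTRUE(polish)) {
      # hybrid local step: simplex over the continuous parameters with tau
      # frozen, clipped to the bounds through the fitness itself
      pol <- suppressWarnings(optim(par_r[1:3], function(p) {
        p <- pmin(pmax(p, lo[1:3]), hi[1:3])
        fitness(c(p, par_r[4]))
      }, method = "Nelder-Mead", control = list(maxit = 200)))
      if (pol$value < obj_r) {
        par_r <- clip_chrom(c(pol$par, par_r[4]), lo, hi)
        obj_r <- pol$value
      }
    }
    restart_best[r] <- obj_r
    if (is.null(best_overall) || obj_r < best_overall$obj)
      best_overall <- list(par = par_r, obj = obj_r)
  }
  ff <- feedforward_params(best_overall$par[1], best_overall$par[2],
                           best_overall$par[3], best_overall$par[4])
  list(ff = ff,
       report = list(objective = best_overall$obj,
                     restart_best = restart_best,
                     trace = traces, bounds = bounds, seeds = seeds,
                     pop = pop, generations = generations,
                     evaluations = evaln))
}

#' Fit the feedback gain with Nelder-Mead restarts
#'
#' Stage two of the controller fit: with the feedforward parameters frozen,
#' minimizes [drive_objective()] over the scalar feedback gain `gamma` with
#' Nelder-Mead simplex searches started from a coarse scan of the gain range
#' (the objective is piecewise flat in `gamma` at the scale of single
#' impulse shifts, so a single simplex can stall on a shelf). `gamma = 0`
#' is always evaluated as a candidate, so the returned gain's objective
#' never exceeds the feedforward-only baseline.
#'
#' @inheritParams drive_objective
#' @param ff Fixed [feedforward_params()] from stage one.
#' @param gamma_max Upper end of the scanned gain range.
#' @param scan_points Coarse scan resolution; the best few scan points seed
#'   the simplex searches.
#' @param seed Recorded in the report (the search itself is deterministic).
#' @param maxit Iteration cap per simplex start.
#' @return List with `gamma`, `objective`, `baseline` (the `gamma = 0`
#'   objective) and `report` (scan and per-start results).
#' @export
optimize_feedback_gain <- function(pool, twitch, tasks, ff, gamma_max = 5,
                                   scan_points = 11, seed = 1,
                                   maxit = 100, amax = NULL) {
  stopifnot(inherits(ff, "ff_params"), gamma_max > 0, scan_points >= 3)
  if (is.null(amax)) amax <- pool_amax(pool, twitch)
  obj_g <- function(gamma)
    drive_objective(pool, twitch, tasks, drive_params(ff, gamma), amax)
  baseline <- obj_g(0)
  scan_g <- seq(0, gamma_max, length.out = scan_points)
  scan_f <- c(baseline, vapply(scan_g[-1], obj_g, numeric(1)))
  cand <- data.frame(gamma = scan_g, objective = scan_f, start = NA_real_)
  starts <- scan_g[order(scan_f)][1:3]
  starts <- unique(pmax(starts, 0.05 * gamma_max))  # keep simplex off zero
  for (s in starts) {
    fit <- suppressWarnings(optim(s, obj_g, method = "Nelder-Mead",
                                  control = list(maxit = maxit,
                                                 reltol = 1e-10)))
    cand <- rbind(cand, data.frame(gamma = fit$par, objective = fit$value,
                                   start = s))
  }
  best <- cand[which.min(cand$objective), ]
  list(gamma = best$gamma, objective = best$objective, baseline = baseline,
       report = list(candidates = cand, seed = seed))
}
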