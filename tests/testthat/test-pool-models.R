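test_that("MU strengths follow the geometric distribution and normalize to Fmax", {
  f <- mu_strengths(ta_spec)
  expect_length(f, 400)
  expect_true(all(diff(f) > 0))
  expect_equal(sum(f), 400)
  expect_equal(f[400] / f[1], 100)
  # closed-form endpoints: sum of the geometric series q^(i-1) with
  # q = Rf^(1/(N-1)) gives fmax_1 = Fmax * (q - 1) / (Rf * q - 1)
  q <- 100^(1 / 399)
  s_geom <- (100 * q - 1) / (q - 1)
  expect_equal(f[1], 400 / s_geom, tolerance = 1e-12)
  expect_equal(f[400], 400 * 100 / s_geom, tolerance = 1e-12)
  expect_equal(round(f[1], 4), 0.0464)
  expect_equal(round(f[400], 2), 4.64)
  expect_error(mu_strengths(muscle_spec(NULL, N = 1L, Fmax = 1, Rf = 2,
                                        delta1 = 0.1, deltaN = 0.5,
                                        rmax1 = 10, Tp = 0.05, Thr = 0.06)),
               "N must be")
})

test_that("derived threshold parameters reproduce the printed identities", {
  expect_equal(derive_threshold_params(ta_spec, "exponential"), 400)
  expect_equal(derive_threshold_params(sf_spec, "exponential"), 380)
  expect_equal(derive_threshold_params(ta_spec, "mixed"),
               (200 - 29.195) / 0.5, tolerance = 1e-12)
  expect_equal(derive_threshold_params(sf_spec, "mixed"),
               (190 - 29.195) / 0.5, tolerance = 1e-12)
  # overlap parameter from the closed-form largest strength
  b1_ta <- derive_threshold_params(ta_spec, "matched")
  fN <- mu_strengths(ta_spec)[400]
  expect_equal(b1_ta, 1 - (200 - 0.5) / (400 - fN), tolerance = 1e-12)
  expect_true(b1_ta > 0 && b1_ta < 1)
  # infeasible mixed family: last threshold at or below c1
  bad <- muscle_spec(NULL, N = 10L, Fmax = 100, Rf = 10, delta1 = 0.5,
                     deltaN = 20, rmax1 = 20, Tp = 0.05, Thr = 0.06)
  expect_error(derive_threshold_params(bad, "mixed"), "c1")
})

test_that("threshold sequences are increasing and hit both endpoints", {
  for (spec in list(ta_spec, sf_spec)) {
    for (fam in c("exponential", "matched", "mixed")) {
      thr <- recruitment_thresholds(spec, fam)
      expect_true(all(diff(thr$delta) > 0), info = paste(spec$label, fam))
      expect_equal(thr$delta[1], spec$delta1)
      expect_lt(abs(thr$delta[spec$N] - spec$deltaN), 0.005 * spec$deltaN)
    }
  }
  # exponential family: constant bandwidth Fmax - delta1 * Rd
  thr <- recruitment_thresholds(ta_spec, "exponential")
  expect_equal(unique(thr$Delta), 400 - 0.5 * 400)
  expect_equal(thr$delta[400], 0.5 * 400)
  # matched family: first recurrence step delta2 = delta1 + fmax1 * (1 - b1)
  thr <- recruitment_thresholds(ta_spec, "matched")
  f <- mu_strengths(ta_spec)
  b1 <- derive_threshold_params(ta_spec, "matched")
  expect_equal(thr$delta[2], 0.5 + f[1] * (1 - b1), tolerance = 1e-12)
  expect_equal(thr$Delta, f)
  # mixed family endpoint recovers delta1 * Rc + c1 and bandwidth is NA
  thr <- recruitment_thresholds(ta_spec, "mixed")
  expect_equal(thr$delta[400], 0.5 * thr$Rc + 29.195, tolerance = 1e-9)
  expect_true(all(is.na(thr$Delta)))
})

test_that("maximum firing-rate schemes match their formulas", {
  expect_equal(rmax_profile(ta_spec, "constant"), rep(25, 400))
  lin <- rmax_profile(ta_spec, "linear")
  expect_equal(lin[1], 25)
  expect_equal(lin[400], 25 * (1 - 0.25))
  ex <- rmax_profile(ta_spec, "exponential")
  expect_equal(ex[1], 25)
  expect_equal(ex[400], 25 * 400^(-0.05), tolerance = 1e-12)
  for (p in list(lin, ex)) expect_true(all(diff(p) <= 0))
  bad <- muscle_spec("TA", rho1 = 1.2)
  expect_error(rmax_profile(bad, "linear"), "rho1")
})

test_that("rate functions are zero at threshold, capped, and monotone in drive", {
  pools <- all_pool_variants(ta_spec)
  for (pool in pools) {
    d <- pool$delta
    r_at <- firing_rates(pool, d[10])
    expect_equal(r_at[10], 0)               # zero at own threshold
    expect_true(all(r_at[10:400] == 0))     # and for all above it
    r_neg <- firing_rates(pool, -5)
    expect_true(all(r_neg == 0))
    r_hi <- firing_rates(pool, 10 * ta_spec$Fmax)
    expect_true(all(r_hi <= pool$rmax + 1e-9))
    if (pool$rate_family == "linear") {
      expect_equal(firing_rates(pool, d[1] + pool$Delta[1])[1], pool$rmax[1])
    } else {
      # saturates towards rmax as drive grows
      expect_gt(firing_rates(pool, 1e6)[1], 0.999 * pool$rmax[1])
    }
  }
  # monotonicity property over random drive grids
  set.seed(11)
  for (pool in pools[c("exp-lin const", "matched-lin lin", "mixed-log exp")]) {
    I <- sort(runif(40, -10, 1.5 * ta_spec$Fmax))
    R <- firing_rates(pool, I)
    expect_true(all(apply(R, 2, function(col) all(diff(col) >= -1e-9))))
    expect_true(all(R >= 0) && all(R <= rep(pool$rmax, each = 40) + 1e-9))
  }
})

test_that("logarithmic rate stays finite and positive above threshold", {
  pool <- pool_model(ta_spec, "mixed", "constant")
  for (i in c(1, 100, 400)) {
    I <- pool$delta[i] * (1 + 10^seq(-10, 3, length.out = 200))
    r <- vapply(I, function(x) firing_rates(pool, x)[i], numeric(1))
    expect_true(all(is.finite(r)))
    expect_true(all(r >= 0 & r <= pool$rmax[i] + 1e-9))
    expect_true(all(diff(r) >= -1e-9))
  }
})

test_that("pool construction enforces the size principle and exports a table", {
  pool <- pool_model(sf_spec, "mixed", "linear")
  expect_true(all(diff(pool$delta) > 0))
  expect_true(all(diff(pool$strengths) > 0))
  expect_equal(pool$rate_family, "logarithmic")
  expect_length(all_pool_variants(ta_spec), 9)
  tab <- pool_table(pool)
  expect_named(tab, c("i", "delta", "Delta", "fmax", "rmax"))
  f <- tempfile(fileext = ".tsv")
  pool_table(pool, f)
  expect_equal(read.table(f, header = TRUE, sep = "\t")$delta, pool$delta)
})
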