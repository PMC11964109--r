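test_that("minimum-jerk trajectory has the standard quintic properties", {
  t <- seq(0, 1.5, by = 0.0005)
  mj <- minimum_jerk(1, -0.3, 1.5, t)
  expect_equal(mj$position[1], 1)
  expect_equal(mj$position[length(t)], 0.7)
  expect_equal(minimum_jerk(0, 1, 2, 1)$position, 0.5)  # symmetry at u = 1/2
  expect_equal(mj$velocity[1], 0)
  expect_equal(mj$velocity[length(t)], 0)
  # peak speed of the quintic is 15/8 * |delta| / T
  expect_equal(max(abs(mj$velocity)), 15 / 8 * 0.3 / 1.5, tolerance = 1e-5)
})

test_that("elementary suite has six tasks with the prescribed structure", {
  suite <- elementary_tasks(ta_spec)
  expect_length(suite, 6)
  peaks <- vapply(suite, function(tk) max(tk$Fd), numeric(1))
  expect_setequal(round(unique(peaks), 6), c(120, 200))
  for (tk in suite) {
    expect_equal(tk$Fd[1], 0)
    expect_equal(tk$Fd[length(tk$Fd)], 0)
    expect_true(all(tk$g > 0))
    expect_equal(tk$T_end, 2)
  }
  iso <- suite[["TA-isometric-0.30Fmax"]]
  expect_true(all(iso$g == 1))
  con <- suite[["TA-concentric-0.30Fmax"]]
  expect_equal(con$length[1], 1)
  expect_equal(con$length[length(con$length)], 0.8, tolerance = 1e-9)
  expect_true(all(con$Fd[con$t > 1 + 1e-9] == 0))   # force in first half only
  ecc <- suite[["TA-eccentric-0.30Fmax"]]
  expect_true(all(ecc$Fd[ecc$t < 1 - 1e-9] == 0))   # force in second half
  expect_equal(max(ecc$length), 1.2, tolerance = 1e-9)
  # SF amplitudes default to the low-force pair
  sf <- elementary_tasks(sf_spec)
  expect_setequal(round(unique(vapply(sf, function(tk) max(tk$Fd), 1)), 6),
                  c(0.05, 0.2) * 200)
  expect_error(elementary_tasks(ta_spec, amplitudes = 1.4), "amplitudes")
})

test_that("trapezoid tasks ramp, hold and descend symmetrically", {
  tk <- trapezoid_task(ta_spec, 0.3)
  expect_equal(max(tk$Fd), 120)
  tk5 <- trapezoid_task(ta_spec, 0.5)
  expect_equal(max(tk5$Fd), 200)
  expect_true(all(tk$g == 1))
  # monotone nondecreasing ramp-up, time symmetry about the plateau midpoint
  up <- tk$Fd[tk$t <= tk$plateau_window[1]]
  expect_true(all(diff(up) >= 0))
  mid <- mean(tk$plateau_window)
  i_mid <- round(mid / tk$dt)
  fwd <- tk$Fd[seq_len(i_mid)]
  bwd <- rev(tk$Fd)[seq_len(i_mid)]
  expect_equal(fwd, bwd, tolerance = 1e-9)
  plateau_vals <- tk$Fd[tk$t >= tk$plateau_window[1] &
                        tk$t <= tk$plateau_window[2]]
  expect_true(all(abs(plateau_vals - 120) < 1e-9))
})

test_that("synthetic reaching fixtures are seeded, bounded and multi-peaked", {
  s1 <- synthetic_reach_tasks(sf_spec, n = 4, seed = 9)
  s2 <- synthetic_reach_tasks(sf_spec, n = 4, seed = 9)
  expect_identical(s1, s2)
  s3 <- synthetic_reach_tasks(sf_spec, n = 4, seed = 10)
  expect_false(identical(s1, s3))
  for (tk in s1) {
    expect_gte(max(tk$Fd), 0.05 * 200 - 1e-9)
    expect_lte(max(tk$Fd), 0.2 * 200 + 1e-9)
    expect_equal(tk$Fd[1], 0)
    expect_equal(tk$Fd[length(tk$Fd)], 0)
    expect_true(all(tk$g > 0))
    expect_equal(tk$g[1], 1, tolerance = 1e-6)  # starts at optimum, at rest
  }
  # first task: two peaks with a deep inter-peak minimum
  tk <- s1[[1]]
  third <- floor(length(tk$Fd) / 3)
  p1 <- max(tk$Fd[1:third])
  p2 <- max(tk$Fd[(2 * third):length(tk$Fd)])
  valley <- min(tk$Fd[third:(2 * third)])
  expect_lt(valley, 0.2 * min(p1, p2))
})

test_that("tasks round-trip through the delimited format", {
  dir <- tempfile()
  suite <- elementary_tasks(toy_spec, amplitudes = 0.3)
  write_task_suite(suite, dir, manifest = list(seed = 1))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_length(man$tasks, 3)
  back <- read_task(file.path(dir, man$tasks[[1]]), label = names(suite)[1])
  orig <- suite[[1]]
  expect_equal(back$Fd, orig$Fd, tolerance = 1e-12)
  expect_equal(back$g, orig$g, tolerance = 1e-12)
  # a file with length/velocity but no g column gets its gain computed
  f <- tempfile(fileext = ".tsv")
  d <- data.frame(t = orig$t, Fd = orig$Fd, length = orig$length,
                  velocity = orig$velocity)
  write.table(d, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back2 <- read_task(f)
  expect_equal(back2$g, fvl_gain(orig$length, orig$velocity), tolerance = 1e-9)
})
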