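test_that("threshold conditions pin down two pulses at the reference point", {
  ps <- ref_pulses()
  expect_length(ps, 2)
  for (p in ps) {
    r <- threshold_residuals(p$kernel, p$kappa, p$c, p$d)
    expect_lt(max(abs(r)), 1e-8)
    expect_equal(pulse_profile(p, c(0, p$d)), c(4, 4), tolerance = 1e-8)
    expect_gt(p$c, 0); expect_gt(p$d, 0)
  }
  # the slower solution is the wider one, and it is the stable one
  slow <- ref_stable_pulse(); fast <- ref_fast_pulse()
  expect_lt(slow$c, fast$c)
  expect_gt(slow$d, fast$d)
  expect_identical(slow$stability, "stable")
  expect_identical(fast$stability, "unstable")
})

test_that("profile is a single-superthreshold traveling wave solution", {
  p <- ref_stable_pulse()
  # continuity across the analytic branch points
  for (bp in c(p$kernel$x0, p$kernel$x0 + p$d)) {
    eps <- 1e-7
    expect_lt(abs(pulse_profile(p, bp + eps) - pulse_profile(p, bp - eps)),
              1e-5)
  }
  # exactly one superthreshold interval on a fine grid
  xg <- seq(-30, p$d + 30, length.out = 6000)
  u <- pulse_profile(p, xg)
  above <- u > p$kappa
  runs <- rle(above)
  expect_equal(sum(runs$values), 1)
  # decay in both directions (slow, set by the inhibitory length scale)
  expect_lt(abs(pulse_profile(p, -150)), 1e-3)
  expect_lt(abs(pulse_profile(p, p$d + 200)), 1e-3)
})

test_that("profile satisfies the co-moving ODE (finite differences + deSolve)", {
  p <- ref_stable_pulse()
  k <- p$kernel
  h <- 1e-4
  xs <- c(-4, 1, 5, 9.9, 14, 22)
  dU_fd <- (pulse_profile(p, xs + h) - pulse_profile(p, xs - h)) / (2 * h)
  rhs <- (pulse_profile(p, xs) - window_integral(k, xs, 0, p$d)) / p$c
  expect_lt(max(abs(dU_fd - rhs)), 1e-6)
  # analytic derivative agrees with finite differences
  expect_equal(pulse_profile(p, xs, deriv = TRUE), dU_fd, tolerance = 1e-6)
  # independent ODE-integration oracle with the superthreshold window fixed
  xi_hi <- p$d + 60
  sol <- deSolve::ode(
    y = c(U = pulse_profile(p, xi_hi)),
    times = seq(xi_hi, -20, by = -0.1),
    func = function(t, y, parms)
      list((y[1] - window_integral(k, t, 0, p$d)) / p$c),
    rtol = 1e-10, atol = 1e-10)
  expect_equal(sol[, "U"], pulse_profile(p, sol[, "time"]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("symmetric kernel supports no rightward pulse", {
  k0 <- weight_kernel(5, 1, 0.42, 0.1, x0 = 0)
  ps <- solve_free_pulses(k0, 4, c_range = c(0.1, 15), d_range = c(0.5, 40),
                          classify = FALSE)
  expect_length(ps, 0)
})

test_that("branch scan traces both branches to their fold", {
  k <- ref_kernel()
  sc <- memo("branch_scan",
             branch_scan(k, seq(3.6, 5.6, by = 0.2), classify = TRUE))
  expect_true(all(c("kappa", "c", "d", "stability") %in% names(sc)))
  # branch termination: no solutions beyond the saddle-node
  expect_equal(nrow(dplyr::filter(sc, kappa > 5.45)), 0)
  expect_gt(nrow(dplyr::filter(sc, kappa <= 5.05)), 0)
  stable <- dplyr::arrange(dplyr::filter(sc, stability == "stable"), kappa)
  unst <- dplyr::arrange(dplyr::filter(sc, stability == "unstable"), kappa)
  # recomputed branch shapes: stable speed increases gently with threshold,
  # unstable speed decreases, and the branches approach the fold
  expect_true(all(diff(stable$c) > -1e-6))
  expect_true(all(diff(unst$c) < 1e-6))
  common <- intersect(stable$kappa, unst$kappa)
  gap <- vapply(common, function(kp)
    unst$c[match(kp, unst$kappa)] - stable$c[match(kp, stable$kappa)],
    numeric(1))
  expect_true(all(diff(gap) < 0))  # branches converge toward the fold
  # empty grid -> empty table
  empty <- branch_scan(k, numeric(0))
  expect_equal(nrow(empty), 0)
})

test_that("tidy and glance methods return well-formed tibbles", {
  p <- ref_stable_pulse()
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$value[td$symbol == "c"], p$c)
  gl <- glance(p)
  expect_equal(gl$stability, "stable")
})
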