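test_that("integration is bit-deterministic given the seed", {
  k <- ref_kernel()
  fr <- firing_rule("heaviside", 4)
  fp <- ref_stable_pulse()
  g <- sim_grid(0, 102.4, dx = 0.1, dt = 0.01, t_final = 2,
                boundary = "periodic")
  nm <- ref_noise()
  run <- function() integrate_langevin(g, k, fr, nm,
                                       u0 = pulse_initial_condition(fp, g, 20),
                                       n_trials = 3, seed = 42)
  a <- run(); b <- run()
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$final, b$final)
  # different seed gives different noise
  c2 <- integrate_langevin(g, k, fr, nm,
                           u0 = pulse_initial_condition(fp, g, 20),
                           n_trials = 3, seed = 43)
  expect_false(identical(a$final, c2$final))
})

test_that("noise-free pulse translates at the analytic speed (first-order in dt)", {
  k <- ref_kernel()
  fr <- firing_rule("heaviside", 4)
  fp <- ref_stable_pulse()
  nm0 <- noise_model(0, 1, "linear")
  errs <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    g <- sim_grid(0, 102.4, dx = 0.1, dt = dt, t_final = 12,
                  boundary = "periodic")
    ens <- integrate_langevin(g, k, fr, nm0,
                              u0 = pulse_initial_condition(fp, g, 20),
                              n_trials = 1, seed = 1, levels = 4)
    tr <- dplyr::filter(ens$tracks, edge == "trailing", time >= 2)
    abs(unname(stats::coef(stats::lm(position ~ time, tr))[2]) - fp$c)
  }, numeric(1))
  expect_lt(errs[2] / fp$c, 0.01)        # speed correct to 1% at dt = 0.01
  expect_lt(errs[3], errs[1])            # error shrinks with dt
  expect_gt(errs[1] / errs[3], 2)        # roughly first-order convergence
})

test_that("injected noise has the lattice variance and the Novikov drift", {
  k <- ref_kernel()
  fr <- firing_rule("heaviside", 4)
  fp <- ref_stable_pulse()
  dt <- 0.01
  g <- sim_grid(0, 51.2, dx = 0.1, dt = dt, t_final = dt,
                boundary = "periodic")
  u0 <- pulse_initial_condition(fp, g, 15)
  eps <- 0.05; C0 <- 10; g0 <- 1.3
  nm <- noise_model(eps, g0, "linear", C0 = C0)
  ens <- integrate_langevin(g, k, fr, nm, u0 = u0, n_trials = 8000,
                            seed = 9, record_dt = dt)
  inc <- ens$final - u0          # one-step increments, per site x trial
  # deterministic part of the increment
  m <- rowMeans(inc)
  v <- apply(inc, 1, stats::var)
  # variance of the injected increments: 2 C0 dt eps g(u0)^2 per site;
  # mean of the increments: the drift with the Novikov correction included
  pred_var <- 2 * C0 * dt * eps * (g0 * u0)^2
  big <- pred_var > 1e-6
  expect_lt(stats::median(abs(v[big] / pred_var[big] - 1)), 0.1)
  # Novikov correction: mean increment minus the correction-free drift
  # equals eps*C0*g'(u)g(u)*dt; tested through the regression slope of
  # the residual drift on u0 across all lattice sites
  n <- g$n
  mseq <- seq_len(n) - 1
  disp <- ifelse(mseq <= n / 2, mseq, mseq - n) * g$dx
  what <- stats::fft(weight(k, disp)) * g$dx
  conv <- Re(stats::fft(stats::fft(as.numeric(u0 > 4)) * what,
                        inverse = TRUE)) / n
  base_drift <- (-u0 + conv) * dt
  corr <- m - base_drift
  slope <- sum(corr * u0) / sum(u0^2)
  expect_equal(slope, eps * C0 * g0^2 * dt, tolerance = 0.1)
})

test_that("sampled initial condition crosses threshold at the right spots", {
  fp <- ref_stable_pulse()
  g <- sim_grid(0, 102.4, dx = 0.1, dt = 0.01, t_final = 1,
                boundary = "periodic")
  u0 <- pulse_initial_condition(fp, g, offset = 31.4)
  cr <- level_crossings(u0, g$x, fp$kappa)
  expect_lt(abs(cr[["trailing"]] - 31.4), g$dx)
  expect_lt(abs(cr[["leading"]] - (31.4 + fp$d)), g$dx)
  # zero-noise run preserves the two-crossing geometry
  ens <- integrate_langevin(g, ref_kernel(), firing_rule("heaviside", 4),
                            noise_model(0, 1, "linear"), u0 = u0,
                            n_trials = 1, seed = 1, levels = fp$kappa)
  s <- ens$final[, 1] - fp$kappa
  ncross <- sum(abs(diff(s > 0)))
  expect_equal(ncross, 2)
})

test_that("noise configuration guards work", {
  expect_error(noise_model(0.01, 1, corr_len = 0.5), "lattice")
  expect_warning(
    integrate_langevin(sim_grid(0, 25.6, 0.1, 0.01, t_final = 0.02,
                                boundary = "periodic"),
                       ref_kernel(), firing_rule("heaviside", 4),
                       noise_model(0.005, 1, "linear", C0 = 7),
                       u0 = rep(0, 256), n_trials = 1, seed = 1),
    "overrides")
})

test_that("blow-up guard aborts a diverging run with a warning", {
  g <- sim_grid(0, 25.6, dx = 0.1, dt = 0.01, t_final = 5,
                boundary = "periodic")
  fp <- ref_stable_pulse()
  u0 <- pulse_initial_condition(fp, g, 5)
  expect_warning(
    integrate_langevin(g, ref_kernel(), firing_rule("heaviside", 4),
                       noise_model(3, 8, "linear", C0 = 10),
                       u0 = u0, n_trials = 2, seed = 1, blowup = 100),
    "blow-up")
})

test_that("clamped buffer keeps the boundary silent", {
  k <- ref_kernel()
  fp <- ref_stable_pulse()
  g <- sim_grid(-60, 120, dx = 0.1, dt = 0.01, t_final = 6,
                boundary = "buffer")
  ens <- integrate_langevin(g, k, firing_rule("heaviside", 4),
                            noise_model(0, 1, "linear"),
                            u0 = pulse_initial_condition(fp, g, 0),
                            n_trials = 1, seed = 1, levels = 4)
  expect_false(ens$boundary_touch)
  nbuf <- ceiling(5 / k$sigma_i / g$dx)
  expect_true(all(ens$final[seq_len(nbuf), 1] == 0))
  tr <- dplyr::filter(ens$tracks, edge == "trailing", time >= 2)
  spd <- unname(stats::coef(stats::lm(position ~ time, tr))[2])
  expect_equal(spd, fp$c, tolerance = 0.01)
})
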