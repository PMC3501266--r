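ref_effective <- function() {
  memo("ref_effective", effective_pulse(ref_kernel(), 4, ref_noise()))
}

ref_locked_effective <- function() {
  memo("ref_locked_effective",
       effective_pulse(ref_kernel(), 4, ref_noise(),
                       stimulus = stimulus_spec(5, 5, 5)))
}

test_that("noise-modified pulse reduces correctly and obeys the Gamma identity", {
  k <- ref_kernel()
  fp <- ref_stable_pulse()
  # eps = 0 recovers the deterministic pulse
  ep0 <- effective_pulse(k, 4, noise_model(0, 1, "linear", C0 = 10),
                         base = fp)
  expect_equal(ep0$c_eps, fp$c, tolerance = 1e-8)
  expect_equal(ep0$width, fp$d, tolerance = 1e-8)
  # Gamma(eps) * c_eps + eps C0 g0^2 = 1 identically
  ep <- ref_effective()
  nm <- ep$noise
  expect_equal(ep$Gamma * ep$c_eps + nm$eps * ep$C0 * nm$g0^2, 1)
  # noise slows and widens this pulse
  expect_lt(ep$c_eps, fp$c)
  expect_gt(ep$width, fp$d)
  # threshold conditions hold for the modified profile
  expect_equal(pulse_profile(ep, c(0, ep$width)), c(4, 4), tolerance = 1e-8)
  # too-strong noise is rejected
  expect_error(effective_pulse(k, 4, noise_model(0.2, 1, "linear", C0 = 10)),
               "too strong")
})

test_that("b function: quadrature agreement, decay, derivative identity", {
  ep <- ref_effective()
  k <- ep$kernel
  set.seed(6)
  for (z in c(-12, -3, 0, 4.7, 15)) {
    want <- quad(function(y) exp(-ep$Gamma * (y - z)) * weight(k, y) /
                   ep$c_eps, z, Inf)
    expect_equal(b_function(ep, z), want, tolerance = 1e-8)
  }
  expect_lt(abs(b_function(ep, 400)), 1e-12)
  # U0'(xi) = b(xi) - b(xi - width), checked by finite differences
  h <- 1e-5
  for (xi in c(0, 3.2, ep$width)) {
    fd <- (pulse_profile(ep, xi + h) - pulse_profile(ep, xi - h)) / (2 * h)
    expect_equal(fd, b_function(ep, xi) - b_function(ep, xi - ep$width),
                 tolerance = 1e-6)
  }
})

test_that("free adjoint null vector: rank-1, support, annihilated by the adjoint", {
  ep <- ref_effective()
  null <- adjoint_null_vector(ep)
  expect_lt(null$rel_det, 1e-8)
  expect_equal(null$lambda, 0)
  # V vanishes left of the first crossing
  expect_equal(adjoint_null_eval(null, c(-5, -0.01)), c(0, 0))
  # away from the crossing deltas the adjoint ODE  -c V' + h' V = 0 holds
  xg <- seq(0.5, ep$width - 0.5, by = 0.05)
  V <- adjoint_null_eval(null, xg)
  dV <- (adjoint_null_eval(null, xg + 1e-5) -
           adjoint_null_eval(null, xg - 1e-5)) / 2e-5
  resid <- -ep$c_eps * dV - (1 - ep$a) * V
  expect_lt(max(abs(resid)) / max(abs(V)), 1e-4)
  # rank-1 structure holds across random kernels in the valid regime
  set.seed(7)
  for (i in 1:4) {
    kk <- random_kernel()
    if (kk$x0 <= 0.5) next
    ps <- solve_free_pulses(kk, 0.5 * weight(kk, kk$x0), classify = FALSE)
    if (!length(ps)) next
    epr <- tryCatch(
      effective_pulse(kk, 0.5 * weight(kk, kk$x0),
                      noise_model(0.002, 1, "linear", C0 = 10),
                      base = ps[[1]]),
      error = function(e) NULL)
    if (is.null(epr)) next
    expect_lt(adjoint_null_vector(epr)$rel_det, 1e-8)
  }
})

test_that("diffusivity: closed form equals quadrature, scales linearly in eps", {
  ep <- ref_effective()
  null <- adjoint_null_vector(ep)
  de <- diffusivity(ep, null)
  expect_gt(de$D, 0)
  expect_equal(de$A, 0)
  Vf <- function(x) adjoint_null_eval(null, x)
  U0 <- function(x) pulse_profile(ep, x)
  dU0 <- function(x) pulse_profile(ep, x, deriv = TRUE)
  num <- quad(function(x) Vf(x)^2 * U0(x)^2, 0, 500)
  den <- quad(function(x) Vf(x) * dU0(x), 0, 500)
  expect_equal(de$D, ep$noise$eps * num / den^2, tolerance = 1e-8)
  # exact linearity in eps for a frozen profile
  ep2 <- ep; ep2$noise$eps <- 2 * ep$noise$eps
  expect_equal(diffusivity(ep2, null)$D, 2 * de$D, tolerance = 1e-12)
  # eps = 0 has no wandering
  ep0 <- effective_pulse(ref_kernel(), 4,
                         noise_model(0, 1, "linear", C0 = 10))
  expect_equal(diffusivity(ep0)$D, 0)
})

test_that("locked adjoint vector sits at the slow eigenvalue; A = -lambda_s", {
  ep <- ref_locked_effective()
  null <- adjoint_null_vector(ep)
  expect_lt(null$rel_det, 1e-8)
  expect_lt(null$lambda, 0)
  A <- ou_rate(ep, null)
  expect_gt(A, 0)
  expect_equal(A, -null$lambda, tolerance = 1e-10)
  # at eps -> 0 the slow eigenvalue matches the locked Evans root
  nm0 <- noise_model(1e-12, 1, "linear", C0 = 10)
  ep0 <- effective_pulse(ref_kernel(), 4, nm0, stimulus = ep$stimulus)
  null0 <- adjoint_null_vector(ep0)
  p <- Filter(function(q) q$stability == "stable",
              solve_locked_pulses(ref_kernel(), ep$stimulus, 4))[[1]]
  roots <- classify_stability(p)$eigenvalues
  expect_equal(null0$lambda, max(Re(roots)), tolerance = 1e-6)
})

test_that("variance curve limits: origin, Brownian limit, saturation", {
  expect_equal(variance_curve(0, 0.01, 0.5), 0)
  tt <- c(0.5, 2, 7)
  expect_equal(variance_curve(tt, 0.01, 1e-12), 2 * 0.01 * tt,
               tolerance = 1e-9)
  expect_equal(variance_curve(1e6, 0.01, 0.5), 0.02, tolerance = 1e-9)
  de <- diffusivity(ref_locked_effective())
  expect_equal(variance_curve(1e7, de), de$D / de$A, tolerance = 1e-8)
})

test_that("ensemble mean displacement of a locked pulse relaxes at rate A", {
  ep <- ref_locked_effective()
  A_th <- ou_rate(ep)
  k <- ref_kernel(); s <- ep$stimulus
  fr <- firing_rule("heaviside", 4)
  g <- sim_grid(0, 102.4, dx = 0.1, dt = 0.01, t_final = 36,
                boundary = "periodic")
  ens <- integrate_langevin(g, k, fr, ep$noise,
                            u0 = pulse_profile(ep, g$x - 20 - 2),
                            stimulus = s, stim_pos0 = 20,
                            n_trials = 192, seed = 5, record_dt = 0.5)
  es <- ensemble_stats(ens)
  d <- dplyr::arrange(dplyr::filter(es, edge == "leading"), time)
  late <- dplyr::filter(d, time >= 28)
  const <- mean(late$mean_pos - s$v * late$time)
  d$delta <- d$mean_pos - s$v * d$time - const
  win <- dplyr::filter(d, time >= 4, time <= 20, delta > 0.02)
  expect_gte(nrow(win), 10)
  fit <- stats::lm(log(delta) ~ time, win)
  A_emp <- -unname(stats::coef(fit)[2])
  expect_equal(A_emp, A_th, tolerance = 0.25)
})
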