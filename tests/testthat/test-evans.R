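test_that("translation zero and conjugation symmetry of the Evans function", {
  p <- ref_stable_pulse()
  expect_lt(Mod(evans_free(p, 0 + 0i)), 1e-8)
  set.seed(5)
  for (i in 1:6) {
    lam <- complex(real = runif(1, -0.8, 1), imaginary = runif(1, -2, 2))
    expect_equal(evans_free(p, Conj(lam)), Conj(evans_free(p, lam)),
                 tolerance = 1e-12)
  }
})

test_that("stable pulse has exactly one extra eigenvalue, real and negative", {
  p <- ref_stable_pulse()
  roots <- find_evans_roots(function(l) evans_free(p, l),
                            re_range = c(-0.95, 1),
                            im_range = c(-2.5, 2.5))
  nz <- roots[Mod(roots) > 1e-8]
  expect_length(nz, 1)
  expect_equal(Im(nz), 0)
  expect_lt(Re(nz), 0)
  # simplicity of the translation zero: nonzero Evans derivative
  h <- 1e-6
  dE <- (evans_free(p, h + 0i) - evans_free(p, -h + 0i)) / (2 * h)
  expect_gt(Mod(dE), 1e-4)
})

test_that("root finding is stable under grid refinement", {
  p <- ref_stable_pulse()
  ev <- function(l) evans_free(p, l)
  r1 <- find_evans_roots(ev, c(-0.9, 1), c(-2, 2), n_re = 40, n_im = 30)
  r2 <- find_evans_roots(ev, c(-0.9, 1), c(-2, 2), n_re = 80, n_im = 60)
  expect_equal(length(r1), length(r2))
  for (z in r1) expect_lt(min(Mod(r2 - z)), 1e-6)
})

test_that("essential spectrum is the vertical line at -1 for any speed", {
  for (v in c(0.5, 3.896, -2.5)) {
    es <- essential_spectrum(v)
    expect_equal(es$abscissa, -1)
    kk <- seq(-3, 3, by = 0.37)
    expect_equal(Re(es$line(kk)), rep(-1, length(kk)))
    expect_equal(es$line(0), -1 + 0i)
    # Fourier symbol of the half-line factor blows up on the line
    lam_on <- es$line(0.4)
    phat <- function(lam, kf) 1 / ((lam + 1) / v + 2i * pi * kf)
    expect_gt(Mod(phat(lam_on + 1e-9, 0.4)), 1e6)
  }
  expect_error(essential_spectrum(0))
})

test_that("Evans roots agree with the discretized-operator eigenvalues", {
  # moderate resolution here; the full-precision version (dx = 0.02,
  # tolerance 1e-3) runs in the acceptance suite
  p <- ref_stable_pulse()
  A <- linearization_matrix(p, dx = 0.05, pad = 25)
  evs <- eigen(A, only.values = TRUE)$values
  roots <- find_evans_roots(function(l) evans_free(p, l),
                            c(-0.9, 1), c(-2, 2))
  for (z in roots) expect_lt(min(Mod(evs - z)), 2e-2)
})

test_that("classification matches direct simulation of a perturbed pulse", {
  p <- ref_stable_pulse()
  rep <- classify_stability(p)
  expect_true(rep$is_stable)
  expect_equal(rep$essential_re, -1)
  nz <- rep$eigenvalues[Mod(rep$eigenvalues) > 1e-6]
  lam1 <- max(Re(nz))
  # zero-noise simulation from a width-perturbed profile: the width
  # deviation decays at the leading nonzero eigenvalue's rate
  k <- p$kernel
  fr <- firing_rule("heaviside", p$kappa)
  g <- sim_grid(0, 102.4, dx = 0.05, dt = 0.005, t_final = 20,
                boundary = "periodic")
  u0 <- pulse_initial_condition(p, g, offset = 30) +
    0.35 * exp(-0.25 * (g$x - 30 - p$d / 2)^2)
  ens <- integrate_langevin(g, k, fr, noise_model(0, 1, "linear"),
                            u0 = u0, n_trials = 1, seed = 1,
                            levels = p$kappa, record_dt = 0.2)
  wide <- tidyr::pivot_wider(ens$tracks, names_from = "edge",
                             values_from = "position")
  width <- wide$leading - wide$trailing
  tt <- wide$time
  # decay measured against the simulation's own settled width, which
  # carries a small discretization offset from the analytic d
  w_inf <- mean(width[tt >= 18])
  dev <- abs(width - w_inf)
  # window after the perturbation feeds into the width and before the
  # deviation decays into the discretization floor
  sel <- tt >= 2 & tt <= 8 & dev > 1e-3
  fit <- stats::lm(log(dev[sel]) ~ tt[sel])
  rate <- -stats::coef(fit)[2]
  expect_equal(unname(rate), -lam1, tolerance = 0.15)
})
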