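ref_slow_stim <- function() stimulus_spec(I0 = 8, width = 5, v = 3)
ref_fast_stim <- function() stimulus_spec(I0 = 5, width = 5, v = 5)

locked_slow <- function() {
  memo("locked_slow",
       solve_locked_pulses(ref_kernel(), ref_slow_stim(), 4))
}
locked_fast <- function() {
  memo("locked_fast",
       solve_locked_pulses(ref_kernel(), ref_fast_stim(), 4))
}

test_that("a stable pulse locks to the slow strong stimulus", {
  ps <- locked_slow()
  st <- Filter(function(p) p$stability == "stable", ps)
  expect_gte(length(st), 1)
  p <- st[[1]]
  expect_lt(max(abs(locked_residuals(p$kernel, p$stimulus, p$kappa,
                                     p$d1, p$d2))), 1e-8)
  expect_lt(p$d1, p$d2)
})

test_that("fast-stimulus scan: at most one stable, up to three unstable", {
  ps <- locked_fast()
  st <- vapply(ps, `[[`, character(1), "stability")
  expect_lte(sum(st == "stable"), 1)
  expect_lte(sum(st == "unstable"), 3)
  expect_gte(length(ps) + attr(ps, "n_invalid"), 2)
})

test_that("locked profile is continuous and solves the co-moving ODE", {
  p <- Filter(function(q) q$stability == "stable", locked_slow())[[1]]
  s <- p$stimulus; k <- p$kernel
  # continuity at all analytic breakpoints
  for (bp in c(0, s$width, k$x0 + p$d1, k$x0 + p$d2)) {
    expect_lt(abs(pulse_profile(p, bp + 1e-7) - pulse_profile(p, bp - 1e-7)),
              1e-5)
  }
  # ODE oracle with the superthreshold interval fixed to (d1, d2)
  Ifun <- function(x) ifelse(x >= 0 & x <= s$width, s$I0, 0)
  xi_hi <- p$d2 + 60
  sol <- deSolve::ode(
    y = c(U = pulse_profile(p, xi_hi)),
    times = seq(xi_hi, p$d1 - 15, by = -0.05),
    func = function(t, y, parms)
      list((y[1] - window_integral(k, t, p$d1, p$d2) - Ifun(t)) / s$v),
    rtol = 1e-10, atol = 1e-10)
  expect_equal(sol[, "U"], pulse_profile(p, sol[, "time"]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("zero amplitude at the free speed recovers the free pulse", {
  fp <- ref_stable_pulse()
  s0 <- stimulus_spec(0, 5, fp$c)
  ps <- solve_locked_pulses(ref_kernel(), s0, 4, classify = FALSE)
  expect_gte(length(ps), 1)
  widths <- vapply(ps, function(p) p$d2 - p$d1, numeric(1))
  expect_lt(min(abs(widths - fp$d)), 1e-6)
})

test_that("mirror symmetry: reflecting kernel and stimulus speed", {
  k <- ref_kernel()
  km <- weight_kernel(k$a_e, k$a_i, k$sigma_e, k$sigma_i, x0 = -k$x0)
  s <- stimulus_spec(5, 5, 5)
  sm <- stimulus_spec(5, 5, -5)
  ps <- locked_fast()
  pm <- solve_locked_pulses(km, sm, 4, classify = FALSE)
  expect_equal(length(pm), length(ps))
  # solutions map (d1, d2) -> (width - d2, width - d1)
  fwd <- sort(vapply(ps, `[[`, numeric(1), "d1"))
  mir <- sort(vapply(pm, function(p) s$width - p$d2, numeric(1)))
  expect_equal(mir, fwd, tolerance = 1e-6)
})

test_that("locked Evans function: symmetry and degenerate-edge guard", {
  p <- Filter(function(q) q$stability == "stable", locked_slow())[[1]]
  lam <- 0.3 + 0.7i
  expect_equal(evans_locked(p, Conj(lam)), Conj(evans_locked(p, lam)),
               tolerance = 1e-12)
  # stable pulse: no roots in the right half plane
  roots <- find_evans_roots(function(l) evans_locked(p, l),
                            c(-0.9, 2), c(-4, 4), n_re = 60, n_im = 40)
  expect_true(all(Re(roots) < -1e-6))
  # crossing on a stimulus edge is flagged degenerate
  bad <- p; bad$d1 <- 0
  expect_error(evans_locked(bad, 0.1 + 0i), "degenerate")
})

test_that("deterministic field locks onto the predicted profile from rest", {
  k <- ref_kernel()
  s <- ref_slow_stim()
  p <- Filter(function(q) q$stability == "stable", locked_slow())[[1]]
  fr <- firing_rule("heaviside", 4)
  g <- sim_grid(0, 204.8, dx = 0.1, dt = 0.01, t_final = 50,
                boundary = "periodic")
  ens <- integrate_langevin(g, k, fr, noise_model(0, 1, "linear"),
                            u0 = rep(0, g$n), stimulus = s, stim_pos0 = 30,
                            n_trials = 1, seed = 1, levels = 4)
  # final crossings must sit at the analytic (d1, d2) relative to the
  # stimulus position at t = 50
  stim_pos <- 30 + s$v * 50
  cr <- level_crossings(ens$final[, 1], g$x, 4)
  # compare circular distance to the predicted crossings (tolerance covers
  # the first-order time-discretization shift of the locked equilibrium)
  circ <- function(a, b, L) { d <- (a - b) %% L; pmin(d, L - d) }
  L <- g$x_max - g$x_min
  expect_lt(circ(cr[["trailing"]], (stim_pos + p$d1) %% L, L), 0.6)
  expect_lt(circ(cr[["leading"]], (stim_pos + p$d2) %% L, L), 0.6)
})

test_that("locking tongue opens from the free-pulse speed", {
  k <- ref_kernel()
  sc <- memo("tongue_slice", locking_tongues(
    k, 4, s_width = 5, v_grid = c(2.5, 3.9, 5.5), I0_grid = c(0.75, 2)))
  expect_true(all(sc$status == "ok"))
  # near the free speed c = 3.896 a small-amplitude stimulus locks stably
  at_c <- dplyr::filter(sc, v == 3.9, I0 == 0.75)
  expect_gte(at_c$n_stable, 1)
  # far from it the same amplitude cannot lock
  off <- dplyr::filter(sc, v %in% c(2.5, 5.5), I0 == 0.75)
  expect_true(all(off$n_stable == 0))
  # tongue widens with amplitude: count of locking speeds nondecreasing
  n_lock <- function(i0) sum(dplyr::filter(sc, I0 == i0)$n_stable > 0)
  expect_gte(n_lock(2), n_lock(0.75))
})
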