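# Shared fixtures: the reference kernel and pulses, quadrature oracles,
# and memoized heavy objects (computed once per test run).

ref_kernel <- function() weight_kernel(5, 1, 0.42, 0.1, x0 = 3)

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

ref_pulses <- function() {
  memo("ref_pulses", solve_free_pulses(ref_kernel(), kappa = 4))
}

ref_stable_pulse <- function() {
  ps <- ref_pulses()
  ps[[which(vapply(ps, `[[`, character(1), "stability") == "stable")[1]]]
}

ref_fast_pulse <- function() {
  ps <- ref_pulses()
  ps[[which.max(vapply(ps, `[[`, numeric(1), "c"))]]
}

ref_noise <- function() noise_model(0.005, 1, "linear", C0 = 10)

# adaptive-quadrature oracle for int_a^b f, with optional improper tails
quad <- function(f, a, b, ...) {
  stats::integrate(f, a, b, rel.tol = 1e-12, subdivisions = 2000L,
                   ...)$value
}

# random kernels respecting the type invariants
random_kernel <- function() {
  a_i <- runif(1, 0.2, 2)
  a_e <- a_i + runif(1, 0.5, 6)
  s_i <- runif(1, 0.05, 0.5)
  s_e <- s_i + runif(1, 0.1, 1)
  weight_kernel(a_e, a_i, s_e, s_i, x0 = runif(1, -2, 4))
}

# ---- heavy shared ensembles for the acceptance checks ------------------
# Desk-scale study conditions (trial counts and horizons stated in the
# methods vignette); computed once and shared across test blocks.

acc_free_ensemble <- function(kap) {
  memo(paste0("acc_free_", kap), {
    k <- ref_kernel()
    t_final <- if (kap == 4) 48 else 36
    g <- sim_grid(0, 102.4, dx = 0.1, dt = 0.01, t_final = t_final,
                  boundary = "periodic")
    fp <- solve_free_pulses(k, kap, classify = FALSE)[[1]]
    integrate_langevin(g, k, firing_rule("heaviside", kap), ref_noise(),
                       u0 = pulse_initial_condition(fp, g, 20),
                       n_trials = if (kap == 4) 1024 else 512, seed = 101,
                       levels = c(0.6, 0.8, 1) * kap)
  })
}

acc_locked_ensemble <- function() {
  memo("acc_locked", {
    k <- ref_kernel()
    s <- stimulus_spec(5, 5, 5)
    ep <- effective_pulse(k, 4, ref_noise(), stimulus = s)
    g <- sim_grid(0, 102.4, dx = 0.1, dt = 0.01, t_final = 48,
                  boundary = "periodic")
    integrate_langevin(g, k, firing_rule("heaviside", 4), ref_noise(),
                       u0 = pulse_profile(ep, g$x - 20),
                       stimulus = s, stim_pos0 = 20,
                       n_trials = 200, seed = 7)
  })
}
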