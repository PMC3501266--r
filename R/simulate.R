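#' Simulation grid
#'
#' Space-time lattice for the Langevin integrator.  The spatial step also
#' fixes the lattice-noise normalization: in the white-noise limit the
#' correlation amplitude is \eqn{C(0) = 1/\Delta x}.
#'
#' @param x_min,x_max Domain ends.
#' @param dx Spatial step.
#' @param dt Time step.
#' @param t_final Final time.
#' @param boundary "periodic" (ring of circumference \code{x_max - x_min})
#'   or "buffer" (a clamped-to-zero buffer of width \code{buffer} at each
#'   end; the pulse must not approach it).
#' @param buffer Buffer width (length units) for \code{boundary =
#'   "buffer"}; defaults to \code{5 / sigma_i} of the kernel at
#'   integration time.
#' @return A \code{sim_grid} object with the lattice \code{x}.
#' @export
sim_grid <- function(x_min, x_max, dx = 0.1, dt = 0.01, t_final,
                     boundary = c("periodic", "buffer"), buffer = NULL) {
  boundary <- match.arg(boundary)
  stopifnot(dx > 0, dt > 0, t_final > 0, x_max > x_min)
  n <- round((x_max - x_min) / dx)
  structure(list(x_min = x_min, x_max = x_min + n * dx, dx = dx, dt = dt,
                 t_final = t_final, boundary = boundary, buffer = buffer,
                 n = n, x = x_min + (seq_len(n) - 1) * dx),
            class = "sim_grid")
}

#' Multiplicative noise model
#'
#' Extrinsic Stratonovich noise \eqn{\epsilon^{1/2} g(U) dW} with spatial
#' correlator \eqn{2 C(|x-x'|/\lambda)\delta(t-t')}.  The default is the
#' lattice white-noise limit \eqn{\lambda \to 0}, \eqn{C(0) = 1/\Delta x}.
#' Supported activity dependencies: linear \eqn{g(U) = g_0 U} and additive
#' \eqn{g(U) = g_0}.
#'
#' @param eps Noise strength \eqn{\epsilon \ge 0} (weak-noise theory
#'   assumes it small).
#' @param g0 Noise amplitude coefficient.
#' @param form "linear" or "additive".
#' @param C0 Correlation amplitude \eqn{C(0)}; when \code{NULL} it is set
#'   to \eqn{1/\Delta x} at integration time.  Supplying a value that
#'   disagrees with \eqn{1/\Delta x} triggers a warning.
#' @param corr_len Spatial correlation length; only the lattice limit 0 is
#'   integrated (finite values are an extension point and are rejected).
#' @return A \code{noise_model} object.
#' @export
noise_model <- function(eps, g0 = 1, form = c("linear", "additive"),
                        C0 = NULL, corr_len = 0) {
  form <- match.arg(form)
  stopifnot(eps >= 0, is.null(C0) || C0 > 0)
  if (corr_len != 0)
    stop("only the lattice white-noise limit (corr_len = 0) is implemented")
  structure(list(eps = eps, g0 = g0, form = form, C0 = C0,
                 corr_len = corr_len),
            class = "noise_model")
}

.noise_C0 <- function(noise, dx) {
  if (is.null(noise$C0)) return(1 / dx)
  if (abs(noise$C0 - 1 / dx) > 1e-9)
    warning(sprintf(
      "noise C0 = %g overrides the lattice white-noise value 1/dx = %g",
      noise$C0, 1 / dx))
  noise$C0
}

#' Sample a pulse profile onto a simulation grid
#'
#' @param p A \code{free_pulse}, \code{locked_pulse} or
#'   \code{effective_pulse}.
#' @param grid A \code{\link{sim_grid}}.
#' @param offset Lab-frame position of the profile's co-moving origin
#'   \eqn{\xi = 0} (for a locked pulse this is where the stimulus's left
#'   edge must sit at \eqn{t = 0}; pass the same value as
#'   \code{stim_pos0} to \code{\link{integrate_langevin}}).
#' @return Numeric initial field on \code{grid$x}.
#' @export
pulse_initial_condition <- function(p, grid, offset = 0) {
  stopifnot(inherits(grid, "sim_grid"))
  u <- pulse_profile(p, grid$x - offset)
  u[!is.finite(u)] <- 0
  u
}

#' Integrate the Langevin neural field
#'
#' Forward Euler--Maruyama integration of the stochastic field equation in
#' its Ito-equivalent form: deterministic drift \eqn{-U + \epsilon C(0)
#' g'(U)g(U)} plus the kernel convolution of the firing rate and an
#' optional rigidly translating rectangular stimulus, plus independent
#' per-site Gaussian increments of variance \eqn{2 C(0) \Delta t} scaled
#' by \eqn{\epsilon^{1/2} g(U)}.  Trials run as independent columns of one
#' lattice ensemble (single seeded RNG stream; identical seed gives
#' bit-identical output).  Level-set crossing positions of both pulse
#' edges are extracted at the recording cadence with temporal-continuity
#' tracking; full field snapshots can be kept for a few trials.
#'
#' @param grid A \code{\link{sim_grid}}.
#' @param k A \code{\link{weight_kernel}}.
#' @param firing A \code{\link{firing_rule}}.
#' @param noise A \code{\link{noise_model}} (use \code{eps = 0} for
#'   deterministic runs).
#' @param u0 Initial field: numeric vector on \code{grid$x}, or a pulse
#'   object (sampled via \code{\link{pulse_initial_condition}}).
#' @param stimulus Optional \code{\link{stimulus_spec}}; its leading edge
#'   starts at \code{stim_pos0}.
#' @param n_trials Ensemble size.
#' @param seed RNG seed (integer); all randomness derives from it.
#' @param levels Level values tracked for each edge (defaults to
#'   \code{c(0.6, 0.8, 1) * kappa}).
#' @param record_dt Recording cadence in time units.
#' @param n_snapshot_trials Number of trials whose full fields are stored.
#' @param stim_pos0 Initial position of the stimulus leading edge.
#' @param blowup Abort threshold on \eqn{\max |U|}.
#' @return A \code{wave_ensemble}: list with \code{tracks} (tibble of
#'   \code{time, trial, level, edge, position}), \code{times},
#'   \code{snapshots} (array x-by-trial-by-time), \code{final}, flags and
#'   the resolved parameters.
#' @export
integrate_langevin <- function(grid, k, firing, noise, u0, stimulus = NULL,
                               n_trials = 1, seed = 1, levels = NULL,
                               record_dt = 0.25, n_snapshot_trials = 0,
                               stim_pos0 = 0, blowup = 1e4) {
  stopifnot(inherits(grid, "sim_grid"), inherits(k, "weight_kernel"),
            inherits(firing, "firing_rule"), inherits(noise, "noise_model"))
  if (inherits(u0, c("free_pulse", "locked_pulse", "effective_pulse")))
    u0 <- pulse_initial_condition(u0, grid)
  stopifnot(length(u0) == grid$n)
  if (is.null(levels)) levels <- c(0.6, 0.8, 1) * firing$kappa
  C0 <- .noise_C0(noise, grid$dx)

  nbuf <- 0L
  if (grid$boundary == "buffer") {
    bw <- if (is.null(grid$buffer)) 5 / k$sigma_i else grid$buffer
    nbuf <- as.integer(ceiling(bw / grid$dx))
  }
  # ring displacement kernel and its FFT (includes the dx quadrature
  # weight of the Riemann-sum convolution)
  n <- grid$n
  m <- seq_len(n) - 1
  disp <- ifelse(m <= n / 2, m, m - n) * grid$dx
  what <- stats::fft(weight(k, disp)) * grid$dx

  nsteps <- round(grid$t_final / grid$dt)
  record_every <- max(1L, round(record_dt / grid$dt))
  has_stim <- !is.null(stimulus) && stimulus$I0 > 0
  set.seed(seed)
  res <- em_simulate_cpp(
    matrix(u0, n, n_trials), what, grid$x_min, grid$dx, grid$dt, nsteps,
    firing$kappa, if (firing$kind == "heaviside") 0L else 1L,
    if (is.null(firing$gamma)) 0 else firing$gamma,
    noise$eps, C0, noise$g0, if (noise$form == "linear") 0L else 1L,
    has_stim, if (has_stim) stimulus$I0 else 0,
    if (has_stim) stimulus$width else 1,
    if (has_stim) stimulus$v else 0, stim_pos0,
    grid$boundary == "periodic", nbuf, levels, record_every,
    n_snapshot_trials, blowup)

  nrec <- res$n_recorded
  pos <- res$positions
  times <- res$times[seq_len(nrec)]
  tracks <- tidyr::expand_grid(
    edge = c("trailing", "leading"),
    level = levels, trial = seq_len(n_trials),
    time = times)
  # positions layout: [rec, trial, level, edge]
  tracks$position <- as.vector(pos[seq_len(nrec), , , , drop = FALSE])
  tracks <- dplyr::select(tracks, "time", "trial", "level", "edge",
                          "position")
  if (res$blew_up)
    warning("field magnitude exceeded the blow-up guard; run truncated")
  if (res$boundary_touch)
    warning("superthreshold activity approached the clamped buffer")
  structure(list(tracks = tibble::as_tibble(tracks), times = times,
                 snapshots = if (n_snapshot_trials > 0)
                   res$snapshots[, , seq_len(nrec), drop = FALSE]
                 else NULL,
                 final = res$final, x = grid$x,
                 blew_up = res$blew_up,
                 boundary_touch = res$boundary_touch,
                 grid = grid, kernel = k, firing = firing, noise = noise,
                 stimulus = stimulus, levels = levels, seed = seed,
                 n_trials = n_trials),
            class = "wave_ensemble")
}

#' @export
print.wave_ensemble <- function(x, ...) {
  cat(sprintf(
    "<wave_ensemble> %d trial(s), t in [0, %g], %d x %g lattice (dx = %g)\n",
    x$n_trials, max(x$times), x$grid$n, x$grid$dx, x$grid$dx))
  cat(sprintf("  eps = %g, levels tracked: %s\n", x$noise$eps,
              paste(signif(x$levels, 4), collapse = ", ")))
  invisible(x)
}
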