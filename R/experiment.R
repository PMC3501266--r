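# Experiment orchestration: named parameter presets, YAML configuration,
# and a subcommand dispatcher that ties the analysis modules into
# reproducible runs with on-disk artifacts.

#' Named parameter presets
#'
#' The reference parameter sets used throughout the package's examples
#' and reproduction experiments: the standard offset Mexican-hat kernel
#' (a_e = 5, a_i = 1, sigma_e = 0.42, sigma_i = 0.1, x0 = 3, threshold
#' kappa = 4), the standard weak multiplicative noise (eps = 0.005,
#' g(U) = U, C0 = 10 on a dx = 0.1 lattice), the slow strong stimulus
#' (I0 = 8, width 5, v = 3) and the fast moderate stimulus (I0 = 5,
#' width 5, v = 5).
#'
#' @return Named list of preset parameter lists.
#' @export
np_presets <- function() {
  list(
    kernel_default = list(a_e = 5, a_i = 1, sigma_e = 0.42, sigma_i = 0.1,
                          x0 = 3),
    threshold_default = 4,
    noise_default = list(eps = 0.005, g0 = 1, form = "linear", C0 = 10),
    grid_default = list(dx = 0.1, dt = 0.01),
    stimulus_slow = list(I0 = 8, width = 5, v = 3),
    stimulus_fast = list(I0 = 5, width = 5, v = 5)
  )
}

.cfg_field <- function(cfg, path, default = NULL, required = FALSE) {
  node <- cfg
  for (p in path) {
    if (is.null(node[[p]])) {
      if (required)
        stop(sprintf("config validation: missing required field '%s'",
                     paste(path, collapse = ".")), call. = FALSE)
      return(default)
    }
    node <- node[[p]]
  }
  node
}

#' Read and validate an experiment configuration
#'
#' Reads a YAML configuration with sections \code{kernel} (a_e, a_i,
#' sigma_e, sigma_i, x0), \code{firing} (kappa, optionally kind/gain),
#' optional \code{stimulus} (I0, width, v), optional \code{noise} (eps,
#' g0, form, C0), optional \code{grid} (x_min, x_max, dx, dt, t_final,
#' boundary) and \code{run} (seed, n_trials, out_dir) plus
#' subcommand-specific blocks (\code{scan}, \code{tongues}, \code{fit}).
#' Missing required fields raise errors naming the field.  The lattice
#' consistency C0 = 1/dx is checked at load time (warning if overridden).
#'
#' @param path Path to a YAML file, or a list already in config shape.
#' @return A validated \code{experiment_config} list.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  kp <- .cfg_field(cfg, "kernel", required = TRUE)
  for (f in c("a_e", "a_i", "sigma_e", "sigma_i"))
    if (is.null(kp[[f]]))
      stop(sprintf("config validation: missing required field 'kernel.%s'", f),
           call. = FALSE)
  .cfg_field(cfg, c("firing", "kappa"), required = TRUE)
  if (!is.null(cfg$noise) && !is.null(cfg$noise$C0) && !is.null(cfg$grid$dx)) {
    if (abs(cfg$noise$C0 - 1 / cfg$grid$dx) > 1e-9)
      warning(sprintf(
        "config: noise C0 = %g overrides the lattice value 1/dx = %g",
        cfg$noise$C0, 1 / cfg$grid$dx))
  }
  structure(cfg, class = "experiment_config")
}

.cfg_objects <- function(cfg) {
  kp <- cfg$kernel
  k <- weight_kernel(kp$a_e, kp$a_i, kp$sigma_e, kp$sigma_i,
                     if (is.null(kp$x0)) 0 else kp$x0)
  fr <- firing_rule(.cfg_field(cfg, c("firing", "kind"), "heaviside"),
                    cfg$firing$kappa,
                    .cfg_field(cfg, c("firing", "gain")))
  s <- NULL
  if (!is.null(cfg$stimulus))
    s <- stimulus_spec(cfg$stimulus$I0, cfg$stimulus$width, cfg$stimulus$v)
  nm <- noise_model(.cfg_field(cfg, c("noise", "eps"), 0),
                    .cfg_field(cfg, c("noise", "g0"), 1),
                    .cfg_field(cfg, c("noise", "form"), "linear"),
                    .cfg_field(cfg, c("noise", "C0")))
  g <- NULL
  if (!is.null(cfg$grid))
    g <- sim_grid(.cfg_field(cfg, c("grid", "x_min"), 0),
                  .cfg_field(cfg, c("grid", "x_max"), required = TRUE),
                  .cfg_field(cfg, c("grid", "dx"), 0.1),
                  .cfg_field(cfg, c("grid", "dt"), 0.01),
                  .cfg_field(cfg, c("grid", "t_final"), required = TRUE),
                  .cfg_field(cfg, c("grid", "boundary"), "periodic"))
  list(kernel = k, firing = fr, stimulus = s, noise = nm, grid = g)
}

.np_log <- function(module, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%OS2"), module,
                  sprintf(...)))
}

.write_table <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  .np_log("io", "wrote %s (%d rows)", path, nrow(df))
  path
}

#' Run a named experiment subcommand
#'
#' Dispatches a configuration to one of the module pipelines:
#' \describe{
#'   \item{free-pulse}{branch scan of pulse speed/width over a threshold
#'     grid (\code{scan: kappa_from/kappa_to/kappa_by}).}
#'   \item{stability}{solve free pulses at the configured threshold and
#'     report Evans eigenvalues and verdicts; optionally exports an
#'     Evans-function sample grid (\code{evans_grid: TRUE}).}
#'   \item{locked}{solve stimulus-locked pulses at the configured
#'     threshold and stimulus.}
#'   \item{tongues}{classification grid over stimulus speed/amplitude
#'     (\code{tongues: v_from/v_to/v_n/I0_from/I0_to/I0_n}).}
#'   \item{simulate}{Langevin ensemble with level-set tracking.}
#'   \item{diffusion}{theory-vs-simulation diffusivity table over a
#'     threshold grid.}
#'   \item{wander}{chained simulate + track + fit experiment for the
#'     free (Brownian) or locked (OU) wandering laws.}
#' }
#' Every run writes the resolved configuration and seed next to its
#' outputs (when \code{run.out_dir} is set) and is deterministic given
#' the seed.
#'
#' @param name Subcommand name.
#' @param cfg An \code{\link{read_experiment_config}} object (or list).
#' @return The result tibble(s), invisibly for commands with file output.
#' @export
run_experiment <- function(name = c("free-pulse", "stability", "locked",
                                    "tongues", "simulate", "diffusion",
                                    "wander"),
                           cfg) {
  name <- match.arg(name)
  cfg <- read_experiment_config(cfg)
  ob <- .cfg_objects(cfg)
  out_dir <- .cfg_field(cfg, c("run", "out_dir"))
  seed <- .cfg_field(cfg, c("run", "seed"), 1L)
  n_trials <- .cfg_field(cfg, c("run", "n_trials"), 1L)
  kap <- cfg$firing$kappa
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_resolved.yaml"))
  }
  .np_log("run", "subcommand '%s' (seed %d)", name, seed)

  if (name == "free-pulse") {
    kg <- seq(.cfg_field(cfg, c("scan", "kappa_from"), required = TRUE),
              .cfg_field(cfg, c("scan", "kappa_to"), required = TRUE),
              by = .cfg_field(cfg, c("scan", "kappa_by"), 0.1))
    res <- branch_scan(ob$kernel, kg)
    .write_table(res, out_dir, "free_pulse_branches")
    return(res)
  }
  if (name == "stability") {
    ps <- solve_free_pulses(ob$kernel, kap)
    rows <- lapply(ps, function(p) {
      rep <- classify_stability(p)
      tibble::tibble(c = p$c, d = p$d, verdict = rep$verdict,
                     eigenvalues = paste(format(rep$eigenvalues, digits = 6),
                                         collapse = "; "))
    })
    res <- dplyr::bind_rows(rows)
    .write_table(res, out_dir, "stability")
    if (isTRUE(.cfg_field(cfg, "evans_grid")) && length(ps)) {
      p <- ps[[1]]
      re <- seq(-0.95, 1, length.out = 60); im <- seq(-3, 3, length.out = 60)
      gr <- tidyr::expand_grid(re = re, im = im)
      ev <- evans_free(p, complex(real = gr$re, imaginary = gr$im))
      gr$re_E <- Re(ev); gr$im_E <- Im(ev)
      .write_table(gr, out_dir, "evans_grid")
    }
    return(res)
  }
  if (name == "locked") {
    ps <- solve_locked_pulses(ob$kernel, ob$stimulus, kap)
    res <- dplyr::bind_rows(lapply(ps, glance))
    res$n_invalid <- attr(ps, "n_invalid")
    .write_table(res, out_dir, "locked_pulses")
    return(res)
  }
  if (name == "tongues") {
    tg <- cfg$tongues
    vg <- seq(tg$v_from, tg$v_to, length.out = tg$v_n)
    ig <- seq(tg$I0_from, tg$I0_to, length.out = tg$I0_n)
    res <- locking_tongues(ob$kernel, kap, ob$stimulus$width,
                           vg[vg != 0], ig)
    .write_table(res, out_dir, "locking_tongues")
    return(res)
  }
  if (name == "simulate") {
    fp <- if (is.null(ob$stimulus)) {
      cand <- solve_free_pulses(ob$kernel, kap)
      Filter(function(p) p$stability == "stable", cand)[[1]]
    } else {
      cand <- solve_locked_pulses(ob$kernel, ob$stimulus, kap)
      Filter(function(p) p$stability == "stable", cand)[[1]]
    }
    off <- .cfg_field(cfg, c("run", "offset"),
                      ob$grid$x_min + 0.2 * (ob$grid$x_max - ob$grid$x_min))
    ens <- integrate_langevin(ob$grid, ob$kernel, ob$firing, ob$noise,
                              u0 = pulse_initial_condition(fp, ob$grid, off),
                              stimulus = ob$stimulus, stim_pos0 = off,
                              n_trials = n_trials, seed = seed)
    .write_table(ens$tracks, out_dir, "tracks")
    .write_table(ensemble_stats(ens), out_dir, "ensemble_stats")
    return(invisible(ens))
  }
  if (name == "diffusion") {
    kg <- seq(.cfg_field(cfg, c("scan", "kappa_from"), kap),
              .cfg_field(cfg, c("scan", "kappa_to"), kap),
              by = .cfg_field(cfg, c("scan", "kappa_by"), 0.5))
    res <- diffusion_experiment(ob$kernel, kg, ob$noise,
                                n_trials = n_trials, seed = seed,
                                t_final = .cfg_field(cfg, c("grid", "t_final"), 36))
    .write_table(res, out_dir, "diffusion")
    return(res)
  }
  # wander: simulate + track + fit
  process <- if (is.null(ob$stimulus)) "brownian" else "ou"
  fp <- if (process == "brownian")
    effective_pulse(ob$kernel, kap, ob$noise)
  else effective_pulse(ob$kernel, kap, ob$noise, stimulus = ob$stimulus)
  off <- ob$grid$x_min + 0.2 * (ob$grid$x_max - ob$grid$x_min)
  ens <- integrate_langevin(ob$grid, ob$kernel, ob$firing, ob$noise,
                            u0 = pulse_initial_condition(fp, ob$grid, off),
                            stimulus = ob$stimulus, stim_pos0 = off,
                            n_trials = n_trials, seed = seed)
  st <- ensemble_stats(ens)
  fit <- fit_wandering(st, process)
  .write_table(st, out_dir, "wander_curves")
  .write_table(fit, out_dir, "wander_fits")
  list(stats = st, fits = fit)
}

#' Theory-versus-simulation diffusivity table
#'
#' For each threshold: computes the predicted effective diffusivity from
#' the adjoint-projection formula and measures the empirical diffusivity
#' from the late-time slope of the level-set position variance of a
#' seeded ensemble, with a jackknife standard error.
#'
#' @inheritParams solve_free_pulses
#' @param kappa_grid Thresholds to scan.
#' @param noise A \code{\link{noise_model}} with explicit C0.
#' @param n_trials Trials per threshold.
#' @param t_final Integration horizon.
#' @param seed Base RNG seed (incremented per threshold).
#' @param ring_length Periodic domain circumference.
#' @return Tibble with columns \code{kappa, D_theory, D_empirical,
#'   D_se, edge, n_trials}.
#' @export
diffusion_experiment <- function(k, kappa_grid, noise, n_trials = 512,
                                 t_final = 36, seed = 1,
                                 ring_length = 102.4) {
  rows <- list()
  for (i in seq_along(kappa_grid)) {
    kap <- kappa_grid[i]
    ep <- effective_pulse(k, kap, noise)
    D_th <- diffusivity(ep)$D
    fr <- firing_rule("heaviside", kap)
    g <- sim_grid(0, ring_length, dx = 0.1, dt = 0.01, t_final = t_final,
                  boundary = "periodic")
    fp <- solve_free_pulses(k, kap, classify = FALSE)[[1]]
    ens <- integrate_langevin(g, k, fr, noise,
                              u0 = pulse_initial_condition(fp, g, 20),
                              n_trials = n_trials, seed = seed + i,
                              levels = c(0.6, 0.8, 1) * kap)
    fit <- fit_wandering(ensemble_stats(ens), "brownian",
                         t_min = 0.25 * t_final)
    for (j in seq_len(nrow(fit)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kappa = kap, D_theory = D_th, D_empirical = fit$D[j],
        edge = fit$edge[j], r2 = fit$r2_var[j], n_trials = n_trials)
    .np_log("diffusion", "kappa=%.3g D_theory=%.4g D_emp=%s", kap, D_th,
            paste(signif(fit$D, 3), collapse = "/"))
  }
  dplyr::bind_rows(rows)
}
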