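# Level-set wave tracking and ensemble statistics.
#
# Wave position is measured as the interpolated location where the field
# crosses chosen activity levels; the trailing edge is the up-crossing and
# the leading edge the down-crossing of the superthreshold component
# containing the pulse.  Ensemble mean and variance curves use two-stage
# averaging (over levels, then trials) and are fitted against the
# Brownian (free pulse) or Ornstein--Uhlenbeck (locked pulse) wandering
# laws.

#' Level crossings of a sampled field
#'
#' Finds the trailing (up-crossing) and leading (down-crossing) edge
#' positions of the pulse at a given level, with sub-grid linear
#' interpolation.  On a frame with several crossings (noise can graze the
#' level repeatedly) the crossing nearest \code{prev} is chosen for each
#' edge; without a previous position the outermost crossings of the
#' widest superthreshold run are used.
#'
#' @param u Field values sampled on \code{x}.
#' @param x Grid positions (uniform).
#' @param level Level value \eqn{a}.
#' @param prev Optional numeric pair (trailing, leading) from the previous
#'   frame for temporal-continuity selection.
#' @return Named numeric pair \code{c(trailing =, leading =)}; \code{NA}
#'   when the field never crosses the level.
#' @export
level_crossings <- function(u, x, level, prev = NULL) {
  stopifnot(length(u) == length(x), length(x) >= 2)
  s <- u - level
  n <- length(u)
  iu <- which(s[-n] <= 0 & s[-1] > 0)
  id <- which(s[-n] > 0 & s[-1] <= 0)
  interp <- function(i) x[i] + (x[i + 1] - x[i]) * (-s[i]) / (s[i + 1] - s[i])
  ups <- vapply(iu, interp, numeric(1))
  downs <- vapply(id, interp, numeric(1))
  if (!length(ups) || !length(downs))
    return(c(trailing = NA_real_, leading = NA_real_))
  if (!is.null(prev) && all(is.finite(prev))) {
    tr <- ups[which.min(abs(ups - prev[1]))]
    le <- downs[which.min(abs(downs - prev[2]))]
  } else {
    # widest run
    width <- vapply(ups, function(up) {
      dn <- downs[downs > up]
      if (!length(dn)) return(-Inf)
      min(dn) - up
    }, numeric(1))
    if (all(!is.finite(width)))
      return(c(trailing = NA_real_, leading = NA_real_))
    tr <- ups[which.max(width)]
    le <- tr + max(width)
  }
  c(trailing = tr, leading = le)
}

#' Ensemble mean and variance curves of tracked wave positions
#'
#' Two-stage averaging of the level-set positions \eqn{X_a(t)}: the mean
#' position per edge averages over the sampled levels and then over
#' trials; the variance averages, over levels, the across-trial variance
#' of \eqn{X_a(t)} (so systematic offsets between levels do not inflate
#' it and the curve estimates the wandering variance
#' \eqn{\langle\Delta(t)^2\rangle}).
#'
#' @param tracks Tibble with columns \code{time, trial, level, edge,
#'   position} (as produced by \code{\link{integrate_langevin}}), or a
#'   \code{wave_ensemble}.
#' @return Tibble with columns \code{time, edge, mean_pos, var_pos, n}.
#' @export
ensemble_stats <- function(tracks) {
  if (inherits(tracks, "wave_ensemble")) tracks <- tracks$tracks
  stopifnot(all(c("time", "trial", "level", "edge", "position")
                %in% names(tracks)))
  if (dplyr::n_distinct(tracks$trial) < 2)
    stop("ensemble_stats requires at least 2 trials")
  per_level <- dplyr::summarise(
    dplyr::group_by(tracks, .data$time, .data$edge, .data$level),
    m = mean(.data$position, na.rm = TRUE),
    v = stats::var(.data$position[is.finite(.data$position)]),
    n = sum(is.finite(.data$position)), .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_level, .data$time, .data$edge),
    mean_pos = mean(.data$m), var_pos = mean(.data$v),
    n = min(.data$n), .groups = "drop")
}

#' Fit drift and wandering laws to ensemble curves
#'
#' Least-squares fits over a post-transient window: the mean position is
#' fitted as \eqn{\bar X(t) = c t + x_0}; the variance as the Brownian
#' line \eqn{\sigma^2_X(t) = 2 D t + b} or the Ornstein--Uhlenbeck
#' saturation curve \eqn{\sigma^2_X(t) = (D/A)(1 - e^{-2At})}.
#'
#' @param stats Curves from \code{\link{ensemble_stats}}.
#' @param process "brownian" or "ou".
#' @param t_min Start of the fit window; default drops the first 25% of
#'   the recorded span (transients reflect relaxation of the mean pulse
#'   width).
#' @return A tibble with one row per edge: \code{speed}, \code{intercept},
#'   \code{r2_mean} from the drift fit; \code{D}, \code{A} (OU only,
#'   otherwise 0), \code{r2_var} from the variance fit.
#' @export
fit_wandering <- function(stats, process = c("brownian", "ou"),
                          t_min = NULL) {
  process <- match.arg(process)
  if (is.null(t_min)) t_min <- 0.25 * max(stats$time)
  win <- dplyr::filter(stats, .data$time >= t_min)
  if (dplyr::n_distinct(win$time) < 3)
    stop("fit window must contain at least 3 recording instants")
  fit_edge <- function(df) {
    fm <- stats::lm(mean_pos ~ time, data = df)
    r2m <- summary(fm)$r.squared
    if (process == "brownian") {
      fv <- stats::lm(var_pos ~ time, data = df)
      D <- unname(stats::coef(fv)["time"]) / 2
      A <- 0
      r2v <- summary(fv)$r.squared
    } else {
      # OU saturation fit on the full curve (saturation level D/A and
      # rate A are only jointly identifiable with the early-time rise,
      # so the OU fit uses all recorded times)
      st <- stats[stats$edge == df$edge[1], ]
      vsat <- mean(df$var_pos)
      slope0 <- stats::coef(stats::lm(
        var_pos ~ time,
        data = st[st$time <= max(0.25 * max(st$time), 4 * min(diff(unique(st$time)))), ]))["time"]
      A0 <- max(slope0 / (2 * vsat), 1e-3)
      fit <- minpack.lm::nlsLM(
        var_pos ~ (D / A) * (1 - exp(-2 * A * time)),
        data = st, start = list(D = max(vsat * A0, 1e-8), A = A0),
        lower = c(0, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      D <- stats::coef(fit)[["D"]]; A <- stats::coef(fit)[["A"]]
      res <- stats::resid(fit)
      r2v <- 1 - sum(res^2) / sum((st$var_pos - mean(st$var_pos))^2)
    }
    tibble::tibble(edge = df$edge[1],
                   speed = unname(stats::coef(fm)["time"]),
                   intercept = unname(stats::coef(fm)["(Intercept)"]),
                   r2_mean = r2m, D = D, A = A, r2_var = r2v)
  }
  dplyr::bind_rows(lapply(split(win, win$edge), fit_edge))
}

#' Pulse-width statistics from threshold-level tracks
#'
#' The stochastic width is the distance between the leading and trailing
#' crossings of the firing threshold, \eqn{D(t) = X_d(t) - Y_d(t)}.
#'
#' @param tracks Track tibble or \code{wave_ensemble}.
#' @param level The level to use (the firing threshold); defaults to the
#'   largest tracked level.
#' @return Tibble with \code{time, mean_width, var_width, n}.
#' @export
width_stats <- function(tracks, level = NULL) {
  if (inherits(tracks, "wave_ensemble")) tracks <- tracks$tracks
  if (is.null(level)) level <- max(tracks$level)
  th <- dplyr::filter(tracks, abs(.data$level - !!level) < 1e-12)
  if (!nrow(th)) stop("requested level was not tracked")
  wide <- tidyr::pivot_wider(th, names_from = "edge",
                             values_from = "position")
  wide$width <- wide$leading - wide$trailing
  dplyr::summarise(
    dplyr::group_by(wide, .data$time),
    mean_width = mean(.data$width, na.rm = TRUE),
    var_width = stats::var(.data$width[is.finite(.data$width)]),
    n = sum(is.finite(.data$width)), .groups = "drop")
}

#' Synthetic Brownian / Ornstein--Uhlenbeck level-set tracks
#'
#' Generates tracks with the exact statistical structure the wandering
#' theory predicts: a per-trial displacement process \eqn{\Delta(t)}
#' (Brownian when \eqn{A = 0}, OU otherwise, diffusivity \eqn{D}) shared
#' by all levels of both edges, drift speed \code{speed}, and fixed
#' per-level geometric offsets.  Used for estimator validation
#' (parameter-recovery tests) and available as a lightweight data
#' generator.
#'
#' @param n_trials Number of trials.
#' @param times Recording instants (uniformly spaced).
#' @param speed Drift speed.
#' @param D Diffusivity.
#' @param A OU restoring rate (0 = Brownian).
#' @param level_offsets Named list with numeric offsets per edge (one
#'   entry per synthetic level).
#' @param delta0 Initial displacement \eqn{\Delta(0)}.
#' @param seed RNG seed.
#' @return Track tibble compatible with \code{\link{ensemble_stats}}.
#' @export
synthetic_tracks <- function(n_trials, times, speed, D, A = 0,
                             level_offsets = list(trailing = c(-0.5, -0.2, 0),
                                                  leading = c(0, 0.2, 0.5)),
                             delta0 = 0, seed = 1) {
  stopifnot(n_trials >= 1, length(times) >= 3, D >= 0, A >= 0)
  set.seed(seed)
  dts <- diff(times)
  rows <- list()
  for (tr in seq_len(n_trials)) {
    delta <- numeric(length(times))
    delta[1] <- delta0
    for (i in seq_along(dts)) {
      h <- dts[i]
      delta[i + 1] <- delta[i] - A * delta[i] * h +
        sqrt(2 * D * h) * stats::rnorm(1)
    }
    for (edge in names(level_offsets)) {
      offs <- level_offsets[[edge]]
      for (l in seq_along(offs)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          time = times, trial = tr, level = l, edge = edge,
          position = speed * times + offs[l] + delta)
      }
    }
  }
  dplyr::bind_rows(rows)
}
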