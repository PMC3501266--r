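#' Moving rectangular stimulus
#'
#' A pulse-like external drive of amplitude \code{I0} on the interval
#' \eqn{[0, \mathrm{width}]} in its own co-moving coordinate, translating
#' rigidly at speed \code{v} (which may be negative; the stationary case
#' \code{v = 0} is outside the scope of the locked-pulse constructions).
#'
#' @param I0 Stimulus amplitude, nonnegative.
#' @param width Stimulus width, positive.
#' @param v Stimulus speed, nonzero for locked-pulse analysis.
#' @return A \code{stimulus_spec} object.
#' @export
stimulus_spec <- function(I0, width, v) {
  stopifnot(I0 >= 0, width > 0, is.numeric(v))
  structure(list(I0 = I0, width = width, v = v), class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> I0 = %g on [0, %g], speed v = %g\n",
              x$I0, x$width, x$v))
  invisible(x)
}

new_locked_pulse <- function(d1, d2, stimulus, kernel, kappa,
                             stability = "unknown") {
  structure(list(d1 = d1, d2 = d2, stimulus = stimulus, kernel = kernel,
                 kappa = kappa, stability = stability),
            class = "locked_pulse")
}

#' @export
print.locked_pulse <- function(x, ...) {
  cat(sprintf(
    "<locked_pulse> crossings d1 = %.6g, d2 = %.6g (width %.6g)\n",
    x$d1, x$d2, x$d2 - x$d1))
  cat(sprintf("  stimulus I0 = %g, width %g, v = %g; kappa = %g; stability: %s\n",
              x$stimulus$I0, x$stimulus$width, x$stimulus$v, x$kappa,
              x$stability))
  invisible(x)
}

#' @export
tidy.locked_pulse <- function(x, ...) {
  tibble::tibble(quantity = c("trailing crossing", "leading crossing",
                              "width", "stimulus speed"),
                 symbol = c("d1", "d2", "d2 - d1", "v"),
                 value = c(x$d1, x$d2, x$d2 - x$d1, x$stimulus$v))
}

#' @export
glance.locked_pulse <- function(x, ...) {
  tibble::tibble(d1 = x$d1, d2 = x$d2, v = x$stimulus$v,
                 I0 = x$stimulus$I0, kappa = x$kappa,
                 stability = x$stability)
}

#' @export
pulse_profile.locked_pulse <- function(p, xi, deriv = FALSE) {
  s <- p$stimulus
  f <- if (deriv)
    .profile_deriv_fun(p$kernel, c(p$d1, p$d2), s$v, stimulus = s)
  else .profile_fun(p$kernel, c(p$d1, p$d2), s$v, stimulus = s)
  f(xi)
}

#' Threshold residuals for a stimulus-locked pulse
#'
#' In the stimulus frame a locked pulse has two unknown crossing points
#' \eqn{d_1 < d_2} with \eqn{U(d_1) = U(d_2) = \kappa}; the profile is the
#' closed-form solution of the co-moving equation at speed \eqn{v} driven
#' by the kernel window over \eqn{(d_1, d_2)} plus the rectangular
#' stimulus.
#'
#' @inheritParams threshold_residuals
#' @param s A \code{\link{stimulus_spec}} with nonzero speed.
#' @param d1,d2 Trial crossing points (\code{d1 < d2}).
#' @return Numeric length-2 residuals.
#' @export
locked_residuals <- function(k, s, kappa, d1, d2) {
  stopifnot(inherits(s, "stimulus_spec"), s$v != 0, d1 < d2)
  U <- .profile_fun(k, c(d1, d2), s$v, stimulus = s)
  c(U(d1) - kappa, U(d2) - kappa)
}

#' Solve for stimulus-locked pulses
#'
#' Finds all \eqn{(d_1, d_2)} roots of the locked threshold conditions by
#' damped-Newton iteration (in \eqn{(d_1, d_2 - d_1)} coordinates) from a
#' multistart family seeded by the free pulse shifted across several
#' widths plus a coarse grid.  Roots whose profile exceeds threshold on
#' more than one interval violate the single-interval ansatz; they are
#' dropped from the solution list and counted in the \code{n_invalid}
#' attribute (that count marks where solutions are lost to multiple
#' superthreshold regions as the stimulus strengthens).
#'
#' @inheritParams locked_residuals
#' @param width_range Search range for the pulse width \eqn{d_2 - d_1}.
#' @param d1_range Search range for the trailing crossing.
#' @param classify Fill in stability via \code{\link{classify_stability}}.
#' @param max_roots Enumeration cap per parameter point.
#' @return List of \code{locked_pulse} objects (possibly empty outside
#'   the locking tongue), with attribute \code{n_invalid}.
#' @examples
#' k <- weight_kernel(5, 1, 0.42, 0.1, x0 = 3)
#' s <- stimulus_spec(I0 = 8, width = 5, v = 3)
#' ps <- solve_locked_pulses(k, s, kappa = 4, classify = FALSE)
#' @export
solve_locked_pulses <- function(k, s, kappa, width_range = c(0.2, 60),
                                d1_range = c(-40, 40), classify = TRUE,
                                max_roots = 8) {
  stopifnot(inherits(s, "stimulus_spec"), s$v != 0)
  resid <- function(x) locked_residuals(k, s, kappa, x[1], x[1] + x[2])
  d1s <- seq(d1_range[1], d1_range[2], length.out = 12)
  ws <- exp(seq(log(width_range[1]), log(width_range[2]), length.out = 8))
  starts <- as.matrix(expand.grid(d1s, ws))
  roots <- .newton2_multi(resid, starts,
                          lower = c(d1_range[1] - 20, width_range[1] / 4))
  roots <- Filter(function(x) x[1] >= d1_range[1] && x[1] <= d1_range[2] &&
                    x[2] >= width_range[1] && x[2] <= width_range[2], roots)
  pulses <- list(); n_invalid <- 0L
  for (x in roots) {
    d1 <- x[1]; d2 <- x[1] + x[2]
    U <- .profile_fun(k, c(d1, d2), s$v, stimulus = s)
    if (.single_interval_ok(U, c(d1, d2), kappa)) {
      pulses[[length(pulses) + 1L]] <-
        new_locked_pulse(d1, d2, s, k, kappa)
    } else {
      n_invalid <- n_invalid + 1L
    }
    if (length(pulses) >= max_roots) break
  }
  if (length(pulses) > 1L)
    pulses <- pulses[order(vapply(pulses, `[[`, numeric(1), "d1"))]
  if (classify && length(pulses))
    pulses <- lapply(pulses, function(p) {
      p$stability <- tryCatch(classify_stability(p)$verdict,
                              error = function(e) "unknown")
      p
    })
  attr(pulses, "n_invalid") <- n_invalid
  pulses
}

#' Locking-tongue stability diagram
#'
#' Scans a grid of stimulus speeds and amplitudes, solving for locked
#' pulses and classifying each, to chart where the pulse entrains to the
#' stimulus: a tongue of stable/unstable pairs opens from the free pulse
#' speed at vanishing amplitude, a second all-unstable tongue from the
#' unstable free branch, regions where tongues overlap carry all
#' solutions, and at strong drive solutions disappear through the
#' development of multiple superthreshold regions (tracked by
#' \code{n_invalid}).
#'
#' @inheritParams solve_locked_pulses
#' @param s_width Stimulus width used for every cell.
#' @param v_grid,I0_grid Grids of stimulus speed (nonzero) and amplitude.
#' @return A tibble with one row per \code{(v, I0)} cell: counts
#'   \code{n_stable}, \code{n_unstable}, \code{n_unknown},
#'   \code{n_invalid}, and \code{status} ("ok" or the error message for
#'   cells whose solve failed).
#' @export
locking_tongues <- function(k, kappa, s_width, v_grid, I0_grid, ...) {
  stopifnot(all(v_grid != 0))
  grid <- expand.grid(v = v_grid, I0 = I0_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$v[i]; I0 <- grid$I0[i]
    out <- tryCatch({
      ps <- solve_locked_pulses(k, stimulus_spec(I0, s_width, v), kappa,
                                ...)
      st <- vapply(ps, `[[`, character(1), "stability")
      tibble::tibble(v = v, I0 = I0,
                     n_stable = sum(st == "stable"),
                     n_unstable = sum(st == "unstable"),
                     n_unknown = sum(st == "unknown"),
                     n_invalid = attr(ps, "n_invalid"),
                     status = "ok")
    }, error = function(e)
      tibble::tibble(v = v, I0 = I0, n_stable = NA_integer_,
                     n_unstable = NA_integer_, n_unknown = NA_integer_,
                     n_invalid = NA_integer_,
                     status = conditionMessage(e)))
    out
  })
  dplyr::bind_rows(rows)
}
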