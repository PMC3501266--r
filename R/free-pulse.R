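#' Firing-rate rule
#'
#' The pointwise nonlinearity turning activity into firing rate: either the
#' sigmoid \eqn{F(u) = 1/(1 + e^{-\gamma(u-\kappa)})} or its high-gain
#' (Heaviside) limit \eqn{F(u) = H(u - \kappa)}.  All analytic
#' constructions in the package (pulse existence, Evans function,
#' wandering theory) require the Heaviside rule; the sigmoid is supported
#' by the Langevin simulator only.
#'
#' @param kind "heaviside" or "sigmoid".
#' @param kappa Firing threshold, positive.
#' @param gamma Sigmoid gain (ignored for the Heaviside rule).
#' @return A \code{firing_rule} object.
#' @export
firing_rule <- function(kind = c("heaviside", "sigmoid"), kappa,
                        gamma = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(kappa), kappa > 0)
  if (kind == "sigmoid") {
    stopifnot(is.numeric(gamma), gamma > 0)
  }
  structure(list(kind = kind, kappa = kappa, gamma = gamma),
            class = "firing_rule")
}

.firing_eval <- function(f, u) {
  if (f$kind == "heaviside") as.numeric(u > f$kappa)
  else 1 / (1 + exp(-f$gamma * (u - f$kappa)))
}

# ---- generic profile machinery ----------------------------------------
#
# Every deterministic pulse profile in this model is
#   U(xi) = e^{G xi}/speed * int_xi^{z0} (W + I)(y) e^{-G y} dy
# with W the kernel window integral over the superthreshold interval,
# I an optional rectangular stimulus, G the decay rate (1/c for a free
# pulse, (1 - eps C0 g0^2)/c_eps with noise, 1/v or its noise-modified
# analogue when locked) and z0 = +Inf for rightward speed, -Inf leftward.

.stim_pwexp <- function(I0, width) {
  new_pwexp(c(0, width), list(pw_empty(), pw_term(I0, 0), pw_empty()))
}

.drive_pwexp <- function(k, window, stimulus = NULL) {
  drive <- .window_pwexp(k, window[1], window[2])
  if (!is.null(stimulus) && stimulus$I0 > 0)
    drive <- pwexp_add(drive, .stim_pwexp(stimulus$I0, stimulus$width))
  drive
}

.profile_fun <- function(k, window, speed, gamma = 1 / speed,
                         stimulus = NULL) {
  drive <- .drive_pwexp(k, window, stimulus)
  if (speed > 0) {
    function(xi) exp(gamma * xi) / speed * Re(pwexp_tail_at(drive, gamma, xi))
  } else {
    function(xi) -exp(gamma * xi) / speed * Re(pwexp_head_at(drive, gamma, xi))
  }
}

# U' = gamma U - drive/speed (the profile ODE rearranged)
.profile_deriv_fun <- function(k, window, speed, gamma = 1 / speed,
                               stimulus = NULL) {
  U <- .profile_fun(k, window, speed, gamma, stimulus)
  drive <- .drive_pwexp(k, window, stimulus)
  function(xi) gamma * U(xi) - pwexp_eval(drive, xi) / speed
}

# profile as an exact pwexp (positive speed only); used by the closed-form
# wandering-theory integrals
.profile_pwexp <- function(k, window, speed, gamma = 1 / speed,
                           stimulus = NULL) {
  stopifnot(speed > 0)
  drive <- .drive_pwexp(k, window, stimulus)
  pwexp_scale(pwexp_mul_exp(pwexp_tail_fn(drive, gamma), gamma), 1 / speed)
}

# ---- damped-Newton multistart solver -----------------------------------

# resid: function(x) -> length-2 residual; starts: matrix of start points;
# lower: componentwise lower bounds.  Returns deduplicated converged roots.
.newton2_multi <- function(resid, starts, lower, tol = 1e-10,
                           dedupe = 1e-6, max_iter = 80) {
  one <- function(x) {
    for (it in seq_len(max_iter)) {
      r <- tryCatch(resid(x), error = function(e) NULL)
      if (is.null(r) || !all(is.finite(r))) return(NULL)
      if (sqrt(sum(r^2)) < tol) return(x)
      h <- 1e-7 * pmax(abs(x), 1)
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        xp <- x; xp[j] <- xp[j] + h[j]
        rp <- tryCatch(resid(xp), error = function(e) NULL)
        if (is.null(rp) || !all(is.finite(rp))) return(NULL)
        J[, j] <- (rp - r) / h[j]
      }
      # SVD-based step with truncation: handles the rank-deficient
      # Jacobian that arises from translation invariance at zero stimulus
      # amplitude by taking the minimum-norm least-squares step.
      sv <- svd(J)
      if (max(sv$d) == 0) return(NULL)
      dinv <- ifelse(sv$d > 1e-9 * max(sv$d), 1 / sv$d, 0)
      step <- as.vector(sv$v %*% (dinv * crossprod(sv$u, r)))
      lam <- 1
      ok <- FALSE
      while (lam > 1e-8) {
        xn <- x - lam * step
        if (all(xn > lower)) {
          rn <- tryCatch(resid(xn), error = function(e) NULL)
          if (!is.null(rn) && all(is.finite(rn)) &&
              sum(rn^2) < sum(r^2)) { ok <- TRUE; break }
        }
        lam <- lam / 2
      }
      if (!ok) return(NULL)
      x <- xn
    }
    r <- tryCatch(resid(x), error = function(e) NULL)
    if (!is.null(r) && all(is.finite(r)) && sqrt(sum(r^2)) < tol) x else NULL
  }
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    x <- one(unname(as.numeric(starts[i, ])))
    if (is.null(x)) next
    if (!any(vapply(roots, function(z) max(abs(z - x)) < dedupe, logical(1))))
      roots[[length(roots) + 1L]] <- x
  }
  roots
}

# single-superthreshold-interval validity check on a dense grid
.single_interval_ok <- function(U, crossings, kappa, pad = 40,
                                n_grid = 4000, slack = 1e-7) {
  lo <- crossings[1]; hi <- crossings[2]
  xg <- seq(lo - pad, hi + pad, length.out = n_grid)
  u <- U(xg)
  inside <- xg > lo + slack & xg < hi - slack
  outside <- xg < lo - slack | xg > hi + slack
  all(u[inside] > kappa - slack) && all(u[outside] < kappa + slack)
}

# ---- free pulses -------------------------------------------------------

new_free_pulse <- function(c, d, kernel, kappa, stability = "unknown") {
  structure(list(c = c, d = d, kernel = kernel, kappa = kappa,
                 stability = stability),
            class = "free_pulse")
}

#' @export
print.free_pulse <- function(x, ...) {
  cat(sprintf("<free_pulse> c = %.6g, d = %.6g (kappa = %g, stability: %s)\n",
              x$c, x$d, x$kappa, x$stability))
  invisible(x)
}

#' Threshold-condition residuals for a free pulse
#'
#' A rightward traveling pulse with speed \eqn{c} and width \eqn{d} must
#' satisfy the two threshold conditions \eqn{U(0) = \kappa} and
#' \eqn{U(d) = \kappa}.  This evaluates \eqn{(U(0) - \kappa,
#' U(d) - \kappa)} from the closed-form profile; the transcendental system
#' is solved numerically by \code{\link{solve_free_pulses}}.
#'
#' @inheritParams weight
#' @param kappa Firing threshold.
#' @param c Trial wave speed (> 0).
#' @param d Trial pulse width (> 0).
#' @return Numeric length-2 residual vector.
#' @export
threshold_residuals <- function(k, kappa, c, d) {
  stopifnot(c > 0, d > 0)
  U <- .profile_fun(k, c(0, d), c)
  c(U(0) - kappa, U(d) - kappa)
}

#' Solve for freely propagating pulses
#'
#' Finds all isolated \eqn{(c, d)} roots of the threshold conditions
#' within a search box, by damped-Newton iteration from a log-spaced
#' multistart grid.  Each converged root is validated against the ansatz
#' behind the construction (the profile must exceed threshold on exactly
#' one interval); invalid roots are discarded.  Duplicates within
#' \code{1e-6} are merged.
#'
#' @inheritParams threshold_residuals
#' @param c_range,d_range Search ranges for speed and width.
#' @param n_starts Multistart grid resolution per axis.
#' @param classify If \code{TRUE}, fill in linear stability of each pulse
#'   via the Evans function (see \code{\link{classify_stability}}).
#' @return A list of \code{free_pulse} objects ordered by speed (possibly
#'   empty when the threshold exceeds the saddle-node value).
#' @examples
#' k <- weight_kernel(5, 1, 0.42, 0.1, x0 = 3)
#' ps <- solve_free_pulses(k, kappa = 4, classify = FALSE)
#' vapply(ps, `[[`, numeric(1), "c")
#' @export
solve_free_pulses <- function(k, kappa, c_range = c(0.05, 20),
                              d_range = c(0.1, 50), n_starts = 8,
                              classify = TRUE) {
  stopifnot(all(c_range > 0), all(d_range > 0))
  resid <- function(x) threshold_residuals(k, kappa, x[1], x[2])
  starts <- as.matrix(expand.grid(
    exp(seq(log(c_range[1]), log(c_range[2]), length.out = n_starts)),
    exp(seq(log(d_range[1]), log(d_range[2]), length.out = n_starts))))
  roots <- .newton2_multi(resid, starts, lower = c(c_range[1] / 2,
                                                   d_range[1] / 2))
  roots <- Filter(function(x) x[1] >= c_range[1] && x[1] <= c_range[2] &&
                    x[2] >= d_range[1] && x[2] <= d_range[2], roots)
  pulses <- list()
  for (x in roots) {
    U <- .profile_fun(k, c(0, x[2]), x[1])
    if (.single_interval_ok(U, c(0, x[2]), kappa))
      pulses[[length(pulses) + 1L]] <- new_free_pulse(x[1], x[2], k, kappa)
  }
  if (length(pulses) > 1L)
    pulses <- pulses[order(vapply(pulses, `[[`, numeric(1), "c"))]
  if (classify && length(pulses))
    pulses <- lapply(pulses, function(p) {
      p$stability <- classify_stability(p)$verdict
      p
    })
  pulses
}

#' Evaluate a traveling-pulse profile
#'
#' Closed-form evaluation of the wave profile \eqn{U(\xi)} in the
#' co-moving frame, with threshold crossings at \eqn{\xi = 0} and
#' \eqn{\xi = d} (free pulses) or \eqn{d_1, d_2} (locked pulses).
#'
#' @param p A \code{free_pulse}, \code{locked_pulse} or
#'   \code{effective_pulse}.
#' @param xi Positions in the co-moving frame (vectorized).
#' @param deriv If \code{TRUE} return \eqn{U'(\xi)} instead.
#' @return Activity values.
#' @export
pulse_profile <- function(p, xi, deriv = FALSE) UseMethod("pulse_profile")

#' @export
pulse_profile.free_pulse <- function(p, xi, deriv = FALSE) {
  f <- if (deriv) .profile_deriv_fun(p$kernel, c(0, p$d), p$c)
       else .profile_fun(p$kernel, c(0, p$d), p$c)
  f(xi)
}

#' Trace free-pulse branches across a threshold grid
#'
#' Re-solves the threshold conditions along a monotone grid of thresholds,
#' warm-starting each solve from the roots at the previous threshold (plus
#' a coarse multistart to catch branches the continuation misses).  Branch
#' termination (the saddle-node where both branches meet) is recorded as
#' an absence of rows rather than an error.
#'
#' @inheritParams solve_free_pulses
#' @param kappa_grid Monotone vector of thresholds.
#' @param classify Classify stability of every point (slower; default
#'   TRUE).
#' @return A tibble with columns \code{kappa}, \code{c}, \code{d},
#'   \code{stability}.
#' @export
branch_scan <- function(k, kappa_grid, c_range = c(0.05, 20),
                        d_range = c(0.1, 50), classify = TRUE) {
  if (!length(kappa_grid))
    return(tibble::tibble(kappa = numeric(0), c = numeric(0),
                          d = numeric(0), stability = character(0)))
  stopifnot(!is.unsorted(kappa_grid) || !is.unsorted(rev(kappa_grid)))
  prev <- NULL
  rows <- list()
  for (kap in kappa_grid) {
    resid <- function(x) threshold_residuals(k, kap, x[1], x[2])
    starts <- as.matrix(expand.grid(
      exp(seq(log(c_range[1]), log(c_range[2]), length.out = 6)),
      exp(seq(log(d_range[1]), log(d_range[2]), length.out = 6))))
    if (!is.null(prev) && length(prev)) {
      starts <- rbind(do.call(rbind, prev), starts)
    }
    roots <- .newton2_multi(resid, starts,
                            lower = c(c_range[1] / 2, d_range[1] / 2))
    roots <- Filter(function(x) {
      U <- .profile_fun(k, c(0, x[2]), x[1])
      .single_interval_ok(U, c(0, x[2]), kap)
    }, roots)
    prev <- roots
    for (x in roots) {
      stab <- "unknown"
      if (classify) {
        p <- new_free_pulse(x[1], x[2], k, kap)
        stab <- classify_stability(p)$verdict
      }
      rows[[length(rows) + 1L]] <-
        tibble::tibble(kappa = kap, c = x[1], d = x[2], stability = stab)
    }
  }
  if (!length(rows))
    return(tibble::tibble(kappa = numeric(0), c = numeric(0),
                          d = numeric(0), stability = character(0)))
  dplyr::arrange(dplyr::bind_rows(rows), .data$kappa, .data$c)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.free_pulse <- function(x, ...) {
  tibble::tibble(quantity = c("speed", "width", "threshold"),
                 symbol = c("c", "d", "kappa"),
                 value = c(x$c, x$d, x$kappa))
}

#' @export
glance.free_pulse <- function(x, ...) {
  tibble::tibble(c = x$c, d = x$d, kappa = x$kappa,
                 stability = x$stability)
}
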