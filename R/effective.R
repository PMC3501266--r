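# Noise-modified mean pulse.
#
# Stratonovich multiplicative noise shifts the deterministic profile the
# stochastic wave fluctuates about: the Novikov correction adds
# eps*C(0)*g'(U)g(U) to the drift, which for linear g(U) = g0*U rescales
# the decay rate to Gamma(eps) = (1 - eps*C(0)*g0^2)/c_eps.  The modified
# threshold conditions are solved with the same machinery as the
# deterministic pulses, with Gamma in place of 1/c.

new_effective_pulse <- function(type, kernel, kappa, noise, C0, a,
                                c_eps = NULL, width = NULL,
                                d1 = NULL, d2 = NULL, stimulus = NULL) {
  speed <- if (type == "free") c_eps else stimulus$v
  structure(list(type = type, kernel = kernel, kappa = kappa,
                 noise = noise, C0 = C0, a = a,
                 c_eps = c_eps, width = width, d1 = d1, d2 = d2,
                 stimulus = stimulus, speed = speed,
                 Gamma = (1 - a) / speed),
            class = "effective_pulse")
}

#' @export
print.effective_pulse <- function(x, ...) {
  if (x$type == "free")
    cat(sprintf(
      "<effective_pulse> free: c_eps = %.6g, width = %.6g, Gamma = %.6g\n",
      x$c_eps, x$width, x$Gamma))
  else
    cat(sprintf(
      "<effective_pulse> locked: d1 = %.6g, d2 = %.6g (v = %g), Gamma = %.6g\n",
      x$d1, x$d2, x$stimulus$v, x$Gamma))
  cat(sprintf("  eps = %g, C0 = %g, g0 = %g (%s noise), kappa = %g\n",
              x$noise$eps, x$C0, x$noise$g0, x$noise$form, x$kappa))
  invisible(x)
}

.ep_window <- function(p) {
  if (p$type == "free") c(0, p$width) else c(p$d1, p$d2)
}

#' @export
pulse_profile.effective_pulse <- function(p, xi, deriv = FALSE) {
  f <- if (deriv)
    .profile_deriv_fun(p$kernel, .ep_window(p), p$speed, gamma = p$Gamma,
                       stimulus = p$stimulus)
  else .profile_fun(p$kernel, .ep_window(p), p$speed, gamma = p$Gamma,
                    stimulus = p$stimulus)
  f(xi)
}

#' Noise-modified mean pulse
#'
#' Solves the noise-modified threshold conditions for the profile
#' \eqn{U_0} the stochastic wave wanders about.  For a free pulse the
#' unknowns are the modified speed \eqn{c_\epsilon} and width; with a
#' stimulus the speed is locked to \eqn{v} and the unknowns are the two
#' crossing points.  The decay constant obeys \eqn{\Gamma(\epsilon) =
#' (1 - \epsilon C(0) g_0^2)/c_\epsilon} (linear noise \eqn{g(U) = g_0 U};
#' additive noise leaves the profile unmodified).  Requires
#' \eqn{\epsilon C(0) g_0^2 < 1}.
#'
#' @inheritParams threshold_residuals
#' @param noise A \code{\link{noise_model}} with explicit \code{C0}.
#' @param stimulus Optional \code{\link{stimulus_spec}} (positive speed)
#'   for the locked case.
#' @param base Optional deterministic pulse used as the continuation
#'   seed; defaults to the stable deterministic solution.
#' @return An \code{effective_pulse}.
#' @examples
#' k <- weight_kernel(5, 1, 0.42, 0.1, x0 = 3)
#' nm <- noise_model(eps = 0.005, g0 = 1, C0 = 10)
#' effective_pulse(k, kappa = 4, noise = nm)
#' @export
effective_pulse <- function(k, kappa, noise, stimulus = NULL, base = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(noise$C0))
    stop("effective_pulse requires an explicit C0 in the noise model")
  C0 <- noise$C0
  a <- if (noise$form == "linear") noise$eps * C0 * noise$g0^2 else 0
  if (a >= 1)
    stop("noise too strong: eps * C0 * g0^2 must be < 1")
  if (is.null(stimulus)) {
    if (is.null(base)) {
      cand <- solve_free_pulses(k, kappa, classify = TRUE)
      cand <- Filter(function(p) p$stability == "stable", cand)
      if (!length(cand)) stop("no stable free pulse to continue from")
      base <- cand[[1]]
    }
    resid <- function(x) {
      U <- .profile_fun(k, c(0, x[2]), x[1], gamma = (1 - a) / x[1])
      c(U(0) - kappa, U(x[2]) - kappa)
    }
    roots <- .newton2_multi(resid, rbind(c(base$c, base$d)),
                            lower = c(1e-3, 1e-3))
    if (!length(roots)) stop("noise-modified threshold conditions have no solution")
    x <- roots[[1]]
    new_effective_pulse("free", k, kappa, noise, C0, a,
                        c_eps = x[1], width = x[2])
  } else {
    stopifnot(inherits(stimulus, "stimulus_spec"))
    if (stimulus$v <= 0)
      stop("locked effective pulse implemented for positive stimulus speed")
    if (is.null(base)) {
      cand <- solve_locked_pulses(k, stimulus, kappa, classify = TRUE)
      cand <- Filter(function(p) p$stability == "stable", cand)
      if (!length(cand)) stop("no stable locked pulse to continue from")
      base <- cand[[1]]
    }
    gv <- (1 - a) / stimulus$v
    resid <- function(x) {
      U <- .profile_fun(k, c(x[1], x[1] + x[2]), stimulus$v, gamma = gv,
                        stimulus = stimulus)
      c(U(x[1]) - kappa, U(x[1] + x[2]) - kappa)
    }
    roots <- .newton2_multi(resid, rbind(c(base$d1, base$d2 - base$d1)),
                            lower = c(-Inf, 1e-3))
    if (!length(roots)) stop("noise-modified threshold conditions have no solution")
    x <- roots[[1]]
    new_effective_pulse("locked", k, kappa, noise, C0, a,
                        d1 = x[1], d2 = x[1] + x[2], stimulus = stimulus)
  }
}

#' @export
tidy.effective_pulse <- function(x, ...) {
  if (x$type == "free")
    tibble::tibble(quantity = c("modified speed", "modified width",
                                "decay constant", "noise strength"),
                   symbol = c("c_eps", "Delta", "Gamma", "eps"),
                   value = c(x$c_eps, x$width, x$Gamma, x$noise$eps))
  else
    tibble::tibble(quantity = c("trailing crossing", "leading crossing",
                                "decay constant", "noise strength"),
                   symbol = c("d1", "d2", "Gamma", "eps"),
                   value = c(x$d1, x$d2, x$Gamma, x$noise$eps))
}

#' @export
glance.effective_pulse <- function(x, ...) {
  tibble::tibble(type = x$type, speed = x$speed,
                 width = diff(.ep_window(x)), Gamma = x$Gamma,
                 eps = x$noise$eps, C0 = x$C0, g0 = x$noise$g0)
}
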