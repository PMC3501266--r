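#' Asymmetric Mexican-hat connectivity kernel
#'
#' Constructs the offset difference-of-exponentials weight distribution
#' \deqn{w(x) = a_e e^{-\sigma_e |x - x_0|} - a_i e^{-\sigma_i |x - x_0|},}
#' the connectivity of a 1D neural field with local excitation and broad
#' inhibition whose peak is shifted by \code{x0}.  The shift breaks
#' reflection symmetry and is what allows the field to support freely
#' propagating pulses (in the direction of the offset) instead of
#' stationary bumps.
#'
#' @param a_e Excitatory amplitude; must exceed \code{a_i}.
#' @param a_i Inhibitory amplitude, positive.
#' @param sigma_e Excitatory inverse length scale; must exceed
#'   \code{sigma_i} so the kernel is locally excitatory with inhibitory
#'   flanks.
#' @param sigma_i Inhibitory inverse length scale, positive.
#' @param x0 Offset of the kernel peak from the origin.
#'
#' @return An object of class \code{weight_kernel}.
#' @examples
#' k <- weight_kernel(a_e = 5, a_i = 1, sigma_e = 0.42, sigma_i = 0.1, x0 = 3)
#' weight(k, c(0, 3, 10))
#' @export
weight_kernel <- function(a_e, a_i, sigma_e, sigma_i, x0 = 0) {
  stopifnot(is.numeric(a_e), is.numeric(a_i), is.numeric(sigma_e),
            is.numeric(sigma_i), is.numeric(x0))
  if (!(a_e > a_i && a_i > 0))
    stop("require a_e > a_i > 0 (Mexican-hat amplitude ordering)")
  if (!(sigma_e > sigma_i && sigma_i > 0))
    stop("require sigma_e > sigma_i > 0 (excitation narrower than inhibition)")
  k <- structure(list(a_e = a_e, a_i = a_i, sigma_e = sigma_e,
                      sigma_i = sigma_i, x0 = x0),
                 class = "weight_kernel")
  k$pw <- .kernel_pwexp(k)
  k$cum <- .kernel_cum(k)    # P(x) = int_{-Inf}^x w, as a pwexp
  k
}

#' @export
print.weight_kernel <- function(x, ...) {
  cat("<weight_kernel> w(x) = a_e exp(-sigma_e|x-x0|) - a_i exp(-sigma_i|x-x0|)\n")
  cat(sprintf("  a_e = %g, a_i = %g, sigma_e = %g, sigma_i = %g, x0 = %g\n",
              x$a_e, x$a_i, x$sigma_e, x$sigma_i, x$x0))
  cat(sprintf("  peak value w(x0) = %g, total mass = %g\n",
              x$a_e - x$a_i, kernel_mass(x)))
  invisible(x)
}

# piecewise-exponential form of w, with the break at x0
.kernel_pwexp <- function(k) {
  left <- pw_term(c(k$a_e * exp(-k$sigma_e * k$x0),
                    -k$a_i * exp(-k$sigma_i * k$x0)),
                  c(k$sigma_e, k$sigma_i))
  right <- pw_term(c(k$a_e * exp(k$sigma_e * k$x0),
                     -k$a_i * exp(k$sigma_i * k$x0)),
                   c(-k$sigma_e, -k$sigma_i))
  new_pwexp(k$x0, list(left, right))
}

# cumulative kernel P(x) = int_{-Inf}^x w(y) dy
.kernel_cum <- function(k) {
  half <- k$a_e / k$sigma_e - k$a_i / k$sigma_i
  left <- pw_term(c(k$a_e / k$sigma_e * exp(-k$sigma_e * k$x0),
                    -k$a_i / k$sigma_i * exp(-k$sigma_i * k$x0)),
                  c(k$sigma_e, k$sigma_i))
  right <- rbind(pw_term(2 * half, 0),
                 pw_term(c(-k$a_e / k$sigma_e * exp(k$sigma_e * k$x0),
                           k$a_i / k$sigma_i * exp(k$sigma_i * k$x0)),
                         c(-k$sigma_e, -k$sigma_i)))
  new_pwexp(k$x0, list(left, right))
}

#' Evaluate the connectivity kernel
#'
#' @param k A \code{\link{weight_kernel}}.
#' @param x Positions (vectorized).
#' @return Synaptic weight values \code{w(x)}.
#' @export
weight <- function(k, x) {
  stopifnot(inherits(k, "weight_kernel"), all(is.finite(x)))
  k$a_e * exp(-k$sigma_e * abs(x - k$x0)) -
    k$a_i * exp(-k$sigma_i * abs(x - k$x0))
}

#' Total synaptic mass of the kernel
#'
#' \eqn{\int w = 2(a_e/\sigma_e - a_i/\sigma_i)}.
#' @inheritParams weight
#' @export
kernel_mass <- function(k) 2 * (k$a_e / k$sigma_e - k$a_i / k$sigma_i)

#' Window integral of the kernel
#'
#' Computes \eqn{W(\xi) = \int_{\xi - s_2}^{\xi - s_1} w(x)\,dx}, the
#' synaptic drive at \eqn{\xi} from a superthreshold interval whose
#' crossing points sit at shifts \eqn{(s_1, s_2)} behind \eqn{\xi}.  For a
#' free pulse the window is \eqn{(0, d)}; for a stimulus-locked pulse it is
#' \eqn{(d_1, d_2)}.  Evaluated in closed form from the cumulative kernel,
#' which handles all three branch cases (window entirely right of the
#' kernel peak, straddling it, or entirely left) automatically.
#'
#' @inheritParams weight
#' @param xi Positions (vectorized).
#' @param lower_shift,upper_shift The window shifts \eqn{s_1 < s_2}.
#' @return Values of \eqn{W(\xi)}.
#' @export
window_integral <- function(k, xi, lower_shift, upper_shift) {
  stopifnot(inherits(k, "weight_kernel"), lower_shift <= upper_shift)
  pwexp_eval(k$cum, xi - lower_shift) - pwexp_eval(k$cum, xi - upper_shift)
}

# window drive W as a pwexp in xi (breaks at x0 + s1, x0 + s2)
.window_pwexp <- function(k, lower_shift, upper_shift) {
  pwexp_sub(pwexp_shift(k$cum, lower_shift),
            pwexp_shift(k$cum, upper_shift))
}

#' Exponentially weighted window integrals (pulse building blocks)
#'
#' The piecewise closed form of a pulse profile is assembled from integrals
#' of the branch window functions \eqn{W_n} against an exponential weight:
#' forward blocks \eqn{M_n(\xi) = \int_\xi^{\xi_n} W_n(\xi') e^{-\xi'/c}
#' d\xi'} (used when the wave speed is positive) and backward blocks
#' \eqn{N_n(\xi) = \int_{\xi_n}^{\xi} W_n(\xi') e^{-\xi'/c} d\xi'} (negative
#' speed), with branch-dependent reference points \eqn{\xi_n}.  The decay
#' argument is \eqn{1/c} for the deterministic profile, \eqn{(\lambda+1)/c}
#' in spectral calculations, and the noise-modified rate \eqn{\Gamma(\epsilon)}
#' for stochastic mean profiles.
#'
#' @inheritParams weight
#' @param xi Evaluation positions (vectorized).
#' @param decay Exponential decay rate multiplying \eqn{-\xi'} in the weight.
#' @param branch Which branch window \eqn{W_n} to use (1, 2 or 3).
#' @param window Numeric pair \code{c(s1, s2)} of crossing shifts.
#' @param direction +1 for the forward blocks \eqn{M_n}, -1 for the
#'   backward blocks \eqn{N_n}.
#' @return Values of \eqn{M_n(\xi)} (or \eqn{N_n(\xi)}).
#' @export
exp_weighted_window <- function(k, xi, decay, branch, window,
                                direction = 1) {
  stopifnot(inherits(k, "weight_kernel"), branch %in% 1:3,
            length(window) == 2L, window[1] < window[2])
  s1 <- window[1]; s2 <- window[2]
  wn <- .branch_window(k, branch, s1, s2)
  if (direction > 0) {
    upper <- switch(branch, `1` = Inf, `2` = k$x0 + s2, `3` = k$x0 + s1)
    out <- vapply(xi, function(z) {
      if (z >= upper) -Re(.int_terms(wn, upper, z, decay))
      else Re(.int_terms(wn, z, upper, decay))
    }, numeric(1))
  } else {
    lower <- switch(branch, `1` = k$x0 + s2, `2` = k$x0 + s1, `3` = -Inf)
    out <- vapply(xi, function(z) {
      if (z >= lower) Re(.int_terms(wn, lower, z, decay))
      else -Re(.int_terms(wn, z, lower, decay))
    }, numeric(1))
  }
  out
}

# The branch windows W1, W2, W3 extended over the whole line as single
# closed-form expressions (each is exact on its own region of validity):
# W1 integrates the right tail w1, W3 the left tail w2, W2 straddles x0.
.branch_window <- function(k, branch, s1, s2) {
  # antiderivative terms of w1 (valid x >= x0 region formula, used globally)
  A1 <- pw_term(c(-k$a_e / k$sigma_e * exp(k$sigma_e * k$x0),
                  k$a_i / k$sigma_i * exp(k$sigma_i * k$x0)),
                c(-k$sigma_e, -k$sigma_i))
  # antiderivative terms of w2
  A2 <- pw_term(c(k$a_e / k$sigma_e * exp(-k$sigma_e * k$x0),
                  -k$a_i / k$sigma_i * exp(-k$sigma_i * k$x0)),
                c(k$sigma_e, k$sigma_i))
  shift_terms <- function(p, s) pw_term(p[, "coef"] * exp(-p[, "rate"] * s),
                                        p[, "rate"])
  neg <- function(p) pw_term(-p[, "coef"], p[, "rate"])
  at_const <- function(p, x) sum(p[, "coef"] * exp(p[, "rate"] * x))
  terms <- switch(as.character(branch),
    "1" = rbind(shift_terms(A1, s1), neg(shift_terms(A1, s2))),
    "3" = rbind(shift_terms(A2, s1), neg(shift_terms(A2, s2))),
    "2" = rbind(shift_terms(A1, s1),
                neg(shift_terms(A2, s2)),
                pw_term(at_const(A2, k$x0) - at_const(A1, k$x0), 0)))
  terms
}

#' Convolution of the kernel with the half-line spectral factor
#'
#' Evaluates \eqn{(w \star P_\lambda)(\xi)} where \eqn{P_\lambda(\xi) =
#' H(-\mathrm{sgn}(v)\xi) e^{(\lambda+1)\xi/v}}, the building block of the
#' Evans function for a pulse traveling at speed \eqn{v}.  For positive
#' speed this is \eqn{\int_\xi^\infty w(y) e^{(\lambda+1)(\xi-y)/v} dy};
#' for negative speed the mirrored half-line integral.  Requires
#' \eqn{\mathrm{Re}(\lambda) > -1} (right of the essential spectrum) so the
#' improper integral converges.
#'
#' @inheritParams weight
#' @param xi Evaluation positions (vectorized).
#' @param lambda Complex spectral parameter.
#' @param speed Wave speed \eqn{v \neq 0}.
#' @return Complex values of the convolution.
#' @export
convolve_wP <- function(k, xi, lambda, speed) {
  stopifnot(inherits(k, "weight_kernel"), speed != 0)
  lambda <- as.complex(lambda)
  if (Re(lambda) <= -1)
    stop("convolve_wP requires Re(lambda) > -1 (right of the essential spectrum)")
  mu <- (lambda + 1) / speed
  if (speed > 0) {
    exp(mu * xi) * pwexp_tail_at(k$pw, mu, xi)
  } else {
    exp(mu * xi) * pwexp_head_at(k$pw, mu, xi)
  }
}
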