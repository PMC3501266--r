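# Perturbative wandering theory.
#
# On long time-scales weak noise displaces the pulse rigidly by Delta(t);
# projecting the Langevin dynamics onto the translation mode with the
# adjoint null vector V gives pure Brownian wandering for free pulses,
# <Delta(t)^2> = 2 D(eps) t, and an Ornstein--Uhlenbeck process with
# restoring rate A for stimulus-locked pulses, whose variance saturates
# at D(eps)/A.

#' Kernel tail moment b(z)
#'
#' \deqn{b(z) = \frac{1}{c_\epsilon}\int_z^\infty e^{-\Gamma(\xi'-z)}
#'   w(\xi')\, d\xi'}
#' the exponentially discounted forward mass of the kernel seen from
#' \eqn{z}.  The profile derivative satisfies \eqn{U_0'(\xi) = b(\xi) -
#' b(\xi - \Delta)} for free pulses, and \eqn{b} supplies the
#' self-consistency coefficients of the adjoint null vector.
#'
#' @param ep An \code{\link{effective_pulse}}.
#' @param z Positions (vectorized).
#' @return Values of \eqn{b(z)}.
#' @export
b_function <- function(ep, z) {
  stopifnot(inherits(ep, "effective_pulse"))
  if (ep$Gamma <= 0) stop("b_function requires a positive decay constant")
  exp(ep$Gamma * z) / ep$speed *
    Re(pwexp_tail_at(ep$kernel$pw, ep$Gamma, z))
}

#' Adjoint null vector of the linearized wave operator
#'
#' The adjoint linearization about the mean pulse has eigenfunctions of
#' the two-exponential form \eqn{V(\xi) = A H(\xi - \xi_1)
#' e^{-\Gamma_\lambda(\xi-\xi_1)} + B H(\xi - \xi_2)
#' e^{-\Gamma_\lambda(\xi-\xi_2)}} with jumps at the threshold crossings
#' \eqn{(\xi_1, \xi_2)} and decay \eqn{\Gamma_\lambda = (1 - \epsilon
#' C_0 g_0^2 + \lambda)/v}.  Substituting the ansatz yields a 2x2
#' self-consistency system \eqn{M(\lambda)}.
#'
#' For a free pulse translation invariance forces \eqn{\lambda = 0}:
#' \eqn{M(0)} is exactly rank 1 (checked; failure is a hard error) with
#' null direction \eqn{(A, B) = (b(\Delta), -b(-\Delta))}.  A locked
#' pulse has no zero eigenvalue (the determinant of \eqn{M(0)} equals the
#' Evans function at zero, nonzero once the stimulus breaks translation
#' symmetry); the projection vector of the wandering reduction is instead
#' the adjoint eigenfunction at the slow relaxation eigenvalue
#' \eqn{\lambda_s}, the real root of \eqn{\det M(\lambda)} nearest zero.
#' \eqn{M(\lambda_s)} is rank 1 by construction, and with this choice the
#' Ornstein--Uhlenbeck rate formula is exact:
#' \eqn{A = \int V I' / \int V U_0' = -\lambda_s} (because the
#' linearization maps \eqn{U_0'} to \eqn{-I'}).
#'
#' @param ep An \code{\link{effective_pulse}} (free or locked, positive
#'   speed).
#' @param rank_tol Relative determinant tolerance for the rank-1 check at
#'   the selected eigenvalue.
#' @return An \code{adjoint_null} object with fields \code{crossings},
#'   \code{Gamma} (the decay of V), \code{lambda} (0 for free pulses,
#'   \eqn{\lambda_s} for locked), \code{coeffs} (A, B) and
#'   \code{rel_det}; evaluate it with \code{\link{adjoint_null_eval}}.
#' @export
adjoint_null_vector <- function(ep, rank_tol = 1e-8) {
  stopifnot(inherits(ep, "effective_pulse"))
  cr <- .ep_window(ep)
  del <- cr[2] - cr[1]
  dU <- pulse_profile(ep, cr, deriv = TRUE)
  b_lam <- function(z, lam) {
    g <- ep$Gamma + lam / ep$speed
    if (g <= 0) stop("b_function decay must be positive")
    exp(g * z) / ep$speed * Re(pwexp_tail_at(ep$kernel$pw, g, z))
  }
  Mfun <- function(lam) {
    b0 <- b_lam(0, lam); bp <- b_lam(del, lam); bm <- b_lam(-del, lam)
    rbind(c(b0 / abs(dU[1]) - 1, bp / abs(dU[1])),
          c(bm / abs(dU[2]), b0 / abs(dU[2]) - 1))
  }
  lam <- 0
  if (ep$type == "locked") {
    detf <- function(l) det(Mfun(l))
    # scan outward from 0 for the nearest real root of det M(lambda)
    lmin <- -(1 - ep$a) * 0.98
    grid <- sort(unique(c(seq(lmin, 2, by = 0.01))))
    dv <- vapply(grid, detf, numeric(1))
    flips <- which(dv[-1] * dv[-length(dv)] <= 0)
    if (!length(flips))
      stop("no real slow eigenvalue found for the locked adjoint problem")
    cand <- (grid[flips] + grid[flips + 1]) / 2
    lam <- cand[which.min(abs(cand))]
    lam <- stats::uniroot(detf, c(grid[flips[which.min(abs(cand))]],
                                  grid[flips[which.min(abs(cand))] + 1]),
                          tol = 1e-13)$root
  }
  M <- Mfun(lam)
  rel_det <- abs(det(M)) / norm(M, "F")
  if (rel_det > rank_tol)
    stop(sprintf(
      "adjoint self-consistency matrix is not rank 1 (rel det %.3g): invalid pulse context",
      rel_det))
  if (ep$type == "free") {
    co <- c(A = b_function(ep, del), B = -b_function(ep, -del))
  } else {
    sv <- svd(M)
    co <- sv$v[, 2]
    if (abs(co[1]) > 1e-12) co <- co * sign(co[1]) else co <- co * sign(co[2])
    co <- c(A = co[1], B = co[2])
  }
  structure(list(crossings = cr, Gamma = ep$Gamma + lam / ep$speed,
                 lambda = lam, coeffs = co, rel_det = rel_det,
                 speed = ep$speed, type = ep$type),
            class = "adjoint_null")
}

#' @export
print.adjoint_null <- function(x, ...) {
  cat(sprintf(
    "<adjoint_null> V(xi) = %.4g H(xi-%.4g) e^{-%.4g (xi-%.4g)} %+.4g H(xi-%.4g) e^{-%.4g (xi-%.4g)}\n",
    x$coeffs[1], x$crossings[1], x$Gamma, x$crossings[1],
    x$coeffs[2], x$crossings[2], x$Gamma, x$crossings[2]))
  cat(sprintf("  rel. determinant of self-consistency matrix: %.3g\n",
              x$rel_det))
  invisible(x)
}

.adjoint_pwexp <- function(null) {
  g <- null$Gamma; cr <- null$crossings; co <- null$coeffs
  t1 <- pw_term(co[[1]] * exp(g * cr[1]), -g)
  t2 <- pw_term(co[[2]] * exp(g * cr[2]), -g)
  new_pwexp(cr, list(pw_empty(), t1, rbind(t1, t2)))
}

#' Evaluate an adjoint null vector
#'
#' @param null An \code{adjoint_null}.
#' @param xi Positions (vectorized).
#' @return Values of \eqn{V(\xi)} (zero left of the first crossing).
#' @export
adjoint_null_eval <- function(null, xi) {
  stopifnot(inherits(null, "adjoint_null"))
  pwexp_eval(.adjoint_pwexp(null), xi)
}

# exact pwexp of the mean profile (positive speed)
.ep_profile_pwexp <- function(ep) {
  .profile_pwexp(ep$kernel, .ep_window(ep), ep$speed, gamma = ep$Gamma,
                 stimulus = ep$stimulus)
}

#' Effective diffusivity of the wandering pulse
#'
#' \deqn{D(\epsilon) = \epsilon \frac{\int V^2(\xi) g(U_0(\xi))^2 d\xi}
#'   {\left[\int V(\xi) U_0'(\xi) d\xi\right]^2}}
#' evaluated in closed form (the integrands are piecewise exponential).
#' For a locked pulse the Ornstein--Uhlenbeck restoring rate is filled in
#' via \code{\link{ou_rate}}.
#'
#' @param ep An \code{\link{effective_pulse}}.
#' @param null Optional precomputed \code{\link{adjoint_null_vector}}.
#' @return A \code{diffusion_estimate} with fields \code{D}, \code{A}
#'   (0 for free pulses) and \code{eps}.
#' @examples
#' k <- weight_kernel(5, 1, 0.42, 0.1, x0 = 3)
#' nm <- noise_model(eps = 0.005, g0 = 1, C0 = 10)
#' diffusivity(effective_pulse(k, 4, nm))
#' @export
diffusivity <- function(ep, null = NULL) {
  stopifnot(inherits(ep, "effective_pulse"))
  if (is.null(null)) null <- adjoint_null_vector(ep)
  Vp <- .adjoint_pwexp(null)
  U0 <- .ep_profile_pwexp(ep)
  gU <- if (ep$noise$form == "linear")
    pwexp_scale(U0, ep$noise$g0)
  else new_pwexp(numeric(0), list(pw_term(ep$noise$g0, 0)))
  VG <- pwexp_mul(Vp, gU)
  num <- pwexp_integral(pwexp_mul(VG, VG))
  dU0 <- pwexp_deriv(U0)
  den <- pwexp_integral(pwexp_mul(Vp, dU0))
  if (abs(den) < 1e-12 * sqrt(abs(num)))
    stop("projection integral of V against U0' vanishes")
  D <- unname(ep$noise$eps * num / den^2)
  A <- if (ep$type == "locked") ou_rate(ep, null) else 0
  structure(list(D = D, A = A, eps = ep$noise$eps),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D = %.6g, A = %.6g (eps = %g)\n",
              x$D, x$A, x$eps))
  if (x$A > 0)
    cat(sprintf("  OU wandering: variance saturates at D/A = %.6g\n",
                x$D / x$A))
  else cat("  Brownian wandering: variance 2 D t\n")
  invisible(x)
}

#' @export
tidy.diffusion_estimate <- function(x, ...) {
  tibble::tibble(quantity = c("diffusivity", "restoring rate"),
                 symbol = c("D", "A"), value = c(x$D, x$A))
}

#' @export
glance.diffusion_estimate <- function(x, ...) {
  tibble::tibble(D = x$D, A = x$A, eps = x$eps,
                 saturation = if (x$A > 0) x$D / x$A else Inf)
}

#' Ornstein--Uhlenbeck restoring rate of a locked pulse
#'
#' \deqn{A = \frac{\int V(\xi) I'(\xi) d\xi}{\int V(\xi) U_0'(\xi) d\xi}
#'   = \frac{I_0 [V(0) - V(d)]}{\int V U_0'}}
#' using \eqn{I'(\xi) = I_0[\delta(\xi) - \delta(\xi - d)]} for the
#' rectangular stimulus of width \eqn{d}.  Positive \eqn{A} is the
#' restoring force that keeps the stochastic pulse entrained.
#'
#' @param ep A locked \code{\link{effective_pulse}}.
#' @param null Optional precomputed adjoint null vector.
#' @return The rate \eqn{A} (0 when the stimulus amplitude vanishes).
#' @export
ou_rate <- function(ep, null = NULL) {
  stopifnot(inherits(ep, "effective_pulse"), ep$type == "locked")
  s <- ep$stimulus
  if (s$I0 == 0) return(0)
  if (is.null(null)) null <- adjoint_null_vector(ep)
  edge_tol <- 1e-8
  if (any(abs(outer(null$crossings, c(0, s$width), `-`)) < edge_tol))
    stop("degenerate geometry: a crossing coincides with a stimulus edge")
  Vp <- .adjoint_pwexp(null)
  U0 <- .ep_profile_pwexp(ep)
  den <- pwexp_integral(pwexp_mul(Vp, pwexp_deriv(U0)))
  num <- s$I0 * (pwexp_eval(Vp, 0) - pwexp_eval(Vp, s$width))
  unname(num / den)
}

#' Wandering variance curve
#'
#' \eqn{\langle\Delta(t)^2\rangle = 2 D t} for Brownian wandering
#' (\eqn{A = 0}) and \eqn{(D/A)(1 - e^{-2At})} for the locked OU case.
#'
#' @param t Times (vectorized, nonnegative).
#' @param est A \code{diffusion_estimate}, or a numeric \code{D}.
#' @param A Restoring rate when \code{est} is numeric.
#' @return Variance values.
#' @export
variance_curve <- function(t, est, A = 0) {
  stopifnot(all(t >= 0))
  if (inherits(est, "diffusion_estimate")) {
    D <- est$D; A <- est$A
  } else D <- est
  if (A == 0) 2 * D * t else -(D / A) * expm1(-2 * A * t)
}
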