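# Internal piecewise-exponential algebra.
#
# Every analytic object in the package -- the connectivity kernel, its
# window integrals, pulse profiles, adjoint null vectors and the integrands
# of the diffusivity formula -- is a finite sum of terms coef * exp(rate * x)
# on each piece of a partition of the real line.  Representing that family
# explicitly lets all integrals be evaluated in closed form; adaptive
# quadrature appears only as a test oracle.
#
# Representation: list(breaks = sorted finite breakpoints (length m),
# pieces = list of m+1 two-column matrices cbind(coef, rate)).  Piece i
# covers [breaks[i-1], breaks[i]) -- left-closed, so an evaluation at an
# exact breakpoint uses the right-hand piece (value-neutral for the
# continuous functions built here).  Terms with rate 0 are constants.

new_pwexp <- function(breaks, pieces) {
  stopifnot(length(pieces) == length(breaks) + 1L, !is.unsorted(breaks))
  structure(list(breaks = as.numeric(breaks), pieces = pieces),
            class = "pwexp")
}

pw_term <- function(coef, rate) cbind(coef = coef, rate = rate)
pw_empty <- function() cbind(coef = numeric(0), rate = numeric(0))

#' @noRd
pwexp_eval <- function(f, x) {
  idx <- findInterval(x, f$breaks) + 1L
  out <- numeric(length(x))
  for (i in unique(idx)) {
    p <- f$pieces[[i]]
    sel <- idx == i
    if (nrow(p) == 0L) next
    xi <- x[sel]
    out[sel] <- as.vector(exp(outer(xi, p[, "rate"])) %*% p[, "coef"])
  }
  out
}

# ---- closed-form exponential integrals --------------------------------

# int_a^b exp(s*y) dy, stable near s = 0; a may be -Inf and b may be Inf
# (then the sign of Re(s) must make the integral converge).  Works for
# complex s.
.int_exp1 <- function(s, a, b) {
  if (is.infinite(a) && is.infinite(b))
    stop("divergent improper integral (doubly infinite range)", call. = FALSE)
  if (is.infinite(a)) {
    if (Re(s) <= 0) stop("divergent improper integral (Re(rate) <= 0 at -Inf)",
                         call. = FALSE)
    return(exp(s * b) / s)
  }
  if (is.infinite(b)) {
    if (Re(s) >= 0) stop("divergent improper integral (Re(rate) >= 0)",
                         call. = FALSE)
    return(-exp(s * a) / s)
  }
  h <- b - a
  z <- s * h
  if (abs(z) < 1e-8) {
    # series for (exp(z)-1)/z
    exp(s * a) * h * (1 + z / 2 + z * z / 6)
  } else {
    exp(s * a) * (exp(z) - 1) / s
  }
}

# sum over terms of int_a^b coef*exp(rate*y)*exp(-gamma*y) dy
.int_terms <- function(terms, a, b, gamma = 0) {
  if (nrow(terms) == 0L || a >= b) return(0 * gamma)
  tot <- 0 * gamma
  for (j in seq_len(nrow(terms))) {
    s <- terms[j, "rate"] - gamma
    if (abs(s) == 0 && (is.infinite(b) || is.infinite(a))) {
      if (abs(terms[j, "coef"]) == 0) next
      stop("divergent improper integral (zero effective exponent)",
           call. = FALSE)
    }
    tot <- tot + terms[j, "coef"] *
      (if (abs(s) == 0) (b - a) else .int_exp1(s, a, b))
  }
  tot
}

piece_bounds <- function(f, i) {
  m <- length(f$breaks)
  c(if (i == 1L) -Inf else f$breaks[i - 1L],
    if (i == m + 1L) Inf else f$breaks[i])
}

# definite integral int_a^b f(y) exp(-gamma*y) dy (a, b may be infinite)
pwexp_integral <- function(f, a = -Inf, b = Inf, gamma = 0) {
  tot <- 0 * gamma
  for (i in seq_along(f$pieces)) {
    bd <- piece_bounds(f, i)
    lo <- max(a, bd[1]); hi <- min(b, bd[2])
    if (lo < hi) tot <- tot + .int_terms(f$pieces[[i]], lo, hi, gamma)
  }
  tot
}

# T(xi) = int_xi^Inf f(y) exp(-gamma*y) dy, evaluated at each xi.
# gamma may be complex; convergence requires Re(rate - gamma) < 0 on the
# right-infinite piece.
pwexp_tail_at <- function(f, gamma, xi) {
  m <- length(f$pieces)
  # full-piece integrals, then suffix sums
  full <- vapply(seq_len(m), function(i) {
    bd <- piece_bounds(f, i)
    if (is.infinite(bd[1])) return(0 * gamma + 0i)  # handled per-point
    as.complex(.int_terms(f$pieces[[i]], bd[1], bd[2], gamma))
  }, complex(1))
  suffix <- rev(cumsum(rev(c(full[-1], 0 + 0i))))
  idx <- findInterval(xi, f$breaks) + 1L
  out <- complex(length(xi))
  for (k in seq_along(xi)) {
    i <- idx[k]
    bd <- piece_bounds(f, i)
    out[k] <- .int_terms(f$pieces[[i]], xi[k], bd[2], gamma) + suffix[i]
    if (i == 1L && is.infinite(bd[1])) {
      # nothing extra: integral starts at xi anyway
    }
  }
  if (is.complex(gamma)) out else Re(out)
}

# H(xi) = int_{-Inf}^xi f(y) exp(-gamma*y) dy
pwexp_head_at <- function(f, gamma, xi) {
  m <- length(f$pieces)
  full <- vapply(seq_len(m), function(i) {
    bd <- piece_bounds(f, i)
    if (is.infinite(bd[2])) return(0 * gamma + 0i)
    as.complex(.int_terms(f$pieces[[i]], bd[1], bd[2], gamma))
  }, complex(1))
  prefix <- cumsum(c(0 + 0i, full[-m]))
  idx <- findInterval(xi, f$breaks) + 1L
  out <- complex(length(xi))
  for (k in seq_along(xi)) {
    i <- idx[k]
    bd <- piece_bounds(f, i)
    out[k] <- .int_terms(f$pieces[[i]], bd[1], xi[k], gamma) + prefix[i]
  }
  if (is.complex(gamma)) out else Re(out)
}

# ---- symbolic transforms ----------------------------------------------

# T(xi) = int_xi^Inf f(y) exp(-gamma*y) dy as a pwexp in xi (gamma real).
# Requires that no term rate equals gamma (no linear terms arise).
pwexp_tail_fn <- function(f, gamma) {
  m <- length(f$pieces)
  full <- numeric(m)
  for (i in seq_len(m)) {
    bd <- piece_bounds(f, i)
    if (!is.infinite(bd[1]))
      full[i] <- .int_terms(f$pieces[[i]], bd[1], bd[2], gamma)
  }
  suffix <- rev(cumsum(rev(c(full[-1], 0))))
  pieces <- vector("list", m)
  for (i in seq_len(m)) {
    p <- f$pieces[[i]]
    bd <- piece_bounds(f, i)
    terms <- pw_empty()
    const <- suffix[i]
    for (j in seq_len(nrow(p))) {
      s <- p[j, "rate"] - gamma
      if (abs(s) < 1e-13)
        stop("rate collides with decay; linear terms unsupported",
             call. = FALSE)
      # int_xi^{hi} coef e^{s y} dy = coef/s (e^{s hi} - e^{s xi})
      if (is.finite(bd[2])) {
        const <- const + p[j, "coef"] / s * exp(s * bd[2])
      } else if (Re(s) >= 0 && abs(p[j, "coef"]) > 0) {
        stop("divergent improper integral in pwexp_tail_fn", call. = FALSE)
      }
      terms <- rbind(terms, pw_term(-p[j, "coef"] / s, s))
    }
    if (abs(const) > 0) terms <- rbind(terms, pw_term(const, 0))
    pieces[[i]] <- terms
  }
  new_pwexp(f$breaks, pieces)
}

pwexp_shift <- function(f, s) {
  # g(x) = f(x - s)
  pieces <- lapply(f$pieces, function(p) {
    if (nrow(p) == 0L) return(p)
    pw_term(p[, "coef"] * exp(-p[, "rate"] * s), p[, "rate"])
  })
  new_pwexp(f$breaks + s, pieces)
}

pwexp_scale <- function(f, a) {
  new_pwexp(f$breaks, lapply(f$pieces, function(p) {
    if (nrow(p) == 0L) return(p); pw_term(p[, "coef"] * a, p[, "rate"])
  }))
}

pwexp_mul_exp <- function(f, gamma) {
  # g(x) = f(x) * exp(gamma * x)
  new_pwexp(f$breaks, lapply(f$pieces, function(p) {
    if (nrow(p) == 0L) return(p); pw_term(p[, "coef"], p[, "rate"] + gamma)
  }))
}

.piece_at <- function(f, x) f$pieces[[findInterval(x, f$breaks) + 1L]]

.merge_breaks <- function(f, g) sort(unique(c(f$breaks, g$breaks)))

pwexp_add <- function(f, g) {
  br <- .merge_breaks(f, g)
  mids <- .piece_mids(br)
  pieces <- lapply(mids, function(x) {
    rbind(.piece_at(f, x), .piece_at(g, x))
  })
  new_pwexp(br, pieces)
}

pwexp_sub <- function(f, g) pwexp_add(f, pwexp_scale(g, -1))

pwexp_mul <- function(f, g) {
  br <- .merge_breaks(f, g)
  mids <- .piece_mids(br)
  pieces <- lapply(mids, function(x) {
    pf <- .piece_at(f, x); pg <- .piece_at(g, x)
    if (nrow(pf) == 0L || nrow(pg) == 0L) return(pw_empty())
    pw_term(as.vector(outer(pf[, "coef"], pg[, "coef"])),
            as.vector(outer(pf[, "rate"], pg[, "rate"], `+`)))
  })
  new_pwexp(br, pieces)
}

# representative interior points of the partition defined by br
.piece_mids <- function(br) {
  m <- length(br)
  if (m == 0L) return(0)
  lo <- c(br[1] - 1, br)
  hi <- c(br, br[m] + 1)
  (lo + hi) / 2
}

# zero the function outside [lo, hi)
pwexp_mask <- function(f, lo, hi) {
  br <- sort(unique(c(f$breaks, lo, hi)))
  br <- br[is.finite(br)]
  mids <- .piece_mids(br)
  pieces <- lapply(mids, function(x) {
    if (x >= lo && x < hi) .piece_at(f, x) else pw_empty()
  })
  new_pwexp(br, pieces)
}

pwexp_deriv <- function(f) {
  new_pwexp(f$breaks, lapply(f$pieces, function(p) {
    if (nrow(p) == 0L) return(p)
    keep <- p[, "rate"] != 0
    pw_term(p[keep, "coef"] * p[keep, "rate"], p[keep, "rate"])
  }))
}
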