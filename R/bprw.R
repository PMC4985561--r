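#' Biased persistent random walk parameters
#'
#' The BPRW describes each cell step's heading as a two-component mixture:
#' with probability `w` the heading is drawn from a circular kernel centred
#' on the direction toward the attractant (concentration set by the bias
#' `b`), otherwise from a kernel centred on the previous heading
#' (concentration set by the persistence `p`). `b` and `p` are expressed as
#' mean resultant lengths so that both live on the same 0--1 scale: 0 means
#' a uniformly random heading, values approaching 1 a deterministic one.
#'
#' @param b bias strength in `[0, 1)`.
#' @param p persistence strength in `[0, 1)`.
#' @param w probability of a biased step in `[0, 1]`.
#' @return an object of class `bprw_params`.
#' @examples
#' bprw_params(b = 0.6, p = 0.3, w = 0.5)
#' @export
bprw_params <- function(b, p, w) {
  if (!is.numeric(b) || b < 0 || b >= 1) stopf("b must be in [0, 1)")
  if (!is.numeric(p) || p < 0 || p >= 1) stopf("p must be in [0, 1)")
  if (!is.numeric(w) || w < 0 || w > 1) stopf("w must be in [0, 1]")
  structure(list(b = b, p = p, w = w), class = "bprw_params")
}

#' @export
print.bprw_params <- function(x, ...) {
  cat(sprintf("<bprw_params> b = %.3f, p = %.3f, w = %.3f\n", x$b, x$p, x$w))
  invisible(x)
}

# cap below 1: A(kappa) = 1 - 1/(2 kappa) + O(1/kappa^2), so r = 1 - 1e-8
# corresponds to kappa ~ 5e7, still representable with scaled Bessels.
.MRL_CAP <- 1 - 1e-8

#' Map a mean resultant length to a von Mises concentration
#'
#' Solves `A(kappa) = r` where `A(kappa) = I1(kappa) / I0(kappa)` is the
#' ratio of modified Bessel functions of the first kind; this is the mean
#' resultant length of a von Mises distribution with concentration `kappa`.
#' The inverse is computed by a Newton iteration refined to machine
#' precision (well inside the 1e-8 relative tolerance contract), so
#' `kappa_to_mrl(mrl_to_kappa(r))` round-trips.
#'
#' @param r mean resultant length(s) in `[0, 1)`. Values at or above
#'   `1 - 1e-8` are rejected (the concentration diverges).
#' @return concentration `kappa >= 0`, same length as `r`.
#' @examples
#' mrl_to_kappa(0.5)
#' kappa_to_mrl(mrl_to_kappa(0.5))
#' @export
mrl_to_kappa <- function(r) {
  if (any(!is.finite(r)) || any(r < 0)) stopf("r must be finite and >= 0")
  if (any(r >= .MRL_CAP))
    stopf("mean resultant length %g >= 1 - 1e-8: concentration unreachable",
          max(r))
  vapply(r, cpp_mrl_to_kappa, numeric(1))
}

#' @rdname mrl_to_kappa
#' @param kappa von Mises concentration(s), `>= 0`.
#' @export
kappa_to_mrl <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < 0)) stopf("kappa must be >= 0")
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Von Mises density and sampler
#'
#' `dvonmises` evaluates the density (optionally log) of the von Mises
#' distribution; `rvonmises` draws from it by the Best-Fisher
#' wrapped-Cauchy rejection method. `kappa = 0` is the uniform circular
#' distribution.
#'
#' @param theta angles in radians.
#' @param mu mean direction (radians).
#' @param kappa concentration `>= 0`; recycled against `theta`/`n`.
#' @param log logical; return log-density?
#' @return `dvonmises`: densities; `rvonmises`: `n` angles in `(-pi, pi]`.
#' @export
dvonmises <- function(theta, mu = 0, kappa = 1, log = FALSE) {
  logi0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  ld <- kappa * cos(theta - mu) - log(2 * pi) - logi0
  if (log) ld else exp(ld)
}

#' @rdname dvonmises
#' @param n number of draws.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  mu <- rep_len(mu, n)
  kappa <- rep_len(kappa, n)
  out <- numeric(n)
  unif <- kappa < 1e-10
  out[unif] <- runif(sum(unif), -pi, pi)
  todo <- which(!unif)
  if (length(todo)) {
    k <- kappa[todo]
    tau <- 1 + sqrt(1 + 4 * k^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * k)
    rr <- (1 + rho^2) / (2 * rho)
    res <- rep(NA_real_, length(todo))
    need <- seq_along(todo)
    while (length(need)) {
      m <- length(need)
      u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
      z <- cos(pi * u1)
      f <- (1 + rr[need] * z) / (rr[need] + z)
      c0 <- k[need] * (rr[need] - f)
      ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
      ang <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      res[need[ok]] <- ang[ok]
      need <- need[!ok]
    }
    out[todo] <- res
  }
  wrap_angle(out + mu)
}

#' BPRW step log-density
#'
#' Log-density of observing heading `theta` given the previous heading
#' `theta_prev` and the direction toward the attractant `phi_w`, under the
#' mixture `w * VM(phi_w, kappa_b) + (1 - w) * VM(theta_prev, kappa_p)`.
#' The density integrates to 1 over the circle for any parameter values.
#'
#' @param theta observed heading(s), radians in `(-pi, pi]`.
#' @param theta_prev previous heading(s).
#' @param phi_w direction(s) toward the attractant; `NA` means no defined
#'   biased direction (pure persistence for that step).
#' @param params a [bprw_params()]; alternatively `b` may be a vector the
#'   length of `theta` to allow a space-time-varying effective bias.
#' @param b optional per-step bias overriding `params$b`.
#' @return total log-likelihood (sum over steps).
#' @export
bprw_step_loglik <- function(theta, theta_prev, phi_w, params, b = NULL) {
  b <- b %||% rep_len(params$b, length(theta))
  b <- rep_len(b, length(theta))
  has_dir <- !is.na(phi_w)
  beta <- ifelse(has_dir, wrap_angle(theta - phi_w), 0)
  alpha <- wrap_angle(theta - theta_prev)
  cpp_bprw_loglik(beta, alpha, b, params$p, params$w, has_dir)
}

#' Sample one BPRW step heading per cell
#'
#' Draws the latent component (biased with probability `w`) and then the
#' heading from the corresponding von Mises kernel. Steps with `phi_w = NA`
#' (no attractant direction) use the persistence kernel regardless of `w`.
#'
#' @inheritParams bprw_step_loglik
#' @return vector of headings in `(-pi, pi]`, one per element of
#'   `theta_prev`.
#' @export
sample_step <- function(theta_prev, phi_w, params, b = NULL) {
  n <- length(theta_prev)
  b <- rep_len(b %||% params$b, n)
  phi_w <- rep_len(phi_w, n)
  biased <- runif(n) < params$w & !is.na(phi_w)
  kb <- mrl_to_kappa(ifelse(is.na(b), 0, b))
  kp <- mrl_to_kappa(params$p)
  out <- numeric(n)
  if (any(biased))
    out[biased] <- rvonmises(sum(biased), phi_w[biased], kb[biased])
  if (any(!biased))
    out[!biased] <- rvonmises(sum(!biased), theta_prev[!biased], kp)
  out
}
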