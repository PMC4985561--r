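#' Chemotaxis link parameters
#'
#' Maps the local attractant field to each cell's effective directional
#' bias. A cell of sensing length `l_sense` measures the receptor-occupancy
#' difference across its body,
#' `du = l_sense * |grad C| * K_d / (C + K_d)^2`,
#' and its bias is `b_eff = min(b_max, b0 + s * du)` while sensitive, or
#' the baseline `b0` while refractory. The occupancy difference vanishes
#' both in the absence of a gradient and in the receptor-saturated regime
#' `C >> K_d` (the loss of orientation near very large wounds).
#'
#' @param K_d half-saturation concentration, field units (> 0).
#' @param l_sense effective cell sensing length, um (> 0).
#' @param s dimensionless sensitivity scale (>= 0).
#' @param b0 baseline bias in `[0, 1)`.
#' @param b_max ceiling bias in `(b0, 1)`.
#' @return object of class `link_params`.
#' @export
link_params <- function(K_d, l_sense = 10, s = 1, b0 = 0.05, b_max = 0.85) {
  if (!is.numeric(K_d) || K_d <= 0) stopf("K_d must be > 0")
  if (l_sense <= 0) stopf("l_sense must be > 0")
  if (s < 0) stopf("s must be >= 0")
  if (b0 < 0 || b0 >= 1) stopf("b0 must be in [0, 1)")
  if (b_max <= b0 || b_max >= 1) stopf("b_max must be in (b0, 1)")
  structure(list(K_d = K_d, l_sense = l_sense, s = s, b0 = b0,
                 b_max = b_max),
            class = "link_params")
}

#' @export
print.link_params <- function(x, ...) {
  cat(sprintf("<link_params> K_d = %.3g, l = %.3g um, s = %.3g, b0 = %.2f, b_max = %.2f\n",
              x$K_d, x$l_sense, x$s, x$b0, x$b_max))
  invisible(x)
}

#' Receptor occupancy
#'
#' Standard hyperbolic receptor-ligand binding: `C / (C + K_d)`, monotone
#' increasing and saturating at 1.
#'
#' @param C concentration(s), `>= 0`.
#' @param K_d half-saturation concentration (> 0).
#' @return occupancy fraction(s) in `[0, 1)`.
#' @examples
#' occupancy(c(0, 1, 9), K_d = 1)
#' @export
occupancy <- function(C, K_d) {
  if (any(C < 0)) stopf("concentration must be >= 0")
  C / (C + K_d)
}

#' Local effective bias from the attractant field
#'
#' Computes each cell's effective bias strength and biased direction from
#' the local concentration and gradient. Refractory cells and cells in a
#' gradient-free location fall back to the baseline bias; with no gradient
#' there is no defined direction (`phi = NA`) and the walker uses pure
#' persistence.
#'
#' @param C concentration at the cells, length n.
#' @param grad n x 2 matrix of the concentration gradient.
#' @param link a [link_params()].
#' @param sensitive logical length n (default all `TRUE`); `FALSE` pins the
#'   cell to baseline bias.
#' @param grad_floor gradient magnitudes below this are treated as zero
#'   (field units / um).
#' @return list with `b_eff` (in `[b0, b_max]`), `phi` (up-gradient
#'   direction, radians; `NA` where no gradient) and `du` (occupancy
#'   difference).
#' @export
local_bias <- function(C, grad, link, sensitive = TRUE,
                       grad_floor = 1e-12) {
  n <- length(C)
  grad <- matrix(as.numeric(grad), ncol = 2)
  sensitive <- rep_len(sensitive, n)
  gmag <- sqrt(grad[, 1]^2 + grad[, 2]^2)
  du <- link$l_sense * gmag * link$K_d / (C + link$K_d)^2
  b_eff <- pmin(link$b_max, link$b0 + link$s * du)
  b_eff[!sensitive] <- link$b0
  phi <- ifelse(gmag > grad_floor, atan2(grad[, 2], grad[, 1]), NA_real_)
  b_eff[gmag <= grad_floor] <- link$b0
  list(b_eff = b_eff, phi = phi, du = du)
}

#' Desensitization settings
#'
#' A sensitive cell whose local concentration exceeds `C_trigger` becomes
#' refractory (baseline bias only) for `tau_refractory` minutes, then
#' reverts to sensitive. The default refractory duration of 120 min sits
#' inside the experimentally bracketed window: cells are still blind to a
#' second wound made 90 min after the first but have recovered by 3 hr.
#'
#' @param C_trigger concentration threshold (field units).
#' @param tau_refractory refractory duration, min.
#' @param enabled logical; the mechanism is off by default and switched on
#'   by the sequential-wound scenarios.
#' @return object of class `desens_params`.
#' @export
desens_params <- function(C_trigger, tau_refractory = 120, enabled = TRUE) {
  if (C_trigger < 0) stopf("C_trigger must be >= 0")
  if (tau_refractory <= 0) stopf("tau_refractory must be > 0")
  structure(list(C_trigger = C_trigger, tau_refractory = tau_refractory,
                 enabled = enabled),
            class = "desens_params")
}

#' Initialise per-cell sensitivity state
#' @param n number of cells.
#' @return a `sensitivity_state` data.frame (one row per cell).
#' @export
init_sensitivity <- function(n) {
  structure(data.frame(sensitive = rep(TRUE, n),
                       refractory_until = rep(-Inf, n),
                       triggered_at = rep(NA_real_, n)),
            class = c("sensitivity_state", "data.frame"))
}

#' Update the per-cell sensitivity state machine
#'
#' Transitions are sensitive -> refractory (when the local concentration
#' exceeds the trigger) and refractory -> sensitive (at expiry); the update
#' is idempotent within a time step.
#'
#' @param state a `sensitivity_state` from [init_sensitivity()].
#' @param C concentration at each cell.
#' @param t current time, min.
#' @param desens a [desens_params()].
#' @return updated state.
#' @export
update_sensitivity <- function(state, C, t, desens) {
  if (!desens$enabled) return(state)
  # expiry first, then (possibly immediate re-)triggering
  expired <- !state$sensitive & t >= state$refractory_until
  state$sensitive[expired] <- TRUE
  trig <- state$sensitive & C > desens$C_trigger
  state$sensitive[trig] <- FALSE
  state$refractory_until[trig] <- t + desens$tau_refractory
  state$triggered_at[trig] <- ifelse(is.na(state$triggered_at[trig]), t,
                                     state$triggered_at[trig])
  state
}
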