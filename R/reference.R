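#' Reference parameter set
#'
#' The package's "stated world": the parameter values used by the scenario
#' presets, the synthetic-data generator and the validation suite.
#'
#' The attractant diffusion coefficient (200 um^2/min) and the active
#' production duration (30 min) are the headline inferred values for the
#' wound attractant; wound radii 27.5 / 55 / 65 um correspond to the
#' small / large / extra-large (55 / 110 / 130 um diameter) wound presets.
#' The remaining constants are package choices on the relative
#' concentration scale fixed by `q = 1` (per um of wound margin per min),
#' documented in the methods vignette:
#' \itemize{
#'   \item `K_d = 0.1`: half-saturation sits just above the peak
#'     concentration reached in the first spatial band of a large wound
#'     (~0.2 at the margin), so responses near standard wounds are below
#'     saturation while very large or multiple wounds push into it.
#'   \item `s = 11`, `l_sense = 10` um: scales the occupancy difference so
#'     that the 0--100 um band of a large wound peaks at an effective bias
#'     of roughly 0.6--0.7 in the first 20--30 min.
#'   \item baseline bias `b0 = 0.05` (very low basal bias), ceiling
#'     `b_max = 0.85`.
#'   \item persistence `p = 0.5`, biased-step probability `w = 0.5`.
#'   \item speed model: gamma step lengths, mean 3 um/min, shape 2.
#'   \item desensitization: trigger `C_trigger = 0.002`, refractory
#'     duration 120 min (inside the bracketed 90 min-blind / 3 hr-restored
#'     window); used together with attractant clearance
#'     `decay = 0.03`/min by the sequential-wound presets.
#' }
#'
#' @return a named list with components `bprw` ([bprw_params()]), `attractant`
#'   ([attractant_params()]), `link` ([link_params()]), `desens`
#'   ([desens_params()], disabled), `speed` (gamma shape/mean), and scalars
#'   `n_cells`, `duration`, `dt`.
#' @export
reference_params <- function() {
  link <- link_params(K_d = 0.1, l_sense = 10, s = 11, b0 = 0.05,
                      b_max = 0.85)
  list(
    bprw = bprw_params(b = link$b0, p = 0.5, w = 0.5),
    attractant = attractant_params(D = 200, T_prod = 30, q = 1,
                                   geometry = "margin_ring"),
    link = link,
    desens = desens_params(C_trigger = 0.002, tau_refractory = 120,
                           enabled = FALSE),
    speed = list(shape = 2, mean = 3),
    seq_decay = 0.03,
    n_cells = 300, duration = 100, dt = 1
  )
}

#' Reference wound radii (um) for the paper-style presets
#' @return named vector: small / large / xl radii in micrometres.
#' @export
reference_radii <- function() {
  c(small = 27.5, large = 55, xl = 65)
}

#' Write the reference attractant parameter file
#'
#' Serialises [reference_params()] to JSON so runs can record exactly which
#' stated world generated them.
#'
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_params <- function(path) {
  rp <- reference_params()
  write_json_config(list(
    bprw = unclass(rp$bprw), attractant = unclass(rp$attractant),
    link = unclass(rp$link), desens = unclass(rp$desens),
    speed = rp$speed, seq_decay = rp$seq_decay,
    n_cells = rp$n_cells, duration = rp$duration, dt = rp$dt), path)
}
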