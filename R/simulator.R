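#' Scenario specification for the agent-based simulator
#'
#' @param domain a [wing_domain()].
#' @param wounds list of [wound_event()]s (possibly empty for unwounded
#'   controls).
#' @param n_cells cohort size.
#' @param duration simulated time, min.
#' @param dt frame interval, min.
#' @param params parameter list as from [reference_params()] (`bprw`,
#'   `attractant`, `link`, `desens`, `speed`); `attractant` may be a list of
#'   one [attractant_params()] per wound.
#' @param cil `NULL` (off) or `list(radius, repol)`: contact inhibition of
#'   locomotion with the given contact radius (um) and repolarization
#'   duration (min).
#' @param field_method `"free"` (free-space superposition; default) or
#'   `"bounded"` (finite-difference solve with wing-boundary effects).
#' @param t_start simulation start time, min.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(domain, wounds, n_cells = 300, duration = 100,
                          dt = 1, params = reference_params(), cil = NULL,
                          field_method = c("free", "bounded"), t_start = 0) {
  field_method <- match.arg(field_method)
  if (inherits(wounds, "wound_event")) wounds <- list(wounds)
  for (w in wounds)
    if (!all(domain_contains(domain, rbind(w$center))))
      stopf("wound center outside domain")
  if (n_cells < 1) stopf("n_cells must be >= 1")
  structure(list(domain = domain, wounds = wounds, n_cells = n_cells,
                 duration = duration, dt = dt, params = params, cil = cil,
                 field_method = field_method, t_start = t_start),
            class = "scenario_spec")
}

.uniform_in_domain <- function(domain, n) {
  bb <- domain$bbox
  out <- matrix(NA_real_, n, 2)
  need <- n
  while (need > 0) {
    m <- 2 * need + 16
    cand <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]))
    ok <- domain_contains(domain, cand)
    take <- min(need, sum(ok))
    if (take > 0)
      out[(n - need + 1):(n - need + take), ] <- cand[which(ok)[seq_len(take)], ]
    need <- need - take
  }
  out
}

.make_field <- function(spec) {
  if (length(spec$wounds) == 0) {
    return(list(eval = function(xy, t)
      list(C = numeric(nrow(xy)), grad = matrix(0, nrow(xy), 2))))
  }
  if (spec$field_method == "free") {
    ff <- free_field(spec$wounds, spec$params$attractant,
                     r_max = 1.2 * max(dist(spec$domain$bbox)),
                     t_max = spec$t_start + spec$duration + 1)
    list(eval = function(xy, t) list(C = ff$conc(xy, t), grad = ff$grad(xy, t)))
  } else {
    times <- seq(spec$t_start, spec$t_start + spec$duration, by = spec$dt)
    fg <- bounded_field(spec$domain, spec$wounds, spec$params$attractant,
                        times = times)
    list(eval = function(xy, t) field_eval(fg, xy, t), grid = fg)
  }
}

#' Simulate a hemocyte cohort
#'
#' Agent-based forward simulation of the biased persistent random walk in
#' the attractant field. Cells start uniformly distributed in the wing
#' domain; at each frame the per-cell sensitivity state is updated, the
#' local effective bias and up-gradient direction are computed via the
#' chemotaxis link, a heading is drawn from the BPRW mixture, a step length
#' is drawn from the gamma speed model, and the move is reflected
#' specularly at the domain boundary.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param init_pos optional n x 2 matrix of starting positions (inside the
#'   domain); default uniform.
#' @return list with `tracks` (list of [cell_track()]), `truth` (per
#'   cell-frame data.frame of ground-truth effective bias, direction and
#'   sensitivity) and `spec`.
#' @export
simulate_cohort <- function(spec, seed = NULL, init_pos = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_cells
  par <- spec$params
  field <- .make_field(spec)
  desens <- par$desens
  pos <- if (is.null(init_pos)) .uniform_in_domain(spec$domain, n) else {
    stopifnot(nrow(init_pos) == n,
              all(domain_contains(spec$domain, init_pos)))
    matrix(as.numeric(init_pos), n, 2)
  }
  theta_prev <- rep(NA_real_, n)
  state <- init_sensitivity(n)
  cil <- spec$cil
  cil_until <- rep(-Inf, n)
  cil_heading <- rep(NA_real_, n)
  steps <- seq(spec$t_start, spec$t_start + spec$duration - spec$dt,
               by = spec$dt)
  nt <- length(steps) + 1
  X <- array(NA_real_, c(n, 2, nt))
  X[, , 1] <- pos
  truth <- vector("list", length(steps))
  scale_len <- par$speed$mean * spec$dt / par$speed$shape
  for (k in seq_along(steps)) {
    tcur <- steps[k]
    fe <- field$eval(pos, tcur)
    state <- update_sensitivity(state, fe$C, tcur, desens)
    lb <- local_bias(fe$C, fe$grad, par$link, sensitive = state$sensitive)
    theta <- .draw_headings(theta_prev, lb$phi, par$bprw, lb$b_eff)
    if (!is.null(cil) && cil$radius > 0) {
      contacts <- cpp_contacts(pos[, 1], pos[, 2], cil$radius)
      if (nrow(contacts)) {
        for (row in seq_len(nrow(contacts))) {
          i <- contacts[row, 1]; j <- contacts[row, 2]
          away <- atan2(pos[i, 2] - pos[j, 2], pos[i, 1] - pos[j, 1])
          if (tcur >= cil_until[i]) {
            cil_heading[i] <- away; cil_until[i] <- tcur + cil$repol
          }
          if (tcur >= cil_until[j]) {
            cil_heading[j] <- wrap_angle(away + pi)
            cil_until[j] <- tcur + cil$repol
          }
        }
      }
      repol <- tcur < cil_until & !is.na(cil_heading)
      theta[repol] <- cil_heading[repol]
    }
    len <- rgamma(n, shape = par$speed$shape, scale = scale_len)
    prop <- pos + len * cbind(cos(theta), sin(theta))
    newpos <- reflect_into_domain(spec$domain, pos, prop)
    moved <- (newpos[, 1] != pos[, 1]) | (newpos[, 2] != pos[, 2])
    real_theta <- theta
    real_theta[moved] <- atan2(newpos[moved, 2] - pos[moved, 2],
                               newpos[moved, 1] - pos[moved, 1])
    theta_prev <- ifelse(moved, real_theta, theta_prev)
    truth[[k]] <- data.frame(cell = seq_len(n), t = tcur,
                             x = pos[, 1], y = pos[, 2],
                             C = fe$C, b_eff = lb$b_eff, phi = lb$phi,
                             sensitive = state$sensitive)
    pos <- newpos
    X[, , k + 1] <- pos
  }
  times <- c(steps, spec$t_start + spec$duration)
  tracks <- lapply(seq_len(n), function(i)
    cell_track(sprintf("c%04d", i), times, t(X[i, , ])))
  list(tracks = tracks, truth = do.call(rbind, truth), spec = spec)
}

# first-frame cells have no previous heading: biased component if a
# direction exists, otherwise uniform
.draw_headings <- function(theta_prev, phi, bprw, b_eff) {
  n <- length(theta_prev)
  theta <- numeric(n)
  fresh <- is.na(theta_prev)
  if (any(!fresh))
    theta[!fresh] <- sample_step(theta_prev[!fresh], phi[!fresh], bprw,
                                 b = b_eff[!fresh])
  if (any(fresh)) {
    kb <- mrl_to_kappa(b_eff[fresh])
    use_bias <- runif(sum(fresh)) < bprw$w & !is.na(phi[fresh])
    th <- runif(sum(fresh), -pi, pi)
    if (any(use_bias))
      th[use_bias] <- rvonmises(sum(use_bias), phi[fresh][use_bias],
                                kb[use_bias])
    theta[fresh] <- th
  }
  theta
}

#' Simulate with contact inhibition of locomotion
#'
#' Convenience wrapper: when two cells come within the contact radius both
#' repolarize away from the contact for the repolarization duration
#' (overriding bias), then resume normal behaviour. With `radius = 0` the
#' tracks are identical to a CIL-free run under the same seed.
#'
#' @param spec a [scenario_spec()] (its `cil` field is overridden).
#' @param cil list with `radius` (um) and `repol` (min).
#' @param seed integer seed.
#' @return as [simulate_cohort()].
#' @export
simulate_with_cil <- function(spec, cil = list(radius = 10, repol = 5),
                              seed = NULL) {
  spec$cil <- cil
  simulate_cohort(spec, seed = seed)
}

#' Count cells recruited to the wound
#'
#' Number of distinct cells entering the arrival disc around the wound
#' centre within a time window.
#'
#' @param tracks list of [cell_track()]s.
#' @param wound a [wound_event()].
#' @param arrival_radius disc radius, um (must be >= the wound radius).
#' @param window length-2 time window (min), default the whole recording.
#' @return integer count.
#' @export
recruitment_count <- function(tracks, wound, arrival_radius,
                              window = c(-Inf, Inf)) {
  if (arrival_radius < wound$radius)
    stopf("arrival radius must be >= wound radius")
  sum(vapply(tracks, function(tr) {
    sel <- tr$times >= window[1] & tr$times <= window[2]
    if (!any(sel)) return(FALSE)
    d <- sqrt((tr$positions[sel, 1] - wound$center[1])^2 +
                (tr$positions[sel, 2] - wound$center[2])^2)
    any(d <= arrival_radius)
  }, logical(1)))
}

#' Scenario presets
#'
#' Named presets reproducing the modelled experiments: unwounded control,
#' single wounds of 55/110/130 um diameter, synchronous double wounds with
#' centres 150/330/480 um apart, sequential wounds offset by 90 min or 3 hr
#' (desensitization and attractant clearance enabled), and
#' healer-like / non-healer-like extra-large wound cohorts.
#'
#' @return named list of zero-argument functions returning a
#'   [scenario_spec()].
#' @export
scenario_presets <- function() {
  rp <- reference_params()
  radii <- reference_radii()
  dom <- default_wing()
  single <- function(R, params = rp) {
    scenario_spec(dom, wound_event(c(0, 0), R), n_cells = rp$n_cells,
                  duration = rp$duration, dt = rp$dt, params = params)
  }
  double <- function(sep) {
    w <- list(wound_event(c(-sep / 2, 0), radii[["small"]]),
              wound_event(c(sep / 2, 0), radii[["small"]]))
    scenario_spec(dom, w, n_cells = rp$n_cells, duration = rp$duration,
                  dt = rp$dt, params = rp)
  }
  sequential <- function(offset) {
    par <- rp
    par$desens$enabled <- TRUE
    par$attractant$decay <- rp$seq_decay
    w <- list(wound_event(c(-60, 0), radii[["large"]], t0 = 0),
              wound_event(c(60, 0), radii[["large"]], t0 = offset))
    scenario_spec(dom, w, n_cells = rp$n_cells,
                  duration = offset + rp$duration, dt = rp$dt, params = par)
  }
  chronic <- function(healer) {
    par <- rp
    if (!healer) {
      par$link$s <- 0.5          # near-baseline wound-induced bias
      par$bprw$p <- 0.3          # reduced persistence
    }
    single(radii[["xl"]], par)
  }
  list(
    unwounded = function() scenario_spec(dom, list(), n_cells = rp$n_cells,
                                         duration = rp$duration, dt = rp$dt,
                                         params = rp),
    single_small = function() single(radii[["small"]]),
    single_large = function() single(radii[["large"]]),
    single_xl = function() single(radii[["xl"]]),
    double_close = function() double(150),
    double_mid = function() double(330),
    double_far = function() double(480),
    sequential_90min = function() sequential(90),
    sequential_3hr = function() sequential(180),
    healer = function() chronic(TRUE),
    nonhealer = function() chronic(FALSE)
  )
}

#' Run a scenario preset as a replicate ensemble
#'
#' Runs `replicates` independent simulations of a preset (display
#' convention: the mean of 500 simulations; scale down for exploratory
#' runs), summarising each replicate by its per-cluster empirical bias
#' (mean resultant length of the wound angle beta) and recruitment counts,
#' and averaging summaries across replicates.
#'
#' @param preset preset name (see [scenario_presets()]).
#' @param overrides named list overriding `scenario_spec` fields (e.g.
#'   `n_cells`, `duration`).
#' @param replicates number of replicate simulations.
#' @param seed master seed; replicate r uses `derive_seed(seed, r)`.
#' @param keep_tracks logical: keep each replicate's raw simulation?
#' @param grid_spec [cluster_grid_spec()] used for summaries.
#' @param out_dir optional directory: writes tracks CSV (first replicate),
#'   the averaged summary and a JSON manifest.
#' @return object of class `scenario_run`: `summary` (mean per-cluster
#'   empirical bias matrix), `recruit` (mean recruitment count per wound),
#'   `replicates`, and optionally `sims`.
#' @export
run_scenario <- function(preset, overrides = list(), replicates = 500,
                         seed = 1, keep_tracks = FALSE,
                         grid_spec = cluster_grid_spec(), out_dir = NULL) {
  presets <- scenario_presets()
  if (!preset %in% names(presets))
    stopf("unknown preset '%s'; available: %s", preset,
          paste(names(presets), collapse = ", "))
  spec <- presets[[preset]]()
  for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]
  ns <- length(grid_spec$space_edges) - 1
  nt <- length(grid_spec$time_edges) - 1
  acc <- matrix(0, ns, nt,
                dimnames = list(paste0("S", 1:ns), paste0("T", 1:nt)))
  cnt <- matrix(0, ns, nt, dimnames = dimnames(acc))
  recruit <- rep(0, max(1, length(spec$wounds)))
  sims <- if (keep_tracks) vector("list", replicates) else NULL
  for (r in seq_len(replicates)) {
    sim <- simulate_cohort(spec, seed = derive_seed(seed, r))
    if (length(spec$wounds)) {
      w1 <- spec$wounds[[1]]
      steps <- compute_steps_all(sim$tracks, wound = w1)
      cg <- cluster_steps(steps, grid_spec, t0 = w1$t0)
      emp <- empirical_bias(cg)
      ok <- !is.na(emp)
      acc[ok] <- acc[ok] + emp[ok]
      cnt[ok] <- cnt[ok] + 1
      recruit <- recruit + vapply(spec$wounds, function(w)
        recruitment_count(sim$tracks, w, arrival_radius = w$radius + 10),
        numeric(1))
    }
    if (keep_tracks) sims[[r]] <- sim
  }
  out <- structure(list(preset = preset, spec = spec,
                        summary = ifelse(cnt > 0, acc / cnt, NA),
                        recruit = recruit / replicates,
                        replicates = replicates, seed = seed, sims = sims),
                   class = "scenario_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sim1 <- if (keep_tracks) sims[[1]] else
      simulate_cohort(spec, seed = derive_seed(seed, 1))
    write_tracks_csv(sim1$tracks, file.path(out_dir, "tracks.csv"))
    write.csv(out$summary, file.path(out_dir, "cluster_bias.csv"))
    write_json_config(list(preset = preset, replicates = replicates,
                           seed = seed,
                           package = as.character(utils::packageVersion("hemotaxis"))),
                      file.path(out_dir, "manifest.json"))
  }
  out
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run> %s: %d replicate(s)\n", x$preset, x$replicates))
  if (!all(is.na(x$summary))) {
    cat("mean per-cluster empirical bias (MRL of beta):\n")
    print(round(x$summary, 3))
  }
  invisible(x)
}

#' Empirical per-cluster bias (mean resultant length of beta)
#'
#' Moment summary used for quick scenario comparisons (the full Bayesian
#' treatment is [infer_cluster_params()]): per cluster, the mean resultant
#' length of the wound angles, signed by the mean direction so that
#' anti-wound orientation does not masquerade as bias.
#'
#' @param cg a `cluster_grid` from [cluster_steps()].
#' @return bands x windows matrix; `NA` for empty clusters.
#' @export
empirical_bias <- function(cg) {
  ns <- length(cg$spec$space_edges) - 1
  nt <- length(cg$spec$time_edges) - 1
  out <- matrix(NA_real_, ns, nt,
                dimnames = list(paste0("S", 1:ns), paste0("T", 1:nt)))
  st <- cg$steps
  for (i in seq_len(ns)) for (j in seq_len(nt)) {
    be <- st$beta[!is.na(st$space_bin) & !is.na(st$time_bin) &
                    st$space_bin == i & st$time_bin == j]
    if (length(be) >= 5) {
      mrl <- sqrt(mean(cos(be))^2 + mean(sin(be))^2)
      out[i, j] <- mrl * sign(mean(cos(be)))
    }
  }
  out
}

#' Write tracks in the standard trajectory CSV dialect
#'
#' @param tracks list of [cell_track()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(cell_id = tr$cell_id, t_min = tr$times,
               x_um = tr$positions[, 1], y_um = tr$positions[, 2])))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
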