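#' Attractant model parameters
#'
#' Parameters of the wound chemoattractant forward model: 2D diffusion from
#' a source that is either the wound margin (a ring of circumference
#' `2*pi*R`) or the damaged area (a disc). Production is constant from the
#' wounding time until `T_prod` minutes later; afterwards the attractant
#' keeps diffusing but no new signal is released. Concentration is on a
#' relative (arbitrary-unit) scale set by `q`.
#'
#' @param D diffusion coefficient, um^2/min (> 0). Reference value 200.
#' @param T_prod active production duration, min (> 0). Reference value 30.
#' @param q source strength: per unit length of margin (ring geometry) or
#'   per unit area (disc geometry), per minute, relative units (>= 0).
#' @param geometry `"margin_ring"` or `"damage_disc"`.
#' @param decay optional first-order decay rate (1/min); the default 0
#'   (pure diffusion after production stops) is the supported model and the
#'   knob exists only for sensitivity exploration with the bounded solver.
#' @return object of class `attractant_params`.
#' @export
attractant_params <- function(D = 200, T_prod = 30, q = 1,
                              geometry = c("margin_ring", "damage_disc"),
                              decay = 0) {
  geometry <- match.arg(geometry)
  if (!is.numeric(D) || D <= 0) stopf("D must be > 0")
  if (!is.numeric(T_prod) || T_prod <= 0) stopf("T_prod must be > 0")
  if (!is.numeric(q) || q < 0) stopf("q must be >= 0")
  structure(list(D = D, T_prod = T_prod, q = q, geometry = geometry,
                 decay = decay),
            class = "attractant_params")
}

#' @export
print.attractant_params <- function(x, ...) {
  cat(sprintf("<attractant_params> %s: D = %.3g um^2/min, T = %.3g min, q = %.3g\n",
              x$geometry, x$D, x$T_prod, x$q))
  invisible(x)
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1, idx]^2)
}

# instantaneous ring kernel (unit per-unit-length strength); vectorized
# jointly over r, u and ring radius Rw with recycling
.ring_kernel <- function(r, u, Rw, D) {
  n <- max(length(r), length(u), length(Rw))
  r <- rep_len(r, n); u <- rep_len(u, n); Rw <- rep_len(Rw, n)
  out <- numeric(n)
  pos <- u > 0
  du <- D * u[pos]
  out[pos] <- Rw[pos] / (2 * du) * exp(-(r[pos] - Rw[pos])^2 / (4 * du)) *
    besselI(r[pos] * Rw[pos] / (2 * du), 0, expon.scaled = TRUE)
  out
}

#' Free-space ring-source concentration
#'
#' Closed-form (single-quadrature) concentration at radial distance `r`
#' from the wound centre, time `t` after wounding, for attractant released
#' uniformly from the wound-margin ring at per-unit-length rate `q` for the
#' production duration:
#' `C(r, t) = int_0^.. q R/(2 D u) exp(-(r^2 + R^2)/(4 D u)) I0(r R/(2 D u)) du`
#' with `u` the time since emission. Evaluated by adaptive quadrature to
#' relative tolerance 1e-6.
#'
#' @param r radial distance(s) from the wound centre, um.
#' @param t time(s) since wounding, min (>= 0; recycled against `r`).
#' @param wound a [wound_event()] (only the radius is used).
#' @param params an [attractant_params()] with ring geometry.
#' @return concentration(s), relative units.
#' @export
ring_source_concentration <- function(r, t, wound, params) {
  if (any(t < 0)) stopf("t must be >= 0 (measured from wounding)")
  n <- max(length(r), length(t))
  r <- rep_len(r, n); t <- rep_len(t, n)
  Rw <- wound$radius; D <- params$D; Tp <- params$T_prod; q <- params$q
  vapply(seq_len(n), function(i) {
    ti <- t[i]
    if (ti == 0 || q == 0) return(0)
    lo <- max(0, ti - Tp)
    intg <- integrate(function(u) .ring_kernel(r[i], u, Rw, D) *
                        exp(-params$decay * u),
                      lower = lo, upper = ti, rel.tol = 1e-6,
                      subdivisions = 400L)
    if (intg$message != "OK")
      stopf("quadrature failed at r = %g, t = %g: %s", r[i], ti, intg$message)
    q * intg$value
  }, numeric(1))
}

#' Free-space disc-source concentration
#'
#' As [ring_source_concentration()] but with attractant released uniformly
#' over the damaged disc at per-unit-area rate `q`: the ring kernel is
#' integrated radially over source rings `rho` in `[0, R]` (64-node
#' Gauss-Legendre) inside the adaptive time quadrature.
#'
#' @inheritParams ring_source_concentration
#' @export
disc_source_concentration <- function(r, t, wound, params) {
  if (any(t < 0)) stopf("t must be >= 0 (measured from wounding)")
  n <- max(length(r), length(t))
  r <- rep_len(r, n); t <- rep_len(t, n)
  Rw <- wound$radius; D <- params$D; Tp <- params$T_prod; q <- params$q
  gl <- gauss_legendre(64)
  rho <- (gl$nodes + 1) * Rw / 2
  wts <- gl$weights * Rw / 2
  disc_kernel <- function(u, ri) {
    vapply(u, function(ui) {
      if (ui <= 0) return(0)
      exp(-params$decay * ui) * sum(wts * .ring_kernel(ri, ui, rho, D))
    }, numeric(1))
  }
  vapply(seq_len(n), function(i) {
    ti <- t[i]
    if (ti == 0 || q == 0) return(0)
    lo <- max(0, ti - Tp)
    intg <- integrate(disc_kernel, ri = r[i], lower = lo, upper = ti,
                      rel.tol = 1e-6, subdivisions = 400L)
    if (intg$message != "OK")
      stopf("quadrature failed at r = %g, t = %g: %s", r[i], ti, intg$message)
    q * intg$value
  }, numeric(1))
}

# ---- cached radial field ----------------------------------------------

#' Cached free-space radial field
#'
#' Precomputes the cumulative emission integral `G(r, s)` on an (r, s)
#' lattice so that `C(r, t) = q * (G(r, t) - G(r, max(0, t - T)))` and its
#' radial derivative can be evaluated for tens of thousands of (r, t) pairs
#' by bilinear interpolation. This is the fast path used inside the
#' gradient-model likelihood and the simulator; it is validated against the
#' adaptive-quadrature forms.
#'
#' @param wound a [wound_event()].
#' @param params an [attractant_params()].
#' @param r_max largest radius represented, um.
#' @param t_max largest time represented, min.
#' @param nr,ns lattice sizes in r and s (emission time; graded toward 0).
#' @return object of class `radial_field` with an `eval(r, t)` closure
#'   returning `list(C, dCdr)`.
#' @export
radial_field_cache <- function(wound, params, r_max = 800, t_max = 200,
                               nr = 281, ns = 321) {
  Rw <- wound$radius
  rgrid <- seq(0, r_max, length.out = nr)
  sgrid <- t_max * (seq_len(ns) / ns)^3   # cubic grading toward t = 0
  G <- if (params$geometry == "margin_ring") {
    cpp_ring_G(rgrid, sgrid, Rw, params$D, params$decay)
  } else {
    gl <- gauss_legendre(48)
    cpp_disc_G(rgrid, sgrid, Rw, params$D, params$decay, gl$nodes, gl$weights)
  }
  dr <- rgrid[2] - rgrid[1]
  dGdr <- G
  dGdr[2:(nr - 1), ] <- (G[3:nr, ] - G[1:(nr - 2), ]) / (2 * dr)
  dGdr[1, ] <- 0                      # symmetry at r = 0
  dGdr[nr, ] <- (G[nr, ] - G[nr - 1, ]) / dr
  Tp <- params$T_prod; q <- params$q
  evalfun <- function(r, t) {
    n <- max(length(r), length(t))
    r <- rep_len(r, n); t <- rep_len(t, n)
    tc <- pmin(pmax(t, 0), t_max)
    tl <- pmin(pmax(t - Tp, 0), t_max)
    Cv <- q * (cpp_bilinear(rgrid, sgrid, G, r, tc) -
                 cpp_bilinear(rgrid, sgrid, G, r, tl))
    Dv <- q * (cpp_bilinear(rgrid, sgrid, dGdr, r, tc) -
                 cpp_bilinear(rgrid, sgrid, dGdr, r, tl))
    zero <- t <= 0
    Cv[zero] <- 0; Dv[zero] <- 0
    list(C = pmax(Cv, 0), dCdr = Dv)
  }
  structure(list(wound = wound, params = params, r_max = r_max,
                 t_max = t_max, eval = evalfun),
            class = "radial_field")
}

#' Free-space multi-wound field evaluator
#'
#' Superposition of cached radial fields, one per wound, each with its own
#' clock offset `t0`. Provides concentration and gradient at arbitrary
#' positions and times; this is the field the simulator and the
#' gradient-model likelihood use away from domain boundaries.
#'
#' @param wounds list of [wound_event()]s.
#' @param params an [attractant_params()] shared by all wounds, or a list
#'   of one per wound.
#' @param r_max,t_max cache extents (see [radial_field_cache()]).
#' @return object of class `free_field` with closures `conc(xy, t)` and
#'   `grad(xy, t)` (n x 2 matrix of the spatial gradient).
#' @export
free_field <- function(wounds, params, r_max = 900, t_max = 400) {
  if (inherits(wounds, "wound_event")) wounds <- list(wounds)
  if (inherits(params, "attractant_params"))
    params <- rep(list(params), length(wounds))
  stopifnot(length(params) == length(wounds))
  caches <- Map(function(w, p) radial_field_cache(w, p, r_max, t_max),
                wounds, params)
  conc <- function(xy, t) {
    xy <- matrix(as.numeric(xy), ncol = 2)
    total <- numeric(nrow(xy))
    for (k in seq_along(caches)) {
      w <- wounds[[k]]
      r <- sqrt((xy[, 1] - w$center[1])^2 + (xy[, 2] - w$center[2])^2)
      total <- total + caches[[k]]$eval(r, t - w$t0)$C
    }
    total
  }
  grad <- function(xy, t) {
    xy <- matrix(as.numeric(xy), ncol = 2)
    gx <- numeric(nrow(xy)); gy <- numeric(nrow(xy))
    for (k in seq_along(caches)) {
      w <- wounds[[k]]
      dx <- xy[, 1] - w$center[1]; dy <- xy[, 2] - w$center[2]
      r <- sqrt(dx^2 + dy^2)
      dCdr <- caches[[k]]$eval(r, t - w$t0)$dCdr
      safe <- r > 1e-9
      gx[safe] <- gx[safe] + dCdr[safe] * dx[safe] / r[safe]
      gy[safe] <- gy[safe] + dCdr[safe] * dy[safe] / r[safe]
    }
    cbind(gx, gy)
  }
  structure(list(wounds = wounds, params = params, caches = caches,
                 conc = conc, grad = grad),
            class = "free_field")
}

# ---- bounded finite-difference field -----------------------------------

#' Bounded-domain attractant field (zero-flux finite differences)
#'
#' Explicit finite-difference solution of the diffusion equation on the
#' wing domain mask with reflecting (zero-flux) boundaries, capturing the
#' attractant accumulation near wing margins that the free-space forms
#' miss. Sources (one per wound, ring or disc geometry) are active from
#' each wound's `t0` for its production duration. The scheme is exactly
#' mass-conservative after production stops.
#'
#' @param domain a [wing_domain()].
#' @param wounds list of [wound_event()]s.
#' @param params an [attractant_params()] or list of one per wound.
#' @param times increasing output times (min).
#' @param h grid spacing, um; must resolve the smallest wound
#'   (`h <= R/4`).
#' @param cfl stability safety factor in (0, 1]; the time step is
#'   `cfl * h^2 / (4 D)`.
#' @return object of class `field_grid`: grid axes `x`, `y`, `times`,
#'   `mask`, concentration array `C` (nx x ny x nt) and central-difference
#'   gradients `dCdx`, `dCdy`.
#' @export
bounded_field <- function(domain, wounds, params, times, h = NULL,
                          cfl = 0.9) {
  if (inherits(wounds, "wound_event")) wounds <- list(wounds)
  if (inherits(params, "attractant_params"))
    params <- rep(list(params), length(wounds))
  rmin <- min(vapply(wounds, function(w) w$radius, 0))
  if (is.null(h)) h <- rmin / 4
  if (h > rmin / 4 + 1e-9)
    stopf("grid spacing h = %g does not resolve wound radius %g (need h <= R/4)",
          h, rmin)
  bb <- domain$bbox
  x <- seq(bb[1, 1] + h / 2, bb[2, 1], by = h)
  y <- seq(bb[1, 2] + h / 2, bb[2, 2], by = h)
  gx <- rep(x, times = length(y)); gy <- rep(y, each = length(x))
  mask <- matrix(as.integer(domain_contains(domain, cbind(gx, gy))),
                 length(x), length(y))
  D <- max(vapply(params, function(p) p$D, 0))
  dt <- cfl * h^2 / (4 * D)
  # per-wound source cells and per-step concentration increments
  nx <- length(x); ny <- length(y)
  cell_of <- function(px, py) {
    i <- pmin(pmax(round((px - x[1]) / h) + 1, 1), nx)
    j <- pmin(pmax(round((py - y[1]) / h) + 1, 1), ny)
    (j - 1L) * nx + i
  }
  sources <- Map(function(w, p) {
    # distribute the emission over grid cells by fine sampling of the
    # source geometry, so the effective source matches the continuous one
    # to well below the grid scale
    if (p$geometry == "margin_ring") {
      m <- 4096L
      th <- 2 * pi * (seq_len(m) - 0.5) / m
      px <- w$center[1] + w$radius * cos(th)
      py <- w$center[2] + w$radius * sin(th)
      rate <- p$q * 2 * pi * w$radius          # total mass per min
    } else {
      m <- 128L
      rr <- w$radius * sqrt((seq_len(m) - 0.5) / m)  # area-uniform radii
      pts <- do.call(rbind, lapply(rr, function(r0) {
        k <- max(8L, ceiling(2 * pi * r0 / (w$radius / m)))
        a <- 2 * pi * (seq_len(k) - 0.5) / k
        cbind(w$center[1] + r0 * cos(a), w$center[2] + r0 * sin(a))
      }))
      px <- pts[, 1]; py <- pts[, 2]
      rate <- p$q * pi * w$radius^2
    }
    tab <- table(cell_of(px, py))
    idx <- as.integer(names(tab))
    wt <- as.numeric(tab) / sum(tab)
    inside <- mask[idx] == 1L
    if (!any(inside)) stopf("wound source does not overlap the grid")
    idx <- idx[inside]; wt <- wt[inside] / sum(wt[inside])
    list(idx = idx - 1L, inc_per_step = rate * dt * wt / h^2,
         on = w$t0, off = w$t0 + p$T_prod)
  }, wounds, params)

  breaks <- sort(unique(c(0, times,
                          unlist(lapply(sources, function(s) c(s$on, s$off))))))
  breaks <- breaks[breaks >= 0 & breaks <= max(times)]
  C <- matrix(0, length(x), length(y))
  out <- array(0, dim = c(length(x), length(y), length(times)))
  t_now <- 0
  for (b in breaks[-1]) {
    nstep <- max(1L, as.integer(round((b - t_now) / dt)))
    dt_b <- (b - t_now) / nstep
    active <- Filter(function(s) s$on < b - 1e-9 && s$off > t_now + 1e-9,
                     sources)
    src_idx <- unlist(lapply(active, function(s) s$idx))
    src_inc <- unlist(lapply(active, function(s) s$inc_per_step * dt_b / dt))
    if (is.null(src_idx)) { src_idx <- integer(0); src_inc <- numeric(0) }
    C <- cpp_diffuse(C, mask, D, h, dt_b, nstep, as.integer(src_idx),
                     as.numeric(src_inc), lambda = params[[1]]$decay)
    t_now <- b
    hit <- which(abs(times - t_now) < 1e-9)
    for (k in hit) out[, , k] <- C
  }
  grad <- .central_gradients(out, mask, h)
  structure(list(x = x, y = y, times = times, mask = mask, h = h,
                 C = out, dCdx = grad$dx, dCdy = grad$dy,
                 domain = domain, wounds = wounds, params = params),
            class = "field_grid")
}

.central_gradients <- function(A, mask, h) {
  nx <- dim(A)[1]; ny <- dim(A)[2]; nt <- dim(A)[3]
  dx <- array(0, dim(A)); dy <- array(0, dim(A))
  for (k in seq_len(nt)) {
    M <- A[, , k]
    gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
    gx[2:(nx - 1), ] <- (M[3:nx, ] - M[1:(nx - 2), ]) / (2 * h)
    gy[, 2:(ny - 1)] <- (M[, 3:ny] - M[, 1:(ny - 2)]) / (2 * h)
    gx[mask == 0L] <- 0; gy[mask == 0L] <- 0
    dx[, , k] <- gx; dy[, , k] <- gy
  }
  list(dx = dx, dy = dy)
}

#' Total attractant mass on a field grid
#' @param field a `field_grid`.
#' @return numeric vector, one total (concentration * area) per output time.
#' @export
field_mass <- function(field) {
  apply(field$C, 3, function(M) sum(M[field$mask == 1L]) * field$h^2)
}

#' Evaluate a field grid at arbitrary positions
#'
#' Bilinear interpolation in space and linear interpolation in time.
#'
#' @param field a `field_grid` from [bounded_field()].
#' @param xy n x 2 positions (um).
#' @param t single time (min); must be within the field's time range.
#' @return list with `C` (length n) and `grad` (n x 2).
#' @export
field_eval <- function(field, xy, t) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  ts <- field$times
  if (t < min(ts) - 1e-9 || t > max(ts) + 1e-9)
    stopf("time %g outside field range [%g, %g]", t, min(ts), max(ts))
  bil <- function(M) cpp_bilinear(field$x, field$y, M, xy[, 1], xy[, 2])
  if (length(ts) == 1) {
    k <- 1; k2 <- 1; frac <- 0
  } else {
    k <- findInterval(t, ts, all.inside = TRUE)
    k2 <- k + 1
    frac <- if (ts[k2] > ts[k]) (t - ts[k]) / (ts[k2] - ts[k]) else 0
  }
  C <- (1 - frac) * bil(field$C[, , k]) + frac * bil(field$C[, , k2])
  gx <- (1 - frac) * bil(field$dCdx[, , k]) + frac * bil(field$dCdx[, , k2])
  gy <- (1 - frac) * bil(field$dCdy[, , k]) + frac * bil(field$dCdy[, , k2])
  list(C = C, grad = cbind(gx, gy))
}

#' Superpose attractant fields
#'
#' Adds the concentration (and gradient) arrays of field grids computed on
#' a common lattice; valid because the diffusion model is linear. Sequential
#' wounds are handled upstream by each source's own clock.
#'
#' @param ... `field_grid` objects on identical grids.
#' @return a `field_grid`.
#' @export
superpose_fields <- function(...) {
  fields <- list(...)
  if (length(fields) == 1 && is.list(fields[[1]]) &&
      !inherits(fields[[1]], "field_grid")) fields <- fields[[1]]
  stopifnot(length(fields) >= 1)
  f1 <- fields[[1]]
  for (f in fields[-1]) {
    if (!isTRUE(all.equal(f$x, f1$x)) || !isTRUE(all.equal(f$y, f1$y)) ||
        !isTRUE(all.equal(f$times, f1$times)))
      stopf("fields are not on a common grid")
    f1$C <- f1$C + f$C
    f1$dCdx <- f1$dCdx + f$dCdx
    f1$dCdy <- f1$dCdy + f$dCdy
    f1$wounds <- c(f1$wounds, f$wounds)
    f1$params <- c(f1$params, f$params)
  }
  f1
}
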