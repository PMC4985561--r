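#' Wing domain polygon
#'
#' The imaging field is a bounded planar region (the pupal wing). Tracks are
#' clipped to this region and the bounded diffusion solver and the simulator
#' reflect at its boundary.
#'
#' @param boundary two-column matrix (x, y in micrometres) of polygon
#'   vertices, in order, open or closed (first vertex need not be repeated).
#' @return an object of class `wing_domain` with elements `boundary`
#'   (closed ring matrix) and `bbox`.
#' @examples
#' dom <- wing_domain(cbind(c(0, 100, 100, 0), c(0, 0, 50, 50)))
#' domain_contains(dom, cbind(50, 25))
#' @export
wing_domain <- function(boundary) {
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2 || nrow(boundary) < 3)
    stopf("boundary must be an n x 2 matrix with n >= 3")
  if (anyNA(boundary)) stopf("boundary contains missing coordinates")
  # drop an explicitly repeated closing vertex
  n <- nrow(boundary)
  if (all(boundary[1, ] == boundary[n, ])) boundary <- boundary[-n, , drop = FALSE]
  if (nrow(boundary) < 3) stopf("degenerate polygon")
  if (.polygon_self_intersects(boundary))
    stopf("domain polygon is self-intersecting")
  a <- polygon_area(boundary)
  if (a <= 0) { # enforce counter-clockwise orientation
    boundary <- boundary[rev(seq_len(nrow(boundary))), , drop = FALSE]
    a <- -a
  }
  if (a == 0) stopf("domain polygon has zero area")
  structure(
    list(boundary = boundary, area = a,
         bbox = rbind(apply(boundary, 2, min), apply(boundary, 2, max))),
    class = "wing_domain")
}

#' @export
print.wing_domain <- function(x, ...) {
  cat(sprintf("<wing_domain> %d vertices, area %.0f um^2, bbox [%.0f,%.0f] x [%.0f,%.0f]\n",
              nrow(x$boundary), x$area,
              x$bbox[1, 1], x$bbox[2, 1], x$bbox[1, 2], x$bbox[2, 2]))
  invisible(x)
}

#' Signed polygon area (shoelace)
#' @param ring open ring matrix.
#' @return signed area; positive when counter-clockwise.
#' @keywords internal
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

.polygon_self_intersects <- function(ring) {
  n <- nrow(ring)
  seg <- cbind(ring, ring[c(2:n, 1), ])
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    # skip the closing edge adjacency for i = 1
    if (i == 1) js <- js[js != n]
    for (j in js) {
      if (.segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

.segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Point-in-domain predicate
#'
#' Even-odd ray casting; points on the boundary count as inside.
#'
#' @param domain a [wing_domain()].
#' @param xy two-column matrix of points (micrometres).
#' @return logical vector.
#' @export
domain_contains <- function(domain, xy) {
  stopifnot(inherits(domain, "wing_domain"))
  xy <- matrix(as.numeric(xy), ncol = 2)
  cpp_point_in_polygon(xy[, 1], xy[, 2],
                       domain$boundary[, 1], domain$boundary[, 2])
}

#' Default rounded-rectangle wing domain
#'
#' A rounded rectangle approximating a pupal wing imaging field. Dimensions
#' default to 900 x 450 micrometres, large enough that the standard wound
#' presets (up to 480 um between wound centres) fit with margin bands and
#' that all five 100-um distance bands around a central wound are populated.
#'
#' @param width,height rectangle dimensions in micrometres.
#' @param corner corner radius in micrometres.
#' @param n_arc vertices per corner arc.
#' @return a [wing_domain()], centred on the origin.
#' @export
default_wing <- function(width = 900, height = 450, corner = 60, n_arc = 8) {
  w2 <- width / 2; h2 <- height / 2
  th <- seq(0, pi / 2, length.out = n_arc)
  arc <- function(cx, cy, t0) cbind(cx + corner * cos(t0 + th),
                                    cy + corner * sin(t0 + th))
  ring <- rbind(
    arc(w2 - corner, h2 - corner, 0),        # NE
    arc(-(w2 - corner), h2 - corner, pi / 2),  # NW
    arc(-(w2 - corner), -(h2 - corner), pi),   # SW
    arc(w2 - corner, -(h2 - corner), 3 * pi / 2)) # SE
  wing_domain(ring)
}

#' Wound event
#'
#' A circular wound: centre, radius and time of wounding. The paper-style
#' presets use radii 27.5, 55 and 65 um (55 / 110 / 130 um diameters), but
#' any positive radius is accepted.
#'
#' @param center numeric length-2, micrometres.
#' @param radius wound radius in micrometres (> 0).
#' @param t0 wounding time in minutes.
#' @param domain optional [wing_domain()]; if given, the wound disc must lie
#'   inside it.
#' @return an object of class `wound_event`.
#' @export
wound_event <- function(center, radius, t0 = 0, domain = NULL) {
  center <- as.numeric(center)
  if (length(center) != 2 || anyNA(center)) stopf("center must be length-2 numeric")
  if (!is.numeric(radius) || radius <= 0) stopf("wound radius must be > 0")
  if (!is.null(domain)) {
    th <- seq(0, 2 * pi, length.out = 33)[-33]
    rim <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
    if (!all(domain_contains(domain, rim)))
      stopf("wound disc extends outside the wing domain")
  }
  structure(list(center = center, radius = radius, t0 = t0),
            class = "wound_event")
}

#' @export
print.wound_event <- function(x, ...) {
  cat(sprintf("<wound_event> center (%.1f, %.1f) um, radius %.1f um, t0 %.1f min\n",
              x$center[1], x$center[2], x$radius, x$t0))
  invisible(x)
}

#' Distance from points to a wound
#'
#' @param wound a [wound_event()].
#' @param xy two-column matrix of positions.
#' @param ref `"edge"` (default; distance to the wound margin, floored at 0)
#'   or `"center"`.
#' @return numeric vector of distances (um, >= 0).
#' @export
wound_distance <- function(wound, xy, ref = c("edge", "center")) {
  ref <- match.arg(ref)
  xy <- matrix(as.numeric(xy), ncol = 2)
  d <- sqrt((xy[, 1] - wound$center[1])^2 + (xy[, 2] - wound$center[2])^2)
  if (ref == "edge") pmax(d - wound$radius, 0) else d
}

#' Reflect a move specularly at the domain boundary
#'
#' Used by the simulator: a step leaving the polygon is folded back across
#' the crossed edge. After a few folds without success the mover stays put.
#'
#' @param domain a [wing_domain()].
#' @param from n x 2 matrix of current positions (inside).
#' @param to n x 2 matrix of proposed positions.
#' @return n x 2 matrix of resolved positions, all inside the domain.
#' @keywords internal
reflect_into_domain <- function(domain, from, to) {
  inside <- domain_contains(domain, to)
  if (all(inside)) return(to)
  idx <- which(!inside)
  ring <- domain$boundary
  n <- nrow(ring)
  e1 <- ring
  e2 <- ring[c(2:n, 1), , drop = FALSE]
  for (i in idx) {
    p <- from[i, ]; q <- to[i, ]
    ok <- FALSE
    for (fold in 1:4) {
      hit <- .first_edge_hit(p, q, e1, e2)
      if (is.null(hit)) break
      q <- .reflect_point(q, e1[hit, ], e2[hit, ])
      if (domain_contains(domain, rbind(q))) { ok <- TRUE; break }
    }
    to[i, ] <- if (ok) q else p
  }
  to
}

.first_edge_hit <- function(p, q, e1, e2) {
  # parametric intersection of segment p->q with each boundary edge
  r <- q - p
  sx <- e2[, 1] - e1[, 1]; sy <- e2[, 2] - e1[, 2]
  denom <- r[1] * sy - r[2] * sx
  tnum <- (e1[, 1] - p[1]) * sy - (e1[, 2] - p[2]) * sx
  unum <- (e1[, 1] - p[1]) * r[2] - (e1[, 2] - p[2]) * r[1]
  with_denom <- abs(denom) > 1e-12
  t <- ifelse(with_denom, tnum / denom, NA_real_)
  u <- ifelse(with_denom, unum / denom, NA_real_)
  valid <- !is.na(t) & t > 1e-9 & t <= 1 & u >= 0 & u <= 1
  if (!any(valid)) return(NULL)
  which.min(ifelse(valid, t, Inf))
}

.reflect_point <- function(q, a, b) {
  # reflect q across the infinite line through edge (a, b)
  d <- b - a
  d <- d / sqrt(sum(d^2))
  v <- q - a
  proj <- sum(v * d) * d
  perp <- v - proj
  a + proj - perp
}
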