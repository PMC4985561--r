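#' Construct a single cell track
#'
#' @param cell_id identifier (character or numeric).
#' @param times strictly increasing sample times in minutes.
#' @param positions n x 2 matrix of (x, y) positions in micrometres.
#' @param dt_tol relative tolerance on frame-interval uniformity (default
#'   5\%).
#' @return an object of class `cell_track`.
#' @export
cell_track <- function(cell_id, times, positions, dt_tol = 0.05) {
  positions <- matrix(as.numeric(as.matrix(positions)), ncol = 2)
  times <- as.numeric(times)
  if (length(times) < 2) stopf("track %s: need >= 2 samples", cell_id)
  if (nrow(positions) != length(times))
    stopf("track %s: times/positions length mismatch", cell_id)
  dt <- diff(times)
  if (any(dt <= 0)) stopf("track %s: non-monotone times", cell_id)
  if (diff(range(dt)) > dt_tol * stats::median(dt))
    stopf("track %s: non-uniform frame interval (tolerance %.0f%%)",
          cell_id, 100 * dt_tol)
  structure(list(cell_id = cell_id, times = times, positions = positions,
                 dt = stats::median(dt)),
            class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track> %s: %d samples, t = [%.1f, %.1f] min, dt = %.2f\n",
              x$cell_id, length(x$times), min(x$times), max(x$times), x$dt))
  invisible(x)
}

#' Load cell tracks from a trajectory table
#'
#' Reads the standard trajectory CSV dialect (`cell_id,t_min,x_um,y_um`
#' with optional `z_um`), projects to the wing plane by dropping `z`,
#' clips each track to the samples inside the wing domain (a track is split
#' at excursions outside, and at frame gaps), and discards fragments
#' shorter than `min_len` samples.
#'
#' @param file path to a CSV file, or a data.frame with the same columns.
#' @param domain a [wing_domain()]; `NULL` skips domain filtering.
#' @param min_len minimum number of samples per retained track fragment.
#' @param dt_tol frame-interval tolerance passed to [cell_track()].
#' @return list of [cell_track()]s, with an attribute `report` (counts of
#'   rows read, tracks formed, fragments discarded, samples clipped).
#' @export
load_tracks <- function(file, domain = NULL, min_len = 3, dt_tol = 0.05) {
  df <- if (is.data.frame(file)) file else {
    if (!file.exists(file)) stopf("trajectory file not found: %s", file)
    read.csv(file, stringsAsFactors = FALSE)
  }
  need <- c("cell_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stopf("trajectory table must have columns %s", paste(need, collapse = ", "))
  bad <- which(!stats::complete.cases(df[need]) |
                 !is.finite(df$t_min) | !is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad))
    stopf("malformed trajectory row(s): %s", paste(head(bad, 5), collapse = ", "))
  n_rows <- nrow(df)
  df <- df[order(df$cell_id, df$t_min), , drop = FALSE]

  clipped <- 0L
  tracks <- list()
  discarded <- 0L
  for (id in unique(df$cell_id)) {
    sub <- df[df$cell_id == id, , drop = FALSE]
    if (anyDuplicated(sub$t_min))
      stopf("non-monotone or duplicated times for cell %s", id)
    keep <- if (is.null(domain)) rep(TRUE, nrow(sub)) else
      domain_contains(domain, cbind(sub$x_um, sub$y_um))
    clipped <- clipped + sum(!keep)
    # split into maximal runs of retained, frame-contiguous samples
    dt <- stats::median(diff(sub$t_min))
    gap <- c(FALSE, diff(sub$t_min) > (1 + 0.5) * dt)
    run <- cumsum(!keep | gap)
    for (r in split(which(keep), run[keep])) {
      if (length(r) < max(2, min_len)) { discarded <- discarded + 1L; next }
      frag_id <- if (length(unique(run[keep])) > 1)
        paste0(id, ".", run[r[1]] + 1) else id
      tracks[[length(tracks) + 1L]] <-
        cell_track(frag_id, sub$t_min[r], cbind(sub$x_um[r], sub$y_um[r]),
                   dt_tol = dt_tol)
    }
  }
  attr(tracks, "report") <- list(rows = n_rows,
                                 cells = length(unique(df$cell_id)),
                                 tracks = length(tracks),
                                 discarded_fragments = discarded,
                                 samples_clipped = clipped)
  tracks
}

#' Compute step records (motion vectors and angles) for a track
#'
#' Each consecutive position pair defines a motion vector with heading
#' `theta_t`. The turning angle `alpha_t` is the wrapped difference from
#' the previous heading (defined from the second step on) and the wound
#' angle `beta_t` is the wrapped difference between the heading and the
#' direction from the step origin toward the wound centre. Zero-length
#' steps have no defined heading; they are excluded from the angle record
#' and counted in the `stationary` attribute.
#'
#' @param track a [cell_track()].
#' @param wound a [wound_event()], or `NULL` for unwounded data, in which
#'   case `beta` is computed against `ref_point`.
#' @param distance_ref `"edge"` (default) or `"center"`: convention for the
#'   reported distance-to-wound `d`.
#' @param ref_point reference point used when `wound` is `NULL`.
#' @return data.frame of step records: `cell_id, t, x, y, theta, alpha,
#'   beta, d, len`, one row per non-degenerate step; `alpha` is `NA` on each
#'   track's first step.
#' @export
compute_steps <- function(track, wound = NULL,
                          distance_ref = c("edge", "center"),
                          ref_point = NULL) {
  distance_ref <- match.arg(distance_ref)
  pos <- track$positions
  n <- nrow(pos)
  dx <- diff(pos[, 1]); dy <- diff(pos[, 2])
  len <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  theta[len == 0] <- NA_real_
  origin <- pos[-n, , drop = FALSE]
  t_step <- track$times[-n]
  target <- if (!is.null(wound)) wound$center else ref_point
  if (is.null(target))
    stopf("no wound and no ref_point: cannot define beta")
  phi <- atan2(target[2] - origin[, 2], target[1] - origin[, 1])
  beta <- wrap_angle(theta - phi)
  # alpha relative to the previous *defined* heading
  prev <- c(NA_real_, theta[-length(theta)])
  alpha <- wrap_angle(theta - prev)
  d <- if (!is.null(wound)) wound_distance(wound, origin, ref = distance_ref)
  else sqrt((origin[, 1] - target[1])^2 + (origin[, 2] - target[2])^2)
  out <- data.frame(cell_id = track$cell_id, t = t_step,
                    x = origin[, 1], y = origin[, 2],
                    theta = theta, alpha = alpha, beta = beta,
                    d = d, len = len, stringsAsFactors = FALSE)
  stationary <- sum(len == 0)
  out <- out[len > 0, , drop = FALSE]
  attr(out, "stationary") <- stationary
  out
}

#' Compute step records for many tracks
#'
#' @param tracks list of [cell_track()]s.
#' @inheritParams compute_steps
#' @return combined step data.frame (see [compute_steps()]), with a
#'   `stationary` attribute totalled over tracks.
#' @export
compute_steps_all <- function(tracks, wound = NULL,
                              distance_ref = c("edge", "center"),
                              ref_point = NULL) {
  distance_ref <- match.arg(distance_ref)
  parts <- lapply(tracks, compute_steps, wound = wound,
                  distance_ref = distance_ref, ref_point = ref_point)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "stationary") <- sum(vapply(parts, attr, 0L, "stationary"))
  out
}

#' Spatiotemporal cluster grid specification
#'
#' Default grid: five spatial bands of 100 um from the wound (S1--S5) and
#' five temporal windows of 20 min from the wounding time (T1--T5), the
#' grouping under which bias and persistence are estimated.
#'
#' @param space_edges increasing band edges in um (half-open `[lo, hi)`).
#' @param time_edges increasing window edges in minutes post-wounding.
#' @return object of class `cluster_grid_spec`.
#' @export
cluster_grid_spec <- function(space_edges = seq(0, 500, by = 100),
                              time_edges = seq(0, 100, by = 20)) {
  stopifnot(length(space_edges) >= 2, length(time_edges) >= 2,
            !is.unsorted(space_edges, strictly = TRUE),
            !is.unsorted(time_edges, strictly = TRUE))
  structure(list(space_edges = space_edges, time_edges = time_edges),
            class = "cluster_grid_spec")
}

#' Assign steps to spatiotemporal clusters
#'
#' Steps are pooled by distance band and time window, both half-open
#' `[lo, hi)`. Steps before the wounding time or outside the configured
#' ranges are labelled `"out"` and retained.
#'
#' @param steps step data.frame from [compute_steps_all()].
#' @param spec a [cluster_grid_spec()].
#' @param t0 wounding time (min) subtracted from step times.
#' @return object of class `cluster_grid`: the spec, the step table with
#'   `space_bin`/`time_bin`/`cluster` columns, and a count matrix
#'   (bands x windows) plus `n_out`.
#' @export
cluster_steps <- function(steps, spec = cluster_grid_spec(), t0 = 0) {
  se <- spec$space_edges; te <- spec$time_edges
  ns <- length(se) - 1; nt <- length(te) - 1
  rel_t <- steps$t - t0
  sb <- findInterval(steps$d, se, rightmost.closed = FALSE, left.open = FALSE)
  sb[steps$d >= se[length(se)]] <- NA
  sb[sb == 0] <- NA
  tb <- findInterval(rel_t, te)
  tb[rel_t >= te[length(te)]] <- NA
  tb[tb == 0 | rel_t < te[1]] <- NA
  steps$space_bin <- sb
  steps$time_bin <- tb
  steps$cluster <- ifelse(is.na(sb) | is.na(tb), "out",
                          paste0("S", sb, ".T", tb))
  counts <- matrix(0L, ns, nt,
                   dimnames = list(paste0("S", seq_len(ns)),
                                   paste0("T", seq_len(nt))))
  tab <- table(steps$cluster[steps$cluster != "out"])
  for (nm in names(tab)) {
    ij <- as.integer(sub("S", "", strsplit(nm, "\\.T")[[1]]))
    counts[ij[1], ij[2]] <- as.integer(tab[[nm]])
  }
  structure(list(spec = spec, t0 = t0, steps = steps, counts = counts,
                 n_out = sum(steps$cluster == "out")),
            class = "cluster_grid")
}

#' @export
print.cluster_grid <- function(x, ...) {
  cat(sprintf("<cluster_grid> %d steps (%d out of range)\n",
              nrow(x$steps), x$n_out))
  print(x$counts)
  invisible(x)
}
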