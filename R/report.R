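#' Render per-band bias curves and attractant heatmaps
#'
#' Writes figure files matching the display conventions used throughout
#' the package: per-spatial-band bias-vs-time curves (posterior median
#' with interquartile band; empty clusters are missing, not zero) and,
#' when a field is supplied, heatmaps of attractant concentration rescaled
#' to 0--100% of the maximum.
#'
#' @param cp a `cluster_posteriors` from [infer_clusters()].
#' @param dir output directory.
#' @param field optional `field_grid` from [bounded_field()] for heatmaps.
#' @param measure `"b"` or `"wb"` (see [bias_wave_summary()]).
#' @return character vector of files written, invisibly.
#' @export
render_bias_heatmaps <- function(cp, dir, field = NULL,
                                 measure = c("wb", "b")) {
  measure <- match.arg(measure)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  po <- cp$posteriors
  ns <- nrow(po); nt <- ncol(po)
  tmid <- (head(cp$spec$time_edges, -1) + tail(cp$spec$time_edges, -1)) / 2
  f1 <- file.path(dir, "bias_curves.png")
  grDevices::png(f1, width = 900, height = 600)
  graphics::par(mar = c(4.5, 4.5, 2, 1))
  graphics::plot(NULL, xlim = range(cp$spec$time_edges), ylim = c(0, 1),
                 xlab = "time post-wounding (min)", ylab = "bias (posterior)",
                 main = sprintf("per-band %s", measure))
  cols <- grDevices::hcl.colors(ns, "Zissou 1")
  for (i in seq_len(ns)) {
    med <- q25 <- q75 <- rep(NA_real_, nt)
    for (j in seq_len(nt)) {
      ps <- po[[i, j]]
      if (isTRUE(ps$insufficient)) next
      v <- if (measure == "b") ps$draws[, "b"] else
        ps$draws[, "b"] * ps$draws[, "w"]
      med[j] <- median(v); q25[j] <- quantile(v, .25); q75[j] <- quantile(v, .75)
    }
    ok <- !is.na(med)
    if (!any(ok)) next
    graphics::polygon(c(tmid[ok], rev(tmid[ok])), c(q25[ok], rev(q75[ok])),
                      col = grDevices::adjustcolor(cols[i], 0.25), border = NA)
    graphics::lines(tmid[ok], med[ok], col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = rownames(po), col = cols, lwd = 2,
                   bty = "n")
  grDevices::dev.off()
  files <- c(files, f1)
  if (!is.null(field)) {
    cmax <- max(field$C)
    for (k in seq_along(field$times)) {
      fk <- file.path(dir, sprintf("attractant_t%03d.png",
                                   round(field$times[k])))
      grDevices::png(fk, width = 700, height = 450)
      M <- field$C[, , k] / cmax * 100
      M[field$mask == 0L] <- NA
      graphics::image(field$x, field$y, M, zlim = c(0, 100), asp = 1,
                      col = grDevices::hcl.colors(64, "Inferno"),
                      xlab = "x (um)", ylab = "y (um)",
                      main = sprintf("attractant, %% of max, t = %g min",
                                     field$times[k]))
      grDevices::dev.off()
      files <- c(files, fk)
    }
  }
  invisible(files)
}

#' Early-window wound prognosis (healer vs non-healer)
#'
#' Classifies a wound from the first hour of hemocyte behaviour: fits the
#' BPRW posterior on steps in the first spatial band (0--100 um) within
#' the early window, then applies the rule that a chronic (non-healing)
#' wound shows BOTH low early bias and reduced persistence. When the 90%
#' credible intervals straddle the thresholds the call is indeterminate.
#'
#' @param tracks list of [cell_track()]s (only the first `early_window`
#'   minutes are used).
#' @param wound a [wound_event()].
#' @param theta_b observed-bias threshold (posterior median of the
#'   composite `w * b` below this = chronic-like). The default 0.1 sits
#'   between the early-band composite bias of healthy reference wounds
#'   (~0.2) and of chronic-like cohorts (~0.03).
#' @param theta_p persistence threshold; default `baseline_p - 0.1`, with
#'   `baseline_p` the persistence of the healthy reference world.
#' @param early_window minutes post-wounding used for the fit (default 30,
#'   where the band evidence is strongest).
#' @param min_steps minimum usable steps in the early near band.
#' @param seed integer seed.
#' @return object of class `wound_prognosis`: `call` (`"healer"`,
#'   `"non-healer"` or `"indeterminate"`), the posterior evidence summary
#'   and the thresholds used.
#' @export
prognose_wound <- function(tracks, wound, theta_b = 0.1,
                           theta_p = reference_params()$bprw$p - 0.1,
                           early_window = 30, min_steps = 50, seed = 1) {
  steps <- compute_steps_all(tracks, wound = wound)
  sel <- steps$d < 100 & steps$t >= wound$t0 &
    steps$t < wound$t0 + early_window
  ps <- infer_cluster_params(steps[sel, , drop = FALSE],
                             min_steps = min_steps, seed = seed)
  if (isTRUE(ps$insufficient)) {
    return(structure(list(call = "indeterminate",
                          reason = paste("insufficient early data:", ps$reason),
                          posterior = ps,
                          thresholds = c(theta_b = theta_b, theta_p = theta_p)),
                     class = "wound_prognosis"))
  }
  # observed bias = w * b: identifiable even when the biased component is
  # unused (w -> 0 leaves b prior-wide in an unbiased cohort)
  bq <- quantile(ps$draws[, "b"] * ps$draws[, "w"], c(.05, .5, .95))
  pq <- quantile(ps$draws[, "p"], c(.05, .5, .95))
  low_b <- bq[2] < theta_b
  low_p <- pq[2] < theta_p
  b_straddles <- bq[1] < theta_b && bq[3] > theta_b
  p_straddles <- pq[1] < theta_p && pq[3] > theta_p
  call <- if (b_straddles && p_straddles) "indeterminate"
  else if (low_b && low_p) "non-healer" else "healer"
  structure(list(call = call,
                 evidence = list(bias = bq, persistence = pq,
                                 n_steps = ps$n_steps),
                 posterior = ps,
                 thresholds = c(theta_b = theta_b, theta_p = theta_p)),
            class = "wound_prognosis")
}

#' @export
print.wound_prognosis <- function(x, ...) {
  cat(sprintf("<wound_prognosis> %s\n", x$call))
  if (!is.null(x$evidence)) {
    cat(sprintf("  early bias median %.3f (threshold %.2f), persistence %.3f (threshold %.2f)\n",
                x$evidence$bias[2], x$thresholds["theta_b"],
                x$evidence$persistence[2], x$thresholds["theta_p"]))
  }
  if (!is.null(x$reason)) cat("  ", x$reason, "\n")
  invisible(x)
}

#' Compare bias between two regions by credible-interval overlap
#'
#' The package's stand-in for "significantly reduced" statements: bias in
#' region A is called reduced relative to region B when the 90% credible
#' intervals of the two posteriors do not overlap and A's median is lower.
#'
#' @param ps_a,ps_b `posterior_sample`s (cluster fits).
#' @param param parameter to compare: `"wb"` (composite observed bias,
#'   default), `"b"`, `"p"` or `"w"`.
#' @return list with `reduced` (logical), medians and the two intervals.
#' @export
region_bias_reduced <- function(ps_a, ps_b, param = "wb") {
  ext <- function(ps) if (param == "wb") ps$draws[, "b"] * ps$draws[, "w"]
  else ps$draws[, param]
  qa <- quantile(ext(ps_a), c(.05, .5, .95))
  qb <- quantile(ext(ps_b), c(.05, .5, .95))
  list(reduced = qa[3] < qb[1], median_a = qa[2], median_b = qb[2],
       ci_a = qa[c(1, 3)], ci_b = qb[c(1, 3)])
}
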