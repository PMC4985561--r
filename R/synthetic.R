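#' Generate a synthetic trajectory dataset with known ground truth
#'
#' Runs the agent-based simulator for a scenario preset and corrupts the
#' tracks the way nuclear tracking does: additive isotropic Gaussian
#' positional noise and per-frame detection dropout. Dropout splits tracks
#' at the gap (interpolating would fabricate headings). A ground-truth
#' manifest sufficient to regenerate the dataset bit-for-bit is attached
#' (and written when `out_csv` is given).
#'
#' @param preset scenario preset name (see [scenario_presets()]).
#' @param overrides named list of [scenario_spec()] overrides.
#' @param noise list with `sigma` (positional sd, um; sane range <= 2) and
#'   `dropout` (per-frame detection failure probability; <= 0.2).
#' @param seed integer seed (drives simulation and corruption).
#' @param out_csv optional path: write the trajectory CSV and, alongside
#'   it, `<name>_manifest.json`.
#' @return list with `tracks` (corrupted, split at gaps), `sim` (the clean
#'   simulation with ground truth) and `manifest`.
#' @export
generate_dataset <- function(preset, overrides = list(),
                             noise = list(sigma = 0.5, dropout = 0.02),
                             seed = 1, out_csv = NULL) {
  if (noise$sigma > 2) stopf("positional noise sigma > 2 um is not sane")
  if (noise$dropout > 0.2) stopf("dropout > 0.2 is not sane")
  sim <- {
    presets <- scenario_presets()
    if (!preset %in% names(presets))
      stopf("unknown preset '%s'; available: %s", preset,
            paste(names(presets), collapse = ", "))
    spec <- presets[[preset]]()
    for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]
    simulate_cohort(spec, seed = derive_seed(seed, 1))
  }
  set.seed(derive_seed(seed, 2))
  tracks <- list()
  for (tr in sim$tracks) {
    n <- length(tr$times)
    keep <- runif(n) >= noise$dropout
    pos <- tr$positions + matrix(rnorm(2 * n, sd = noise$sigma), n, 2)
    if (sum(keep) < 2) next
    runs <- split(which(keep), cumsum(!keep)[keep])
    k <- 0
    for (r in runs) {
      if (length(r) < 2) next
      k <- k + 1
      frag_id <- if (length(runs) > 1) paste0(tr$cell_id, ".", k) else tr$cell_id
      tracks[[length(tracks) + 1L]] <-
        cell_track(frag_id, tr$times[r], pos[r, , drop = FALSE])
    }
  }
  manifest <- list(preset = preset, overrides = overrides, noise = noise,
                   seed = seed,
                   params = rapply(sim$spec$params, identity, how = "list"),
                   n_cells = sim$spec$n_cells,
                   duration = sim$spec$duration, dt = sim$spec$dt,
                   wounds = lapply(sim$spec$wounds, unclass),
                   package = as.character(utils::packageVersion("hemotaxis")))
  if (!is.null(out_csv)) {
    write_tracks_csv(tracks, out_csv)
    write_json_config(manifest,
                      file.path(dirname(out_csv),
                                paste0(tools::file_path_sans_ext(basename(out_csv)),
                                       "_manifest.json")))
  }
  list(tracks = tracks, sim = sim, manifest = manifest)
}

#' Regenerate a dataset from its manifest
#'
#' @param manifest a manifest list (or path to a manifest JSON).
#' @return as [generate_dataset()].
#' @export
regenerate_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read_json_config(manifest)
  generate_dataset(manifest$preset,
                   overrides = manifest$overrides %||% list(),
                   noise = manifest$noise, seed = manifest$seed)
}

#' Write the canonical fixture suite
#'
#' Small datasets covering the modelled experimental conditions: unwounded
#' control, the three single wound sizes, the three double-wound
#' separations, the two sequential-wound offsets, and healer-like /
#' non-healer-like chronic cohorts. Sizes are scaled by `cells` and
#' `duration` so the suite stays desk-sized.
#'
#' @param dir output directory (created if needed).
#' @param cells cohort size per fixture.
#' @param duration recording length, min.
#' @param seed master seed.
#' @return named character vector of CSV paths, invisibly.
#' @export
make_fixture_suite <- function(dir, cells = 150, duration = 60, seed = 99) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  names <- c("unwounded", "single_small", "single_large", "single_xl",
             "double_close", "double_mid", "double_far",
             "sequential_90min", "sequential_3hr", "healer", "nonhealer")
  out <- character(0)
  for (i in seq_along(names)) {
    nm <- names[i]
    ov <- list(n_cells = cells)
    # sequential scenarios need to cover the second wound
    if (!startsWith(nm, "sequential")) ov$duration <- duration
    path <- file.path(dir, paste0(nm, ".csv"))
    generate_dataset(nm, overrides = ov, seed = derive_seed(seed, i),
                     out_csv = path)
    out[nm] <- path
  }
  invisible(out)
}
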