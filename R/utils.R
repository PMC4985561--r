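#' Wrap angles to the principal interval
#'
#' Maps any angle (radians) to `(-pi, pi]`.
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length, each element in `(-pi, pi]`.
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # %% maps pi to -pi; keep the closed upper end instead
  y[y == -pi] <- pi
  y
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a child RNG seed from a master seed
#'
#' Deterministic stream splitting used so that one `--seed` drives every
#' random component without reuse. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param k stream index (>= 0).
#' @return integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1103 * as.double(k) + 7919) %%
    2147483629)
}

#' Read or write a JSON config/manifest
#'
#' Thin wrappers around jsonlite with the conventions used throughout the
#' package (auto-unboxing, no digit truncation).
#'
#' @param x list to serialise.
#' @param path file path.
#' @return `read_json_config` returns a list; `write_json_config` returns
#'   `path` invisibly.
#' @export
write_json_config <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_json_config
#' @export
read_json_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @keywords internal
hash_data <- function(x) {
  # content hash for guarding model comparisons; digest is not a dependency,
  # so serialize and fold bytes
  raw <- serialize(x, NULL, version = 2)
  as.character(sum(as.double(raw) * seq_along(raw)) %% 2147483647)
}

#' Posterior percentile summary
#'
#' Percentile convention used for all reported posteriors: 5, 25, 50, 75, 95
#' (the box-and-whisker convention of the reporting layer).
#'
#' @param draws numeric vector of posterior draws.
#' @return named numeric vector of the five percentiles.
#' @export
posterior_percentiles <- function(draws) {
  quantile(draws, probs = c(0.05, 0.25, 0.5, 0.75, 0.95), names = TRUE,
           na.rm = TRUE)
}
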