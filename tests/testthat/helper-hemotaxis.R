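# shared fixtures, all generated in code

square_domain <- function(half = 400) {
  wing_domain(cbind(c(-half, half, half, -half), c(-half, -half, half, half)))
}

# straight-line track builder
line_track <- function(id, from, step, n, dt = 1) {
  t <- seq(0, by = dt, length.out = n)
  pos <- cbind(from[1] + (0:(n - 1)) * step[1], from[2] + (0:(n - 1)) * step[2])
  cell_track(id, t, pos)
}

# BPRW steps at known parameters, independent of the simulator
make_bprw_steps <- function(n, b, p, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th_prev <- runif(n, -pi, pi)
  phi <- runif(n, -pi, pi)
  th <- sample_step(th_prev, phi, bprw_params(b, p, w))
  data.frame(alpha = wrap_angle(th - th_prev), beta = wrap_angle(th - phi))
}

mrl_of <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean(cos(x))^2 + mean(sin(x))^2)
}

signed_bias <- function(beta) {
  beta <- beta[is.finite(beta)]
  mrl_of(beta) * sign(mean(cos(beta)))
}

# memoised expensive artifacts shared across test files
.fixture_env <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small/large joint synthetic dataset + gradient fit used by several tests
shared_gradient_fit <- function() {
  memo("gradient_fit", {
    ds_small <- generate_dataset("single_small",
                                 overrides = list(n_cells = 150, duration = 60),
                                 seed = 11)
    ds_large <- generate_dataset("single_large",
                                 overrides = list(n_cells = 150, duration = 60),
                                 seed = 12)
    mk <- function(ds) {
      w <- ds$sim$spec$wounds[[1]]
      list(steps = compute_steps_all(ds$tracks, wound = w), wound = w)
    }
    datasets <- list(mk(ds_small), mk(ds_large))
    fit <- infer_gradient_model(datasets, "margin_ring", n_iter = 1500,
                                chains = 2, seed = 5)
    list(datasets = datasets, fit = fit)
  })
}
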