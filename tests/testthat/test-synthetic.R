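test_that("noise-free generation equals the raw simulator output", {
  ds <- generate_dataset("single_small",
                         overrides = list(n_cells = 30, duration = 20),
                         noise = list(sigma = 0, dropout = 0), seed = 9)
  expect_equal(length(ds$tracks), length(ds$sim$tracks))
  for (i in seq_along(ds$tracks)) {
    expect_equal(ds$tracks[[i]]$positions, ds$sim$tracks[[i]]$positions)
  }
})

test_that("fixed seed regenerates byte-identical output", {
  out <- withr::local_tempdir()
  f1 <- file.path(out, "a.csv"); f2 <- file.path(out, "b.csv")
  generate_dataset("single_small",
                   overrides = list(n_cells = 25, duration = 15),
                   seed = 5, out_csv = f1)
  generate_dataset("single_small",
                   overrides = list(n_cells = 25, duration = 15),
                   seed = 5, out_csv = f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the manifest regenerates the CSV exactly
  man <- read_json_config(file.path(out, "a_manifest.json"))
  ds <- regenerate_dataset(man)
  f3 <- file.path(out, "c.csv")
  write_tracks_csv(ds$tracks, f3)
  expect_identical(readLines(f1), readLines(f3))
})

test_that("dropout splits tracks instead of interpolating", {
  set.seed(30)
  ds <- generate_dataset("single_small",
                         overrides = list(n_cells = 40, duration = 40),
                         noise = list(sigma = 0, dropout = 0.15), seed = 31)
  # more fragments than cells, and every fragment frame-contiguous
  expect_gt(length(ds$tracks), 40)
  for (tr in ds$tracks) expect_true(all(abs(diff(tr$times) - 1) < 1e-9))
})

test_that("insane noise settings are rejected", {
  expect_error(generate_dataset("single_small",
                                noise = list(sigma = 5, dropout = 0)),
               "sigma")
  expect_error(generate_dataset("single_small",
                                noise = list(sigma = 0, dropout = 0.5)),
               "dropout")
  expect_error(generate_dataset("not_a_preset"), "unknown preset")
})

test_that("positional noise produces the predicted heading jitter", {
  # DERIVED: straight track with speed v and noise sigma on both endpoints:
  # heading error ~ atan(noise_perp / v); simulated angle variance should
  # match the linearized prediction within 15%
  sigma <- 1; v <- 10
  set.seed(44)
  n <- 20000
  x <- seq_len(n) * v
  noisy <- cbind(x + rnorm(n, sd = sigma), rnorm(n, sd = sigma))
  th <- atan2(diff(noisy[, 2]), diff(noisy[, 1]))
  # alpha_i = (y_{i+2} - 2 y_{i+1} + y_i) / v to first order, so
  # var(alpha) = 6 sigma^2 / v^2
  alpha <- wrap_angle(diff(th))
  pred <- 6 * sigma^2 / v^2
  expect_lt(abs(var(alpha) - pred) / pred, 0.15)
})

test_that("statistical structure matches the intended data shape", {
  ds <- generate_dataset("single_large", seed = 50)
  w <- ds$sim$spec$wounds[[1]]
  steps <- compute_steps_all(ds$tracks, wound = w)
  cg <- cluster_steps(steps, t0 = 0)
  # hundreds of cells; every near-wound cluster (S1-S2, all windows) has
  # >= 50 steps; all five bands populated
  expect_gte(length(ds$sim$tracks), 300)
  expect_true(all(cg$counts[1:2, ] >= 50))
  expect_true(all(rowSums(cg$counts) > 0))
})

test_that("inference error grows monotonically with positional noise", {
  # empirical S1-band observed bias degrades with sigma; averaged over seeds
  biases <- sapply(c(0, 1, 2), function(sg) {
    mean(vapply(1:3, function(s) {
      ds <- generate_dataset("single_large",
                             overrides = list(n_cells = 150, duration = 40),
                             noise = list(sigma = sg, dropout = 0),
                             seed = derive_seed(400, s))
      w <- ds$sim$spec$wounds[[1]]
      steps <- compute_steps_all(ds$tracks, wound = w)
      sel <- steps$d < 100 & steps$t < 40
      signed_bias(steps$beta[sel])
    }, numeric(1)))
  })
  # true S1 bias is high; the measured bias decays as noise grows
  expect_true(all(diff(biases) < 0))
})

test_that("fixture suite covers the canonical conditions", {
  out <- withr::local_tempdir()
  files <- make_fixture_suite(out, cells = 40, duration = 25, seed = 2)
  expect_setequal(names(files),
                  c("unwounded", "single_small", "single_large", "single_xl",
                    "double_close", "double_mid", "double_far",
                    "sequential_90min", "sequential_3hr", "healer",
                    "nonhealer"))
  expect_true(all(file.exists(files)))
  expect_true(all(file.exists(file.path(out, paste0(names(files),
                                                    "_manifest.json")))))
  # unwounded fixture: observed bias is low end-to-end
  tracks <- load_tracks(files[["unwounded"]], domain = default_wing())
  steps <- compute_steps_all(tracks, ref_point = c(0, 0))
  ps <- infer_cluster_params(steps, n_iter = 1200, chains = 2, seed = 1)
  expect_lt(median(ps$draws[, "b"] * ps$draws[, "w"]), 0.1)
  # non-healer fixture shows less persistence than the healer fixture
  fit_p <- function(f, w) {
    tracks <- load_tracks(f, domain = default_wing())
    steps <- compute_steps_all(tracks, wound = w)
    sel <- steps$d < 200 & steps$t < 25
    infer_cluster_params(steps[sel, ], n_iter = 1200, chains = 2,
                         seed = 4)$percentiles["50%", "p"]
  }
  w_xl <- wound_event(c(0, 0), 65)
  expect_lt(fit_p(files[["nonhealer"]], w_xl), fit_p(files[["healer"]], w_xl))
})
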