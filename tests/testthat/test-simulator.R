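test_that("identical spec and seed give identical tracks", {
  pres <- scenario_presets()
  spec <- pres$single_small(); spec$n_cells <- 40; spec$duration <- 20
  s1 <- simulate_cohort(spec, seed = 123)
  s2 <- simulate_cohort(spec, seed = 123)
  expect_identical(s1$tracks, s2$tracks)
  s3 <- simulate_cohort(spec, seed = 124)
  expect_false(identical(s1$tracks, s3$tracks))
})

test_that("cells stay inside the domain", {
  pres <- scenario_presets()
  spec <- pres$single_large(); spec$n_cells <- 60; spec$duration <- 40
  sim <- simulate_cohort(spec, seed = 5)
  pos <- do.call(rbind, lapply(sim$tracks, function(tr) tr$positions))
  expect_true(all(domain_contains(spec$domain, pos)))
})

test_that("unwounded cohort round-trips its generating parameters", {
  pres <- scenario_presets()
  spec <- pres$unwounded(); spec$n_cells <- 200; spec$duration <- 60
  sim <- simulate_cohort(spec, seed = 8)
  steps <- compute_steps_all(sim$tracks, ref_point = c(0, 0))
  ps <- infer_cluster_params(steps, n_iter = 2000, chains = 2, seed = 4)
  # persistence recovered; observed bias (w b) near zero
  expect_lt(abs(ps$percentiles["50%", "p"] - spec$params$bprw$p), 0.05)
  wb <- median(ps$draws[, "b"] * ps$draws[, "w"])
  expect_lt(wb, 0.08)
})

test_that("recruitment counting", {
  w <- wound_event(c(0, 0), 20)
  # scripted tracks: 7 of 50 pass through the arrival disc
  tracks <- lapply(1:50, function(i) {
    if (i <= 7) line_track(paste0("in", i), c(200, i * 3), c(-20, 0), 15)
    else line_track(paste0("out", i), c(200, 100 + i), c(0, 2), 15)
  })
  expect_equal(recruitment_count(tracks, w, arrival_radius = 30), 7)
  expect_equal(recruitment_count(tracks[8:50], w, arrival_radius = 30), 0)
  # all cells starting inside count once each
  inside <- lapply(1:5, function(i) line_track(paste0("i", i), c(1, i), c(0.1, 0), 4))
  expect_equal(recruitment_count(inside, w, arrival_radius = 30), 5)
  expect_error(recruitment_count(tracks, w, arrival_radius = 10), ">=")
  # time window restricts counting
  expect_equal(recruitment_count(tracks, w, arrival_radius = 30,
                                 window = c(0, 2)), 0)
})

test_that("CIL: null contact radius is bitwise neutral; head-on cells reverse", {
  pres <- scenario_presets()
  spec <- pres$single_small(); spec$n_cells <- 30; spec$duration <- 15
  plain <- simulate_cohort(spec, seed = 77)
  null_cil <- simulate_with_cil(spec, cil = list(radius = 0, repol = 5),
                                seed = 77)
  expect_identical(plain$tracks, null_cil$tracks)

  # two isolated cells in contact at t = 0 repolarize directly apart and
  # separate monotonically through the repolarization window
  dom <- square_domain(200)
  rp <- reference_params()
  rp$bprw <- bprw_params(b = 0, p = 0.98, w = 0)
  spec2 <- scenario_spec(dom, list(), n_cells = 2, duration = 6, dt = 1,
                         params = rp, cil = list(radius = 8, repol = 4))
  sim2 <- simulate_cohort(spec2, seed = 42,
                          init_pos = rbind(c(-3, 0), c(3, 0)))
  xs1 <- sim2$tracks[[1]]$positions[, 1]
  xs2 <- sim2$tracks[[2]]$positions[, 1]
  gap <- xs2 - xs1
  expect_true(all(diff(gap[1:5]) > 0))
})

test_that("CIL reduces recruitment under paired seeds", {
  pres <- scenario_presets()
  spec <- pres$single_large(); spec$n_cells <- 250; spec$duration <- 50
  w <- spec$wounds[[1]]
  lower <- 0
  for (s in 1:3) {
    off <- simulate_cohort(spec, seed = derive_seed(5, s))
    on <- simulate_with_cil(spec, cil = list(radius = 10, repol = 5),
                            seed = derive_seed(5, s))
    c_off <- recruitment_count(off$tracks, w, arrival_radius = w$radius + 10)
    c_on <- recruitment_count(on$tracks, w, arrival_radius = w$radius + 10)
    lower <- lower + (c_on < c_off)
  }
  expect_gte(lower, 2)
})

test_that("scenario presets encode the experimental geometries", {
  pres <- scenario_presets()
  expect_setequal(names(pres),
                  c("unwounded", "single_small", "single_large", "single_xl",
                    "double_close", "double_mid", "double_far",
                    "sequential_90min", "sequential_3hr", "healer",
                    "nonhealer"))
  dc <- pres$double_close()
  sep <- abs(dc$wounds[[1]]$center[1] - dc$wounds[[2]]$center[1])
  expect_equal(sep, 150)
  expect_equal(abs(pres$double_mid()$wounds[[1]]$center[1] -
                     pres$double_mid()$wounds[[2]]$center[1]), 330)
  expect_equal(abs(pres$double_far()$wounds[[1]]$center[1] -
                     pres$double_far()$wounds[[2]]$center[1]), 480)
  expect_equal(pres$sequential_90min()$wounds[[2]]$t0, 90)
  expect_equal(pres$sequential_3hr()$wounds[[2]]$t0, 180)
  expect_equal(pres$single_small()$wounds[[1]]$radius, 27.5)
  expect_equal(pres$single_large()$wounds[[1]]$radius, 55)
  expect_equal(pres$single_xl()$wounds[[1]]$radius, 65)
  expect_true(pres$sequential_90min()$params$desens$enabled)
  expect_false(pres$single_large()$params$desens$enabled)
  expect_error(run_scenario("nope"), "unknown preset")
})

test_that("ensemble drift along the axis of two equal wounds is ~0", {
  pres <- scenario_presets()
  spec <- pres$double_mid(); spec$n_cells <- 150; spec$duration <- 30
  drift <- vapply(1:6, function(r) {
    sim <- simulate_cohort(spec, seed = derive_seed(99, r))
    mean(vapply(sim$tracks, function(tr)
      tr$positions[nrow(tr$positions), 1] - tr$positions[1, 1], numeric(1)))
  }, numeric(1))
  # mean x-displacement over replicates is small relative to track length
  expect_lt(abs(mean(drift)), 5)
})

test_that("run_scenario averages replicates and writes artifacts", {
  out <- withr::local_tempdir()
  run <- run_scenario("single_small",
                      overrides = list(n_cells = 50, duration = 30),
                      replicates = 2, seed = 3, out_dir = out)
  expect_equal(run$replicates, 2)
  expect_true(file.exists(file.path(out, "tracks.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(any(is.finite(run$summary)))
})
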