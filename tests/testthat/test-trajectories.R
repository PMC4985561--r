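test_that("load_tracks projects z, enforces schema and reports malformed rows", {
  df <- data.frame(cell_id = "a", t_min = 0:4, x_um = 0:4, y_um = 1,
                   z_um = 7)
  tr <- load_tracks(df, domain = NULL)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$positions, cbind(0:4, rep(1, 5)))

  bad <- df; bad$x_um[3] <- NA
  expect_error(load_tracks(bad), "malformed")
  dup <- rbind(df, df[2, ])
  expect_error(load_tracks(dup), "non-monotone|duplicated")
  expect_error(load_tracks(df[, 1:3]), "columns")
})

test_that("load_tracks clips to the domain and drops short fragments", {
  dom <- square_domain(100)
  # wholly outside
  out_df <- data.frame(cell_id = "out", t_min = 0:5, x_um = 500, y_um = 500)
  expect_length(load_tracks(out_df, dom), 0)

  # DERIVED: 100 synthetic tracks, 5 placed outside -> 95 retained
  set.seed(41)
  mk <- function(id, inside) {
    base <- if (inside) runif(2, -60, 60) else c(300, 300)
    data.frame(cell_id = id, t_min = 0:9,
               x_um = base[1] + cumsum(rnorm(10)),
               y_um = base[2] + cumsum(rnorm(10)))
  }
  df <- do.call(rbind, lapply(1:100, function(i) mk(sprintf("c%03d", i),
                                                    i > 5)))
  tr <- load_tracks(df, dom, min_len = 3)
  expect_equal(length(tr), 95)
  expect_equal(attr(tr, "report")$samples_clipped, 50)
})

test_that("compute_steps angle conventions", {
  wound <- wound_event(c(100, 0), 10)
  # radially toward the wound: beta = 0, alpha = 0
  tr <- line_track("in", c(0, 0), c(2, 0), 6)
  st <- compute_steps(tr, wound)
  expect_true(all(abs(st$beta) < 1e-12))
  expect_true(all(abs(st$alpha[-1]) < 1e-12))
  expect_true(is.na(st$alpha[1]))

  # radially away: beta = pi (wrapped)
  tr2 <- line_track("away", c(200, 0), c(2, 0), 5)
  st2 <- compute_steps(tr2, wound)
  expect_true(all(abs(abs(st2$beta) - pi) < 1e-12))

  # DERIVED by atan2: (0,0)->(1,0)->(1,1), wound far on +x axis
  tr3 <- cell_track("L", 0:2, rbind(c(0, 0), c(1, 0), c(1, 1)))
  st3 <- compute_steps(tr3, wound_event(c(1e6, 0), 1))
  expect_equal(st3$alpha[2], pi / 2, tolerance = 1e-6)
  expect_equal(st3$beta[2], pi / 2, tolerance = 1e-6)

  # unwounded data requires a reference point
  expect_error(compute_steps(tr, NULL), "ref_point")
  st4 <- compute_steps(tr, NULL, ref_point = c(100, 0))
  expect_equal(st4$beta, st$beta)
})

test_that("angles are invariant under global rotation and reversal flips", {
  set.seed(7)
  n <- 20
  pos <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))
  wound <- wound_event(c(30, -20), 5)
  st <- compute_steps(cell_track("x", 1:n, pos), wound)
  for (delta in c(0.7, -2.1)) {
    Rm <- matrix(c(cos(delta), sin(delta), -sin(delta), cos(delta)), 2)
    st_r <- compute_steps(cell_track("x", 1:n, pos %*% t(Rm)),
                          wound_event(drop(Rm %*% wound$center), 5))
    expect_equal(st_r$alpha, st$alpha, tolerance = 1e-9)
    expect_equal(st_r$beta, st$beta, tolerance = 1e-9)
  }
  # reversing the track preserves |alpha| in reversed order
  st_rev <- compute_steps(cell_track("x", 1:n, pos[n:1, ]), wound)
  a1 <- abs(st$alpha[-1])
  a2 <- rev(abs(st_rev$alpha[-1]))
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("zero-length steps are excluded and counted", {
  pos <- rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0))
  st <- compute_steps(cell_track("z", 1:4, pos), wound_event(c(10, 0), 1))
  expect_equal(nrow(st), 2)
  expect_equal(attr(st, "stationary"), 1L)
})

test_that("cluster assignment is a half-open exhaustive partition", {
  wound <- wound_event(c(0, 0), 10)
  set.seed(13)
  steps <- data.frame(cell_id = "c", t = runif(500, -10, 130),
                      x = 0, y = 0, theta = 0, alpha = 0, beta = 0,
                      d = runif(500, 0, 600), len = 1)
  cg <- cluster_steps(steps, t0 = 0)
  expect_equal(sum(cg$counts) + cg$n_out, nrow(steps))
  expect_false(any(duplicated(which(cg$steps$cluster != "out"))))

  # PAPER: d = 50, t - t0 = 10 -> S1.T1 (0-100 um band, first 20 min)
  one <- steps[1, ]; one$d <- 50; one$t <- 10
  expect_equal(cluster_steps(one, t0 = 0)$steps$cluster, "S1.T1")
  # boundary: d = 100 exactly -> S2 under the half-open convention
  one$d <- 100
  expect_equal(cluster_steps(one, t0 = 0)$steps$cluster, "S2.T1")
  # empty clusters are retained with count 0
  expect_true(any(cluster_steps(one, t0 = 0)$counts == 0))
})

test_that("track construction validates monotonicity and frame uniformity", {
  expect_error(cell_track("a", c(0, 2, 1), matrix(0, 3, 2)), "non-monotone")
  expect_error(cell_track("a", c(0, 1, 3), matrix(0, 3, 2)), "non-uniform")
  expect_error(cell_track("a", 1, matrix(0, 1, 2)), ">= 2")
})
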