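ref_wound <- wound_event(c(0, 0), 55)
ref_pars <- attractant_params(D = 200, T_prod = 30, q = 1)

test_that("ring source: r = 0 identity, emission conservation, decay input checks", {
  # at r = 0 the Bessel factor is 1: compare with the simplified integrand
  t <- 18
  direct <- integrate(function(u) 55 / (2 * 200 * u) *
                        exp(-55^2 / (4 * 200 * u)), 0, t,
                      rel.tol = 1e-9)$value
  expect_equal(ring_source_concentration(0, t, ref_wound, ref_pars), direct,
               tolerance = 1e-6)
  expect_error(ring_source_concentration(10, -1, ref_wound, ref_pars), ">= 0")
  expect_equal(ring_source_concentration(80, 0, ref_wound, ref_pars), 0)

  # DERIVED: total mass over the plane at t <= T equals q 2 pi R t (< 1%)
  rg <- seq(0, 1500, by = 2)
  C <- ring_source_concentration(rg, 20, ref_wound, ref_pars)
  mass <- sum(2 * pi * rg * C) * 2
  expect_lt(abs(mass - 2 * pi * 55 * 20) / (2 * pi * 55 * 20), 0.01)
})

test_that("ring profile matches a 720-point discrete-source oracle", {
  th <- 2 * pi * (seq_len(720) - 0.5) / 720
  xs <- 55 * cos(th); ys <- 55 * sin(th)
  q_per <- 2 * pi * 55 / 720
  oracle <- function(r, t) {
    d2 <- (r - xs)^2 + ys^2
    f <- function(u) vapply(u, function(ui)
      sum(exp(-d2 / (4 * 200 * ui)) / (4 * pi * 200 * ui)), numeric(1))
    q_per * integrate(f, 0, min(t, 30), rel.tol = 1e-8)$value
  }
  for (r in c(70, 120, 250, 400)) {
    a <- ring_source_concentration(r, 25, ref_wound, ref_pars)
    expect_lt(abs(a - oracle(r, 25)) / oracle(r, 25), 0.005)
  }
})

test_that("disc source: mass, point-source limit, far-field convergence to ring", {
  disc_pars <- attractant_params(D = 200, T_prod = 30, q = 1,
                                 geometry = "damage_disc")
  rg <- seq(0, 1500, by = 2)
  C <- disc_source_concentration(rg, 20, ref_wound, disc_pars)
  mass <- sum(2 * pi * rg * C) * 2
  expect_lt(abs(mass - pi * 55^2 * 20) / (pi * 55^2 * 20), 0.01)

  # R -> 0 with q pi R^2 fixed matches the 2D point-source Green's function
  R0 <- 0.5
  tiny <- wound_event(c(0, 0), R0)
  qa <- 1 / (pi * R0^2)  # unit total rate
  pp <- attractant_params(D = 200, T_prod = 30, q = qa,
                          geometry = "damage_disc")
  green <- function(r, t) integrate(function(u)
    exp(-r^2 / (4 * 200 * u)) / (4 * pi * 200 * u), 0, min(t, 30),
    rel.tol = 1e-9)$value
  for (r in c(50, 150)) {
    expect_equal(disc_source_concentration(r, 20, tiny, pp), green(r, 20),
                 tolerance = 1e-3)
  }

  # disc and ring agree far away when total emission is matched (r = 10 R)
  qa2 <- 2 / 55   # q_a pi R^2 = q_ring 2 pi R
  ppd <- attractant_params(D = 200, T_prod = 30, q = qa2,
                           geometry = "damage_disc")
  # (the asymptotic regime needs r R / (2 D t) << 1, hence the late time)
  a <- disc_source_concentration(550, 150, ref_wound, ppd)
  b <- ring_source_concentration(550, 150, ref_wound, ref_pars)
  expect_lt(abs(a - b) / b, 0.05)
})

test_that("cached radial field reproduces the quadrature forms", {
  fc <- radial_field_cache(ref_wound, ref_pars, r_max = 700, t_max = 120)
  rr <- c(60, 100, 180, 320)
  for (t in c(10, 35, 100)) {
    a <- fc$eval(rr, t)$C
    b <- ring_source_concentration(rr, t, ref_wound, ref_pars)
    expect_lt(max(abs(a - b) / pmax(b, 1e-9)), 0.01)
  }
  # gradient consistency with a finite difference of the quadrature form
  g <- fc$eval(150, 25)$dCdr
  fd <- (ring_source_concentration(151, 25, ref_wound, ref_pars) -
           ring_source_concentration(149, 25, ref_wound, ref_pars)) / 2
  expect_lt(abs(g - fd), 0.02 * abs(fd))
})

test_that("monotone decay outside the source (free space, fixed t)", {
  rr <- seq(60, 600, by = 20)
  for (t in c(15, 40, 80)) {
    C <- ring_source_concentration(rr, t, ref_wound, ref_pars)
    expect_true(all(diff(C) < 0))
  }
})

test_that("bounded solver matches free space far from boundaries", {
  dom <- wing_domain(cbind(c(-800, 800, 800, -800), c(-800, -800, 800, 800)))
  f <- bounded_field(dom, ref_wound, ref_pars, times = c(30, 60), h = 55 / 8)
  for (k in 1:2) {
    t <- f$times[k]
    rr <- seq(110, 300, by = 25)
    a <- field_eval(f, cbind(rr, 0), t)$C
    b <- ring_source_concentration(rr, t, ref_wound, ref_pars)
    expect_lt(max(abs(a - b) / b), 0.02)
  }
})

test_that("bounded solver conserves mass exactly after production stops", {
  dom <- default_wing()
  f <- bounded_field(dom, ref_wound, ref_pars, times = c(30, 60, 120),
                     h = 55 / 4)
  m <- field_mass(f)
  expect_equal(m[1], 2 * pi * 55 * 30, tolerance = 1e-6)
  # drift < 0.1% per hour after production stops
  expect_lt(abs(m[3] - m[2]) / m[2], 0.001)
})

test_that("bounded solver near a straight edge matches method of images", {
  dom <- wing_domain(cbind(c(-800, 800, 800, -800), c(0, 0, 1600, 1600)))
  w <- wound_event(c(0, 100), 55)
  f <- bounded_field(dom, w, ref_pars, times = c(30, 60), h = 55 / 8)
  pts <- cbind(c(0, 50, 120, 200), c(60, 150, 260, 80))
  for (k in 1:2) {
    t <- f$times[k]
    a <- field_eval(f, pts, t)$C
    r1 <- sqrt(pts[, 1]^2 + (pts[, 2] - 100)^2)
    r2 <- sqrt(pts[, 1]^2 + (pts[, 2] + 100)^2)
    b <- ring_source_concentration(r1, t, w, ref_pars) +
      ring_source_concentration(r2, t, w, ref_pars)
    expect_lt(max(abs(a - b) / b), 0.03)
  }
})

test_that("unstable step is rejected with the CFL bound named", {
  expect_error(cpp_diffuse(matrix(0, 4, 4), matrix(1L, 4, 4), D = 200,
                           h = 1, dt = 1, nsteps = 1, integer(0), numeric(0)),
               "CFL")
})

test_that("superposition: symmetry, additive identity, solver linearity", {
  # square domain sized so the lattice is mirror-symmetric about x = 0
  dom <- square_domain(440)
  w1 <- wound_event(c(-100, 0), 27.5)
  w2 <- wound_event(c(100, 0), 27.5)
  pars <- attractant_params(D = 200, T_prod = 30, q = 1)
  f1 <- bounded_field(dom, w1, pars, times = c(25), h = 27.5 / 4)
  f2 <- bounded_field(dom, w2, pars, times = c(25), h = 27.5 / 4)
  fsum <- superpose_fields(f1, f2)
  fboth <- bounded_field(dom, list(w1, w2), list(pars, pars), times = c(25),
                         h = 27.5 / 4)
  # two-source solve equals the sum of single-source solves (< 0.1%)
  scale <- max(fboth$C)
  expect_lt(max(abs(fsum$C - fboth$C)) / scale, 0.001)

  # symmetric about the perpendicular bisector; midpoint along-axis gradient 0
  mid <- field_eval(fboth, cbind(0, 0), 25)
  expect_lt(abs(mid$grad[1, 1]) / max(abs(fboth$dCdx)), 1e-6)
  left <- field_eval(fboth, cbind(-150, 40), 25)$C
  right <- field_eval(fboth, cbind(150, 40), 25)$C
  expect_equal(left, right, tolerance = 1e-6 * scale + 1e-9)

  # second wound with q = 0 adds nothing
  f0 <- bounded_field(dom, list(w1, w2),
                      list(pars, attractant_params(D = 200, T_prod = 30,
                                                   q = 0)),
                      times = c(25), h = 27.5 / 4)
  expect_equal(f0$C, f1$C, tolerance = 1e-12)
  # mismatched grids refuse to superpose
  f_other <- bounded_field(dom, w1, pars, times = c(20), h = 27.5 / 4)
  expect_error(superpose_fields(f1, f_other), "common grid")
})

test_that("grid refinement: halving h changes C by < 1%", {
  dom <- wing_domain(cbind(c(-500, 500, 500, -500), c(-500, -500, 500, 500)))
  f1 <- bounded_field(dom, ref_wound, ref_pars, times = 40, h = 55 / 4)
  f2 <- bounded_field(dom, ref_wound, ref_pars, times = 40, h = 55 / 8)
  pts <- cbind(c(80, 150, 250, 350), c(0, 50, -60, 10))
  a <- field_eval(f1, pts, 40)$C
  b <- field_eval(f2, pts, 40)$C
  # relative to the field scale (the far tail is exponentially small)
  expect_lt(max(abs(a - b)) / max(b), 0.01)
  expect_lt(max((abs(a - b) / b)[1:2]), 0.01)
})

test_that("inter-wound gradients are shallower at 330 um than 480 um spacing", {
  # at matched distance to the nearer wound, the along-axis gradient
  # magnitude between wounds is smaller when the gradients overlap (330 um)
  pars <- attractant_params(D = 200, T_prod = 30, q = 1)
  grad_at <- function(sep, x) {
    w1 <- wound_event(c(-sep / 2, 0), 27.5)
    w2 <- wound_event(c(sep / 2, 0), 27.5)
    ff <- free_field(list(w1, w2), pars, r_max = 900, t_max = 60)
    abs(ff$grad(cbind(x, 0), 25)[1, 1])
  }
  d_near <- 80   # distance from the nearer wound centre
  g330 <- grad_at(330, -165 + d_near)
  g480 <- grad_at(480, -240 + d_near)
  expect_lt(g330, g480)
})
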