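test_that("sag matches closed-form and high-precision oracle values", {
  # vertex: exactly zero for any profile
  p5 <- asphere_profile(-11.66, -1.5,
                        c(-6.34e-3, 1.15e-3, -3.86e-7, -2.47e-8),
                        aperture = 3.5)
  sph <- asphere_profile(12, 0, aperture = 5)
  pl <- asphere_profile(Inf, aperture = 5)
  expect_identical(sag(sph, 0), 0)
  expect_identical(sag(p5, 0), 0)

  # sphere R = 12 at r = 0.1: 12 - sqrt(144 - 0.01), precomputed to high
  # precision with an independent evaluator
  expect_equal(sag(sph, 0.1), 4.166739007141473e-4, tolerance = 1e-10)

  # aspheric IOL back surface at r = 3 and 3.5: frozen values from an
  # independent term-by-term high-precision series evaluation
  expect_equal(sag(p5, 3.0), -0.34714653506033241, tolerance = 1e-12)
  expect_equal(sag(p5, 3.5), -0.42587232660587645, tolerance = 1e-12)

  # plane: sag identically zero
  expect_equal(sag(pl, c(0, 1, 4.9)), c(0, 0, 0))

  # domain error when the conic square root turns negative (r > R on sphere)
  expect_error(sag(asphere_profile(2, 0, aperture = 5), 3), "undefined")
})

test_that("sag_slope agrees with a central finite difference", {
  p5 <- asphere_profile(-11.66, -1.5,
                        c(-6.34e-3, 1.15e-3, -3.86e-7, -2.47e-8),
                        aperture = 3.5)
  cf <- asphere_profile(7.77, -0.18, aperture = 7)
  h <- 1e-6
  for (prof in list(p5, cf)) {
    r <- seq(0.1, 3.2, length.out = 25)
    fd <- (sag(prof, r + h) - sag(prof, r - h)) / (2 * h)
    expect_equal(sag_slope(prof, r), fd, tolerance = 1e-6)
  }
})

test_that("surface normals are exact for planes and spheres and match FD", {
  pl <- asphere_profile(Inf, aperture = 5)
  expect_equal(surface_normal(pl, c(1.3, -0.2, 0)), c(0, 0, 1))

  # sphere: normal collinear with (point - centre)
  R <- 9
  sph <- asphere_profile(R, 0, aperture = 6)
  set.seed(7)
  for (i in 1:20) {
    r <- runif(1, 0, 5.5)
    th <- runif(1, 0, 2 * pi)
    pt <- c(r * cos(th), r * sin(th), sag(sph, r))
    n <- surface_normal(sph, pt)
    to_centre <- c(0, 0, R) - pt      # centre at vertex + R on axis
    to_centre <- to_centre / sqrt(sum(to_centre^2))
    expect_lt(max(abs(n - to_centre)), 1e-10)
  }

  # analytic normal vs finite-difference gradient on random aperture points
  p5 <- asphere_profile(-11.66, -1.5,
                        c(-6.34e-3, 1.15e-3, -3.86e-7, -2.47e-8),
                        aperture = 3.5)
  set.seed(11)
  h <- 1e-6
  for (i in 1:100) {
    r <- runif(1, 0, 3.4)
    th <- runif(1, 0, 2 * pi)
    pt <- c(r * cos(th), r * sin(th), sag(p5, r))
    n <- surface_normal(p5, pt)
    gx <- -(sag(p5, sqrt((pt[1] + h)^2 + pt[2]^2)) -
            sag(p5, sqrt((pt[1] - h)^2 + pt[2]^2))) / (2 * h)
    gy <- -(sag(p5, sqrt(pt[1]^2 + (pt[2] + h)^2)) -
            sag(p5, sqrt(pt[1]^2 + (pt[2] - h)^2))) / (2 * h)
    g <- c(gx, gy, 1)
    g <- g / sqrt(sum(g^2))
    expect_lt(max(abs(n - g)), 1e-6)
  }
})

test_that("intersection matches plane, sphere closed forms and stays on the surface", {
  # axial ray onto a plane at z = 5
  pl <- asphere_profile(Inf, aperture = 10)
  t <- iolglare:::intersect_asphere(pl, 5, matrix(c(0, 0, 0), 1),
                                    matrix(c(0, 0, 1), 1))
  expect_equal(as.numeric(t), 5, tolerance = 1e-12)

  # ray parallel to the axis at height h onto a sphere: quadratic oracle
  R <- 10
  sph <- asphere_profile(R, 0, aperture = 8)
  z0 <- 4
  for (h in c(0.5, 2, 5.5)) {
    p <- c(h, 0, -3); d <- c(0, 0, 1)
    t <- iolglare:::intersect_asphere(sph, z0, matrix(p, 1), matrix(d, 1))
    oracle <- sphere_intersect_oracle(p, d, c(0, 0, z0 + R), R)[1]
    expect_equal(as.numeric(t), oracle, tolerance = 1e-9)
  }

  # Newton vs dense-sampling bisection oracle on the aspheric IOL back
  # surface, 50 random oblique rays
  p5 <- asphere_profile(-11.66, -1.5,
                        c(-6.34e-3, 1.15e-3, -3.86e-7, -2.47e-8),
                        aperture = 3.4)
  z0 <- 5.26
  set.seed(42)
  n_checked <- 0
  for (i in 1:50) {
    rt <- sqrt(runif(1)) * 3.2
    th <- runif(1, 0, 2 * pi)
    target <- c(rt * cos(th), rt * sin(th), z0 + sag(p5, rt))
    d <- c(runif(2, -0.45, 0.45), 1)
    d <- d / sqrt(sum(d^2))
    p <- target - runif(1, 3, 12) * d
    t_newton <- as.numeric(
      iolglare:::intersect_asphere(p5, z0, matrix(p, 1), matrix(d, 1)))
    t_oracle <- bisect_intersect_oracle(p5, z0, p, d)
    if (is.finite(t_newton) && !is.na(t_oracle)) {
      expect_lt(abs(t_newton - t_oracle), 1e-6)
      n_checked <- n_checked + 1
      # intersect-then-evaluate: the hit lies on the sag sheet
      hit <- p + t_newton * d
      r_hit <- sqrt(hit[1]^2 + hit[2]^2)
      expect_lt(abs(hit[3] - z0 - sag(p5, r_hit)), 1e-9)
    }
  }
  expect_gte(n_checked, 40)
})

test_that("intersections are rotationally symmetric about the surface axis", {
  p5 <- asphere_profile(-11.66, -1.5,
                        c(-6.34e-3, 1.15e-3, -3.86e-7, -2.47e-8),
                        aperture = 3.4)
  z0 <- 5.26
  p <- c(1.2, -0.4, 0); d <- c(0.08, 0.11, 1); d <- d / sqrt(sum(d^2))
  t0 <- as.numeric(iolglare:::intersect_asphere(p5, z0, matrix(p, 1),
                                                matrix(d, 1)))
  hit0 <- p + t0 * d
  set.seed(3)
  for (phi in runif(8, 0, 2 * pi)) {
    Rm <- matrix(c(cos(phi), -sin(phi), 0, sin(phi), cos(phi), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    pr <- as.numeric(Rm %*% p); dr <- as.numeric(Rm %*% d)
    tr <- as.numeric(iolglare:::intersect_asphere(p5, z0, matrix(pr, 1),
                                                  matrix(dr, 1)))
    expect_lt(abs(tr - t0), 1e-9)
    expect_lt(max(abs(pr + tr * dr - as.numeric(Rm %*% hit0))), 1e-9)
  }
})

test_that("cylinder and half-sphere intersections honour bounds", {
  # cylinder: ray through the axis hits the wall at the chord distance
  t <- iolglare:::intersect_cylinder(3, 0, 1, matrix(c(-5, 0, 0.5), 1),
                                     matrix(c(1, 0, 0), 1))
  expect_equal(as.numeric(t), 2, tolerance = 1e-12)
  # out-of-band in z: miss
  t <- iolglare:::intersect_cylinder(3, 0, 1, matrix(c(-5, 0, 2), 1),
                                     matrix(c(1, 0, 0), 1))
  expect_identical(as.numeric(t), Inf)
  # half-sphere: axial ray hits the apex, not the anterior hemisphere
  t <- iolglare:::intersect_halfsphere(11.95, 12, matrix(c(0, 0, 0), 1),
                                       matrix(c(0, 0, 1), 1))
  expect_equal(as.numeric(t), 23.95, tolerance = 1e-12)
})
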