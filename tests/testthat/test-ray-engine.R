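test_that("refraction obeys Snell's law in the incidence plane", {
  # normal incidence: direction unchanged
  r <- refract(c(0, 0, 1), c(0, 0, 1), 1, 1.5)
  expect_equal(r$dir, c(0, 0, 1))
  expect_false(r$tir)

  # 30 degrees air -> n = 1.5: theta_t = asin(0.5/1.5), frozen closed form
  d <- c(sin(pi / 6), 0, cos(pi / 6))
  r <- refract(d, c(0, 0, 1), 1, 1.5)
  theta_t <- acos(abs(r$dir[3])) * 180 / pi
  expect_equal(theta_t, 19.471220634490692, tolerance = 1e-10)

  # beyond the critical angle inside the IOL: TIR
  thc <- asin(1.336 / 1.458)
  d <- c(sin(thc + 0.01), 0, cos(thc + 0.01))
  r <- refract(d, c(0, 0, 1), 1.458, 1.336)
  expect_true(r$tir)

  # property: n1 sin(theta1) = n2 sin(theta2) to 1e-12 on random cases
  set.seed(5)
  for (i in 1:200) {
    n1 <- runif(1, 1, 1.7); n2 <- runif(1, 1, 1.7)
    th <- runif(1, 0, pi / 2 - 0.05)
    d <- c(sin(th), 0, cos(th))
    r <- refract(d, c(0, 0, 1), n1, n2)
    if (!r$tir) {
      s2 <- sqrt(r$dir[1]^2 + r$dir[2]^2)
      expect_lt(abs(n1 * sin(th) - n2 * s2), 1e-12)
      # transmitted ray stays in the incidence plane
      expect_lt(abs(r$dir[2]), 1e-12)
    }
  }
})

test_that("unpolarized Fresnel reflectance has the classical anchors", {
  expect_equal(fresnel_unpolarized(0, 1, 1.5), 0.04, tolerance = 1e-12)
  expect_equal(fresnel_unpolarized(0.4, 1.33, 1.33), 0)
  # Brewster: p-component vanishes, total = Rs/2 (Rs computed independently)
  n1 <- 1; n2 <- 1.5
  thb <- atan(n2 / n1)
  tht <- asin(n1 * sin(thb) / n2)
  rs <- ((n1 * cos(thb) - n2 * cos(tht)) / (n1 * cos(thb) + n2 * cos(tht)))^2
  expect_equal(fresnel_unpolarized(thb, n1, n2), rs / 2, tolerance = 1e-12)
  # TIR: unity
  expect_equal(fresnel_unpolarized(80 * pi / 180, 1.458, 1.336), 1)
  # bounded on a grid
  th <- seq(0, pi / 2, length.out = 50)
  R <- fresnel_unpolarized(th, 1.336, 1.458)
  expect_true(all(R >= 0 & R <= 1))
})

test_that("hemisphere samplers have the right distribution and determinism", {
  n <- 2e4
  set.seed(99)
  lam <- scatter_hemisphere(n, c(0, 0, 1), "lambertian")
  set.seed(99)
  lam2 <- scatter_hemisphere(n, c(0, 0, 1), "lambertian")
  expect_identical(lam, lam2)                  # determinism under a fixed seed
  expect_true(all(lam[, 3] > 0))               # correct hemisphere
  expect_equal(max(abs(rowSums(lam^2) - 1)), 0, tolerance = 1e-12)
  # cosine-weighted: cos^2(theta) ~ Uniform(0,1)
  expect_gt(stats::ks.test(lam[, 3]^2, "punif")$p.value, 0.01)

  set.seed(123)
  iso <- scatter_hemisphere(n, c(0, 1, 0), "isotropic")
  expect_true(all(iso[, 2] > 0))
  # uniform solid angle: cos(theta) ~ Uniform(0,1)
  expect_gt(stats::ks.test(iso[, 2], "punif")$p.value, 0.01)
})

test_that("a single axial ray is imaged on-axis with a closed ledger", {
  eye <- build_model(6, pupil_decenter = 0)
  b <- list(P = matrix(c(0.001, 0, -5), 1), D = matrix(c(0, 0, 1), 1), E = 1)
  tr <- trace(eye, b)
  expect_equal(nrow(tr$hits[tr$hits$class == "direct", ]), 1)
  h <- tr$hits[which.max(tr$hits$energy), ]
  expect_lt(abs(h$x), 0.01)
  expect_lt(abs(h$y), 1e-12)
  l <- tr$ledger
  expect_lt(abs(l$emitted - (l$retina + sum(l$absorbed) + l$escaped +
                             l$cutoff)), 1e-9)
})

test_that("the energy ledger closes to 1e-9 relative for every edge mode", {
  for (mode in edge_modes) {
    eye <- build_model(6, mode)
    b <- make_bundle(65, n_rays = 5000, aim = eye$pupil_center)
    tr <- trace(eye, b)
    l <- tr$ledger
    expect_lt(abs(l$emitted - (l$retina + sum(l$absorbed) + l$escaped +
                               l$cutoff)) / l$emitted, 1e-9)
    expect_equal(l$retina, sum(tr$hits$energy), tolerance = 1e-12)
  }
})

test_that("edge idealizations satisfy their defining exclusions", {
  # 65 degrees: the edge is richly illuminated via near-rim entries
  probe <- function(mode) {
    eye <- build_model(6, mode)
    tr <- trace(eye, make_bundle(65, n_rays = 2e4, aim = eye$pupil_center))
    list(h = tr$hits,
         eT = sum(tr$hits$energy[tr$hits$class == "edge_transmitted"]),
         eR = sum(tr$hits$energy[tr$hits$class == "edge_reflected"]))
  }
  std <- probe("standard")
  expect_gt(std$eT, 0)                    # the standard edge transmits...
  expect_gt(std$eR, 0)                    # ...and internally reflects

  ab <- probe("absorbing")
  expect_identical(ab$eT + ab$eR, 0)      # absorbing edge: no edge light

  th <- probe("thin")
  expect_identical(th$eT + th$eR, 0)      # knife edge: no edge interactions
  expect_true(all(th$h$n_edge_t == 0 & th$h$n_edge_r == 0))

  ar <- probe("anti_reflecting")
  expect_identical(ar$eR, 0)              # no reflection off an AR edge
  expect_gt(ar$eT, 0)

  mi <- probe("reflecting")
  expect_identical(mi$eT, 0)              # mirror edge: no transmission
  expect_gt(mi$eR, 0)
})

test_that("frosted edge conserves energy and respects the generation cap", {
  eye <- build_model(6, "frosted")
  pol <- trace_policy(seed = 7)
  tr <- trace(eye, make_bundle(65, n_rays = 5000, aim = eye$pupil_center),
              pol)
  l <- tr$ledger
  expect_lt(abs(l$emitted - (l$retina + sum(l$absorbed) + l$escaped +
                             l$cutoff)) / l$emitted, 1e-9)
  expect_true(all(tr$hits$generation <= pol$max_generation))
  # deterministic under the policy seed
  tr2 <- trace(eye, make_bundle(65, n_rays = 5000, aim = eye$pupil_center),
               pol)
  expect_identical(tr$hits, tr2$hits)
})

test_that("retinal maps mirror when the source is mirrored in the x-z plane", {
  eye <- build_model(6, "standard")
  b <- make_bundle(65, n_rays = 4000, aim = eye$pupil_center)
  b2 <- b
  b2$P[, 2] <- -b2$P[, 2]
  h1 <- trace(eye, b)$hits
  h2 <- trace(eye, b2)$hits
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(h1$x, h2$x, tolerance = 1e-12)
  expect_equal(h1$y, -h2$y, tolerance = 1e-12)
  expect_equal(h1$energy, h2$energy, tolerance = 1e-15)
})
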