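# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the paraxial oracle is textbook reduced-angle
# matrix optics on the prescription table; the bisection oracle locates
# ray-surface intersections by dense sampling + sign-change bisection.

# Paraxial back-focus of the pseudophakic eye (mm from the corneal vertex),
# computed by reduced-angle surface-by-surface raytracing of the
# prescription. The IOL back surface's paraxial curvature includes the r^2
# polynomial term: 1/R_eff = 1/R + 2*alpha_2.
paraxial_focus_oracle <- function() {
  r_eff_back <- 1 / (1 / -11.66 + 2 * -6.34e-3)
  radii <- c(7.77, 6.40, 13.86, r_eff_back)
  n <- c(1.0, 1.376, 1.336, 1.458, 1.336)
  z <- c(0, 0.5, 4.29, 5.26)
  y <- 1
  w <- 0   # reduced angle n*u
  for (i in seq_along(radii)) {
    w <- w - (n[i + 1] - n[i]) / radii[i] * y
    if (i < length(radii)) y <- y + (z[i + 1] - z[i]) * w / n[i + 1]
  }
  z[4] + y * n[5] / (-w)
}

# Dense-sampling bisection intersection oracle: smallest t in (eps, t_max]
# with ray z equal to the surface sag sheet, or NA. Resolution-limited by
# n_samples, then refined by bisection to tol.
bisect_intersect_oracle <- function(profile, z0, p, d, t_max = 40,
                                    n_samples = 1e5, tol = 1e-9) {
  ts <- seq(1e-6, t_max, length.out = n_samples)
  x <- p[1] + ts * d[1]; y <- p[2] + ts * d[2]; z <- p[3] + ts * d[3]
  r <- sqrt(x^2 + y^2)
  f <- z - z0 - sag(profile, r)
  sgn <- sign(f)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    lo <- ts[i]; hi <- ts[i + 1]
    for (k in 1:80) {
      mid <- (lo + hi) / 2
      rm <- sqrt((p[1] + mid * d[1])^2 + (p[2] + mid * d[2])^2)
      fm <- (p[3] + mid * d[3]) - z0 - sag(profile, rm)
      if (sign(fm) == sgn[i]) lo <- mid else hi <- mid
      if (hi - lo < tol) break
    }
    tm <- (lo + hi) / 2
    rm <- sqrt((p[1] + tm * d[1])^2 + (p[2] + tm * d[2])^2)
    if (rm <= profile$aperture && rm >= profile$inner_aperture) return(tm)
  }
  NA_real_
}

# Closed-form intersection of a ray with a full sphere of radius R about
# centre c (both solutions, increasing order).
sphere_intersect_oracle <- function(p, d, centre, R) {
  pc <- p - centre
  B <- 2 * sum(pc * d)
  C <- sum(pc^2) - R^2
  disc <- B^2 - 4 * C
  if (disc < 0) return(numeric(0))
  sort(c((-B - sqrt(disc)) / 2, (-B + sqrt(disc)) / 2))
}

# default-model constants shared by several tests
TBL <- list(axial_length = 23.95, retina_R = 12, iris_z = 3.66,
            iol_front_z = 4.29, iol_back_z = 5.26)
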