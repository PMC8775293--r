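# Even-asphere surface mathematics: sag, slopes, normals and vectorized
# ray-surface intersection for all refracting/reflecting/absorbing surfaces
# and the spherical retina. All lengths are millimetres.

#' Even-asphere surface profile
#'
#' Describes a rotationally symmetric surface by the standard even-asphere
#' prescription: a conic base term plus an even-power polynomial,
#' \deqn{z(r) = \frac{c r^2}{1 + \sqrt{1 - (1+k) c^2 r^2}} + \sum_i \alpha_{2i} r^{2i},}
#' with curvature \eqn{c = 1/R}. The polynomial starts at \eqn{r^2}
#' (coefficient units mm^-1, mm^-3, ...), matching the usual lens-prescription
#' table layout.
#'
#' @param radius Radius of curvature in mm. `Inf` means a plane. Positive
#'   radius places the centre of curvature on the image (+z, retina) side.
#' @param conic Conic constant \eqn{k} (0 = sphere, -1 = paraboloid, ...).
#' @param poly Numeric vector of even-power polynomial coefficients
#'   \eqn{(\alpha_2, \alpha_4, \alpha_6, \alpha_8, \dots)} applying to
#'   \eqn{r^2, r^4, \dots}. May be empty.
#' @param aperture Outer semi-diameter of the usable surface in mm.
#' @param inner_aperture Inner semi-diameter (0 unless annular).
#' @return An object of class `asphere_profile`.
#' @examples
#' p <- asphere_profile(radius = 12, aperture = 5)
#' sag(p, 0.1)
#' @export
asphere_profile <- function(radius = Inf, conic = 0, poly = numeric(),
                            aperture = Inf, inner_aperture = 0) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius != 0,
            is.numeric(conic), length(conic) == 1L,
            is.numeric(poly), aperture > 0, inner_aperture >= 0,
            inner_aperture < aperture)
  structure(list(
    radius = radius,
    c = if (is.finite(radius)) 1 / radius else 0,
    k = conic,
    poly = as.numeric(poly),
    aperture = aperture,
    inner_aperture = inner_aperture
  ), class = "asphere_profile")
}

#' Surface sag
#'
#' Axial height of the surface above its vertex plane at radial distance `r`.
#'
#' @param profile An [asphere_profile()].
#' @param r Radial distance(s) from the axis, mm; must lie inside the conic
#'   domain (the square-root argument must be non-negative).
#' @return Sag z(r) in mm, vectorized over `r`. `sag(profile, 0)` is exactly 0.
#' @export
sag <- function(profile, r) {
  stopifnot(inherits(profile, "asphere_profile"), all(r >= 0))
  c0 <- profile$c
  arg <- 1 - (1 + profile$k) * c0^2 * r^2
  if (any(arg < 0))
    stop("surface undefined: conic square-root argument negative at some r")
  z <- c0 * r^2 / (1 + sqrt(arg))
  if (length(profile$poly)) {
    r2 <- r^2
    rp <- r2
    for (a in profile$poly) {
      z <- z + a * rp
      rp <- rp * r2
    }
  }
  z
}

#' Radial slope dz/dr of the sag
#'
#' @inheritParams sag
#' @return dz/dr in mm/mm, vectorized over `r`.
#' @export
sag_slope <- function(profile, r) {
  stopifnot(inherits(profile, "asphere_profile"), all(r >= 0))
  c0 <- profile$c
  arg <- 1 - (1 + profile$k) * c0^2 * r^2
  if (any(arg < 0))
    stop("surface undefined: conic square-root argument negative at some r")
  # d/dr of the conic term simplifies to c r / sqrt(arg)
  dz <- c0 * r / sqrt(arg)
  if (length(profile$poly)) {
    r2 <- r^2
    for (i in seq_along(profile$poly)) {
      dz <- dz + profile$poly[i] * (2 * i) * r^(2 * i - 1)
    }
  }
  dz
}

#' Unit surface normal at a point on an aspheric surface
#'
#' The normal of the sag sheet `z = z0 + sag(r)`, returned with a positive
#' axial (+z) component; callers flip it against the incident ray as needed.
#'
#' @param profile An [asphere_profile()].
#' @param point Numeric length-3 vector, or an n x 3 matrix of points, given
#'   relative to the surface vertex (vertex at the origin).
#' @return A unit 3-vector (or n x 3 matrix of unit rows).
#' @export
surface_normal <- function(profile, point) {
  pm <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  r <- sqrt(pm[, 1]^2 + pm[, 2]^2)
  n <- matrix(0, nrow(pm), 3)
  n[, 3] <- 1
  nz <- r > 0
  if (any(nz)) {
    sl <- sag_slope(profile, r[nz])
    n[nz, 1] <- -sl * pm[nz, 1] / r[nz]
    n[nz, 2] <- -sl * pm[nz, 2] / r[nz]
  }
  n <- n / sqrt(rowSums(n^2))
  if (is.matrix(point)) n else n[1, ]
}

# --- intersections ----------------------------------------------------------
# All intersection helpers take ray origins P (n x 3) and unit directions
# D (n x 3) and return the smallest forward travel distance t > eps to the
# surface, or Inf for a miss. Points outside the aperture annulus are misses;
# the non-sequential engine decides what happens beyond.

.GEOM_EPS <- 1e-6      # launch epsilon: no re-intersection at the start point
.GEOM_TOL <- 1e-9      # Newton convergence tolerance on the axial residual, mm
.GEOM_MAXIT <- 50L

# Closed-form intersection with the base conic using the implicit quadric
# c(x^2+y^2) + c(1+k) z'^2 - 2 z' = 0 (z' measured from the vertex). Returns
# both roots as an n x 2 matrix (NA where absent). For c = 0 the surface is a
# plane and a single root is returned in column 1.
.conic_roots <- function(c0, k, z0, P, D) {
  pz <- P[, 3] - z0
  if (c0 == 0) {
    t1 <- ifelse(abs(D[, 3]) > 0, -pz / D[, 3], NA_real_)
    return(cbind(t1, NA_real_))
  }
  g <- c0 * (1 + k)
  A <- c0 * (D[, 1]^2 + D[, 2]^2) + g * D[, 3]^2
  B <- 2 * c0 * (P[, 1] * D[, 1] + P[, 2] * D[, 2]) + 2 * g * pz * D[, 3] -
    2 * D[, 3]
  C <- c0 * (P[, 1]^2 + P[, 2]^2) + g * pz^2 - 2 * pz
  lin <- abs(A) < 1e-14
  disc <- B^2 - 4 * A * C
  ok <- !lin & disc >= 0
  sq <- sqrt(pmax(disc, 0))
  # numerically stable quadratic roots
  q <- -0.5 * (B + sign(B + (B == 0)) * sq)
  t1 <- ifelse(ok, q / A, NA_real_)
  t2 <- ifelse(ok & abs(q) > 0, C / q, NA_real_)
  t1[lin & abs(B) > 0] <- (-C / B)[lin & abs(B) > 0]
  cbind(t1, t2)
}

# Newton-polished intersection with a placed even-asphere sheet.
# Candidate roots of the base conic seed the iteration; the plane through the
# vertex provides a fallback seed. Non-converged candidates count as misses
# (reported via the "nonconv" attribute).
intersect_asphere <- function(profile, z0, P, D, eps = .GEOM_EPS) {
  n <- nrow(P)
  seeds <- .conic_roots(profile$c, profile$k, z0, P, D)
  if (length(profile$poly)) {
    # plane seed as a safety net when the conic misses but the poly sheet
    # does not (gentle aspheres: rarely used)
    pl <- .conic_roots(0, 0, z0, P, D)[, 1]
    seeds <- cbind(seeds, pl)
  }
  best <- rep(Inf, n)
  nonconv <- 0L
  pure_conic <- length(profile$poly) == 0L
  for (j in seq_len(ncol(seeds))) {
    t <- seeds[, j]
    live <- !is.na(t) & t > eps
    if (!any(live)) next
    if (!pure_conic) {
      idx <- which(live)
      tt <- t[idx]
      Pl <- P[idx, , drop = FALSE]
      Dl <- D[idx, , drop = FALSE]
      done <- rep(FALSE, length(idx))
      for (it in seq_len(.GEOM_MAXIT)) {
        x <- Pl[, 1] + tt * Dl[, 1]
        y <- Pl[, 2] + tt * Dl[, 2]
        z <- Pl[, 3] + tt * Dl[, 3] - z0
        r <- sqrt(x^2 + y^2)
        arg <- 1 - (1 + profile$k) * profile$c^2 * r^2
        bad <- !is.finite(r) | arg < 0 | r > profile$aperture * 1.5 + 1
        f <- rep(NA_real_, length(tt))
        okr <- !bad
        if (any(okr)) {
          sr <- suppressWarnings(sag(profile, r[okr]))
          f[okr] <- z[okr] - sr
        }
        done <- !is.na(f) & abs(f) < .GEOM_TOL
        if (all(done | bad)) break
        upd <- okr & !done
        if (!any(upd)) break
        sl <- sag_slope(profile, r[upd])
        drdt <- ifelse(r[upd] > 0,
                       (x[upd] * Dl[upd, 1] + y[upd] * Dl[upd, 2]) / r[upd], 0)
        fp <- Dl[upd, 3] - sl * drdt
        fp[abs(fp) < 1e-12] <- 1e-12
        tt[upd] <- tt[upd] - f[upd] / fp[upd]
      }
      nonconv <- nonconv + sum(!done & !bad & live[idx] & tt > eps, na.rm = TRUE)
      tfin <- rep(NA_real_, n)
      tfin[idx[done]] <- tt[done]
      t <- tfin
      live <- !is.na(t) & t > eps
    }
    if (!any(live)) next
    idx <- which(live)
    x <- P[idx, 1] + t[idx] * D[idx, 1]
    y <- P[idx, 2] + t[idx] * D[idx, 2]
    z <- P[idx, 3] + t[idx] * D[idx, 3] - z0
    r <- sqrt(x^2 + y^2)
    ok <- r <= profile$aperture & r >= profile$inner_aperture
    if (pure_conic && any(ok)) {
      # sheet (branch) check: the quadric has two sheets, keep the sag one
      arg <- 1 - (1 + profile$k) * profile$c^2 * r[ok]^2
      okk <- arg >= 0
      resid <- rep(Inf, sum(ok))
      if (any(okk))
        resid[okk] <- abs(z[ok][okk] - sag(profile, r[ok][okk]))
      ok[ok] <- resid < 1e-6
    }
    upd <- idx[ok][t[idx[ok]] < best[idx[ok]]]
    best[upd] <- t[upd]
  }
  attr(best, "nonconv") <- nonconv
  best
}

# Intersection with a right circular cylinder of given radius about the z
# axis, between axial bounds z1 < z2 (the IOL edge). Both quadratic roots are
# candidates: rays can strike the edge from outside or from inside the optic.
intersect_cylinder <- function(radius, z1, z2, P, D, eps = .GEOM_EPS) {
  A <- D[, 1]^2 + D[, 2]^2
  B <- 2 * (P[, 1] * D[, 1] + P[, 2] * D[, 2])
  C <- P[, 1]^2 + P[, 2]^2 - radius^2
  disc <- B^2 - 4 * A * C
  ok <- A > 1e-16 & disc >= 0
  sq <- sqrt(pmax(disc, 0))
  best <- rep(Inf, nrow(P))
  for (sgn in c(-1, 1)) {
    t <- ifelse(ok, (-B + sgn * sq) / (2 * A), Inf)
    z <- P[, 3] + t * D[, 3]
    good <- ok & t > eps & z >= z1 & z <= z2 & t < best
    best[good] <- t[good]
  }
  best
}

# Intersection with the posterior retinal half-sphere: centre on the axis at
# z = cz, radius R_ret, keeping only hits with z >= cz.
intersect_halfsphere <- function(cz, R_ret, P, D, eps = .GEOM_EPS) {
  px <- P[, 1]; py <- P[, 2]; pz <- P[, 3] - cz
  B <- 2 * (px * D[, 1] + py * D[, 2] + pz * D[, 3])
  C <- px^2 + py^2 + pz^2 - R_ret^2
  disc <- B^2 - 4 * C
  ok <- disc >= 0
  sq <- sqrt(pmax(disc, 0))
  best <- rep(Inf, nrow(P))
  for (sgn in c(-1, 1)) {
    t <- ifelse(ok, (-B + sgn * sq) / 2, Inf)
    z <- P[, 3] + t * D[, 3]
    good <- ok & t > eps & z >= cz & t < best
    best[good] <- t[good]
  }
  best
}
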