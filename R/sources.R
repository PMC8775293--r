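# Synthetic illumination: collimated extended-source ray bundles at oblique
# incidence. The glare source is a 6 mm disc of parallel rays aimed at the
# pupil centre from the temporal side; a narrow 5-degree-nasal bundle serves
# to localize the fovea.

# deterministic sunflower (Fibonacci) layout of n points on a disc of
# radius R: Monte-Carlo-noise-free quasi-uniform coverage
.sunflower_disc <- function(n, R) {
  i <- seq_len(n) - 0.5
  r <- R * sqrt(i / n)
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi))
}

#' Collimated oblique glare bundle
#'
#' Generates a collimated pencil of rays from an extended disc source. The
#' propagation direction for incidence angle \eqn{\theta} (measured from the
#' optical axis, source on the temporal +x side) is
#' \eqn{d = (-\sin\theta, 0, \cos\theta)}: rays travel temporally-to-nasally
#' through the pupil. Launch positions lie on a disc perpendicular to the
#' propagation direction, centred on the line through `aim`, and offset
#' `standoff` mm upstream so every ray starts outside the cornea. Negative
#' angles place the source on the nasal side.
#'
#' @param angle_deg Incidence angle in degrees, `< 90` in magnitude.
#' @param n_rays Number of rays (total energy is normalized to 1).
#' @param diameter Source disc diameter, mm (default 6).
#' @param aim Point the central ray passes through; default the pupil-hole
#'   centre of the default model, `c(-0.5, 0, 3.66)`.
#' @param layout `"sunflower"` (deterministic, default) or `"random"`
#'   (uniform on the disc; set `seed`).
#' @param seed RNG seed used only for `layout = "random"`.
#' @param standoff Launch distance upstream of `aim`, mm.
#' @return A ray bundle: list with `P` (n x 3 origins), `D` (n x 3 unit
#'   directions, identical rows), `E` (energies summing to 1), `angle_deg`.
#' @examples
#' b <- make_bundle(77.5, n_rays = 1000)
#' stopifnot(abs(sum(b$E) - 1) < 1e-12)
#' @export
make_bundle <- function(angle_deg, n_rays = 1e5, diameter = 6,
                        aim = c(-0.5, 0, 3.66),
                        layout = c("sunflower", "random"), seed = 1L,
                        standoff = 15) {
  layout <- match.arg(layout)
  stopifnot(angle_deg > -90, angle_deg <= 90, n_rays >= 1, diameter > 0,
            standoff > 0)
  th <- angle_deg * pi / 180
  d <- c(-sin(th), 0, cos(th))
  # orthonormal frame spanning the disc (perpendicular to propagation)
  e1 <- c(cos(th), 0, sin(th))
  e2 <- c(0, 1, 0)
  if (layout == "sunflower") {
    uv <- .sunflower_disc(n_rays, diameter / 2)
  } else {
    set.seed(seed)
    r <- diameter / 2 * sqrt(stats::runif(n_rays))
    a <- 2 * pi * stats::runif(n_rays)
    uv <- cbind(r * cos(a), r * sin(a))
  }
  ctr <- aim - standoff * d
  P <- cbind(ctr[1] + uv[, 1] * e1[1] + uv[, 2] * e2[1],
             ctr[2] + uv[, 1] * e1[2] + uv[, 2] * e2[2],
             ctr[3] + uv[, 1] * e1[3] + uv[, 2] * e2[3])
  D <- matrix(d, n_rays, 3, byrow = TRUE)
  list(P = P, D = D, E = rep(1 / n_rays, n_rays), angle_deg = angle_deg)
}

#' Fovea-localization bundle
#'
#' Narrow collimated bundle entering 5 degrees nasal to the optical axis
#' (the physiological angle between visual and optical axis), with the chief
#' ray through the pupil-hole centre. Its retinal centroid defines the
#' foveal position.
#'
#' @param n_rays Number of rays.
#' @param diameter Bundle diameter, mm; small enough that all rays pass the
#'   4.5 mm pupil.
#' @param aim Chief-ray target, default the pupil-hole centre.
#' @return A ray bundle as in [make_bundle()].
#' @export
visual_axis_bundle <- function(n_rays = 2000, diameter = 2,
                               aim = c(-0.5, 0, 3.66)) {
  # nasal-side source: negative angle in the temporal-positive convention
  make_bundle(-5, n_rays = n_rays, diameter = diameter, aim = aim)
}
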