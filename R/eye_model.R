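# Assembly of the pseudophakic schematic eye: two aspheric corneal surfaces,
# a decentred absorbing iris stop, an intraocular lens (IOL) with a
# configurable optic diameter and edge design, and a spherical detector
# retina. Geometry follows the Liou-Brennan layout with the crystalline lens
# replaced by the IOL.

#' Supported IOL edge designs
#'
#' * `standard` - bare polished dielectric cylinder: Snell refraction plus
#'   Fresnel reflection, the same physics as the optic surfaces.
#' * `absorbing` - rays striking the edge are terminated and their energy
#'   booked as absorbed.
#' * `reflecting` - ideal mirror (reflectance 1, no transmission).
#' * `anti_reflecting` - Fresnel reflectance forced to zero; transmission
#'   still refracts. Rays that would undergo total internal reflection carry
#'   no transmitted solution and are booked as absorbed at the edge, keeping
#'   the idealization exactly reflection-free.
#' * `frosted` - diffusing edge: the Fresnel-split transmitted and internally
#'   reflected portions are each scattered into the corresponding hemisphere
#'   (Lambertian by default, isotropic optional).
#' * `thin` - knife edge: both optic surfaces are extended radially until
#'   they meet, and no edge cylinder exists.
#' @export
edge_modes <- c("standard", "absorbing", "reflecting", "anti_reflecting",
                "frosted", "thin")

# refractive indices of the model media (single design wavelength)
.MEDIA <- c(air = 1.0, cornea = 1.376, aqueous = 1.336, iol = 1.458,
            vitreous = 1.336)

#' Refractive index of a model medium
#'
#' @param model An [eye_model()] (accepted for interface symmetry; the
#'   indices are fixed model constants).
#' @param region One of `"air"`, `"cornea"`, `"aqueous"`, `"iol"`,
#'   `"vitreous"`.
#' @return The refractive index at the single design wavelength.
#' @export
media_index <- function(model = NULL, region) {
  region <- match.arg(region, names(.MEDIA))
  unname(.MEDIA[region])
}

#' Build the pseudophakic eye model
#'
#' Assembles the ordered non-sequential object list: cornea front and back,
#' iris stop (absorbing annulus with a transmitting hole decentred nasally),
#' IOL front surface, IOL edge cylinder (behaviour set by `edge_mode`), IOL
#' back surface, and the detector retina half-sphere. Axial positions come
#' from the cumulative thickness column of the schematic-eye prescription:
#' cornea 0.5 mm, aqueous 3.16 mm to the pupil plane, 0.63 mm pupil-to-IOL
#' gap, 0.97 mm central IOL thickness, 18.69 mm vitreous, total 23.95 mm.
#'
#' The edge cylinder height is the geometric rim gap between the two optic
#' surfaces evaluated at the optic radius (about 0.3 mm for the 6 mm optic);
#' the nominal edge thickness is not forced, which would break surface
#' continuity. In `thin` mode both surfaces are extended until they
#' intersect, forming a knife edge with no cylinder.
#'
#' Axes: light travels in +z from the cornea (vertex at z = 0) to the
#' retina; the nasal direction is -x and temporal is +x.
#'
#' @param optic_diameter IOL optic diameter in mm; the study designs are 6
#'   and 7 (other values are accepted with a warning).
#' @param edge_mode One of [edge_modes].
#' @param pupil_diameter Iris-hole diameter in mm (default 4.5).
#' @param pupil_decenter Signed x-offset of the pupil hole centre in mm
#'   (default -0.5: 0.5 mm nasal).
#' @return An object of class `eye_model`: a list with the ordered `objects`,
#'   the media table, pupil geometry, and derived constants (retina centre
#'   and radius, actual rim gap).
#' @examples
#' eye <- build_model(6, "standard")
#' print(eye)
#' @export
build_model <- function(optic_diameter = 6,
                        edge_mode = c("standard", "absorbing", "reflecting",
                                      "anti_reflecting", "frosted", "thin"),
                        pupil_diameter = 4.5,
                        pupil_decenter = -0.5) {
  edge_mode <- match.arg(edge_mode)
  if (!optic_diameter %in% c(6, 7))
    warning("optic_diameter ", optic_diameter,
            " mm is outside the study designs (6 or 7 mm)")
  stopifnot(optic_diameter > 0, pupil_diameter > 0)

  # axial layout (cumulative thicknesses)
  z_cornea_front <- 0
  z_cornea_back  <- 0.5
  z_iris         <- 0.5 + 3.16
  z_iol_front    <- z_iris + 0.63
  z_iol_back     <- z_iol_front + 0.97
  z_retina_apex  <- z_iol_back + 18.69   # 23.95
  r_retina       <- 12
  z_retina_ctr   <- z_retina_apex - r_retina

  r_opt <- optic_diameter / 2

  prof_cornea_front <- asphere_profile(7.77, -0.18, aperture = 7)
  prof_cornea_back  <- asphere_profile(6.40, -0.6,  aperture = 7)
  iol_poly <- c(-6.34e-3, 1.15e-3, -3.86e-7, -2.47e-8)

  if (edge_mode == "thin") {
    # knife edge: extend both surfaces to their intersection radius
    pf <- asphere_profile(13.86, 0, aperture = 13)
    pb <- asphere_profile(-11.66, -1.5, iol_poly, aperture = 13)
    gap <- function(r) 0.97 + sag(pb, r) - sag(pf, r)
    r_knife <- stats::uniroot(gap, c(r_opt, 6), tol = 1e-12)$root
    prof_iol_front <- asphere_profile(13.86, 0, aperture = r_knife)
    prof_iol_back  <- asphere_profile(-11.66, -1.5, iol_poly,
                                      aperture = r_knife)
    rim_gap <- 0
    edge_obj <- NULL
    r_outer <- r_knife
  } else {
    prof_iol_front <- asphere_profile(13.86, 0, aperture = r_opt)
    prof_iol_back  <- asphere_profile(-11.66, -1.5, iol_poly,
                                      aperture = r_opt)
    z_rim_front <- z_iol_front + sag(prof_iol_front, r_opt)
    z_rim_back  <- z_iol_back + sag(prof_iol_back, r_opt)
    rim_gap <- z_rim_back - z_rim_front
    if (rim_gap <= 0)
      stop("IOL front and back surfaces interpenetrate at the optic radius (",
           "rim gap ", format(rim_gap), " mm)")
    edge_behavior <- switch(edge_mode,
                            standard = "refract",
                            absorbing = "absorb",
                            reflecting = "mirror",
                            anti_reflecting = "anti_reflect",
                            frosted = "scatter")
    edge_obj <- list(name = "iol_edge", kind = "cylinder", radius = r_opt,
                     z1 = z_rim_front, z2 = z_rim_back,
                     behavior = edge_behavior,
                     n_in = .MEDIA[["iol"]], n_out = .MEDIA[["aqueous"]],
                     tag = "edge")
    r_outer <- r_opt
  }

  objects <- list(
    list(name = "cornea_front", kind = "asphere", profile = prof_cornea_front,
         z0 = z_cornea_front, behavior = "refract",
         n_neg = .MEDIA[["air"]], n_pos = .MEDIA[["cornea"]], tag = "cornea"),
    list(name = "cornea_back", kind = "asphere", profile = prof_cornea_back,
         z0 = z_cornea_back, behavior = "refract",
         n_neg = .MEDIA[["cornea"]], n_pos = .MEDIA[["aqueous"]],
         tag = "cornea"),
    list(name = "iris", kind = "plane", z0 = z_iris, behavior = "iris",
         hole_center = c(pupil_decenter, 0), hole_radius = pupil_diameter / 2,
         outer_radius = 7, tag = "iris"),
    list(name = "iol_front", kind = "asphere", profile = prof_iol_front,
         z0 = z_iol_front, behavior = "refract",
         n_neg = .MEDIA[["aqueous"]], n_pos = .MEDIA[["iol"]], tag = "optic"),
    edge_obj,
    list(name = "iol_back", kind = "asphere", profile = prof_iol_back,
         z0 = z_iol_back, behavior = "refract",
         n_neg = .MEDIA[["iol"]], n_pos = .MEDIA[["vitreous"]], tag = "optic"),
    list(name = "retina", kind = "halfsphere", center_z = z_retina_ctr,
         radius = r_retina, behavior = "detector", tag = "retina")
  )
  objects <- Filter(Negate(is.null), objects)

  structure(list(
    objects = objects,
    optic_diameter = optic_diameter,
    optic_radius = r_outer,
    edge_mode = edge_mode,
    edge_thickness = rim_gap,
    pupil_center = c(pupil_decenter, 0, z_iris),
    pupil_radius = pupil_diameter / 2,
    retina_center_z = z_retina_ctr,
    retina_radius = r_retina,
    retina_apex_z = z_retina_apex,
    media = .MEDIA
  ), class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat("Pseudophakic schematic eye (non-sequential object list)\n")
  cat(sprintf("  IOL optic diameter : %.1f mm, edge mode '%s'\n",
              x$optic_diameter, x$edge_mode))
  cat(sprintf("  Edge rim gap       : %.4f mm\n", x$edge_thickness))
  cat(sprintf("  Pupil              : %.2f mm diameter, hole centre x = %+.2f mm\n",
              2 * x$pupil_radius, x$pupil_center[1]))
  cat(sprintf("  Axial length       : %.2f mm (retina R %.1f mm)\n",
              x$retina_apex_z, -x$retina_radius))
  cat("  Surfaces:\n")
  print(surface_table(x), row.names = FALSE)
  invisible(x)
}

#' Human-readable surface table of a built model
#'
#' Mirrors the standard prescription-table layout: radius, conic constant,
#' axial vertex position, and aperture semi-diameter per object.
#'
#' @param model An [eye_model()].
#' @return A data.frame with one row per model object.
#' @export
surface_table <- function(model) {
  stopifnot(inherits(model, "eye_model"))
  rows <- lapply(model$objects, function(o) {
    switch(o$kind,
      asphere = data.frame(object = o$name, kind = o$kind,
                           radius = o$profile$radius, conic = o$profile$k,
                           z_vertex = o$z0, semi_aperture = o$profile$aperture,
                           behavior = o$behavior),
      plane = data.frame(object = o$name, kind = o$kind, radius = Inf,
                         conic = NA, z_vertex = o$z0,
                         semi_aperture = o$outer_radius, behavior = o$behavior),
      cylinder = data.frame(object = o$name, kind = o$kind, radius = o$radius,
                            conic = NA, z_vertex = o$z1,
                            semi_aperture = o$radius, behavior = o$behavior),
      halfsphere = data.frame(object = o$name, kind = o$kind,
                              radius = -o$radius, conic = NA,
                              z_vertex = o$center_z + o$radius,
                              semi_aperture = o$radius, behavior = o$behavior))
  })
  do.call(rbind, rows)
}
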