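# Retinal irradiance analysis: projection of hits on the retinal half-sphere
# into an azimuthal-equidistant map about the posterior pole, path-tagged
# binning, fovea localization, and foveal region-of-interest metrics.

#' Project retinal hit points to flat map coordinates
#'
#' Azimuthal-equidistant projection about the posterior pole: a hit at polar
#' angle \eqn{\phi} from the pole (seen from the retinal sphere centre) maps
#' to radial arc length \eqn{s = R\phi} along its azimuth. Coordinates are
#' millimetres of arc; X is the nasal(-)/temporal(+) axis, Y
#' superior/inferior.
#'
#' @param hits Retinal hits data.frame (from [trace()]) or an n x 3 matrix
#'   of points on the retina.
#' @param model The [build_model()] used for the trace.
#' @return An n x 2 matrix of map coordinates (columns `X`, `Y`).
#' @export
retina_project <- function(hits, model) {
  Pm <- if (is.data.frame(hits)) cbind(hits$x, hits$y, hits$z) else hits
  ux <- Pm[, 1] / model$retina_radius
  uy <- Pm[, 2] / model$retina_radius
  uz <- (Pm[, 3] - model$retina_center_z) / model$retina_radius
  phi <- acos(pmin(1, pmax(-1, uz)))
  s <- model$retina_radius * phi
  rho <- sqrt(ux^2 + uy^2)
  f <- ifelse(rho > 0, s / rho, 0)
  cbind(X = f * ux, Y = f * uy)
}

#' Bin retinal hits into a path-tagged irradiance map
#'
#' Conservative 2-D histogram of hit energy in projected map coordinates,
#' kept as one layer per interaction-path class (see [tag_classes]) so the
#' patterns caused by edge transmission, edge reflection, the iris-IOL
#' interspace and the ordinary image can be separated.
#'
#' @param hits Retinal hits data.frame from [trace()].
#' @param model The [build_model()] used for the trace.
#' @param bin_size Bin width in mm of arc (default 0.05).
#' @param extent Map half-width, mm (default 19, the full half-sphere).
#' @param meta Optional named list stored with the map (angle, edge mode...).
#' @return Object of class `retina_map`: list with `layers` (named list of
#'   matrices), `edges_x`/`edges_y` (bin boundaries), `bin_size`, `meta`.
#' @export
bin_hits <- function(hits, model, bin_size = 0.05, extent = 19,
                     meta = list()) {
  stopifnot(bin_size > 0, extent > 0)
  XY <- retina_project(hits, model)
  edges <- seq(-extent, extent, by = bin_size)
  if (edges[length(edges)] < extent) edges <- c(edges, extent)
  nb <- length(edges) - 1L
  ix <- findInterval(XY[, 1], edges, rightmost.closed = TRUE)
  iy <- findInterval(XY[, 2], edges, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= nb & iy >= 1 & iy <= nb
  layers <- list()
  for (cl in tag_classes) {
    m <- matrix(0, nb, nb)
    sel <- ok & hits$class == cl
    if (any(sel)) {
      li <- ix[sel] + (iy[sel] - 1L) * nb
      agg <- rowsum(hits$energy[sel], li)
      m[as.integer(rownames(agg))] <- agg[, 1]
    }
    layers[[cl]] <- m
  }
  structure(list(layers = layers, edges_x = edges, edges_y = edges,
                 bin_size = bin_size, meta = meta),
            class = "retina_map")
}

#' Locate the fovea on the retina
#'
#' Traces the narrow 5-degree-nasal [visual_axis_bundle()] through the model
#' and returns the energy-weighted centroid of its retinal hits as a signed
#' transverse arc offset from the posterior pole (temporal positive).
#'
#' @param model An [build_model()] result.
#' @param n_rays Rays in the localization bundle.
#' @return Signed foveal offset in mm (positive = temporal).
#' @export
locate_fovea <- function(model, n_rays = 4000) {
  b <- visual_axis_bundle(n_rays = n_rays,
                          aim = model$pupil_center)
  tr <- trace(model, b)
  if (nrow(tr$hits) == 0)
    stop("fovea localization failed: no retinal hits (model misconfigured?)")
  XY <- retina_project(tr$hits, model)
  stats::weighted.mean(XY[, 1], tr$hits$energy)
}

#' Foveal region of interest
#'
#' @param center_x Foveal offset from [locate_fovea()], mm (temporal
#'   positive); Y is 0 by the model's symmetry plane.
#' @param radius ROI radius, mm. Default 0.75 (about a 1.5 mm foveal
#'   diameter, the anatomically standard figure).
#' @return List of class `foveal_roi`.
#' @export
foveal_roi <- function(center_x, radius = 0.75) {
  stopifnot(radius > 0)
  structure(list(center = c(center_x, 0), radius = radius),
            class = "foveal_roi")
}

#' Energy and peak irradiance of a map layer inside the foveal ROI
#'
#' @param map A [bin_hits()] map.
#' @param roi A [foveal_roi()].
#' @param class Tag class(es) to include; default all edge layers plus the
#'   rest, i.e. every layer. Pass e.g. `"edge_transmitted"` to isolate one.
#' @return List with `energy` (summed bin energy in the ROI) and `peak`
#'   (maximum single-bin energy in the ROI).
#' @export
roi_energy <- function(map, roi, class = tag_classes) {
  stopifnot(inherits(map, "retina_map"), inherits(roi, "foveal_roi"))
  class <- match.arg(class, tag_classes, several.ok = TRUE)
  cx <- (map$edges_x[-1] + map$edges_x[-length(map$edges_x)]) / 2
  cy <- (map$edges_y[-1] + map$edges_y[-length(map$edges_y)]) / 2
  dx <- outer(cx - roi$center[1], rep(1, length(cy)))
  dy <- outer(rep(1, length(cx)), cy - roi$center[2])
  inside <- dx^2 + dy^2 <= roi$radius^2
  tot <- matrix(0, length(cx), length(cy))
  for (cl in class) tot <- tot + map$layers[[cl]]
  list(energy = sum(tot[inside]),
       peak = if (any(inside)) max(tot[inside]) else 0)
}

# ROI energy per tag class straight from the hit list (no binning);
# used by the angle-search objectives.
.roi_energy_hits <- function(hits, model, roi, class) {
  if (nrow(hits) == 0) return(0)
  XY <- retina_project(hits, model)
  sel <- hits$class %in% class &
    (XY[, 1] - roi$center[1])^2 + (XY[, 2] - roi$center[2])^2 <=
      roi$radius^2
  sum(hits$energy[sel])
}

#' Export a retinal irradiance map as a delimited grid
#'
#' Writes one tab-separated numeric grid per layer, preceded by `#` header
#' lines carrying the map metadata.
#'
#' @param map A [bin_hits()] map.
#' @param path Output file path.
#' @param layers Which layers to write (default all).
#' @export
write_retina_map <- function(map, path, layers = names(map$layers)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_size_mm: %g", map$bin_size), con)
  writeLines(sprintf("# extent_mm: %g", max(map$edges_x)), con)
  for (nm in names(map$meta))
    writeLines(sprintf("# %s: %s", nm, format(map$meta[[nm]])), con)
  for (nm in layers) {
    writeLines(sprintf("# layer: %s", nm), con)
    utils::write.table(map$layers[[nm]], con, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Render a retinal map to PNG
#'
#' Writes a grayscale (single class set, gamma-compressed) PNG of the summed
#' selected layers. Intensity is relative; the output is a qualitative
#' rendering, not a photometric image.
#'
#' @param map A [bin_hits()] map.
#' @param path Output PNG path.
#' @param classes Layers to sum (default all).
#' @param gamma Display gamma compression exponent.
#' @export
render_retina_map <- function(map, path, classes = tag_classes,
                              gamma = 0.35) {
  tot <- Reduce(`+`, map$layers[classes])
  mx <- max(tot)
  img <- if (mx > 0) (tot / mx)^gamma else tot
  # map X right, Y up: transpose and flip rows for image convention
  png::writePNG(t(img)[rev(seq_len(ncol(img))), ], path)
  invisible(path)
}
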