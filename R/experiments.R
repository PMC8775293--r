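# Study procedures: oblique-angle sweeps, critical-angle searches for the
# foveal photic arc, onset-angle detection for the iris-IOL interspace
# pattern, and the six-way edge-design comparison.

# one traced angle -> per-class retinal and foveal-ROI energies
.angle_point <- function(model, angle, roi, n_rays, policy, diameter = 6,
                         layout = "sunflower") {
  b <- make_bundle(angle, n_rays = n_rays, diameter = diameter,
                   aim = model$pupil_center, layout = layout)
  tr <- trace(model, b, policy)
  h <- tr$hits
  per_class <- vapply(tag_classes, function(cl)
    sum(h$energy[h$class == cl]), numeric(1))
  roi_class <- vapply(tag_classes, function(cl)
    .roi_energy_hits(h, model, roi, cl), numeric(1))
  list(trace = tr,
       row = data.frame(angle = angle,
                        retina_total = tr$ledger$retina,
                        t(stats::setNames(per_class,
                                          paste0("retina_", tag_classes))),
                        t(stats::setNames(roi_class,
                                          paste0("roi_", tag_classes)))))
}

#' Sweep the incidence angle and tabulate tagged retinal energies
#'
#' Traces one collimated 6 mm glare bundle per grid angle through the model
#' and reports, per angle, the retinal energy and foveal-ROI energy of every
#' interaction-path class.
#'
#' @param model An [build_model()] result (or pass `optic_diameter` /
#'   `edge_mode` to build one).
#' @param angles Angle grid in degrees (default 50 to 90 in steps of 5).
#' @param n_rays Rays per angle.
#' @param roi A [foveal_roi()]; located via [locate_fovea()] when `NULL`.
#' @param policy A [trace_policy()].
#' @param optic_diameter,edge_mode Used only when `model` is `NULL`.
#' @param keep_maps If `TRUE`, also return a [bin_hits()] map per angle.
#' @return List of class `angle_sweep`: `table` (one row per angle), `roi`,
#'   `maps` (optional), `model` parameters.
#' @export
angle_sweep <- function(model = NULL, angles = seq(50, 90, by = 5),
                        n_rays = 1e5, roi = NULL,
                        policy = trace_policy(),
                        optic_diameter = 6, edge_mode = "standard",
                        keep_maps = FALSE) {
  stopifnot(all(diff(angles) > 0))
  if (is.null(model)) model <- build_model(optic_diameter, edge_mode)
  if (is.null(roi)) roi <- foveal_roi(locate_fovea(model))
  rows <- list()
  maps <- if (keep_maps) list() else NULL
  for (i in seq_along(angles)) {
    ap <- .angle_point(model, angles[i], roi, n_rays, policy)
    rows[[i]] <- ap$row
    if (keep_maps)
      maps[[as.character(angles[i])]] <-
        bin_hits(ap$trace$hits, model,
                 meta = list(angle_deg = angles[i],
                             edge_mode = model$edge_mode,
                             optic_diameter = model$optic_diameter))
  }
  structure(list(table = do.call(rbind, rows), roi = roi, maps = maps,
                 optic_diameter = model$optic_diameter,
                 edge_mode = model$edge_mode, n_rays = n_rays),
            class = "angle_sweep")
}

#' Find the critical incidence angle of the foveal photic arc
#'
#' Maximizes the foveal-ROI energy of an edge-related tag class over the
#' incidence angle: a coarse scan over the 5-degree grid followed by nested
#' grid refinement down to 0.05-degree resolution. Deterministic for the
#' default deterministic source layout.
#'
#' @param optic_diameter 6 or 7 (mm).
#' @param edge_mode Edge design; `"standard"` probes the transmission arc,
#'   `"reflecting"` the internally reflected one.
#' @param objective Tag class whose foveal-ROI energy is maximized; default
#'   `"edge_transmitted"` for the standard edge and `"edge_reflected"` for
#'   the reflecting edge.
#' @param angles Coarse grid (degrees).
#' @param n_rays_coarse,n_rays_refine Ray budget for the coarse scan and the
#'   refinement stages.
#' @param policy A [trace_policy()].
#' @return List of class `critical_angle`: `angle` (degrees, 0.05 deg
#'   resolution), `objective`, `value` (ROI energy at the optimum),
#'   `evaluations` (data.frame of every probed angle), or `angle = NA` with
#'   `reason` when the objective layer is empty over the whole grid.
#' @export
find_critical_angle <- function(optic_diameter = 6, edge_mode = "standard",
                                objective = NULL,
                                angles = seq(50, 90, by = 5),
                                n_rays_coarse = 1e5,
                                n_rays_refine = n_rays_coarse,
                                policy = trace_policy()) {
  if (is.null(objective))
    objective <- if (edge_mode == "reflecting") "edge_reflected"
                 else "edge_transmitted"
  objective <- match.arg(objective, tag_classes)
  model <- build_model(optic_diameter, edge_mode)
  roi <- foveal_roi(locate_fovea(model))
  evals <- data.frame(angle = numeric(0), value = numeric(0))
  probe <- function(a, n_rays) {
    b <- make_bundle(a, n_rays = n_rays, aim = model$pupil_center)
    tr <- trace(model, b, policy)
    v <- .roi_energy_hits(tr$hits, model, roi, objective)
    evals[nrow(evals) + 1L, ] <<- c(a, v)
    v
  }
  v_coarse <- vapply(angles, probe, numeric(1), n_rays = n_rays_coarse)
  if (all(v_coarse <= 0)) {
    return(structure(list(angle = NA_real_, objective = objective,
                          value = 0, evaluations = evals,
                          reason = "no photic effect reaches the fovea"),
                     class = "critical_angle"))
  }
  best <- angles[which.max(v_coarse)]
  # nested grid refinement: 1, 0.25, 0.05 degree steps
  for (step in c(1, 0.25, 0.05)) {
    span <- switch(as.character(step), "1" = 4, "0.25" = 0.75, "0.05" = 0.2)
    grid <- best + seq(-span, span, by = step)
    grid <- grid[grid > 0 & grid < 90]
    grid <- setdiff(round(grid, 6), round(evals$angle, 6))
    if (length(grid))
      vapply(grid, probe, numeric(1), n_rays = n_rays_refine)
    sub <- evals[abs(evals$angle - best) <= span + 1e-9, ]
    best <- sub$angle[which.max(sub$value)]
  }
  structure(list(angle = best, objective = objective,
                 value = max(evals$value[abs(evals$angle - best) < 1e-9]),
                 evaluations = evals[order(evals$angle), ]),
            class = "critical_angle")
}

#' @export
print.critical_angle <- function(x, ...) {
  if (is.na(x$angle)) {
    cat("Critical-angle search:", x$reason, "\n")
  } else {
    cat(sprintf("Critical incidence angle: %.2f deg (objective %s, ROI energy %.3g)\n",
                x$angle, x$objective, x$value))
  }
  invisible(x)
}

#' Onset angle of the iris-IOL interspace pattern
#'
#' Smallest grid angle at which rays passing through the interspace between
#' iris and IOL (through the pupil, never touching the optic or its edge)
#' deposit more than `floor` of the emitted energy on the retina.
#'
#' @param optic_diameter 6 or 7 (mm).
#' @param angles Grid in degrees (default 50 to 90, step 5).
#' @param floor Detection floor as a fraction of emitted energy.
#' @param n_rays Rays per angle.
#' @param edge_mode Edge design (the interspace layer does not depend on it).
#' @param sweep Optionally, a precomputed [angle_sweep()] to read instead of
#'   re-tracing.
#' @return List: `angle` (degrees, or `NA` with `reason = "none in range"`),
#'   `table` (interspace energy fraction per angle).
#' @export
find_onset_angle <- function(optic_diameter = 6, angles = seq(50, 90, by = 5),
                             floor = 1e-6, n_rays = 1e5,
                             edge_mode = "standard", sweep = NULL) {
  if (is.null(sweep))
    sweep <- angle_sweep(optic_diameter = optic_diameter,
                         edge_mode = edge_mode, angles = angles,
                         n_rays = n_rays)
  tab <- sweep$table
  frac <- tab$retina_interspace   # emitted energy is normalized to 1
  hit <- which(frac > floor)
  structure(list(
    angle = if (length(hit)) tab$angle[min(hit)] else NA_real_,
    reason = if (length(hit)) NULL else "none in range",
    floor = floor,
    table = data.frame(angle = tab$angle, interspace_fraction = frac)),
    class = "onset_angle")
}

#' @export
print.onset_angle <- function(x, ...) {
  if (is.na(x$angle)) cat("Interspace onset:", x$reason, "\n")
  else cat(sprintf("Interspace onset angle: %g deg (floor %g)\n",
                   x$angle, x$floor))
  invisible(x)
}

#' Compare the six edge designs at a fixed incidence angle
#'
#' Traces the same glare bundle through all six edge designs, tabulates the
#' per-class retinal/foveal-ROI energies and ROI peak irradiances, and
#' checks the definitional relations between designs (absorbing and thin
#' edges carry no edge-tagged energy; anti-reflecting none reflected; fully
#' reflecting none transmitted; frosted has a lower edge-layer peak than
#' standard).
#'
#' @param optic_diameter 6 or 7 (mm).
#' @param angle Incidence angle in degrees (typically the critical angle).
#' @param n_rays Rays per design.
#' @param bin_size Map bin size, mm.
#' @param policy A [trace_policy()].
#' @param keep_maps If `TRUE`, return the per-design [bin_hits()] maps.
#' @return List of class `edge_comparison`: `table`, `checks` (named logical
#'   vector), `maps` (optional), `roi`.
#' @export
edge_comparison <- function(optic_diameter = 6, angle, n_rays = 1e5,
                            bin_size = 0.05, policy = trace_policy(),
                            keep_maps = FALSE) {
  rows <- list(); maps <- list()
  roi <- NULL
  edge_layers <- c("edge_transmitted", "edge_reflected")
  for (mode in edge_modes) {
    model <- build_model(optic_diameter, mode)
    if (is.null(roi)) roi <- foveal_roi(locate_fovea(model))
    b <- make_bundle(angle, n_rays = n_rays, aim = model$pupil_center)
    tr <- trace(model, b, policy)
    map <- bin_hits(tr$hits, model, bin_size = bin_size,
                    meta = list(angle_deg = angle, edge_mode = mode,
                                optic_diameter = optic_diameter))
    if (keep_maps) maps[[mode]] <- map
    per_class <- vapply(tag_classes, function(cl)
      sum(tr$hits$energy[tr$hits$class == cl]), numeric(1))
    roiT <- roi_energy(map, roi, "edge_transmitted")
    roiR <- roi_energy(map, roi, "edge_reflected")
    edge_peak_map <- map$layers$edge_transmitted + map$layers$edge_reflected
    rows[[mode]] <- data.frame(
      edge_mode = mode,
      t(stats::setNames(per_class, paste0("retina_", tag_classes))),
      roi_edge_transmitted = roiT$energy,
      roi_edge_reflected = roiR$energy,
      roi_edge_peak = max(roiT$peak, roiR$peak),
      map_edge_peak = if (length(edge_peak_map)) max(edge_peak_map) else 0)
  }
  tab <- do.call(rbind, rows)
  g <- function(mode, col) tab[tab$edge_mode == mode, col]
  checks <- c(
    absorbing_no_edge_energy =
      g("absorbing", "retina_edge_transmitted") == 0 &&
      g("absorbing", "retina_edge_reflected") == 0,
    thin_no_edge_energy =
      g("thin", "retina_edge_transmitted") == 0 &&
      g("thin", "retina_edge_reflected") == 0,
    anti_reflecting_no_edge_reflection =
      g("anti_reflecting", "retina_edge_reflected") == 0,
    reflecting_no_edge_transmission =
      g("reflecting", "retina_edge_transmitted") == 0,
    frosted_peak_below_standard =
      g("frosted", "map_edge_peak") < g("standard", "map_edge_peak"))
  structure(list(table = tab, checks = checks, roi = roi,
                 maps = if (keep_maps) maps else NULL,
                 angle = angle, optic_diameter = optic_diameter),
            class = "edge_comparison")
}

#' @export
print.edge_comparison <- function(x, ...) {
  cat(sprintf("Edge-design comparison at %.2f deg, %g mm optic\n",
              x$angle, x$optic_diameter))
  print(x$table[, c("edge_mode", "retina_edge_transmitted",
                    "retina_edge_reflected", "retina_interspace",
                    "roi_edge_transmitted", "roi_edge_reflected",
                    "map_edge_peak")], row.names = FALSE)
  cat("Definitional checks:\n")
  for (nm in names(x$checks))
    cat(sprintf("  %-36s %s\n", nm, if (x$checks[[nm]]) "ok" else "FAILED"))
  invisible(x)
}
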