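# Run configuration: one flat schema covering the model, source, angle grid
# and policy settings, loadable from YAML so whole experiments are
# reproducible from a single file plus a seed.

#' Assemble a run configuration
#'
#' @param optic_diameter IOL optic diameter, mm.
#' @param edge_mode One of [edge_modes].
#' @param source Named list of [make_bundle()] overrides
#'   (`diameter`, `n_rays`, `layout`).
#' @param angles Angle grid, degrees.
#' @param refine_tol Refinement resolution for angle searches, degrees.
#' @param seed Seed for every stochastic component.
#' @param policy A [trace_policy()].
#' @return List of class `run_config`.
#' @export
run_config <- function(optic_diameter = 6, edge_mode = "standard",
                       source = list(diameter = 6, n_rays = 1e5,
                                     layout = "sunflower"),
                       angles = seq(50, 90, by = 5), refine_tol = 0.05,
                       seed = 1L, policy = trace_policy(seed = seed)) {
  stopifnot(refine_tol > 0, refine_tol < min(diff(angles)))
  structure(list(optic_diameter = optic_diameter, edge_mode = edge_mode,
                 source = source, angles = angles, refine_tol = refine_tol,
                 seed = as.integer(seed), policy = policy),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Accepts the fields of [run_config()]; missing fields take their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("optic_diameter", "edge_mode", "source", "angles",
             "refine_tol", "seed")
  bad <- setdiff(names(y), c(known, "policy"))
  if (length(bad))
    warning("ignoring unknown config fields: ", paste(bad, collapse = ", "))
  args <- y[intersect(names(y), known)]
  if (!is.null(y$angles)) args$angles <- as.numeric(unlist(y$angles))
  if (!is.null(y$policy))
    args$policy <- do.call(trace_policy, y$policy)
  do.call(run_config, args)
}
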