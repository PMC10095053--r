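#' @title Synthetic sounding generator with known ground truth
#' @description
#' Emulates the measurement protocol: a 400-um slice profiled in 50-um steps
#' starting ~200 um above the upper surface and ending ~100 um below the
#' lower one; per-flow curvature following the saturating flow law; a
#' stationary linear-gradient fluid layer, preferentially at the lower
#' interface; paired repeats at a location sharing a biological truth but
#' differing by experimental noise. Flux conservation is built in: the
#' fluid-layer slope is the configured ratio times the analytic tissue
#' boundary gradient, so the pipeline can be scored against exact truth.
#' @name synthetic_data
NULL

#' Study configuration for the synthetic generator
#'
#' Defaults encode the study conditions: half-thickness 200 um, 50-um steps,
#' 200/100-um margins, curvature law `ymax = 7.5e-3` mmHg/um^2,
#' `K = 0.75` mL/min, `n = 0.75`, true mean Krogh ratio 0.562,
#' per-location biological SD `sqrt(0.0194)/2` and per-repeat experimental
#' SD `sqrt(0.0069/2)` (so that the paired-variance identities reproduce
#' 0.0194 and 0.0069), critical tension 10 mmHg, surface tension 150 mmHg
#' and 1 mmHg Gaussian pressure noise. See the methods vignette for the
#' rationale behind invented values.
#'
#' @param flows flow rates, mL/min (one study arm per flow for the
#'   `"single"` design; the location set is shared across flows for
#'   `"paired_flows"`).
#' @param locations_per_flow locations per flow (or per study for paired
#'   designs).
#' @param repeats soundings per location x flow (1 or 2).
#' @param design `"single"`, `"paired_flows"` (same locations profiled at
#'   every flow) or `"paired_repeats"` (repeats = 2 at one flow).
#' @param half_thickness,step,pre_margin,post_margin geometry, um; the step
#'   must divide both margins.
#' @param curvature_law list `ymax`, `k_half`, `n_exp` of the flow law.
#' @param curvature_rel_sd relative SD of curvature across locations.
#' @param true_ratio_mean,sd_biol,sd_expt Krogh-ratio truth distribution.
#' @param p_star,p_surface tensions, mmHg.
#' @param noise_sd pressure noise SD, mmHg.
#' @param lower_layer_prob function of flow giving the probability of a
#'   stationary layer at the lower interface (decreasing in flow).
#' @param upper_layer_prob probability of an upper-interface layer (small).
#' @param layer_thickness stationary-layer thickness, um.
#' @param dataset_id label stamped on generated profiles.
#' @return list of class `study_config`.
#' @export
study_config <- function(flows = 0.5, locations_per_flow = 6L, repeats = 1L,
                         design = c("single", "paired_flows", "paired_repeats"),
                         half_thickness = 200, step = 50,
                         pre_margin = 200, post_margin = 100,
                         curvature_law = list(ymax = 7.5e-3, k_half = 0.75,
                                              n_exp = 0.75),
                         curvature_rel_sd = 0.2,
                         true_ratio_mean = 0.562,
                         sd_biol = sqrt(0.0194) / 2,
                         sd_expt = sqrt(0.0069 / 2),
                         p_star = 10, p_surface = 150, noise_sd = 1.0,
                         lower_layer_prob = function(flow)
                           pmin(0.9, pmax(0.3, 0.85 - 0.03 * flow)),
                         upper_layer_prob = 0.1,
                         layer_thickness = 100,
                         dataset_id = "sim") {
  design <- match.arg(design)
  stopifnot(half_thickness > 0, step > 0,
            pre_margin %% step == 0, post_margin %% step == 0,
            repeats %in% 1:2, upper_layer_prob >= 0, upper_layer_prob <= 1)
  structure(as.list(environment()), class = "study_config")
}

curvature_mean_at <- function(cfg, flow) {
  cl <- cfg$curvature_law
  cl$ymax * flow^cl$n_exp / (cl$k_half^cl$n_exp + flow^cl$n_exp)
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

#' Draw per-location / per-profile ground truth
#'
#' One row per planned profile. Curvature is drawn per location x flow
#' around the flow law (truncated positive); the true Krogh ratio is drawn
#' per location (truncated to (0, 1)) and shared by repeats; stationary-layer
#' flags are drawn per profile with flow-dependent probability at the lower
#' interface. Uses the current RNG state; seed upstream (e.g. in
#' [simulate_study()]) for determinism.
#'
#' @param cfg a [study_config()].
#' @return data.frame of class `ground_truth` with columns `location_id`,
#'   `repeat_index`, `flow`, `two_a`, `ratio_true`, `layer_lower`,
#'   `layer_upper`.
#' @export
make_truth <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  nloc <- cfg$locations_per_flow
  loc_rows <- switch(cfg$design,
    single = expand.grid(flow = cfg$flows, loc = seq_len(nloc),
                         KEEP.OUT.ATTRS = FALSE),
    paired_flows = expand.grid(flow = cfg$flows, loc = seq_len(nloc),
                               KEEP.OUT.ATTRS = FALSE),
    paired_repeats = data.frame(flow = cfg$flows[1], loc = seq_len(nloc)))
  # location ids: unique per (flow, loc) for "single", shared across flows
  # for "paired_flows"
  loc_rows$location_id <- if (cfg$design == "single")
    sprintf("f%g_loc%02d", loc_rows$flow, loc_rows$loc)
  else sprintf("loc%02d", loc_rows$loc)
  uloc <- unique(loc_rows$location_id)
  ratio_by_loc <- stats::setNames(
    rtrunc_norm(length(uloc), cfg$true_ratio_mean, cfg$sd_biol, 0, 1), uloc)
  loc_rows$ratio_true <- ratio_by_loc[loc_rows$location_id]
  mu <- curvature_mean_at(cfg, loc_rows$flow)
  loc_rows$two_a <- rtrunc_norm(nrow(loc_rows), mu,
                                cfg$curvature_rel_sd * mu, lo = 0)
  reps <- if (cfg$design == "paired_repeats") 2L else cfg$repeats
  out <- loc_rows[rep(seq_len(nrow(loc_rows)), each = reps), ]
  out$repeat_index <- rep(seq_len(reps), times = nrow(loc_rows))
  out$layer_lower <- stats::runif(nrow(out)) < cfg$lower_layer_prob(out$flow)
  out$layer_upper <- stats::runif(nrow(out)) < cfg$upper_layer_prob
  rownames(out) <- NULL
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Simulate one sounding from its ground truth
#'
#' Samples the analytic slab solution over the tissue; fluid regions carry a
#' linear gradient of slope ratio x tangent over the layer thickness where a
#' stationary layer exists (slope = tangent, i.e. a smooth no-break
#' continuation, where it does not), then constant bath pressure. A repeat-
#' level ratio perturbation (`sd_expt`) and i.i.d. Gaussian pressure noise
#' are added, and the slice centre receives a random sub-step offset so
#' boundaries never fall on a sample.
#'
#' @param truth one row of [make_truth()] output.
#' @param cfg the [study_config()].
#' @return list `profile` (a [pressure_profile_data()]) and `realized`
#'   (centre depth `x0`, effective ratio, tangent and per-side layer slopes).
#' @export
simulate_profile <- function(truth, cfg) {
  L <- cfg$half_thickness
  model <- consumption_model(truth$two_a, cfg$p_star)
  if (cfg$p_surface <= truth$two_a / 2 * L^2 && cfg$p_surface < cfg$p_star)
    stop("surface pressure too low for the configured curvature")
  sol <- solve_profile(cfg$p_surface, model, L)
  tangent <- boundary_gradient(sol)
  ratio_eff <- rtrunc_norm(1L, truth$ratio_true, cfg$sd_expt, 0, 1)

  u <- stats::runif(1L, 0.05, 0.95) * cfg$step   # sub-step boundary offset
  x0 <- cfg$pre_margin + u + L
  depth <- seq(0, cfg$pre_margin + 2 * L + cfg$post_margin, by = cfg$step)
  xi <- depth - x0
  p <- numeric(length(xi))
  tissue <- abs(xi) <= L
  p[tissue] <- pressure_profile(xi[tissue], sol)
  for (side in c("upper", "lower")) {
    sel <- if (side == "upper") xi < -L else xi > L
    if (!any(sel)) next
    has_layer <- if (side == "upper") truth$layer_upper else truth$layer_lower
    slope <- if (has_layer) ratio_eff * tangent else tangent
    dist <- abs(xi[sel]) - L
    p[sel] <- cfg$p_surface + slope * pmin(dist, cfg$layer_thickness)
  }
  if (cfg$noise_sd > 0)
    p <- pmax(0, p + stats::rnorm(length(p), 0, cfg$noise_sd))
  prof <- pressure_profile_data(depth, p, flow_ml_min = truth$flow,
                                location_id = truth$location_id,
                                repeat_index = truth$repeat_index,
                                dataset_id = cfg$dataset_id)
  list(profile = prof,
       realized = list(x0 = x0, ratio_eff = ratio_eff, tangent = tangent,
                       slope_lower = if (truth$layer_lower)
                         ratio_eff * tangent else tangent,
                       slope_upper = if (truth$layer_upper)
                         ratio_eff * tangent else tangent))
}

#' Preset study configurations
#'
#' `"v3"`: 19 single soundings at 10 mL/min. `"v4"`: 8 locations each
#' profiled at 1 and 2 mL/min (16 profiles). `"v5"`: 6 locations at
#' 0.5 mL/min, each repeated once (12 profiles).
#'
#' @param preset `"v3"`, `"v4"` or `"v5"`.
#' @param ... overrides passed to [study_config()].
#' @return A [study_config()].
#' @export
preset_study <- function(preset = c("v3", "v4", "v5"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    v3 = list(flows = 10, locations_per_flow = 19L, repeats = 1L,
              design = "single", dataset_id = "v3sim"),
    v4 = list(flows = c(2, 1), locations_per_flow = 8L, repeats = 1L,
              design = "paired_flows", dataset_id = "v4sim"),
    v5 = list(flows = 0.5, locations_per_flow = 6L,
              design = "paired_repeats", dataset_id = "v5sim"))
  do.call(study_config, utils::modifyList(args, list(...)))
}

#' Simulate a whole study
#'
#' Seeds the RNG, draws the ground truth and generates every profile.
#' Optionally writes the profile CSV dialect plus a `truth.json` scoring
#' file to a directory. Identical (config, seed) give identical output.
#'
#' @param cfg a [study_config()] or [preset_study()] result.
#' @param seed integer RNG seed.
#' @param out_dir optional output directory.
#' @return (invisibly) list `profiles` (list of [pressure_profile_data()]),
#'   `truth` (the [make_truth()] table with realized per-profile columns
#'   `x0`, `ratio_eff`, `tangent`).
#' @export
simulate_study <- function(cfg, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(seed)
  truth <- make_truth(cfg)
  sims <- lapply(seq_len(nrow(truth)), function(i)
    simulate_profile(truth[i, ], cfg))
  truth$x0 <- vapply(sims, function(s) s$realized$x0, numeric(1))
  truth$ratio_eff <- vapply(sims, function(s) s$realized$ratio_eff, numeric(1))
  truth$tangent <- vapply(sims, function(s) s$realized$tangent, numeric(1))
  profiles <- lapply(sims, `[[`, "profile")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(profiles)) {
      p <- profiles[[i]]
      write_profile_csv(p, file.path(out_dir,
        sprintf("%s_%s_r%d.csv", p$dataset_id, p$location_id, p$repeat_index)))
    }
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         digits = NA, dataframe = "rows")
  }
  invisible(list(profiles = profiles, truth = truth))
}

#' Simulate paired Krogh-ratio observations (no profiles)
#'
#' Draws locations' true ratios and two repeat-level observations each, at
#' the generating-model level (no curve fitting). Used to check that the
#' paired-variance identities recover the configured components.
#'
#' @param n_pairs number of location pairs.
#' @param cfg a [study_config()] (only the ratio fields are used).
#' @return data.frame with columns `a`, `b`, `ratio_true`.
#' @export
simulate_ratio_pairs <- function(n_pairs, cfg = study_config()) {
  truth <- rtrunc_norm(n_pairs, cfg$true_ratio_mean, cfg$sd_biol, 0, 1)
  data.frame(a = rtrunc_norm(n_pairs, truth, cfg$sd_expt, 0, 1),
             b = rtrunc_norm(n_pairs, truth, cfg$sd_expt, 0, 1),
             ratio_true = truth)
}
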