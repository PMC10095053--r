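#' @title Fitting measured soundings to the slab model
#' @description
#' A sounding is processed in stages: (1) locate the slice centre from the
#' pressure minimum by iterated local parabola fitting; (2) fit the in-tissue
#' samples to the parabolic and to the mixed paracosh model; (3) select a
#' model; (4) look for a linear pressure trend in the fluid adjacent to each
#' interface (a stationary, non-flowing boundary layer); (5) where a layer
#' exists, conservation of oxygen flux across the interface gives the
#' tissue:fluid Krogh ratio as (fluid gradient)/(tissue boundary gradient).
#'
#' Coordinate convention: probe depth increases downward; the tissue occupies
#' `[x0 - L, x0 + L]`; "upper" is the smaller-depth side.
#' @name profile_fitting
NULL

window_quadfit <- function(depth, po2, idx) {
  d <- depth[idx] - mean(depth[idx])  # centred for conditioning
  fit <- stats::lm(po2[idx] ~ d + I(d^2))
  cf <- stats::coef(fit)
  list(vertex = if (cf[3] > 0)
         unname(mean(depth[idx]) - cf[2] / (2 * cf[3])) else NA_real_,
       rms = sqrt(mean(stats::residuals(fit)^2)),
       quad = unname(cf[3]))
}

#' Locate the slice centre from the pressure minimum
#'
#' Fits a parabola to the `2*ceiling(L/step) + 1` samples centred on the
#' minimum sample; the vertex estimates the zero-flux centre `x0`. The fit is
#' then iterated with the window re-selected to the samples within `L` of the
#' current estimate (at most 5 iterations, stopping when the estimate moves
#' by less than 1 um). Tied minima are resolved by the window with the lowest
#' fit rms.
#'
#' @param profile a [pressure_profile_data()] object.
#' @param L slab half-thickness, um.
#' @return `x0` in probe-depth coordinates, um.
#' @export
locate_centre <- function(profile, L = 200) {
  depth <- profile$depth; po2 <- profile$po2
  n <- length(depth)
  w <- ceiling(L / profile$step)
  imin <- which(po2 == min(po2))
  if (any(imin == 1L) || any(imin == n))
    stop("no interior minimum: profile unusable for centre location")
  if (length(imin) > 1L) {
    rmss <- vapply(imin, function(i) {
      idx <- max(1L, i - w):min(n, i + w)
      window_quadfit(depth, po2, idx)$rms
    }, numeric(1))
    imin <- imin[which.min(rmss)]
  }
  idx <- max(1L, imin - w):min(n, imin + w)
  x0 <- window_quadfit(depth, po2, idx)$vertex
  if (!is.finite(x0)) stop("window parabola is not convex at the minimum")
  for (it in 1:5) {
    idx <- which(abs(depth - x0) <= L + 1e-9)
    if (length(idx) < 5L) break
    x0_new <- window_quadfit(depth, po2, idx)$vertex
    if (!is.finite(x0_new)) break
    moved <- abs(x0_new - x0)
    x0 <- x0_new
    if (moved < 1) break
  }
  if (x0 < depth[1L] || x0 > depth[n]) stop("centre outside the sampled range")
  x0
}

in_tissue_idx <- function(profile, x0, L) {
  which(abs(profile$depth - x0) <= L + 1e-9)
}

fit_result <- function(x0, solution, rms, n_pts, model_type,
                       converged = TRUE) {
  g <- boundary_gradient(solution)
  structure(list(x0 = x0, solution = solution, rms_residual = rms,
                 n_tissue_points = n_pts,
                 tangent_upper = g, tangent_lower = g,
                 model_type = model_type, converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: 2a = %.4g mmHg/um^2, rms = %.3g mmHg (%d tissue points)\n",
              x$model_type, x$solution$two_a, x$rms_residual, x$n_tissue_points))
  invisible(x)
}

#' Least-squares parabola fit of the in-tissue samples
#'
#' Fits `P = a (x - x0)^2 + c` over the samples within `L` of the centre.
#' The doubled quadratic coefficient is the curvature `2a = Q0/K`; the
#' surface pressure is the fitted `P(+/-L)` and both boundary tangents are
#' `2aL`.
#'
#' @inheritParams locate_centre
#' @param x0 slice centre from [locate_centre()], um.
#' @return A `fit_result`.
#' @export
fit_parabola <- function(profile, x0, L = 200) {
  idx <- in_tissue_idx(profile, x0, L)
  if (length(idx) < 8L) stop("fewer than 8 in-tissue samples")
  x2 <- (profile$depth[idx] - x0)^2
  fit <- stats::lm(profile$po2[idx] ~ x2)
  a <- unname(stats::coef(fit)[2]); c0 <- unname(stats::coef(fit)[1])
  if (a <= 0) stop("non-convex tissue profile: parabola fit has a <= 0")
  sol <- structure(list(case_label = "parabolic", two_a = 2 * a, p_star = 0,
                        p_surface = c0 + a * L^2, half_thickness = L,
                        delta = 0, alpha_decay = Inf),
                   class = "profile_solution")
  fit_result(x0, sol, sqrt(mean(stats::residuals(fit)^2)), length(idx),
             "parabola")
}

#' Surface pressure by bracketing interpolation
#'
#' Linear interpolation of the two samples bracketing the boundary depth
#' `x0 - L` (upper) or `x0 + L` (lower).
#'
#' @inheritParams fit_parabola
#' @param side `"upper"` or `"lower"`.
#' @return `Ps` in mmHg.
#' @export
surface_pressure <- function(profile, x0, L = 200,
                             side = c("lower", "upper")) {
  side <- match.arg(side)
  b <- if (side == "upper") x0 - L else x0 + L
  if (b < min(profile$depth) || b > max(profile$depth))
    stop("boundary depth outside the sampled range")
  stats::approx(profile$depth, profile$po2, xout = b)$y
}

paracosh_objective <- function(par, xi, pi, ps, L) {
  two_a <- exp(par[1]); p_star <- exp(par[2])
  sol <- try(solve_profile(ps, consumption_model(two_a, p_star), L),
             silent = TRUE)
  if (inherits(sol, "try-error")) return(1e12)
  sqrt(mean((pressure_profile(xi, sol) - pi)^2))
}

#' Fit the mixed paracosh model
#'
#' Bounded derivative-free minimisation of the in-tissue rms over the
#' curvature `2a >= 0` and critical tension `P* >= 0` (log-parametrised
#' Nelder-Mead), with the critical depth `delta` re-solved from the matching
#' equation at every iterate and the surface pressure `Ps` held fixed. The
#' optimiser starts from the parabola-fit curvature and `P* = 0.8 x` the
#' fitted minimum pressure. Optionally the centre offset is refined jointly
#' (`refine_centre`), which matters for flat-bottomed profiles whose local
#' parabola vertex is a biased centre estimate; see the methods vignette.
#'
#' @inheritParams fit_parabola
#' @param ps surface pressure; defaults to the mean of the upper and lower
#'   [surface_pressure()] interpolations.
#' @param refine_centre logical; jointly refine the centre within half a
#'   sampling step of `x0`.
#' @param fit_ps logical; treat the surface pressure as a free parameter
#'   started at `ps`. Holding it fixed at the bracketing interpolation
#'   leaves a percent-level bias from tissue-curve curvature between the
#'   bracketing samples; freeing it removes the bias (methods vignette).
#' @param control passed to [stats::optim()] (Nelder-Mead).
#' @return A `fit_result` (with `converged = FALSE` if the optimiser hit its
#'   iteration cap).
#' @export
fit_paracosh <- function(profile, x0, L = 200, ps = NULL,
                         refine_centre = TRUE, fit_ps = TRUE,
                         control = list(reltol = 1e-12, maxit = 4000)) {
  if (is.null(ps))
    ps <- mean(c(surface_pressure(profile, x0, L, "upper"),
                 surface_pressure(profile, x0, L, "lower")))
  start_fit <- fit_parabola(profile, x0, L)
  pmin_fit <- ps - start_fit$solution$two_a / 2 * L^2
  p_star0 <- max(0.8 * pmin_fit, 1e-3)
  step <- profile$step

  unpack <- function(par) {
    k <- 2L
    dx0 <- 0; psv <- ps
    if (refine_centre) { k <- k + 1L; dx0 <- par[k] }
    if (fit_ps) { k <- k + 1L; psv <- par[k] }
    list(two_a = exp(par[1]), p_star = exp(par[2]), dx0 = dx0, ps = psv)
  }
  obj <- function(par) {
    q <- unpack(par)
    if (abs(q$dx0) > step / 2 || q$ps <= 0) return(1e12)
    idx <- in_tissue_idx(profile, q$dx0 + x0, L)
    if (length(idx) < 8L) return(1e12)
    xi <- profile$depth[idx] - (x0 + q$dx0)
    paracosh_objective(par[1:2], xi, profile$po2[idx], q$ps, L)
  }
  par0 <- c(log(start_fit$solution$two_a), log(p_star0))
  if (refine_centre) par0 <- c(par0, 0)
  if (fit_ps) par0 <- c(par0, ps)
  opt <- stats::optim(par0, obj, method = "Nelder-Mead", control = control)
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead", control = control)

  q <- unpack(opt$par)
  sol <- solve_profile(q$ps, consumption_model(q$two_a, q$p_star), L)
  # Nelder-Mead's relative criterion cannot trigger once the rms reaches its
  # numerical floor near zero; treat that as converged too
  fit_result(x0 + q$dx0, sol, opt$value,
             length(in_tissue_idx(profile, x0 + q$dx0, L)),
             "paracosh",
             converged = opt$convergence == 0 || opt$value < 1e-8)
}

#' Choose between the parabola and paracosh fits
#'
#' The paracosh fit is preferred only when its rms is at least 10% lower than
#' the parabola's *and* its fitted critical tension exceeds the fitted
#' minimum pressure (i.e. the cosh basin is actually active). Both fits and
#' the decision are kept on the returned object so the rule can be swapped.
#'
#' @param parab,paracosh `fit_result`s for the same profile.
#' @return The selected `fit_result`, with attributes `rms_parabola`,
#'   `rms_paracosh` and `decision`.
#' @export
select_model <- function(parab, paracosh) {
  pmin_pc <- pressure_profile(0, paracosh$solution)
  use_pc <- paracosh$rms_residual <= 0.9 * parab$rms_residual &&
    paracosh$solution$p_star > pmin_pc
  out <- if (use_pc) paracosh else parab
  attr(out, "rms_parabola") <- parab$rms_residual
  attr(out, "rms_paracosh") <- paracosh$rms_residual
  attr(out, "decision") <- if (use_pc) "paracosh" else "parabola"
  out
}

#' Detect a stationary fluid boundary layer
#'
#' Fits a least-squares line to the fluid samples nearest the boundary
#' (default 3, falling back to 2 when the third sample breaks linearity -
#' stagnant layers are thin and the third sample often sits in the stirred
#' bath). A layer is reported iff the line is linear (r^2 >= `r2_min`) and
#' its unsigned slope is below the tissue tangent; an (anomalous) near-zero
#' slope is still returned and flagged downstream.
#'
#' @inheritParams fit_parabola
#' @param side `"upper"` or `"lower"`.
#' @param tangent tissue boundary gradient on that side, mmHg/um.
#' @param n_fluid number of fluid samples to use (default 3, min 2).
#' @param r2_min linearity gate on r^2.
#' @return A `boundary_layer` (fields `side`, `slope`, `n_points`,
#'   `linearity_r2`) or `NULL` when no layer qualifies.
#' @export
detect_boundary_layer <- function(profile, x0, L = 200,
                                  side = c("lower", "upper"), tangent,
                                  n_fluid = 3L, r2_min = 0.95) {
  side <- match.arg(side)
  b <- if (side == "upper") x0 - L else x0 + L
  fl <- if (side == "upper") which(profile$depth < b - 1e-9) else
    which(profile$depth > b + 1e-9)
  if (length(fl) < 2L) return(NULL)
  # order by proximity to the boundary
  fl <- fl[order(abs(profile$depth[fl] - b))]
  line_of <- function(k) {
    idx <- fl[seq_len(k)]
    d <- profile$depth[idx]; p <- profile$po2[idx]
    fit <- stats::lm(p ~ d)
    ss_tot <- sum((p - mean(p))^2)
    r2 <- if (ss_tot < 1e-12) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
    list(slope = abs(unname(stats::coef(fit)[2])), r2 = r2, n = k)
  }
  cand <- line_of(min(n_fluid, length(fl)))
  if (cand$r2 < r2_min && cand$n > 2L) cand <- line_of(2L)
  if (cand$r2 < r2_min || cand$slope >= tangent) return(NULL)
  structure(list(side = side, slope = cand$slope, n_points = cand$n,
                 linearity_r2 = cand$r2),
            class = "boundary_layer")
}

#' Krogh ratio from flux conservation
#'
#' Oxygen flux is conserved across a stationary fluid layer, so
#' `Kt/Kf = (fluid gradient) / (tissue boundary gradient)`. Candidate ratios
#' at or above 1 are biologically disallowed (tissue cannot be more permeable
#' than fluid) and ratios above the empirical cutoff (default 0.725) are
#' treated as contaminated by residual advection and rejected.
#'
#' @param fit a `fit_result` for the profile.
#' @param layer a `boundary_layer` on the same profile.
#' @param cutoff acceptance cutoff on the ratio (default 0.725).
#' @param kf fluid Krogh coefficient, mol/(m s Pa), to dimension `kt`.
#' @return A `krogh_estimate` with fields `side`, `ratio_candidate`,
#'   `accepted`, `cutoff`, `kt` (NA unless accepted and `kf` given) and
#'   `flag_zero_slope`.
#' @export
krogh_ratio <- function(fit, layer, cutoff = 0.725, kf = NULL) {
  stopifnot(inherits(fit, "fit_result"), inherits(layer, "boundary_layer"))
  tangent <- if (layer$side == "upper") fit$tangent_upper else fit$tangent_lower
  if (tangent <= 0) stop("zero tissue tangent: ratio undefined")
  ratio <- layer$slope / tangent
  # ratios >= 1 are unconditionally disallowed, whatever the cutoff
  accepted <- ratio < cutoff && ratio < 1
  structure(list(side = layer$side, ratio_candidate = ratio,
                 accepted = accepted, cutoff = cutoff,
                 kt = if (accepted && !is.null(kf)) ratio * kf else NA_real_,
                 flag_zero_slope = layer$slope < 1e-3 * tangent),
            class = "krogh_estimate")
}

#' Dimension an accepted Krogh ratio
#'
#' @param est an accepted `krogh_estimate`.
#' @param kf fluid Krogh coefficient, mol/(m s Pa).
#' @return `Kt = ratio x Kf` in mol/(m s Pa).
#' @export
estimate_kt <- function(est, kf) {
  stopifnot(inherits(est, "krogh_estimate"))
  if (!est$accepted) stop("estimate was rejected; Kt is not defined")
  est$ratio_candidate * kf
}

#' Full single-profile pipeline
#'
#' Centre location, both model fits, model selection, boundary-layer
#' detection on both interfaces and Krogh-ratio estimation.
#'
#' @inheritParams locate_centre
#' @param cutoff Krogh-ratio acceptance cutoff.
#' @param kf fluid Krogh coefficient (optional, dimensions `kt`).
#' @return A `profile_fit` list: `x0`, `parabola`, `paracosh`, `fit`
#'   (selected), `layers` and `estimates` (per side; `NULL` where absent).
#' @examples
#' cfg <- study_config(flows = 10, locations_per_flow = 1, noise_sd = 0,
#'                     lower_layer_prob = function(flow) 1)
#' sim <- simulate_study(cfg, seed = 1)
#' pf <- fit_profile(sim$profiles[[1]])
#' pf$estimates$lower$ratio_candidate
#' @export
fit_profile <- function(profile, L = 200, cutoff = 0.725, kf = NULL) {
  x0 <- locate_centre(profile, L)
  parab <- fit_parabola(profile, x0, L)
  pc <- fit_paracosh(profile, x0, L)
  sel <- select_model(parab, pc)
  layers <- estimates <- list(upper = NULL, lower = NULL)
  for (side in c("upper", "lower")) {
    tng <- if (side == "upper") sel$tangent_upper else sel$tangent_lower
    lay <- detect_boundary_layer(profile, sel$x0, L, side, tangent = tng)
    layers[[side]] <- lay
    if (!is.null(lay))
      estimates[[side]] <- krogh_ratio(sel, lay, cutoff = cutoff, kf = kf)
  }
  structure(list(x0 = sel$x0, parabola = parab, paracosh = pc, fit = sel,
                 layers = layers, estimates = estimates, profile = profile),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("profile fit (%s selected): 2a = %.4g, x0 = %.1f um\n",
              attr(x$fit, "decision"), x$fit$solution$two_a, x$x0))
  for (side in c("upper", "lower")) {
    e <- x$estimates[[side]]
    if (is.null(e)) cat(sprintf("  %s: no stationary layer\n", side))
    else cat(sprintf("  %s: Kt/Kf candidate %.3f (%s)\n", side,
                     e$ratio_candidate,
                     if (e$accepted) "accepted" else "rejected"))
  }
  invisible(x)
}

#' Fit many profiles and tabulate the results
#'
#' @param profiles list of [pressure_profile_data()] objects.
#' @inheritParams fit_profile
#' @return A data.frame with one row per profile: identifiers, flow, the
#'   selected model, curvature `two_a`, and per-side candidate ratio and
#'   acceptance flag (NA where no layer was found).
#' @export
fit_profiles <- function(profiles, L = 200, cutoff = 0.725, kf = NULL) {
  rows <- lapply(profiles, function(p) {
    pf <- fit_profile(p, L = L, cutoff = cutoff, kf = kf)
    grab <- function(side, field)
      if (is.null(pf$estimates[[side]])) NA_real_ else pf$estimates[[side]][[field]]
    data.frame(dataset_id = p$dataset_id, location_id = p$location_id,
               repeat_index = p$repeat_index, flow_ml_min = p$flow_ml_min,
               model = attr(pf$fit, "decision"),
               two_a = pf$fit$solution$two_a,
               x0 = pf$x0,
               rms = pf$fit$rms_residual,
               ratio_upper = grab("upper", "ratio_candidate"),
               accepted_upper = as.logical(grab("upper", "accepted")),
               ratio_lower = grab("lower", "ratio_candidate"),
               accepted_lower = as.logical(grab("lower", "accepted")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
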