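#' @title Steady-state tension profiles in a perfused slab
#' @description
#' At steady state the slab obeys `K d2P/dx2 = Q(P)` with symmetric surface
#' tension `Ps` at `x = +/-L` (x = 0 is the slice centre). With the
#' piecewise-linear uptake law the solution takes one of three closed forms,
#' selected by where the profile sits relative to the critical tension `P*`:
#'
#' * `parabolic` - the whole profile stays above `P*`; uptake is zero-order
#'   and `P(x) = Ps - a (L^2 - x^2)` with `2a = Q0/K`.
#' * `paracosh` - the profile crosses `P*` at `x = +/-delta`; a hyperbolic
#'   cosine basin `P = P* cosh(ax)/cosh(ad)` occupies `|x| <= delta`, joined
#'   with continuous value and slope to parabolic wings.
#' * `cosh` - the surface tension is already below `P*`; the basin spans the
#'   whole slab, `P = Ps cosh(ax)/cosh(aL)`.
#'
#' Here `alpha = sqrt(2a/P*)` is the inverse decay length of the basin. The
#' critical depth `delta` is the root of a transcendental matching equation
#' and is found numerically. All profiles are mirror-symmetric in `x`.
#'
#' Flux is reported **unsigned** (`q/K = |dP/dx|`): physically oxygen flows
#' down the pressure gradient, toward the slice centre from both faces.
#' @name diffusion_solutions
NULL

alpha_decay_of <- function(model) {
  if (model$p_star > 0) sqrt(model$q0_over_k / model$p_star) else Inf
}

#' Classify which analytic case a slab profile falls in
#'
#' @param ps surface tension `Ps` at `x = +/-L`, mmHg (> 0).
#' @param model a [consumption_model()].
#' @param L slab half-thickness, um (> 0).
#' @return One of `"parabolic"`, `"paracosh"`, `"cosh"`.
#' @details The parabola minimum is `Ps - a L^2`; if it is at or above `P*`
#' the zero-order parabola applies throughout (the boundary case
#' `Ps = P* (1 + (alpha L)^2 / 2)` is classified parabolic with `delta = 0`).
#' If `Ps < P*` the whole slab is sub-critical (`cosh`). Otherwise mixed.
#' @export
classify_case <- function(ps, model, L) {
  stopifnot(ps > 0, L > 0, inherits(model, "consumption_model"))
  a <- model$q0_over_k / 2
  if (ps < model$p_star) return("cosh")
  if (ps - a * L^2 >= model$p_star) return("parabolic")
  "paracosh"
}

delta_residual <- function(delta, ps, p_star, alpha, L) {
  tanh(alpha * delta) -
    ((1 - ps / p_star) / (alpha * (delta - L)) + 0.5 * alpha * (delta - L))
}

#' Solve for the critical depth of a mixed (paracosh) profile
#'
#' The depth `delta` at which the tension crosses `P*` satisfies
#' `tanh(alpha delta) = (1 - Ps/P*) / (alpha (delta - L)) + alpha (delta - L)/2`.
#' The residual is monotone with a single sign change on `(0, L)` in the
#' paracosh regime; a bracketed root finder is used, with a dense-scan
#' fallback, and the root is polished until the residual is below 1e-10.
#'
#' @inheritParams classify_case
#' @return `delta` in um, in `(0, L)`.
#' @export
solve_delta <- function(ps, model, L) {
  if (classify_case(ps, model, L) != "paracosh")
    stop("delta is only defined for the paracosh case; re-classify the profile")
  alpha <- alpha_decay_of(model)
  eps <- 1e-6 * L
  f <- function(d) delta_residual(d, ps, model$p_star, alpha, L)
  lo <- eps; hi <- L - eps
  if (f(lo) * f(hi) > 0) {
    # fallback: dense scan for the sign change (f is + near 0, - near L)
    grid <- seq(lo, hi, length.out = 4096L)
    fg <- vapply(grid, f, numeric(1))
    i <- which(fg[-1] * fg[-length(fg)] <= 0)[1L]
    if (is.na(i)) stop("no sign change in (0, L); classification error")
    lo <- grid[i]; hi <- grid[i + 1L]
  }
  root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps,
                         maxiter = 2000L)$root
  # Newton polish to push the residual to near machine precision
  for (it in 1:8) {
    r <- f(root)
    if (abs(r) < 1e-13) break
    h <- max(1e-6, 1e-8 * L)
    dr <- (f(root + h) - f(root - h)) / (2 * h)
    step <- r / dr
    cand <- root - step
    if (is.finite(cand) && cand > 0 && cand < L) root <- cand else break
  }
  if (abs(f(root)) > 1e-10)
    stop("delta solver failed to reach residual tolerance 1e-10")
  root
}

#' Construct a complete analytic slab solution
#'
#' Classifies the case, determines `delta` where needed and returns the full
#' parameter set of the closed-form profile.
#'
#' @inheritParams classify_case
#' @return A `profile_solution` with fields `case_label`, `two_a`, `p_star`,
#'   `p_surface`, `half_thickness`, `delta` (0 for parabolic, `L` for cosh)
#'   and `alpha_decay = sqrt(2a/P*)`.
#' @examples
#' m <- consumption_model(4e-3, 10)
#' s <- solve_profile(40, m, 200)
#' s$case_label; s$delta
#' @export
solve_profile <- function(ps, model, L) {
  case <- classify_case(ps, model, L)
  delta <- switch(case,
                  parabolic = 0,
                  cosh = L,
                  paracosh = solve_delta(ps, model, L))
  structure(list(case_label = case,
                 two_a = model$q0_over_k,
                 p_star = model$p_star,
                 p_surface = ps,
                 half_thickness = L,
                 delta = delta,
                 alpha_decay = alpha_decay_of(model)),
            class = "profile_solution")
}

#' @export
print.profile_solution <- function(x, ...) {
  cat(sprintf("slab tension profile: %s\n", x$case_label))
  cat(sprintf("  2a = %.4g mmHg/um^2, P* = %.4g mmHg, Ps = %.4g mmHg\n",
              x$two_a, x$p_star, x$p_surface))
  cat(sprintf("  L = %g um, delta = %.4g um, alpha = %.4g /um\n",
              x$half_thickness, x$delta, x$alpha_decay))
  invisible(x)
}

#' Evaluate the analytic tension profile
#'
#' @param x depth relative to the slice centre, um, in `[-L, L]` (vectorised).
#' @param sol a `profile_solution` from [solve_profile()].
#' @return Oxygen tension in mmHg; `P(x) = P(-x)` and `P(+/-L) = Ps`.
#' @export
pressure_profile <- function(x, sol) {
  stopifnot(inherits(sol, "profile_solution"))
  L <- sol$half_thickness
  if (any(abs(x) > L + 1e-6))
    stop("depth outside the slab [-L, L]")
  ax <- pmin(abs(x), L)
  a <- sol$two_a / 2
  al <- sol$alpha_decay
  switch(sol$case_label,
    parabolic = sol$p_surface - a * (L^2 - ax^2),
    cosh = sol$p_surface * cosh(al * ax) / cosh(al * L),
    paracosh = {
      d <- sol$delta
      inner <- sol$p_star * cosh(al * ax) / cosh(al * d)
      outer <- sol$p_star + al * sol$p_star * tanh(al * d) * (ax - d) +
        a * (ax - d)^2
      ifelse(ax <= d, inner, outer)
    })
}

#' Evaluate the unsigned flux profile
#'
#' Returns `q/K = |dP/dx|` from the analytic derivative of each case; the
#' flux vanishes at the centre of symmetry and, multiplied by a Krogh
#' coefficient `k`, gives the dimensioned flux.
#'
#' @inheritParams pressure_profile
#' @param k Krogh coefficient multiplier (default 1, i.e. report `q/K`).
#' @return Unsigned flux `k * |dP/dx|` (mmHg/um when `k = 1`).
#' @export
flux_profile <- function(x, sol, k = 1) {
  stopifnot(inherits(sol, "profile_solution"))
  L <- sol$half_thickness
  if (any(abs(x) > L + 1e-6))
    stop("depth outside the slab [-L, L]")
  ax <- pmin(abs(x), L)
  a <- sol$two_a / 2
  al <- sol$alpha_decay
  qk <- switch(sol$case_label,
    parabolic = sol$two_a * ax,
    cosh = al * sol$p_surface * sinh(al * ax) / cosh(al * L),
    paracosh = {
      d <- sol$delta
      inner <- al * sol$p_star * sinh(al * ax) / cosh(al * d)
      outer <- al * sol$p_star * tanh(al * d) + sol$two_a * (ax - d)
      ifelse(ax <= d, inner, outer)
    })
  k * abs(qk)
}

#' Tension gradient at the slab surface
#'
#' The boundary gradient `|dP/dx|` at `x = +/-L` is what flux conservation
#' compares against the fluid-layer gradient: `2aL` for the parabola,
#' `sqrt(2a P*) tanh(alpha delta) + 2a (L - delta)` for the mixed case and
#' `sqrt(2a P*) (Ps/P*) tanh(alpha L)` for the sub-critical basin.
#'
#' @param sol a `profile_solution`.
#' @return Gradient in mmHg/um (positive for `2a > 0`).
#' @export
boundary_gradient <- function(sol) {
  stopifnot(inherits(sol, "profile_solution"))
  L <- sol$half_thickness
  switch(sol$case_label,
    parabolic = sol$two_a * L,
    paracosh = sqrt(sol$two_a * sol$p_star) *
      tanh(sol$alpha_decay * sol$delta) + sol$two_a * (L - sol$delta),
    cosh = sqrt(sol$two_a * sol$p_star) * (sol$p_surface / sol$p_star) *
      tanh(sol$alpha_decay * L))
}
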