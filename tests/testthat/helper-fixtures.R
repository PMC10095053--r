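# Fixture builders: profiles constructed from the analytic forward model,
# with full control over offsets, layers and noise.

# depth grid emulating the protocol: 200 um above, tissue 2L, 100 um below
protocol_depths <- function(L = 200, step = 50, pre = 200, post = 100) {
  seq(0, pre + 2 * L + post, by = step)
}

# profile sampled from an analytic solution; fluid sides carry a linear
# gradient of slope ratio*tangent (ratio = 1 emulates "no layer") over
# layer_um, then constant bath pressure
synth_profile <- function(sol, offset_um = 20, ratio_lower = 0.6,
                          ratio_upper = 1, layer_um = 100, noise_sd = 0,
                          step = 50, pre = 200, post = 100, flow = 1) {
  L <- sol$half_thickness
  depth <- protocol_depths(L, step, pre, post)
  x0 <- pre + offset_um + L
  xi <- depth - x0
  tangent <- boundary_gradient(sol)
  p <- numeric(length(xi))
  tis <- abs(xi) <= L
  p[tis] <- pressure_profile(xi[tis], sol)
  for (side in c("upper", "lower")) {
    sel <- if (side == "upper") xi < -L else xi > L
    r <- if (side == "upper") ratio_upper else ratio_lower
    d <- abs(xi[sel]) - L
    p[sel] <- sol$p_surface + r * tangent * pmin(d, layer_um)
  }
  if (noise_sd > 0) p <- pmax(0, p + rnorm(length(p), 0, noise_sd))
  prof <- pressure_profile_data(depth, p, flow_ml_min = flow,
                                location_id = "fix", dataset_id = "fixture")
  attr(prof, "x0_true") <- x0
  attr(prof, "tangent_true") <- tangent
  prof
}

# exact parabola over the whole sounding (no fluid break): the pure-model
# fixture for centre location
parabola_profile <- function(two_a = 6.55e-3, vertex = 367, pmin = 70,
                             step = 50, n = 15) {
  depth <- seq(0, by = step, length.out = n)
  po2 <- two_a / 2 * (depth - vertex)^2 + pmin
  pressure_profile_data(depth, po2, flow_ml_min = 10, location_id = "par")
}

# independent dense-grid + bisection oracle for the critical-depth equation
delta_oracle <- function(ps, p_star, two_a, L, n_grid = 20000L) {
  alpha <- sqrt(two_a / p_star)
  f <- function(d) tanh(alpha * d) -
    ((1 - ps / p_star) / (alpha * (d - L)) + 0.5 * alpha * (d - L))
  g <- seq(1e-9 * L, L * (1 - 1e-9), length.out = n_grid)
  fg <- vapply(g, f, numeric(1))
  i <- which(fg[-1] * fg[-n_grid] <= 0)[1L]
  lo <- g[i]; hi <- g[i + 1L]
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# central finite-difference slope of the analytic pressure profile
fd_slope <- function(x, sol, h = 1e-4) {
  (pressure_profile(x + h, sol) - pressure_profile(x - h, sol)) / (2 * h)
}
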