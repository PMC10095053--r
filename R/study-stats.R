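#' @title Study-level aggregation and variance decomposition
#' @description
#' Aggregates per-profile fit results into per-flow summaries (curvature and
#' accepted Krogh ratios), pools the ratio across groups, decomposes the
#' scatter of paired repeat measurements into experimental and biological
#' variance components, fits the saturating curvature-vs-flow law and
#' dimensions the final tissue Krogh coefficient.
#' @name study_stats
NULL

#' Per-group summaries of curvature and accepted Krogh ratio
#'
#' Sample statistics (n-1 denominator) per group: curvature over all
#' profiles, Krogh ratio over accepted candidates only (above-cutoff ratios
#' are excluded upstream via the `accepted` flag).
#'
#' @param results data.frame from [fit_profiles()] (needs `two_a`,
#'   `ratio_lower`, `accepted_lower` and the grouping column).
#' @param group_by name of the grouping column (default `"flow_ml_min"`).
#' @param side which interface's ratios to summarise (default `"lower"`,
#'   where stationary layers form preferentially).
#' @return data.frame with one row per non-empty group: curvature mean/sd/n
#'   and ratio mean/sd/n; `sd` is 0 with `sd_defined = FALSE` when n = 1.
#' @export
summarize_groups <- function(results, group_by = "flow_ml_min",
                             side = "lower") {
  rcol <- paste0("ratio_", side); acol <- paste0("accepted_", side)
  groups <- split(results, results[[group_by]], drop = TRUE)
  rows <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    ok <- !is.na(df[[rcol]]) & df[[acol]] %in% TRUE
    r <- df[[rcol]][ok]
    sd_or_0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
    data.frame(group_id = g,
               curvature_mean = mean(df$two_a),
               curvature_sd = sd_or_0(df$two_a),
               curvature_n = nrow(df),
               ratio_mean = if (length(r)) mean(r) else NA_real_,
               ratio_sd = sd_or_0(r),
               ratio_n = length(r),
               sd_defined = length(r) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$curvature_n > 0L, , drop = FALSE]
}

#' Pool the Krogh ratio across disjoint groups
#'
#' N-weighted mean of the group means. The pooled sample standard deviation
#' uses the member values when supplied; otherwise it is reconstructed from
#' the group means/sds via the standard within+between decomposition with an
#' overall n-1 denominator.
#'
#' @param means,sds,ns group means, sample sds and counts (accepted ratios).
#' @param values optional vector of all member values; overrides `sds`.
#' @return list `mean`, `stdev`, `n`.
#' @examples
#' pooled_ratio(c(0.553, 0.595, 0.538, 0.568), ns = c(11, 5, 5, 9),
#'              sds = c(0.083, 0.140, 0.082, 0.072))  # mean 0.562
#' @export
pooled_ratio <- function(means, sds = NULL, ns, values = NULL) {
  stopifnot(length(means) == length(ns))
  n_tot <- sum(ns)
  if (n_tot == 0L) stop("no accepted ratios to pool")
  m <- sum(ns * means) / n_tot
  stdev <- if (!is.null(values)) {
    stats::sd(values)
  } else if (!is.null(sds)) {
    within <- sum((ns - 1) * sds^2)
    between <- sum(ns * (means - m)^2)
    sqrt((within + between) / (n_tot - 1))
  } else NA_real_
  list(mean = m, stdev = stdev, n = n_tot)
}

#' Decompose paired repeats into experimental and biological variance
#'
#' For pairs (A, B) of Krogh ratios measured twice at the same location, the
#' biology is common within a pair and cancels in the difference:
#' `var(A - B)` estimates the experimental variance, while `var(A + B)`
#' carries both components, so `var_biol = var(A + B) - var(A - B)` (face
#' value identities, sample n-1 variance). A negative biological component
#' is clamped to zero with a warning.
#'
#' @param a,b first and second ratio of each pair (both accepted).
#' @return list `var_expt`, `var_biol`, `biol_fraction`.
#' @examples
#' # worked values: var(A+B) = 0.0263, var(A-B) = 0.0069 give
#' # var_biol = 0.0194 and a 74% biological fraction
#' @export
variance_decomposition <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) stop("at least 2 pairs are required")
  var_expt <- stats::var(a - b)
  var_biol <- stats::var(a + b) - var_expt
  if (var_biol < 0) {
    warning("negative biological variance clamped to 0")
    var_biol <- 0
  }
  list(var_expt = var_expt, var_biol = var_biol,
       biol_fraction = var_biol / (var_expt + var_biol))
}

#' Pair-separation diagnostic for repeated profiles
#'
#' Cartesian separation of each pair in the (curvature, ratio) plane, a
#' flag for discrepant repeats; outliers are reported, never auto-removed.
#'
#' @param curv_a,curv_b,ratio_a,ratio_b paired curvature and ratio values.
#' @return numeric vector of separations (curvature scaled by 1e3 so both
#'   axes are O(1)).
#' @export
pair_separation <- function(curv_a, curv_b, ratio_a, ratio_b) {
  sqrt((1e3 * (curv_a - curv_b))^2 + (ratio_a - ratio_b)^2)
}

#' Saturating (Hill-type) fit of curvature vs flow rate
#'
#' Least-squares fit of `y = ymax x^n / (K^n + x^n)` describing how profile
#' curvature (hence oxygen consumption per unit permeability) saturates with
#' perfusion flow rate.
#'
#' @param flow flow rates, mL/min (>= 3 points).
#' @param curvature curvatures `2a`, mmHg/um^2.
#' @return list of class `hill_fit`: `ymax`, `k_half`, `n_exp`, `fitted`,
#'   `residuals`, `converged`.
#' @export
hill_fit <- function(flow, curvature) {
  stopifnot(length(flow) == length(curvature), length(flow) >= 3L,
            all(flow > 0), all(curvature > 0))
  df <- data.frame(x = flow, y = curvature)
  fit <- try(stats::nls(y ~ ymax * x^n / (k^n + x^n), data = df,
                        start = list(ymax = max(df$y) * 1.2,
                                     k = stats::median(df$x), n = 1),
                        algorithm = "port",
                        lower = c(ymax = 1e-12, k = 1e-6, n = 1e-3),
                        control = stats::nls.control(maxiter = 500,
                                                     warnOnly = TRUE)),
             silent = TRUE)
  if (inherits(fit, "try-error") || !is.null(attr(fit, "condition"))) {
    if (inherits(fit, "try-error"))
      return(structure(list(ymax = NA_real_, k_half = NA_real_,
                            n_exp = NA_real_, fitted = rep(NA_real_, nrow(df)),
                            residuals = rep(NA_real_, nrow(df)),
                            converged = FALSE), class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(ymax = unname(cf["ymax"]), k_half = unname(cf["k"]),
                 n_exp = unname(cf["n"]),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 converged = fit$convInfo$isConv &&
                   stats::sd(curvature) > 1e-12 * mean(curvature)),
            class = "hill_fit")
}

#' Final dimensioned tissue Krogh coefficient
#'
#' `Kt = ratio_mean x Kf`. The relative uncertainty of the ratio (~16% in a
#' typical study) dominates the ~2% fluid uncertainty, which is neglected.
#'
#' @param ratio_mean,ratio_sd pooled Krogh ratio and its sample SD.
#' @param kf fluid Krogh coefficient, mol/(m s Pa).
#' @param kf_sd fluid SD (accepted for the record, not propagated).
#' @return list `kt`, `kt_sd` in mol/(m s Pa).
#' @export
final_kt <- function(ratio_mean, ratio_sd, kf, kf_sd = 0) {
  stopifnot(ratio_mean > 0, kf > 0)
  kt <- ratio_mean * kf
  list(kt = kt, kt_sd = kt * ratio_sd / ratio_mean)
}
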