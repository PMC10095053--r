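#' A measured (or simulated) oxygen tension sounding
#'
#' A vertical pO2 profile: probe depth (um, increasing downward, arbitrary
#' origin) against oxygen tension (mmHg), sampled at a uniform step (nominal
#' 50 um) from the fluid above the slice, through the tissue, into the fluid
#' below. Carries the perfusion flow rate and identifiers used for grouping
#' and pairing.
#'
#' @param depth numeric vector of probe depths, um; strictly increasing with
#'   uniform spacing.
#' @param po2 numeric vector of oxygen tensions, mmHg (>= 0).
#' @param flow_ml_min perfusion flow rate, mL/min.
#' @param location_id,repeat_index,dataset_id identifiers.
#' @param step sampling interval, um; inferred from `depth` if omitted.
#' @return An object of class `pressure_profile`.
#' @export
pressure_profile_data <- function(depth, po2, flow_ml_min = NA_real_,
                                  location_id = NA_character_,
                                  repeat_index = 1L,
                                  dataset_id = NA_character_,
                                  step = NULL) {
  stopifnot(length(depth) == length(po2), length(depth) >= 12L)
  d <- diff(depth)
  if (any(d <= 0)) stop("depths must be strictly increasing")
  if (diff(range(d)) > 1e-6 * mean(d)) stop("sampling step must be uniform")
  if (any(po2 < 0)) stop("po2 must be non-negative")
  structure(list(depth = as.numeric(depth), po2 = as.numeric(po2),
                 flow_ml_min = flow_ml_min,
                 location_id = as.character(location_id),
                 repeat_index = as.integer(repeat_index),
                 dataset_id = as.character(dataset_id),
                 step = if (is.null(step)) mean(d) else step),
            class = "pressure_profile")
}

#' @export
print.pressure_profile <- function(x, ...) {
  cat(sprintf("pO2 sounding %s/%s rep %d: %d samples, step %g um, flow %g mL/min\n",
              x$dataset_id, x$location_id, x$repeat_index,
              length(x$depth), x$step, x$flow_ml_min))
  invisible(x)
}

#' Write a profile to the CSV dialect
#'
#' Header lines `# key=value` (dataset_id, location_id, repeat_index,
#' flow_ml_min, step_um) followed by columns `depth_um,po2_mmHg`.
#'
#' @param profile a [pressure_profile_data()] object.
#' @param path output path.
#' @export
write_profile_csv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dataset_id=%s", profile$dataset_id),
    sprintf("# location_id=%s", profile$location_id),
    sprintf("# repeat_index=%d", profile$repeat_index),
    sprintf("# flow_ml_min=%.17g", profile$flow_ml_min),
    sprintf("# step_um=%.17g", profile$step),
    "depth_um,po2_mmHg"), con)
  writeLines(sprintf("%.17g,%.17g", profile$depth, profile$po2), con)
  invisible(path)
}

#' Read a profile from the CSV dialect
#'
#' @param path path to a profile CSV written by [write_profile_csv()].
#' @return A [pressure_profile_data()] object.
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  pressure_profile_data(body$depth_um, body$po2_mmHg,
                        flow_ml_min = as.numeric(meta$flow_ml_min %||% NA),
                        location_id = meta$location_id %||% NA_character_,
                        repeat_index = as.integer(meta$repeat_index %||% 1L),
                        dataset_id = meta$dataset_id %||% NA_character_,
                        step = as.numeric(meta$step_um %||% NA))
}
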