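#' Nutrient environment with a static or orbiting sink
#'
#' Nutrient availability is a dimensionless scalar in \[0, 1\] determined by
#' the distance to a sink (the point of zero availability): it increases
#' linearly with distance from the sink and saturates at 1 at
#' `decay_radius`.  The sink either sits at the box center (`"static"`) or
#' orbits it on a circle in the xy plane with amplitude `amplitude` and
#' period `period_mcs` (`"orbiting"`), modeling spatiotemporal nutrient
#' fluctuation in the tumor microenvironment.
#'
#' @param mode `"static"` or `"orbiting"`.
#' @param box_center Numeric 3-vector, the fixed box center (voxel units).
#' @param amplitude Orbit radius in voxels (default 50).
#' @param period_mcs Orbit period in MCS; required (> 0) in orbiting mode.
#' @param decay_radius Distance at which availability saturates at 1.
#' @return An object of class `"nutrient_env"`.
#' @export
nutrient_env <- function(mode = c("static", "orbiting"), box_center,
                         amplitude = 50, period_mcs = NULL,
                         decay_radius) {
  mode <- match.arg(mode)
  stopifnot(length(box_center) == 3, is.numeric(box_center),
            amplitude >= 0, decay_radius > 0)
  if (mode == "orbiting") {
    if (is.null(period_mcs) || period_mcs <= 0)
      stop("orbiting mode requires a positive period_mcs", call. = FALSE)
  } else {
    period_mcs <- Inf
  }
  structure(
    list(mode = mode, box_center = as.numeric(box_center),
         amplitude = amplitude, period_mcs = period_mcs,
         decay_radius = decay_radius),
    class = "nutrient_env"
  )
}

#' Sink center at a given time
#'
#' In static mode the sink is the box center.  In orbiting mode it follows
#' `box_center + A * (cos(2*pi*t/T), sin(2*pi*t/T), 0)`, starting on the +x
#' axis at `t = 0`.
#'
#' @param env A [nutrient_env()].
#' @param time Time in MCS.
#' @return Numeric 3-vector.
#' @export
sink_center <- function(env, time) {
  stopifnot(inherits(env, "nutrient_env"))
  if (env$mode == "static") return(env$box_center)
  phase <- 2 * pi * time / env$period_mcs
  env$box_center + env$amplitude * c(cos(phase), sin(phase), 0)
}

#' Nutrient availability at a position
#'
#' `clamp(|position - sink_center(time)| / decay_radius, 0, 1)`: zero at the
#' sink, linear within the saturation sphere, one beyond it.
#'
#' @param env A [nutrient_env()].
#' @param position Numeric 3-vector or an n-by-3 matrix of positions.
#' @param time Time in MCS.
#' @return Availability value(s) in \[0, 1\].
#' @export
nutrient_at <- function(env, position, time = 0) {
  stopifnot(inherits(env, "nutrient_env"))
  s <- sink_center(env, time)
  if (is.matrix(position)) {
    stopifnot(ncol(position) == 3)
    d <- sqrt((position[, 1] - s[1])^2 + (position[, 2] - s[2])^2 +
                (position[, 3] - s[3])^2)
  } else {
    stopifnot(length(position) == 3)
    d <- sqrt(sum((position - s)^2))
  }
  pmin(pmax(d / env$decay_radius, 0), 1)
}

#' Nutrient availability of a cell
#'
#' A cell's position is its center of mass, so its availability is
#' [nutrient_at()] evaluated there.
#'
#' @param cell Either a numeric 3-vector (center of mass) or a one-row data
#'   frame with columns `com_x`, `com_y`, `com_z` as returned in
#'   `sim_state()$cells`.
#' @param env A [nutrient_env()].
#' @param time Time in MCS.
#' @return Availability in \[0, 1\].
#' @export
cell_nutrient <- function(cell, env, time = 0) {
  com <- if (is.data.frame(cell)) {
    c(cell$com_x[1], cell$com_y[1], cell$com_z[1])
  } else {
    cell
  }
  if (anyNA(com)) stop("cell has no valid center of mass", call. = FALSE)
  nutrient_at(env, com, time)
}

#' Nutrient environment implied by a run configuration
#'
#' @param config A [run_config()].
#' @return A [nutrient_env()] whose box center matches the simulation grid.
#' @export
config_nutrient_env <- function(config) {
  ctr <- rep((config$grid_side - 1) / 2, 3)
  nutrient_env(
    mode = config$nutrient_mode, box_center = ctr,
    amplitude = config$orbit_amplitude,
    period_mcs = if (config$nutrient_mode == "orbiting") config$orbit_period else NULL,
    decay_radius = config$decay_radius
  )
}
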