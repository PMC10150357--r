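#' Lifecycle parameters
#'
#' Convenience constructor for the division/death block of a configuration;
#' [run_config()] embeds the same fields.
#'
#' @param division_age_min Minimum age (MCS) for division eligibility (2000).
#' @param death_age_min Minimum age (MCS) for death eligibility (4000).
#' @param division_volume_fraction Volume gate as a fraction of the target
#'   volume (0.9).
#' @param max_division_rate Division probability per MCS at full nutrient
#'   availability (0.005).
#' @param max_death_rate Death probability per MCS at zero availability
#'   (0.001).
#' @param dependency_mode `"linear"` or `"none"`.
#' @return A list of class `"lifecycle_params"`.
#' @export
lifecycle_params <- function(division_age_min = 2000, death_age_min = 4000,
                             division_volume_fraction = 0.9,
                             max_division_rate = 0.005,
                             max_death_rate = 0.001,
                             dependency_mode = c("linear", "none")) {
  dependency_mode <- match.arg(dependency_mode)
  stopifnot(division_age_min >= 0, death_age_min >= 0,
            max_division_rate >= 0, max_division_rate <= 1,
            max_death_rate >= 0, max_death_rate <= 1)
  structure(list(division_age_min = division_age_min,
                 death_age_min = death_age_min,
                 division_volume_fraction = division_volume_fraction,
                 max_division_rate = max_division_rate,
                 max_death_rate = max_death_rate,
                 dependency_mode = dependency_mode),
            class = "lifecycle_params")
}

as_lifecycle_params <- function(x) {
  if (inherits(x, "lifecycle_params")) return(x)
  if (inherits(x, "run_config"))
    return(lifecycle_params(x$division_age_min, x$death_age_min,
                            x$division_volume_fraction, x$max_division_rate,
                            x$max_death_rate, x$dependency_mode))
  stop("expected lifecycle_params or run_config", call. = FALSE)
}

#' Per-MCS division and death rates
#'
#' Under linear nutrient dependency the division rate rises linearly from 0
#' at zero availability to `max_division_rate` at full availability, while
#' the death rate falls linearly from `max_death_rate` to 0.  With
#' `dependency_mode = "none"` both rates are constant at their maxima, so
#' the two modes agree at the availability endpoints.
#'
#' @param n Nutrient availability in \[0, 1\] (vectorized).
#' @param params A [lifecycle_params()] or [run_config()].
#' @return Probability (per MCS, per eligible cell).
#' @export
division_rate <- function(n, params) {
  p <- as_lifecycle_params(params)
  if (any(n < 0 | n > 1)) stop("availability must lie in [0, 1]", call. = FALSE)
  if (p$dependency_mode == "linear") n * p$max_division_rate
  else rep(p$max_division_rate, length(n))
}

#' @rdname division_rate
#' @export
death_rate <- function(n, params) {
  p <- as_lifecycle_params(params)
  if (any(n < 0 | n > 1)) stop("availability must lie in [0, 1]", call. = FALSE)
  if (p$dependency_mode == "linear") (1 - n) * p$max_death_rate
  else rep(p$max_death_rate, length(n))
}

#' Division eligibility
#'
#' A cancer cell may divide once its age strictly exceeds
#' `division_age_min` and its volume strictly exceeds
#' `division_volume_fraction * target_volume` (450 voxels at defaults).
#' Healthy cells never divide; dying cells never divide.
#'
#' @param cell One row of `sim_state()$cells`.
#' @param time Current time (MCS).
#' @param params A [lifecycle_params()] or [run_config()].
#' @param target_volume Target cell volume V0.
#' @return Logical.
#' @export
eligible_to_divide <- function(cell, time, params, target_volume = 500) {
  p <- as_lifecycle_params(params)
  if (cell$type[1] != 1L || isTRUE(cell$dying[1]) || !isTRUE(cell$alive[1]))
    return(FALSE)
  (time - cell$birth_time[1]) > p$division_age_min &&
    cell$volume[1] > p$division_volume_fraction * target_volume
}

#' Divide a cell now
#'
#' Splits the cell's voxels by a plane of uniformly random orientation
#' through its center of mass; the smaller side becomes a new cell id.  Both
#' daughters restart their age at the current time and phenotypes are
#' assigned by the mutation-at-division rule of the configuration.
#' Degenerate planes (an empty side) are resampled a bounded number of
#' times, after which the division is skipped.
#'
#' This applies the division mechanics unconditionally; during a run the
#' engine draws division events stochastically from [division_rate()] for
#' eligible cells.
#'
#' @param sim A `"cpm_sim"`.
#' @param cell_id Id of a live, non-dying cancer cell.
#' @return List with `divided` (logical) and, when successful, `parent_id`
#'   and `daughter_id`.
#' @export
divide_cell <- function(sim, cell_id) {
  stopifnot(inherits(sim, "cpm_sim"))
  cpp_sim_divide(sim$ptr, as.integer(cell_id))
}

#' Mark a cell as dying
#'
#' Rate-based death is gradual: the cell's target volume and surface are set
#' to zero and the ordinary Potts dynamics shrink it until its last voxel is
#' copied away, at which point it is retired.  Killing an already-dying cell
#' is a no-op.  Only cancer cells die.
#'
#' @param sim A `"cpm_sim"`.
#' @param cell_id Cell id.
#' @return `sim`, invisibly.
#' @export
kill_cell <- function(sim, cell_id) {
  stopifnot(inherits(sim, "cpm_sim"))
  cpp_sim_kill(sim$ptr, as.integer(cell_id))
  invisible(sim)
}

#' One lifecycle pass over all cancer cells
#'
#' For every live, non-dying cancer cell, draws a division event (if the age
#' and volume gates pass) with probability [division_rate()] at the cell's
#' local nutrient availability, then a death event (if the death age gate
#' passes) with probability [death_rate()].  Healthy cells take no part.
#' Events are appended to the engine's event log.  The run loop calls this
#' once per MCS after the sweep.
#'
#' @param sim A `"cpm_sim"`.
#' @return `sim`, invisibly.
#' @export
lifecycle_step <- function(sim) {
  stopifnot(inherits(sim, "cpm_sim"))
  cpp_sim_lifecycle(sim$ptr)
  invisible(sim)
}

#' Nutrient availability of a cell in a running simulation
#'
#' @param sim A `"cpm_sim"`.
#' @param cell_id Cell id.
#' @return Availability in \[0, 1\] at the cell's center of mass and the
#'   engine's current time.
#' @export
sim_cell_nutrient <- function(sim, cell_id) {
  cpp_sim_cell_nutrient(sim$ptr, as.integer(cell_id))
}

#' Low-level state setters
#'
#' Direct manipulation of single cells, intended for constructing controlled
#' scenarios (e.g. making a cell division-eligible or fixing its motility
#' direction in a test).
#'
#' @param sim A `"cpm_sim"`.
#' @param cell_id Cell id.
#' @param time,adh_index,mot_index,direction New values.
#' @return `sim`, invisibly.
#' @name sim_setters
NULL

#' @rdname sim_setters
#' @export
sim_set_birth_time <- function(sim, cell_id, time) {
  cpp_sim_set_birth(sim$ptr, as.integer(cell_id), as.numeric(time))
  invisible(sim)
}

#' @rdname sim_setters
#' @export
sim_set_phenotype <- function(sim, cell_id, adh_index, mot_index) {
  cpp_sim_set_phenotype(sim$ptr, as.integer(cell_id), as.integer(adh_index),
                        as.integer(mot_index))
  invisible(sim)
}

#' @rdname sim_setters
#' @export
sim_set_direction <- function(sim, cell_id, direction) {
  cpp_sim_set_direction(sim$ptr, as.integer(cell_id), as.numeric(direction))
  invisible(sim)
}
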