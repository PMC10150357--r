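#' Specification for a synthetic drifting composition
#'
#' Describes a phenotype-space trajectory with known ground truth: a
#' population whose distribution is a bivariate Gaussian drifting at a
#' prescribed velocity, sampled onto the discrete 12x12 grid.  Used to
#' validate the centroid/MSD/speed estimators without running the
#' simulator.
#'
#' @param start Numeric 2-vector (adhesion, motility) of the initial center.
#' @param velocity Numeric 2-vector, drift in parameter units per kMCS.
#' @param dispersion Standard deviation (parameter units) of the Gaussian in
#'   both axes.
#' @param population Number of cells drawn at every sample time.
#' @param sample_times Numeric vector of sampling times (MCS), strictly
#'   increasing.
#' @return A list of class `"drift_spec"`.
#' @export
drift_spec <- function(start = c(50, 50), velocity = c(-1, 0),
                       dispersion = 10, population = 1000,
                       sample_times = seq(0, 50000, by = 1000)) {
  stopifnot(length(start) == 2, length(velocity) == 2, dispersion >= 0,
            population >= 1, length(sample_times) >= 1,
            !is.unsorted(sample_times, strictly = TRUE))
  structure(list(start = as.numeric(start), velocity = as.numeric(velocity),
                 dispersion = dispersion, population = as.integer(population),
                 sample_times = as.numeric(sample_times)),
            class = "drift_spec")
}

#' Generate a drifting composition series with known ground truth
#'
#' At each sample time the Gaussian center is `start + velocity * (t - t0) /
#' 1000`; `population` cells are drawn from it (multinomial sampling noise)
#' and snapped to the nearest grid phenotype, with mass outside the grid
#' reassigned to the boundary.  Errors if the center drifts far outside the
#' grid (beyond 30 parameter units).  Uses R's RNG; seed with [set.seed()].
#'
#' @param spec A [drift_spec()].
#' @return Composition data frame with the same schema as
#'   [sim_composition()]: `time_mcs`, `adhesion`, `motility`, `count`.
#' @export
generate_drifting_composition <- function(spec) {
  stopifnot(inherits(spec, "drift_spec"))
  t0 <- spec$sample_times[1]
  grid <- phenotype_grid()
  rows <- lapply(spec$sample_times, function(t) {
    mu <- spec$start + spec$velocity * (t - t0) / 1000
    if (any(mu < -30 | mu > 140))
      stop("drift center far outside the phenotype grid at t = ", t,
           call. = FALSE)
    a <- rnorm(spec$population, mu[1], spec$dispersion)
    m <- rnorm(spec$population, mu[2], spec$dispersion)
    i <- pmin(11, pmax(0, round(a / 10)))
    j <- pmin(11, pmax(0, round(m / 10)))
    cnt <- tabulate(12 * i + j + 1, nbins = 144)
    data.frame(time_mcs = t, adhesion = grid$adhesion,
               motility = grid$motility, count = cnt[grid$phenotype_id])
  })
  do.call(rbind, rows)
}

#' Generate a synthetic event log with prescribed radial laws
#'
#' Draws division and death events whose radii follow caller-supplied
#' samplers, for testing [radial_event_histogram()].  Positions are the
#' radii along uniform random directions from the origin.  Uses R's RNG.
#'
#' @param n_division,n_death Number of events per kind.
#' @param division_radius,death_radius Functions `n -> numeric(n)` sampling
#'   event radii.
#' @return Event-log data frame with the [sim_events()] schema.
#' @export
generate_event_log <- function(n_division = 100, n_death = 100,
                               division_radius = function(n) runif(n, 20, 30),
                               death_radius = function(n) runif(n, 0, 10)) {
  one_kind <- function(kind, n, rsamp) {
    if (n == 0) {
      return(data.frame(time_mcs = numeric(0), event = character(0),
                        cell_id = integer(0), phenotype_id = integer(0),
                        x = numeric(0), y = numeric(0), z = numeric(0),
                        radius = numeric(0), mutated = logical(0)))
    }
    r <- rsamp(n)
    stopifnot(length(r) == n, all(r >= 0))
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    data.frame(time_mcs = seq_len(n), event = kind, cell_id = seq_len(n),
               phenotype_id = sample.int(144, n, replace = TRUE),
               x = r * s * cos(phi), y = r * s * sin(phi), z = r * z,
               radius = r, mutated = FALSE)
  }
  out <- rbind(one_kind("division", n_division, division_radius),
               one_kind("death", n_death, death_radius))
  out[order(out$time_mcs), , drop = FALSE]
}
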