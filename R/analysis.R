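#' Centroid of a phenotype-space composition
#'
#' The count-weighted mean (adhesion, motility) of the tumor composition;
#' its trajectory over time tracks the evolution of the tumor through
#' phenotype space.  Invariant under uniform scaling of the counts.
#'
#' @param counts Either a data frame with columns `adhesion`, `motility`,
#'   `count` (one time point), or a 12 x 12 matrix of counts with rows
#'   indexed by adhesion value (0, 10, ..., 110) and columns by motility.
#' @return Named numeric vector `c(adhesion = , motility = )`.
#' @export
#' @examples
#' centroid(data.frame(adhesion = c(0, 10), motility = 0, count = c(3, 1)))
centroid <- function(counts) {
  if (is.matrix(counts)) {
    stopifnot(all(dim(counts) == c(12, 12)))
    vals <- seq(0, 110, by = 10)
    tot <- sum(counts)
    if (tot <= 0) stop("empty composition: centroid undefined", call. = FALSE)
    return(c(adhesion = sum(rowSums(counts) * vals) / tot,
             motility = sum(colSums(counts) * vals) / tot))
  }
  stopifnot(is.data.frame(counts),
            all(c("adhesion", "motility", "count") %in% names(counts)))
  tot <- sum(counts$count)
  if (tot <= 0) stop("empty composition: centroid undefined", call. = FALSE)
  c(adhesion = sum(counts$count * counts$adhesion) / tot,
    motility = sum(counts$count * counts$motility) / tot)
}

#' Centroid trajectory of a composition series
#'
#' @param composition Data frame as returned by [sim_composition()]:
#'   columns `time_mcs`, `adhesion`, `motility`, `count`.
#' @return Data frame with `time_mcs`, `adhesion`, `motility` (centroid
#'   coordinates), and `n_cells`; sampling times with an empty composition
#'   are dropped.
#' @export
composition_centroids <- function(composition) {
  stopifnot(all(c("time_mcs", "adhesion", "motility", "count") %in%
                  names(composition)))
  tot <- rowsum(composition$count, composition$time_mcs)
  sa <- rowsum(composition$count * composition$adhesion, composition$time_mcs)
  sm <- rowsum(composition$count * composition$motility, composition$time_mcs)
  times <- as.numeric(rownames(tot))
  keep <- tot[, 1] > 0
  out <- data.frame(time_mcs = times[keep],
                    adhesion = sa[keep, 1] / tot[keep, 1],
                    motility = sm[keep, 1] / tot[keep, 1],
                    n_cells = tot[keep, 1])
  out[order(out$time_mcs), , drop = FALSE]
}

#' Mean squared displacement of the centroid
#'
#' Squared distance in phenotype space from the trajectory's first sample,
#' `|c(t) - c(t0)|^2`, in squared parameter units.
#'
#' @param centroids Data frame from [composition_centroids()].
#' @return Data frame with `time_mcs` and `msd`; `msd` is 0 at the first
#'   sample.
#' @export
msd <- function(centroids) {
  stopifnot(nrow(centroids) >= 1)
  da <- centroids$adhesion - centroids$adhesion[1]
  dm <- centroids$motility - centroids$motility[1]
  data.frame(time_mcs = centroids$time_mcs, msd = da^2 + dm^2)
}

#' Evolution speed of a centroid trajectory
#'
#' The centroid trajectory is smoothed component-wise by a centered moving
#' average of `window_mcs` (so sampling noise does not inflate the speed
#' through the modulus), then differentiated by centered finite differences:
#' `speed(t_k) = |c(t_{k+1}) - c(t_{k-1})| / (t_{k+1} - t_{k-1})`, reported
#' in parameter units per kMCS.  The raw (unsmoothed) speed series and the
#' time derivative of the mean squared displacement are returned alongside.
#' Edge samples without a full window or centered difference are NA.
#'
#' @param centroids Data frame from [composition_centroids()] (>= 2 rows).
#' @param window_mcs Smoothing window in MCS (default 10000, i.e. 10 kMCS).
#' @param burn_in_frac Fraction of the earliest samples excluded from the
#'   run mean (default 0.1): the initial expansion phase is not the
#'   evolutionary steady state.
#' @return List with `series` (data frame: `time_mcs`, `speed_raw`,
#'   `speed`), `msd_gradient` (data frame: `time_mcs`, `dmsd_dt`, in squared
#'   parameter units per kMCS), `mean_speed` (run mean of the smoothed
#'   speed after burn-in), and `window_samples`.
#' @export
evolution_speed <- function(centroids, window_mcs = 10000,
                            burn_in_frac = 0.1) {
  n <- nrow(centroids)
  if (n < 2) stop("need at least two samples to estimate a speed", call. = FALSE)
  t_k <- centroids$time_mcs / 1000   # kMCS
  dt_med <- stats::median(diff(t_k))
  w <- max(1L, as.integer(round((window_mcs / 1000) / dt_med)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > n) stop("smoothing window larger than the series", call. = FALSE)

  smooth1 <- function(x) {
    if (w == 1L) return(x)
    as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  }
  cdiff_speed <- function(a, m) {
    sp <- rep(NA_real_, n)
    if (n >= 3) {
      i <- 2:(n - 1)
      sp[i] <- sqrt((a[i + 1] - a[i - 1])^2 + (m[i + 1] - m[i - 1])^2) /
        (t_k[i + 1] - t_k[i - 1])
    }
    sp
  }
  speed_raw <- cdiff_speed(centroids$adhesion, centroids$motility)
  speed <- cdiff_speed(smooth1(centroids$adhesion), smooth1(centroids$motility))
  if (n == 2) {
    v <- sqrt(diff(centroids$adhesion)^2 + diff(centroids$motility)^2) /
      diff(t_k)
    speed_raw <- speed <- rep(v, 2)
  }

  ms <- msd(centroids)$msd
  dmsd <- rep(NA_real_, n)
  if (n >= 3) {
    i <- 2:(n - 1)
    dmsd[i] <- (ms[i + 1] - ms[i - 1]) / (t_k[i + 1] - t_k[i - 1])
  }

  drop_n <- ceiling(burn_in_frac * n)
  post <- seq_len(n) > drop_n
  list(series = data.frame(time_mcs = centroids$time_mcs,
                           speed_raw = speed_raw, speed = speed),
       msd_gradient = data.frame(time_mcs = centroids$time_mcs,
                                 dmsd_dt = dmsd),
       mean_speed = mean(speed[post], na.rm = TRUE),
       window_samples = w)
}

#' Spread of the phenotype distribution
#'
#' The number of phenotypes occupied by strictly more than `min_cells`
#' cells, a heterogeneity measure of the tumor composition.
#'
#' @param counts Data frame with a `count` column, a matrix, or a numeric
#'   vector of per-phenotype counts (one time point).
#' @param min_cells Strict occupancy threshold (default 10).
#' @return Integer count of phenotypes above threshold.
#' @export
#' @examples
#' spread(c(11, 10, 200))  # 2
spread <- function(counts, min_cells = 10) {
  x <- if (is.data.frame(counts)) counts$count else as.numeric(counts)
  sum(x > min_cells)
}

#' Spread trajectory of a composition series
#'
#' @inheritParams composition_centroids
#' @inheritParams spread
#' @return Data frame with `time_mcs` and `spread`.
#' @export
composition_spread <- function(composition, min_cells = 10) {
  s <- rowsum((composition$count > min_cells) + 0, composition$time_mcs)
  data.frame(time_mcs = as.numeric(rownames(s)), spread = s[, 1],
             row.names = NULL)
}

#' Radial histogram of division and death events
#'
#' Bins event radii (distance from the box center) per event kind.  In the
#' spheroid, deaths concentrate toward the nutrient-poor center and
#' divisions toward the rim, so the mean division radius exceeds the mean
#' death radius.
#'
#' @param events Event log data frame (see [sim_events()]).
#' @param bin_width Radial bin width in voxels.
#' @param kinds Event kinds to include.
#' @return List with `histogram` (data frame: `event`, `bin_lo`, `bin_hi`,
#'   `bin_mid`, `count`) and `mean_radius` (data frame: `event`,
#'   `mean_radius`, `n`).
#' @export
radial_event_histogram <- function(events, bin_width = 5,
                                   kinds = c("division", "death")) {
  ev <- events[events$event %in% kinds, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(list(
      histogram = data.frame(event = character(0), bin_lo = numeric(0),
                             bin_hi = numeric(0), bin_mid = numeric(0),
                             count = integer(0)),
      mean_radius = data.frame(event = character(0),
                               mean_radius = numeric(0), n = integer(0))))
  }
  rmax <- max(ev$radius)
  breaks <- seq(0, bin_width * ceiling(rmax / bin_width + 1e-9), by = bin_width)
  if (length(breaks) < 2) breaks <- c(0, bin_width)
  hist_rows <- lapply(kinds, function(k) {
    r <- ev$radius[ev$event == k]
    cnt <- if (length(r) == 0) integer(length(breaks) - 1) else
      as.integer(table(cut(r, breaks, right = FALSE,
                           include.lowest = TRUE)))
    data.frame(event = k, bin_lo = breaks[-length(breaks)],
               bin_hi = breaks[-1],
               bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
               count = cnt)
  })
  means <- lapply(kinds, function(k) {
    r <- ev$radius[ev$event == k]
    data.frame(event = k,
               mean_radius = if (length(r)) mean(r) else NA_real_,
               n = length(r))
  })
  list(histogram = do.call(rbind, hist_rows),
       mean_radius = do.call(rbind, means))
}

#' Summarize one run's evolutionary trajectory
#'
#' @param composition Composition series (see [sim_composition()]).
#' @param window_mcs,burn_in_frac Passed to [evolution_speed()].
#' @param min_cells Spread threshold.
#' @return List of class `"evolution_summary"`: `centroids`, `msd`, `speed`
#'   (the [evolution_speed()] result, or NULL for short series),
#'   `spread_series`, `mean_speed`, `mean_spread` (burn-in excluded).
#' @export
summarize_run <- function(composition, window_mcs = 10000,
                          burn_in_frac = 0.1, min_cells = 10) {
  cen <- composition_centroids(composition)
  spd <- if (nrow(cen) >= 2) {
    w_ok <- tryCatch(evolution_speed(cen, window_mcs, burn_in_frac),
                     error = function(e) NULL)
    w_ok
  } else NULL
  spr <- composition_spread(composition, min_cells)
  drop_n <- ceiling(burn_in_frac * nrow(spr))
  post <- seq_len(nrow(spr)) > drop_n
  structure(
    list(centroids = cen, msd = msd(cen),
         speed = spd, spread_series = spr,
         mean_speed = if (is.null(spd)) NA_real_ else spd$mean_speed,
         mean_spread = mean(spr$spread[post])),
    class = "evolution_summary")
}

#' @export
print.evolution_summary <- function(x, ...) {
  cat(sprintf(
    "<evolution_summary: %d samples, mean speed %.4g /kMCS, mean spread %.3g>\n",
    nrow(x$centroids), x$mean_speed, x$mean_spread))
  invisible(x)
}

#' Compare period-sweep groups against the constant control
#'
#' For every fluctuation period, computes the mean and standard deviation of
#' the per-run mean evolution speed and spread, and a Welch two-sample
#' t-test against the constant-environment control group.  p-values below
#' `alpha` (default 0.04) are flagged as significant.
#'
#' @param sweep_summary Data frame from [sweep_periods()] (columns
#'   `period_mcs`, `mean_speed`, `mean_spread`; rows with NA metrics are
#'   dropped).
#' @param control_period Period value labeling the control group (0).
#' @param alpha Significance threshold.
#' @return Data frame with one row per period: group size, speed and spread
#'   means and SDs, Welch p-values vs control, and significance flags
#'   (control rows carry NA p-values).
#' @export
compare_periods <- function(sweep_summary, control_period = 0, alpha = 0.04) {
  ss <- sweep_summary[!is.na(sweep_summary$mean_speed) &
                        !is.na(sweep_summary$mean_spread), , drop = FALSE]
  if (!control_period %in% ss$period_mcs)
    stop("no control group (period ", control_period, ") in the summary",
         call. = FALSE)
  ctrl <- ss[ss$period_mcs == control_period, , drop = FALSE]
  welch <- function(x, y) {
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (sd(x) == 0 && sd(y) == 0) {
      warning("degenerate variance in both groups; p reported as NA",
              call. = FALSE)
      return(NA_real_)
    }
    tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
  }
  periods <- sort(unique(ss$period_mcs))
  rows <- lapply(periods, function(Tp) {
    g <- ss[ss$period_mcs == Tp, , drop = FALSE]
    p_sp <- if (Tp == control_period) NA_real_ else
      welch(g$mean_speed, ctrl$mean_speed)
    p_sd <- if (Tp == control_period) NA_real_ else
      welch(g$mean_spread, ctrl$mean_spread)
    data.frame(period_mcs = Tp, n = nrow(g),
               speed_mean = mean(g$mean_speed), speed_sd = sd(g$mean_speed),
               p_speed = p_sp,
               speed_significant = isTRUE(p_sp < alpha),
               spread_mean = mean(g$mean_spread),
               spread_sd = sd(g$mean_spread),
               p_spread = p_sd,
               spread_significant = isTRUE(p_sd < alpha))
  })
  do.call(rbind, rows)
}

#' Plot helpers
#'
#' `plot_trajectory()` draws the centroid path through phenotype space;
#' `plot_period_sweep()` draws mean +/- SD of speed (or spread) against the
#' fluctuation period.  Both require ggplot2.
#'
#' @param centroids Data frame from [composition_centroids()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(centroids) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot helpers require ggplot2", call. = FALSE)
  ggplot2::ggplot(centroids,
                  ggplot2::aes(x = .data$adhesion, y = .data$motility,
                               color = .data$time_mcs / 1000)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_fixed(xlim = c(0, 110), ylim = c(0, 110)) +
    ggplot2::labs(x = "cell-cell adhesion", y = "motility",
                  color = "time [kMCS]") +
    ggplot2::theme_minimal()
}

#' @rdname plot_trajectory
#' @param period_stats Data frame from [compare_periods()].
#' @param metric `"speed"` or `"spread"`.
#' @export
plot_period_sweep <- function(period_stats, metric = c("speed", "spread")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot helpers require ggplot2", call. = FALSE)
  metric <- match.arg(metric)
  m <- period_stats[[paste0(metric, "_mean")]]
  s <- period_stats[[paste0(metric, "_sd")]]
  df <- data.frame(period = period_stats$period_mcs, mean = m,
                   lo = m - s, hi = m + s,
                   sig = period_stats[[paste0(metric, "_significant")]])
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$period), y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                          color = .data$sig)) +
    ggplot2::labs(x = "fluctuation period T [MCS] (0 = constant)",
                  y = paste("mean evolution", metric),
                  color = "p < 0.04") +
    ggplot2::theme_minimal()
}
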