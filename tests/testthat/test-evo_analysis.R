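test_that("centroid is the count-weighted mean of phenotype coordinates", {
  one <- data.frame(adhesion = 50, motility = 50, count = 7)
  expect_equal(centroid(one), c(adhesion = 50, motility = 50))
  sym <- data.frame(adhesion = c(0, 110), motility = c(0, 110), count = 1)
  expect_equal(centroid(sym), c(adhesion = 55, motility = 55))
  hand <- data.frame(adhesion = c(0, 10), motility = c(0, 0), count = c(3, 1))
  expect_equal(centroid(hand), c(adhesion = 2.5, motility = 0))
  # matrix input, and invariance under uniform scaling of the counts
  set.seed(2)
  m <- matrix(rpois(144, 3), 12, 12)
  expect_equal(centroid(m), centroid(7 * m))
  expect_error(centroid(0 * m), "empty composition")
})

test_that("MSD is the squared displacement from the first sample", {
  cen <- data.frame(time_mcs = c(0, 1000, 2000),
                    adhesion = c(50, 48, 46), motility = c(50, 50, 50),
                    n_cells = 10)
  expect_equal(msd(cen)$msd, c(0, 4, 16))
  # straight-line drift at speed v: msd(t) = v^2 t^2
  t <- seq(0, 20000, by = 1000)
  v <- 0.7  # parameter units per kMCS
  drift <- data.frame(time_mcs = t, adhesion = 50 - v * t / 1000,
                      motility = 50, n_cells = 1)
  expect_lt(max(abs(msd(drift)$msd - v^2 * (t / 1000)^2)), 1e-12)
  expect_equal(msd(drift[1, ])$msd, 0)
})

test_that("evolution speed recovers a noise-free constant drift exactly", {
  t <- seq(0, 30000, by = 1000)
  v <- c(-0.6, 0.8)  # |v| = 1
  cen <- data.frame(time_mcs = t, adhesion = 50 + v[1] * t / 1000,
                    motility = 40 + v[2] * t / 1000, n_cells = 1)
  es <- evolution_speed(cen, window_mcs = 5000)
  interior <- !is.na(es$series$speed)
  expect_true(any(interior))
  expect_lt(max(abs(es$series$speed[interior] - 1)), 1e-12)
  expect_equal(es$mean_speed, 1, tolerance = 1e-12)
  # static trajectory: zero speed
  stat <- data.frame(time_mcs = t, adhesion = 50, motility = 50, n_cells = 1)
  expect_equal(evolution_speed(stat, 5000)$mean_speed, 0)
  # msd gradient of linear drift grows linearly: d(v^2 t^2)/dt = 2 v^2 t
  g <- evolution_speed(cen, window_mcs = 5000)$msd_gradient
  i <- 5
  expect_equal(g$dmsd_dt[i], 2 * 1 * (t[i] / 1000), tolerance = 1e-12)
  expect_error(evolution_speed(cen, window_mcs = 50000), "window larger")
  expect_error(evolution_speed(cen[1, , drop = FALSE]), "two samples")
})

test_that("evolution speed is symmetric under time reversal", {
  set.seed(9)
  t <- seq(0, 20000, by = 500)
  cen <- data.frame(time_mcs = t,
                    adhesion = 50 - 0.3 * t / 1000 + rnorm(length(t), 0, 0.5),
                    motility = 50 + rnorm(length(t), 0, 0.5), n_cells = 1)
  rev_cen <- cen
  rev_cen$adhesion <- rev(cen$adhesion)
  rev_cen$motility <- rev(cen$motility)
  a <- evolution_speed(cen, 4000)$series$speed
  b <- evolution_speed(rev_cen, 4000)$series$speed
  expect_equal(a, rev(b), tolerance = 1e-12)
})

test_that("spread counts phenotypes with strictly more than the threshold", {
  expect_equal(spread(rep(0, 144)), 0)
  expect_equal(spread(c(11, 10, 200)), 2)
  expect_equal(spread(rep(11, 144)), 144)
  expect_equal(spread(data.frame(count = c(5, 15, 10))), 1)
  expect_equal(spread(c(20, 30), min_cells = 25), 1)
})

test_that("radial histograms bin events exactly and order the means", {
  empty <- radial_event_histogram(data.frame(event = character(0),
                                             radius = numeric(0)))
  expect_equal(nrow(empty$histogram), 0)
  fixed <- data.frame(event = c("division", "division", "death"),
                      radius = c(12, 13, 2))
  h <- radial_event_histogram(fixed, bin_width = 5)
  hd <- h$histogram[h$histogram$event == "division", ]
  expect_equal(hd$count[hd$bin_lo == 10], 2)
  expect_equal(sum(hd$count), 2)
  expect_equal(h$mean_radius$mean_radius[h$mean_radius$event == "death"], 2)

  set.seed(31)
  ev <- generate_event_log(300, 300,
                           division_radius = function(n) runif(n, 20, 30),
                           death_radius = function(n) runif(n, 0, 10))
  m <- radial_event_histogram(ev)$mean_radius
  expect_gt(m$mean_radius[m$event == "division"],
            m$mean_radius[m$event == "death"])
})

test_that("period comparison reproduces a hand-evaluated Welch test", {
  mk <- function(period, speeds, spreads)
    data.frame(period_mcs = period, replicate = seq_along(speeds),
               mean_speed = speeds, mean_spread = spreads)
  ctrl <- mk(0, c(1.0, 1.1, 0.9), c(10, 11, 12))
  grp <- mk(5000, c(2.0, 2.2, 1.8), c(10, 11, 12))
  st <- compare_periods(rbind(ctrl, grp))
  # direct Welch-Satterthwaite evaluation on the fixed numbers
  x <- grp$mean_speed; y <- ctrl$mean_speed
  se2 <- var(x) / 3 + var(y) / 3
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  p_manual <- 2 * pt(-abs(tstat), df)
  row <- st[st$period_mcs == 5000, ]
  expect_equal(row$p_speed, p_manual, tolerance = 1e-12)
  expect_true(row$speed_significant)
  expect_equal(row$speed_mean, 2)
  expect_equal(row$speed_sd, sd(c(2.0, 2.2, 1.8)))
  # identical groups (with internal variance): p = 1, not flagged
  same <- rbind(ctrl, mk(200, c(1.0, 1.1, 0.9), c(10, 11, 12)))
  st2 <- compare_periods(same)
  expect_equal(st2$p_speed[st2$period_mcs == 200], 1)
  expect_false(st2$speed_significant[st2$period_mcs == 200])
  # control rows carry no p-value
  expect_true(is.na(st$p_speed[st$period_mcs == 0]))
})

test_that("degenerate variance yields a warning, not a significance flag", {
  mk <- function(period, speeds)
    data.frame(period_mcs = period, replicate = seq_along(speeds),
               mean_speed = speeds, mean_spread = speeds)
  # both the speed and the spread comparison are degenerate here
  expect_warning(expect_warning(
    st <- compare_periods(rbind(mk(0, c(1, 1, 1)), mk(100, c(2, 2, 2)))),
    "degenerate"), "degenerate")
  expect_true(is.na(st$p_speed[st$period_mcs == 100]))
  expect_false(st$speed_significant[st$period_mcs == 100])
  expect_error(compare_periods(mk(100, c(1, 2))), "control")
})

test_that("run summaries assemble centroids, speed, and spread", {
  set.seed(77)
  comp <- generate_drifting_composition(
    drift_spec(start = c(60, 50), velocity = c(-1, 0), dispersion = 6,
               population = 2000, sample_times = seq(0, 30000, 1000)))
  summ <- summarize_run(comp, window_mcs = 5000)
  expect_s3_class(summ, "evolution_summary")
  expect_equal(nrow(summ$centroids), 31)
  expect_equal(summ$mean_speed, 1, tolerance = 0.1)
  expect_true(summ$mean_spread >= 1 && summ$mean_spread <= 144)
})
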