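# Grid construction, site sampling, scheduling, detection and simulation.

test_that("the default grid reproduces the low-density survey design", {
  arr <- build_grid_array()
  expect_equal(attr(arr, "n_units"), 20)
  expect_equal(attr(arr, "density"), 20 / 30, tolerance = 1e-12)
  expect_equal(nrow(arr), 40)  # two channels per recorder
  # all recorders inside the study area
  expect_true(all(arr$x >= 0 & arr$x <= 6000 & arr$y >= 0 & arr$y <= 5000))
  # co-located stereo channels 0.4 m apart
  sep <- tidyr::pivot_wider(tibble::as_tibble(arr), id_cols = "recorder_id",
                            names_from = "channel", values_from = "x")
  expect_true(all(abs(sep$B - sep$A - 0.4) < 1e-12))
})

test_that("degenerate and jittered grids behave", {
  one <- build_grid_array(n_cols = 1, n_rows = 1, study_area = c(2000, 2000))
  expect_equal(mean(one$x), 1000)
  expect_equal(mean(one$y), 1000)
  expect_equal(attr(one, "density"), 1 / 4)

  a1 <- build_grid_array(jitter_sd = 5, seed = 7)
  a2 <- build_grid_array(jitter_sd = 5, seed = 7)
  expect_identical(a1$x, a2$x)

  expect_error(build_grid_array(n_cols = 10, spacing = 1000), "exceeds")
})

test_that("site sampling follows stratum weights by largest remainder", {
  s <- sample_broadcast_sites(n_sites = 60, strata = c(a = 0.5, b = 0.5), seed = 3)
  expect_equal(unname(table(s$stratum)[c("a", "b")]), c(30L, 30L),
               ignore_attr = TRUE)
  s2 <- sample_broadcast_sites(n_sites = 10,
                               strata = c(a = 0.24, b = 0.37, c = 0.39), seed = 3)
  expect_equal(sort(as.integer(table(s2$stratum))), c(2L, 4L, 4L))
  expect_error(sample_broadcast_sites(strata = c(a = 0.6, b = 0.6)), "sum to 1")
})

test_that("site-to-nearest-recorder distances span the field range", {
  arr <- build_grid_array()
  units <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(arr), recorder_id),
                            x = mean(x), y = mean(y), .groups = "drop")
  nearest <- unlist(lapply(1:20, function(s) {
    st <- sample_broadcast_sites(seed = s)
    vapply(seq_len(nrow(st)), function(i) {
      min(sqrt((units$x - st$x[i])^2 + (units$y - st$y[i])^2))
    }, numeric(1))
  }))
  # the field campaign saw 67--3595 m; the default buffer reproduces that span
  expect_lt(min(nearest), 300)
  expect_gt(max(nearest), 2500)
  expect_lt(max(nearest), 4500)
})

test_that("the campaign schedule is a Latin rotation with correct totals", {
  sites <- sample_broadcast_sites(seed = 2)
  plan <- schedule_campaign(sites, seed = 2)
  expect_equal(nrow(plan), 180)  # 60 sites x 3 nights
  # each site once per night, in three different periods
  per_site <- dplyr::summarise(dplyr::group_by(plan, site_id),
                               n = dplyr::n(),
                               n_nights = dplyr::n_distinct(night),
                               n_periods = dplyr::n_distinct(period))
  expect_true(all(per_site$n == 3))
  expect_true(all(per_site$n_nights == 3))
  expect_true(all(per_site$n_periods == 3))
  # broadcast time falls inside its period window
  win <- c(dusk = 0, night = 3 * 3600, dawn = 6 * 3600)
  rel <- plan$t0_s %% 86400
  expect_true(all(rel >= win[plan$period] & rel < win[plan$period] + 3 * 3600))

  # exclusions: two inaccessible sites drop 6 broadcasts
  plan_vm <- schedule_campaign(sites, excluded_sites = sites$site_id[1:2], seed = 2)
  expect_equal(nrow(plan_vm), 174)
  expect_error(schedule_campaign(sites, excluded_sites = "nope"), "subset")
  expect_error(schedule_campaign(sites, nights = 3, periods = 2), "periods")
})

test_that("detection probability is a decreasing logistic with midpoint d50", {
  env <- environment_model()
  expect_equal(detection_probability(env$detection_d50, env), 0.5)
  expect_gt(detection_probability(1, env), 0.99)
  expect_lt(detection_probability(1e6, env), 1e-10)
  d <- seq(10, 5000, by = 10)
  expect_true(all(diff(detection_probability(d, env)) < 0))
  expect_error(detection_probability(0, env), "distance")
})

test_that("campaign-level detection matches the calibration target", {
  arr <- build_grid_array()
  rates <- vapply(1:20, function(s) {
    sites <- sample_broadcast_sites(seed = s)
    plan <- schedule_campaign(sites, seed = s)
    det <- simulate_campaign(arr, plan, sites, seed = s)
    rec <- dplyr::summarise(
      dplyr::group_by(det, broadcast_id),
      n_rec = dplyr::n_distinct(recorder_id[detected == 1]), .groups = "drop"
    )
    mean(rec$n_rec >= 1)
  }, numeric(1))
  # about three quarters of broadcasts caught by at least one recorder
  expect_lt(abs(mean(rates) - 0.76), 0.10)
})

test_that("multiplicity histogram has a declining upper tail", {
  arr <- build_grid_array()
  mult <- unlist(lapply(1:5, function(s) {
    sites <- sample_broadcast_sites(seed = s)
    plan <- schedule_campaign(sites, seed = s)
    det <- simulate_campaign(arr, plan, sites, seed = s)
    rec <- dplyr::summarise(
      dplyr::group_by(det, broadcast_id),
      n_rec = dplyr::n_distinct(recorder_id[detected == 1]), .groups = "drop"
    )
    rec$n_rec
  }))
  h <- tabulate(mult, nbins = max(mult))
  top <- length(h)
  # pooled counts decline over the top multiplicities, and few-recorder
  # detections outnumber many-recorder ones
  expect_true(all(diff(h[(top - 2):top]) <= 0))
  expect_gt(sum(h[1:2]), sum(h[(top - 1):top]))
})

test_that("simulation is noise-free exact, deterministic and causal", {
  cp <- tiny_campaign(seed = 5, toa_noise_sd = 0, force_detection = TRUE)
  det <- cp$detections
  with_truth <- dplyr::left_join(
    det, dplyr::select(cp$plan, broadcast_id, t0_s), by = "broadcast_id"
  )
  cc <- sound_speed(with_truth$temp_c)
  expect_equal(with_truth$toa_s,
               with_truth$t0_s + with_truth$distance_m / cc, tolerance = 1e-12)

  d1 <- tiny_campaign(seed = 8)$detections
  d2 <- tiny_campaign(seed = 8)$detections
  expect_identical(d1, d2)

  # causality: arrival not earlier than the fastest physical delay
  noisy <- tiny_campaign(seed = 9)$detections
  noisy <- dplyr::left_join(noisy, dplyr::select(tiny_campaign(seed = 9)$plan,
                                                 broadcast_id, t0_s),
                            by = "broadcast_id")
  det1 <- noisy[noisy$detected == 1, ]
  c_max <- sound_speed(max(environment_model()$temperature_c$mean_temp_c))
  slack <- 5 * environment_model()$toa_noise_sd
  expect_true(all(det1$toa_s - det1$t0_s >= det1$distance_m / c_max - slack))
  expect_true(all(is.na(noisy$toa_s[noisy$detected == 0])))
})

test_that("noise-free forced-detection campaign localizes every site to < 1 m", {
  cp <- tiny_campaign(seed = 3, n_sites = 8, toa_noise_sd = 0,
                      force_detection = TRUE)
  est <- localize_all(cp$detections)
  expect_equal(nrow(est), nrow(cp$plan))
  truth <- dplyr::left_join(
    dplyr::left_join(est, cp$plan, by = "broadcast_id"),
    cp$sites, by = "site_id"
  )
  acc <- localization_accuracy(truth$x_est, truth$y_est, truth$x, truth$y)
  expect_lt(max(acc), 1)
  expect_lt(max(truth$temporal_error_ms), 0.01)
})
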