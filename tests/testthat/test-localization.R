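# Sound speed, microphone selection, solver, oracle, temporal error, filter.

test_that("sound speed follows the dry-air formula and is monotone", {
  expect_equal(sound_speed(0), 331.3)
  expect_equal(sound_speed(20), 331.3 * sqrt(1 + 20 / 273.15))
  expect_equal(sound_speed(20), 343.2, tolerance = 1e-3)
  t_grid <- seq(-40, 50, by = 1)
  expect_true(all(diff(sound_speed(t_grid)) > 0))
  expect_error(sound_speed(-41), "range")
  expect_error(sound_speed(51), "range")
})

test_that("microphone selection picks best channels with the stereo fallback", {
  det <- tibble::tibble(
    broadcast_id = "B1",
    recorder_id = rep(c("R01", "R02", "R03", "R04"), each = 2),
    channel = rep(c("A", "B"), 4),
    x = rep(c(0, 1000, 2000, 3000), each = 2) + rep(c(-0.2, 0.2), 4),
    y = 0,
    detected = 1L,
    snr_db = c(10, 12, 15, 14, 8, 8, 20, 3),
    toa_s = 1:8, temp_c = 10
  )
  ts4 <- select_microphones(det)
  expect_s3_class(ts4, "toa_set")
  expect_equal(nrow(ts4), 4)
  expect_equal(length(unique(ts4$recorder_id)), 4)
  # best SNR per recorder; equal-SNR tie broken towards channel A
  expect_setequal(ts4$mic_id, c("R01B", "R02A", "R03A", "R04A"))

  # three recorders: spare channel of the best-SNR recorder completes the set
  det3 <- det[det$recorder_id != "R04", ]
  ts3 <- select_microphones(det3)
  expect_equal(nrow(ts3), 4)
  expect_equal(sum(ts3$recorder_id == "R02"), 2)

  # two recorders: failure value
  det2 <- det[det$recorder_id %in% c("R01", "R02"), ]
  expect_null(select_microphones(det2))

  # three recorders but no spare detected channel: cannot reach four mics
  det3b <- det3[det3$channel == "A", ]
  expect_null(select_microphones(det3b))
})

test_that("localization recovers known sources", {
  # symmetry: equal TOAs on a centred square give the centre
  mics <- square_mics(500)
  eq <- make_toaset(mics, src = c(0, 0), t0 = 0, temp = 15)
  est <- localize(eq)
  expect_lt(abs(est$x), 1e-6)
  expect_lt(abs(est$y), 1e-6)

  # noise-free recovery anywhere inside the hull: < 1 m, < 0.01 ms
  for (s in 1:10) {
    set.seed(s)
    src <- runif(2, -450, 450)
    ts <- make_toaset(square_mics(500), src = src, t0 = 3, temp = 8)
    e <- localize(ts)
    expect_lt(localization_accuracy(e$x, e$y, src[1], src[2]), 1)
    expect_lt(e$temporal_error_ms, 0.01)
    expect_equal(e$t0, 3, tolerance = 1e-6)
    expect_true(e$converged)
  }

  # outside the hull but within 1 km of it: < 5 m
  for (src in list(c(1200, 0), c(0, -1300), c(1100, 1100))) {
    ts <- make_toaset(square_mics(500), src = src, t0 = 1, temp = 12)
    e <- localize(ts)
    expect_lt(localization_accuracy(e$x, e$y, src[1], src[2]), 5)
  }
})

test_that("temperature consistency: TOAs regenerated at another temperature
           give the same position", {
  src <- c(210, -340)
  cold <- make_toaset(square_mics(600), src = src, temp = 0)
  warm <- make_toaset(square_mics(600), src = src, temp = 30)
  ec <- localize(cold); ew <- localize(warm)
  expect_lt(sqrt((ec$x - ew$x)^2 + (ec$y - ew$y)^2), 0.1)
})

test_that("co-located stereo fallback geometry is flagged ill-conditioned", {
  mics <- square_mics(500)[1:3, ]
  mics <- rbind(mics, mics[1, ])
  mics$mic_id[4] <- "R01B"; mics$channel[4] <- "B"; mics$x[4] <- mics$x[4] + 0.4
  ts <- make_toaset(mics, src = c(100, 50))
  e <- localize(ts)
  expect_equal(e$condition_flag, "ill_conditioned")
  expect_equal(e$n_recorders, 3)
  # collinear mics likewise
  lin <- tibble::tibble(
    mic_id = paste0("R0", 1:4, "A"), recorder_id = paste0("R0", 1:4),
    channel = "A", x = c(0, 1000, 2000, 3000), y = 0
  )
  e2 <- localize(make_toaset(lin, src = c(500, 400)))
  expect_equal(e2$condition_flag, "ill_conditioned")
})

test_that("grid oracle agrees with the solver and refines monotonically", {
  ts <- random_toaset(42)
  # noise-free objective at the true source is zero
  tsf <- random_toaset(42, noise_sd = 0)
  src <- attr(tsf, "true_source")
  o0 <- localize_grid_oracle(tsf, bounds = c(src[1] - 200, src[1] + 200,
                                             src[2] - 200, src[2] + 200),
                             resolution = 10)
  expect_lt(o0$objective, 1e-8)

  # refinement: objective non-increasing as the grid sharpens
  objs <- vapply(c(100, 10, 1), function(res) {
    localize_grid_oracle(ts, bounds = c(src[1] - 500, src[1] + 500,
                                        src[2] - 500, src[2] + 500),
                         resolution = res)$objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-15))

  # solver vs oracle on seeded noisy sets (the full 100-case sweep runs in
  # the acceptance suite)
  for (s in 1:10) {
    tsn <- random_toaset(s)
    l <- localize(tsn)
    o <- localize_grid_oracle(tsn, bounds = c(-2500, 8500, -2500, 7500),
                              resolution = 10)
    d <- sqrt((l$x - o$x)^2 + (l$y - o$y)^2)
    expect_true(d <= 10 || l$objective <= o$objective + 1e-10)
  }
})

test_that("temporal error matches hand computation and its invariances", {
  mics <- square_mics(500)
  src <- c(0, 0)
  ts <- make_toaset(mics, src = src, t0 = 2, temp = 10)
  expect_equal(temporal_error(src, ts), 0, tolerance = 1e-9)

  # +10 ms on one TOA: 3 of 6 pairs off by 10 ms -> RMS = 10 / sqrt(2)
  pert <- ts
  pert$toa[1] <- pert$toa[1] + 0.010
  expect_equal(temporal_error(src, pert), 10 / sqrt(2), tolerance = 1e-9)

  # invariant to a common TOA shift
  shifted <- ts
  shifted$toa <- shifted$toa + 123.456
  set.seed(1); probe <- runif(2, -400, 400)
  expect_equal(temporal_error(probe, shifted), temporal_error(probe, ts),
               tolerance = 1e-9)
})

test_that("the reliability filter keeps at-threshold estimates and preserves order", {
  est <- tibble::tibble(broadcast_id = c("a", "b", "c"),
                        temporal_error_ms = c(199, 200, 201))
  f <- filter_reliable(est)
  expect_equal(f$kept$broadcast_id, c("a", "b"))
  expect_equal(f$excluded$broadcast_id, "c")
  expect_equal(nrow(f$kept) + nrow(f$excluded), nrow(est))

  f_inf <- filter_reliable(est, threshold_ms = Inf)
  expect_equal(nrow(f_inf$kept), 3)
  expect_error(filter_reliable(est, threshold_ms = 0), "threshold")
})

test_that("median accuracy does not improve as TOA noise grows", {
  meds <- vapply(c(0, 0.01, 0.02, 0.05), function(sdv) {
    acc <- vapply(1:50, function(s) {
      ts <- random_toaset(s, noise_sd = sdv, n_rec = 5)
      src <- attr(ts, "true_source")
      e <- localize(ts)
      localization_accuracy(e$x, e$y, src[1], src[2])
    }, numeric(1))
    median(acc)
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
})
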