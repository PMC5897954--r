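# Fixtures built in code: small arrays, TOA sets and campaigns.

# four single-channel recorders at the corners of a square (side 2*half m)
square_mics <- function(half = 500) {
  tibble::tibble(
    mic_id = paste0("R0", 1:4, "A"),
    recorder_id = paste0("R0", 1:4),
    channel = "A",
    x = c(-half, -half, half, half),
    y = c(-half, half, -half, half)
  )
}

# noise-free (or noisy) TOA set from a known source over given mics
make_toaset <- function(mics, src = c(0, 0), t0 = 10, temp = 10,
                        noise_sd = 0, seed = NULL, broadcast_id = "B1") {
  cc <- howlspot::sound_speed(temp)
  d <- sqrt((mics$x - src[1])^2 + (mics$y - src[2])^2)
  if (!is.null(seed)) set.seed(seed)
  mics$toa <- t0 + d / cc + if (noise_sd > 0) rnorm(nrow(mics), sd = noise_sd) else 0
  mics$snr_db <- 20
  howlspot::toa_set(mics, temp, broadcast_id = broadcast_id)
}

# a campaign-realistic random TOA set: source in the study area, the
# nearest n_rec recorders of the default grid (A channels), noisy TOAs
random_toaset <- function(seed, array = build_grid_array(), noise_sd = 0.02,
                          n_rec = NULL, temp = 12) {
  units <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(array), recorder_id),
    x = mean(x), y = mean(y), .groups = "drop"
  )
  set.seed(seed)
  src <- c(runif(1, 0, 6000), runif(1, 0, 5000))
  if (is.null(n_rec)) n_rec <- sample(4:6, 1)
  dd <- sqrt((units$x - src[1])^2 + (units$y - src[2])^2)
  sel <- units[order(dd)[seq_len(n_rec)], ]
  mics <- tibble::tibble(
    mic_id = paste0(sel$recorder_id, "A"),
    recorder_id = sel$recorder_id, channel = "A",
    x = sel$x, y = sel$y
  )
  ts <- make_toaset(mics, src = src, t0 = 10, temp = temp,
                    noise_sd = noise_sd, seed = seed + 5000)
  attr(ts, "true_source") <- src
  ts
}

# one-area miniature campaign for fast end-to-end tests
tiny_campaign <- function(seed = 1, n_sites = 12, toa_noise_sd = 0.02,
                          force_detection = FALSE) {
  arr <- build_grid_array()
  env <- environment_model(toa_noise_sd = toa_noise_sd)
  sites <- sample_broadcast_sites(n_sites = n_sites, seed = seed)
  plan <- schedule_campaign(sites, seed = seed)
  det <- simulate_campaign(arr, plan, sites, env, seed = seed,
                           force_detection = force_detection)
  list(array = arr, sites = sites, plan = plan,
       detections = join_array(det, arr), env = env)
}
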