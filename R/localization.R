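# TOA localization: sound speed, microphone selection, least-squares
# solver, grid-search oracle, pairwise temporal error, reliability filter.

#' Speed of sound in air
#'
#' Dry-air approximation `c = 331.3 * sqrt(1 + T / 273.15)` m/s.
#'
#' @param temperature_c Air temperature(s), degrees Celsius, in
#'   `[-40, 50]`.
#' @return Speed(s) of sound, metres per second.
#' @examples
#' sound_speed(0)   # 331.3
#' sound_speed(20)  # ~343.2
#' @export
sound_speed <- function(temperature_c) {
  if (any(temperature_c < -40 | temperature_c > 50)) {
    abort("temperature out of supported range [-40, 50] degrees C")
  }
  331.3 * sqrt(1 + temperature_c / 273.15)
}

#' Build a TOA observation set
#'
#' Validates the observations used for one localization attempt: at least
#' four microphones, at most two sharing a recorder (the stereo channels),
#' and a plausible temperature.
#'
#' @param observations Tibble with `mic_id`, `recorder_id`, `channel`,
#'   `x`, `y`, `toa`, `snr_db`.
#' @param temperature_c Mean air temperature during the broadcast period.
#' @param broadcast_id Identifier carried through to the estimate.
#' @return The observations tibble with class `toa_set` and attributes
#'   `temperature_c` and `broadcast_id`.
#' @export
toa_set <- function(observations, temperature_c, broadcast_id = NA_character_) {
  obs <- as_tibble(observations)
  req <- c("mic_id", "recorder_id", "x", "y", "toa")
  missing_cols <- setdiff(req, names(obs))
  if (length(missing_cols)) {
    abort(paste0("toa_set observations lack columns: ", toString(missing_cols)))
  }
  if (nrow(obs) < 4) abort("a toa_set needs at least 4 microphones")
  if (any(table(obs$recorder_id) > 2)) {
    abort("at most two channels may share a recorder")
  }
  if (!all(is.finite(obs$toa)) || !all(is.finite(obs$x)) || !all(is.finite(obs$y))) {
    abort("toa_set positions and TOAs must be finite")
  }
  if (temperature_c < -40 || temperature_c > 50) {
    abort("temperature out of supported range [-40, 50] degrees C")
  }
  structure(obs, class = c("toa_set", class(obs)),
            temperature_c = temperature_c, broadcast_id = broadcast_id)
}

#' Select microphones for one broadcast
#'
#' Applies the field rule for assembling a localization set from the
#' channels that detected a broadcast: one channel per detecting recorder
#' (the better SNR; ties broken by channel label A before B). When exactly
#' three recorders detected, the spare channel of the highest-SNR recorder
#' (falling back to the next recorders in SNR order) is added to reach four
#' microphones. Two or fewer detecting recorders cannot be localized and
#' return `NULL` (a failure value, not an error).
#'
#' @param detections Detection records for a single broadcast (rows with
#'   `detected == 1` are used) including channel positions `x`, `y`; see
#'   [simulate_campaign()] and [join_array()].
#' @param temperature_c Temperature for the set; defaults to the records'
#'   `temp_c` if present.
#' @return A [toa_set()] or `NULL` when fewer than 3 recorders detected
#'   (or the 3-recorder fallback cannot reach 4 microphones).
#' @export
select_microphones <- function(detections, temperature_c = NULL) {
  det <- detections %>% filter(.data$detected == 1L, !is.na(.data$toa_s))
  if (nrow(det) == 0) return(NULL)
  if (length(unique(det$broadcast_id)) > 1) {
    abort("select_microphones expects records for a single broadcast")
  }
  if (is.null(temperature_c)) {
    if (!"temp_c" %in% names(det)) abort("temperature_c not given and no temp_c column")
    temperature_c <- det$temp_c[1]
  }
  best <- det %>%
    group_by(.data$recorder_id) %>%
    arrange(desc(.data$snr_db), .data$channel, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup()
  n_rec <- nrow(best)
  if (n_rec <= 2) return(NULL)
  chosen <- best
  if (n_rec == 3) {
    # add the spare channel of the best-SNR recorder(s), best first
    spares <- det %>%
      dplyr::anti_join(best %>% select("recorder_id", "channel"),
                       by = c("recorder_id", "channel"))
    if (nrow(spares) == 0) return(NULL)
    order_rec <- best %>% arrange(desc(.data$snr_db)) %>% dplyr::pull("recorder_id")
    spares <- spares %>%
      mutate(rank = match(.data$recorder_id, order_rec)) %>%
      arrange(.data$rank) %>%
      dplyr::slice(1) %>%
      select(-"rank")
    chosen <- bind_rows(best, spares)
  }
  obs <- chosen %>%
    mutate(mic_id = paste0(.data$recorder_id, .data$channel)) %>%
    select("mic_id", "recorder_id", "channel", "x", "y",
           toa = "toa_s", "snr_db")
  toa_set(obs, temperature_c, broadcast_id = det$broadcast_id[1])
}

#' Attach channel coordinates to detection records
#'
#' @param detections Detection-record tibble (`recorder_id`, `channel`, ...).
#' @param array A [build_grid_array()] table (`recorder_id`, `channel`,
#'   `x`, `y`).
#' @return `detections` with `x`, `y` columns added.
#' @export
join_array <- function(detections, array) {
  detections %>%
    left_join(as_tibble(array) %>% select("recorder_id", "channel", "x", "y"),
              by = c("recorder_id", "channel"))
}

# sum of squared TOA residuals with the emission time profiled out in
# closed form: t0_hat = mean(t_i - d_i / c)
toa_objective <- function(xy, mx, my, t, c_ms) {
  d <- sqrt((xy[1] - mx)^2 + (xy[2] - my)^2)
  r <- t - d / c_ms
  t0 <- mean(r)
  sum((r - t0)^2)
}

#' Localize a sound source from its TOA set
#'
#' Minimises the sum of squared TOA residuals
#' `sum_i (t_i - t0 - d_i(x, y) / c)^2` over the source position, with the
#' emission time `t0` profiled out in closed form and the speed of sound
#' taken at the set's temperature. Optimisation starts from the microphone
#' centroid (Nelder-Mead, then a BFGS polish). The pairwise RMS temporal
#' error of the solution is attached; near-collinear or co-located
#' microphone geometry is flagged `ill_conditioned` but still solved, and a
#' non-converged optimiser is reported via `converged = FALSE`, never an
#' exception.
#'
#' @param toaset A [toa_set()].
#' @param start Optional starting position `c(x, y)`; default the
#'   microphone centroid.
#' @return An object of class `toa_localization`. Use [tidy()] for the
#'   one-row estimate table and [glance()] for fit diagnostics.
#' @export
localize <- function(toaset, start = NULL) {
  stopifnot(inherits(toaset, "toa_set"))
  c_ms <- sound_speed(attr(toaset, "temperature_c"))
  mx <- toaset$x; my <- toaset$y; t <- toaset$toa
  if (is.null(start)) start <- c(mean(mx), mean(my))
  nm <- optim(start, toa_objective, mx = mx, my = my, t = t, c_ms = c_ms,
              method = "Nelder-Mead",
              control = list(reltol = 1e-14, maxit = 2000))
  bf <- tryCatch(
    optim(nm$par, toa_objective, mx = mx, my = my, t = t, c_ms = c_ms,
          method = "BFGS", control = list(reltol = 1e-14, maxit = 500)),
    error = function(e) nm
  )
  opt <- if (bf$value <= nm$value) bf else nm
  d <- sqrt((opt$par[1] - mx)^2 + (opt$par[2] - my)^2)
  t0 <- mean(t - d / c_ms)
  # conditioning: singular-value ratio of centred mic coordinates, or any
  # two microphones closer than 1 m (the stereo-fallback signature)
  centred <- cbind(mx - mean(mx), my - mean(my))
  sv <- svd(centred, nu = 0, nv = 0)$d
  min_sep <- min(dist(cbind(mx, my)))
  ill <- sv[length(sv)] < 1e-3 * sv[1] || min_sep < 1
  structure(
    list(
      x = opt$par[1], y = opt$par[2], t0 = t0,
      temporal_error_ms = temporal_error(opt$par, toaset),
      n_mics = nrow(toaset),
      n_recorders = length(unique(toaset$recorder_id)),
      condition_flag = if (ill) "ill_conditioned" else "ok",
      converged = opt$convergence == 0,
      objective = opt$value, c_ms = c_ms,
      broadcast_id = attr(toaset, "broadcast_id"),
      toaset = toaset
    ),
    class = "toa_localization"
  )
}

#' @export
print.toa_localization <- function(x, ...) {
  cat(sprintf(
    "<toa_localization> %s\n  position (%.1f, %.1f) m, t0 %.3f s\n  temporal error %.2f ms, %d mics (%d recorders), %s%s\n",
    x$broadcast_id, x$x, x$y, x$t0, x$temporal_error_ms,
    x$n_mics, x$n_recorders, x$condition_flag,
    if (x$converged) "" else ", NOT converged"
  ))
  invisible(x)
}

#' @rdname localize
#' @param x A `toa_localization`.
#' @param ... Unused.
#' @method tidy toa_localization
#' @export
tidy.toa_localization <- function(x, ...) {
  tibble(
    broadcast_id = x$broadcast_id,
    x_est = x$x, y_est = x$y, t0_est = x$t0,
    temporal_error_ms = x$temporal_error_ms,
    n_mics = x$n_mics, n_recorders = x$n_recorders,
    condition_flag = x$condition_flag, converged = x$converged
  )
}

#' @rdname localize
#' @method glance toa_localization
#' @export
glance.toa_localization <- function(x, ...) {
  tibble(
    objective = x$objective,
    rms_residual_s = sqrt(x$objective / x$n_mics),
    c_ms = x$c_ms,
    temporal_error_ms = x$temporal_error_ms,
    converged = x$converged
  )
}

#' Exhaustive grid-search localization oracle
#'
#' Evaluates the same profiled TOA objective as [localize()] on a regular
#' grid and returns the argmin: a brute-force reference used to verify the
#' solver, deliberately independent of it.
#'
#' @param toaset A [toa_set()].
#' @param bounds `c(xmin, xmax, ymin, ymax)` metres; default the microphone
#'   bounding box padded by 2 km.
#' @param resolution Grid step, metres.
#' @return One-row tibble: `x`, `y`, `t0`, `objective`, `resolution`.
#' @export
localize_grid_oracle <- function(toaset, bounds = NULL, resolution = 10) {
  stopifnot(inherits(toaset, "toa_set"))
  c_ms <- sound_speed(attr(toaset, "temperature_c"))
  if (is.null(bounds)) {
    bounds <- c(
      min(toaset$x) - 2000, max(toaset$x) + 2000,
      min(toaset$y) - 2000, max(toaset$y) + 2000
    )
  }
  gx <- seq(bounds[1], bounds[2], by = resolution)
  gy <- seq(bounds[3], bounds[4], by = resolution)
  t <- toaset$toa
  # accumulate sum and sum of squares of residuals over mics, vectorised
  # over the whole grid
  nx <- length(gx); ny <- length(gy)
  s1 <- matrix(0, nx, ny); s2 <- matrix(0, nx, ny)
  for (i in seq_len(nrow(toaset))) {
    d <- sqrt(outer((gx - toaset$x[i])^2, (gy - toaset$y[i])^2, "+"))
    r <- t[i] - d / c_ms
    s1 <- s1 + r
    s2 <- s2 + r^2
  }
  n <- nrow(toaset)
  obj <- s2 - s1^2 / n   # sum((r - mean r)^2)
  k <- arrayInd(which.min(obj), dim(obj))
  x <- gx[k[1]]; y <- gy[k[2]]
  d <- sqrt((x - toaset$x)^2 + (y - toaset$y)^2)
  tibble(
    x = x, y = y, t0 = mean(t - d / c_ms),
    objective = obj[k[1], k[2]], resolution = resolution
  )
}

#' Pairwise RMS temporal error
#'
#' The reliability statistic of a localization: over all unordered
#' microphone pairs (i, j), the discrepancy between the observed TOA delay
#' `t_i - t_j` and the delay `(d_i - d_j) / c` predicted from the estimated
#' position, combined as a root mean square and reported in milliseconds.
#' A perfectly consistent solution scores 0 ms.
#'
#' @param estimate A `toa_localization`, or a numeric `c(x, y)` position.
#' @param toaset The [toa_set()] the estimate was computed from.
#' @return Temporal error in milliseconds.
#' @export
temporal_error <- function(estimate, toaset) {
  stopifnot(inherits(toaset, "toa_set") || nrow(toaset) >= 2)
  if (inherits(estimate, "toa_localization")) estimate <- c(estimate$x, estimate$y)
  if (nrow(toaset) < 2) abort("temporal error needs at least 2 microphones")
  c_ms <- sound_speed(attr(toaset, "temperature_c"))
  d <- sqrt((estimate[1] - toaset$x)^2 + (estimate[2] - toaset$y)^2)
  pairs <- utils::combn(nrow(toaset), 2)
  d_obs <- toaset$toa[pairs[1, ]] - toaset$toa[pairs[2, ]]
  d_theo <- (d[pairs[1, ]] - d[pairs[2, ]]) / c_ms
  sqrt(mean((d_obs - d_theo)^2)) * 1000
}

#' Localize every broadcast in a campaign
#'
#' Runs [select_microphones()] and [localize()] for each broadcast in a
#' detection table and collects the tidy estimates.
#'
#' @param detections Detection records (see [simulate_campaign()]); channel
#'   coordinates are joined from `array` if absent.
#' @param array Optional [build_grid_array()] table.
#' @param threshold_ms Reliability threshold used to fill the
#'   `kept_after_filter` column (the rows themselves are not dropped).
#' @return Tibble of estimates, one row per localizable broadcast:
#'   `broadcast_id`, `x_est`, `y_est`, `t0_est`, `temporal_error_ms`,
#'   `n_mics`, `n_recorders`, `condition_flag`, `converged`,
#'   `kept_after_filter`.
#' @export
localize_all <- function(detections, array = NULL, threshold_ms = 200) {
  det <- detections
  if (!all(c("x", "y") %in% names(det))) {
    if (is.null(array)) abort("detections lack x/y; supply `array`")
    det <- join_array(det, array)
  }
  ests <- det %>%
    filter(.data$detected == 1L) %>%
    dplyr::group_split(.data$broadcast_id) %>%
    purrr::map(function(d) {
      ts <- select_microphones(d)
      if (is.null(ts)) return(NULL)
      tidy(localize(ts))
    }) %>%
    purrr::compact() %>%
    bind_rows()
  if (nrow(ests) == 0) return(ests)
  ests %>% mutate(kept_after_filter = .data$temporal_error_ms <= threshold_ms)
}

#' Split estimates by the temporal-error reliability threshold
#'
#' Estimates whose temporal error is at or below the threshold are kept
#' (boundary equality keeps); the rest are excluded as unreliable. Input
#' order is preserved in both parts.
#'
#' @param estimates Tibble with a `temporal_error_ms` column (e.g. from
#'   [localize_all()]).
#' @param threshold_ms Reliability threshold in milliseconds; default
#'   200 ms.
#' @return A list with tibbles `kept` and `excluded`.
#' @export
filter_reliable <- function(estimates, threshold_ms = 200) {
  if (threshold_ms <= 0) abort("threshold_ms must be > 0")
  keep <- estimates$temporal_error_ms <= threshold_ms
  list(
    kept = estimates[keep, , drop = FALSE],
    excluded = estimates[!keep, , drop = FALSE]
  )
}
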