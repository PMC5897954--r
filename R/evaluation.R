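# Accuracy, geometric covariates (hull area, centroid distance, in/out),
# correlation, grouped summaries and the optional aberrant-value filter.

#' Localization accuracy
#'
#' Euclidean distance (metres) between an estimated position and the true
#' broadcast-site position. Smaller is better, despite the name.
#'
#' @param x_est,y_est Estimated coordinates, metres.
#' @param x_true,y_true True coordinates, metres.
#' @return Distance(s) in metres.
#' @examples
#' localization_accuracy(0, 0, 300, 400) # 500
#' @export
localization_accuracy <- function(x_est, y_est, x_true, y_true) {
  sqrt((x_est - x_true)^2 + (y_est - y_true)^2)
}

# convex hull of a point set as an ordered vertex matrix (NULL when the
# points are collinear or fewer than 3)
hull_vertices <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(NULL)
  h <- chull(pts)
  if (length(h) < 3) return(NULL)
  pts[h, , drop = FALSE]
}

#' Microphone-area geometry
#'
#' `mic_hull_area()` is the area (m^2) of the convex hull of the
#' microphones used in one estimate (shoelace formula over the hull
#' vertices); `mic_centroid()` is the mean of the hull vertices; and
#' `classify_inout()` reports whether the broadcast site lies inside the
#' hull (points on the boundary count as inside). Degenerate microphone
#' sets (collinear or < 3 distinct points) get area 0, centroid equal to
#' the point mean, and `inout = "out"`.
#'
#' @param x,y Microphone coordinates, metres.
#' @param px,py Site coordinates for `classify_inout()`.
#' @param tol Boundary tolerance in metres for the on-edge test.
#' @return `mic_hull_area()`: numeric m^2. `mic_centroid()`: named vector
#'   `c(x, y)`. `classify_inout()`: `"in"` or `"out"`.
#' @export
mic_hull_area <- function(x, y) {
  v <- hull_vertices(x, y)
  if (is.null(v)) return(0)
  i2 <- c(seq_len(nrow(v))[-1], 1)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}

#' @rdname mic_hull_area
#' @export
mic_centroid <- function(x, y) {
  v <- hull_vertices(x, y)
  if (is.null(v)) return(c(x = mean(x), y = mean(y)))
  c(x = mean(v[, 1]), y = mean(v[, 2]))
}

#' @rdname mic_hull_area
#' @export
classify_inout <- function(x, y, px, py, tol = 1e-9) {
  v <- hull_vertices(x, y)
  if (is.null(v)) return("out")
  n <- nrow(v)
  i2 <- c(seq_len(n)[-1], 1)
  # on-boundary test: distance from the point to each hull edge
  for (e in seq_len(n)) {
    ax <- v[e, 1]; ay <- v[e, 2]; bx <- v[i2[e], 1]; by <- v[i2[e], 2]
    len2 <- (bx - ax)^2 + (by - ay)^2
    tt <- if (len2 == 0) 0 else pmin(pmax(((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / len2, 0), 1)
    if (sqrt((ax + tt * (bx - ax) - px)^2 + (ay + tt * (by - ay) - py)^2) <= tol) {
      return("in")
    }
  }
  # ray casting
  inside <- FALSE
  for (e in seq_len(n)) {
    ax <- v[e, 1]; ay <- v[e, 2]; bx <- v[i2[e], 1]; by <- v[i2[e], 2]
    if ((ay > py) != (by > py)) {
      x_int <- ax + (py - ay) / (by - ay) * (bx - ax)
      if (px < x_int) inside <- !inside
    }
  }
  if (inside) "in" else "out"
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors, `n >= 3`, each with non-zero variance.
#' @return The correlation coefficient `r`.
#' @export
pearson_r <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("pearson_r needs n >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("pearson_r needs non-zero variance")
  cor(x, y)
}

#' Accuracy vs temporal-error correlation
#'
#' Tests the association between localization accuracy and the temporal
#' error reliability statistic (Pearson's r via [stats::cor.test()]).
#'
#' @param records Evaluation records with `loc_accuracy` and
#'   `temporal_error_ms`.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
accuracy_error_correlation <- function(records) {
  ok <- complete.cases(records$loc_accuracy, records$temporal_error_ms)
  ct <- stats::cor.test(records$loc_accuracy[ok], records$temporal_error_ms[ok])
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Build evaluation records for a localized campaign
#'
#' Joins estimates to the ground truth and computes, per broadcast: the
#' localization accuracy, the microphones-area covariates (`areamic` hull
#' area of the microphones used, `dist` from the hull centroid to the true
#' site, `inout` site-in-hull flag) and the design covariates (`period`,
#' `night`, `array`). The microphones used by each estimate are rederived
#' with [select_microphones()] (the selection rule is deterministic);
#' `hull_mode = "array"` instead uses the whole recorder array for the
#' geometric covariates.
#'
#' @param estimates Estimates from [localize_all()].
#' @param detections The detection records the estimates came from (with
#'   channel coordinates, see [join_array()]).
#' @param sites Site table with true positions.
#' @param array Required for `hull_mode = "array"` or when `detections`
#'   lack coordinates.
#' @param hull_mode `"used"` (default) or `"array"`.
#' @return Tibble of evaluation records: `broadcast_id`, `loc_accuracy`,
#'   `dist`, `areamic`, `inout`, `period`, `night`, `array`,
#'   `temporal_error_ms`, `kept_after_filter`.
#' @export
evaluate_campaign <- function(estimates, detections, sites, array = NULL,
                              hull_mode = c("used", "array")) {
  hull_mode <- match.arg(hull_mode)
  det <- detections
  if (!all(c("x", "y") %in% names(det))) {
    if (is.null(array)) abort("detections lack x/y; supply `array`")
    det <- join_array(det, array)
  }
  geo <- estimates %>%
    dplyr::pull("broadcast_id") %>%
    purrr::map(function(bid) {
      d <- det %>% filter(.data$broadcast_id == bid)
      site <- sites %>% filter(.data$site_id == d$site_id[1])
      mics <- if (hull_mode == "array") {
        as_tibble(array) %>% select("x", "y")
      } else {
        ts <- select_microphones(d)
        if (is.null(ts)) return(NULL)
        ts %>% select("x", "y")
      }
      cen <- mic_centroid(mics$x, mics$y)
      tibble(
        broadcast_id = bid,
        x_true = site$x, y_true = site$y,
        areamic = mic_hull_area(mics$x, mics$y),
        dist = sqrt((cen["x"] - site$x)^2 + (cen["y"] - site$y)^2),
        inout = classify_inout(mics$x, mics$y, site$x, site$y),
        period = d$period[1], night = d$night[1], array = d$area_label[1]
      )
    }) %>%
    purrr::compact() %>%
    bind_rows()
  estimates %>%
    left_join(geo, by = "broadcast_id") %>%
    mutate(
      loc_accuracy = localization_accuracy(
        .data$x_est, .data$y_est, .data$x_true, .data$y_true
      )
    ) %>%
    select(
      "broadcast_id", "loc_accuracy", "dist", "areamic", "inout",
      "period", "night", "array", "temporal_error_ms",
      dplyr::any_of("kept_after_filter")
    )
}

#' Drop aberrant low-error / high-accuracy records
#'
#' Optional outlier rule applied after the reliability filter: records with
#' accuracy above `Q3 + 3 IQR` of the kept accuracies are removed. Off by
#' default in [run_pipeline()].
#'
#' @param records Evaluation records.
#' @return The records with aberrant rows removed.
#' @export
drop_aberrant <- function(records) {
  q <- quantile(records$loc_accuracy, c(0.25, 0.75), na.rm = TRUE)
  cut <- q[2] + 3 * (q[2] - q[1])
  records %>% filter(.data$loc_accuracy <= cut)
}

#' Grouped descriptive summary
#'
#' Per-group `n`, mean, sd, min and max of a value column, plus a pooled
#' `Total` row — the layout of a campaign accuracy table.
#'
#' @param records A tibble.
#' @param group_by Character vector of grouping columns (may be empty).
#' @param var Name of the value column to summarise.
#' @return Tibble with the grouping columns (`"Total"` in the pooled row),
#'   `n`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_records <- function(records, group_by = "array", var = "loc_accuracy") {
  v <- records[[var]]
  if (is.null(v)) abort(paste0("no column `", var, "` in records"))
  stat <- function(d) {
    tibble(
      n = sum(!is.na(d[[var]])),
      mean = mean(d[[var]], na.rm = TRUE),
      sd = sd(d[[var]], na.rm = TRUE),
      min = min(d[[var]], na.rm = TRUE),
      max = max(d[[var]], na.rm = TRUE)
    )
  }
  total <- stat(records)
  for (g in group_by) total[[g]] <- "Total"
  if (length(group_by) == 0) return(total)
  per <- records %>%
    group_by(across(dplyr::all_of(group_by))) %>%
    dplyr::group_modify(~ stat(.x)) %>%
    ungroup() %>%
    mutate(across(dplyr::all_of(group_by), as.character))
  bind_rows(per, total) %>%
    select(dplyr::all_of(group_by), "n", "mean", "sd", "min", "max")
}
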