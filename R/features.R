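#' Sliding-window segmentation and feature extraction
#'
#' Unified sensor streams are cut into fixed-length windows (default 2 s with
#' a 1 s hop, i.e. 50% overlap; at the nominal 50 Hz that is 100 inertial
#' samples per window) and each window is reduced to an ordered vector of 12
#' continuous features:
#'
#' 1-3  per-axis accelerometer mean (`accel_mean_x/y/z`)
#' 4-6  per-axis accelerometer standard deviation (`accel_sd_x/y/z`)
#' 7    acceleration magnitude mean (`accel_mag_mean`)
#' 8    acceleration magnitude standard deviation (`accel_mag_sd`)
#' 9-11 per-axis gyroscope standard deviation (`gyro_sd_x/y/z`)
#' 12   proximity mean (`prox_mean`)
#'
#' Standard deviations are population (divide by N), matching the
#' chunk-statistics convention `sigma^2 = v - mu^2` used by the trainer.
#' GPS is never placed in the feature vector: it is summarized per window
#' (mean speed, last fix, fix-quality range) and routed to the hierarchical
#' layer, which uses it for venue matching, indoor/outdoor discrimination
#' and the speed heuristic.
#'
#' @name features
NULL

#' Feature-extraction configuration
#'
#' @param window_s Window length in seconds (> 0).
#' @param hop_s Hop between window starts in seconds (0 < hop_s <= window_s).
#' @param use_gyroscope Include gyroscope features (zeros if the channel is
#'   absent).
#' @param use_proximity Include the proximity feature (zero if absent).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(window_s = 2, hop_s = 1, use_gyroscope = TRUE,
                           use_proximity = TRUE) {
  if (!is.numeric(window_s) || window_s <= 0) {
    harf_config_error("window_s must be > 0")
  }
  if (!is.numeric(hop_s) || hop_s <= 0 || hop_s > window_s) {
    harf_config_error("hop_s must satisfy 0 < hop_s <= window_s")
  }
  structure(list(window_s = window_s, hop_s = hop_s,
                 use_gyroscope = isTRUE(use_gyroscope),
                 use_proximity = isTRUE(use_proximity)),
            class = "feature_config")
}

#' Canonical feature order
#'
#' @param config A `feature_config`.
#' @return Character vector of feature names in the fixed canonical order.
#' @export
harf_feature_names <- function(config = feature_config()) {
  nm <- c("accel_mean_x", "accel_mean_y", "accel_mean_z",
          "accel_sd_x", "accel_sd_y", "accel_sd_z",
          "accel_mag_mean", "accel_mag_sd")
  if (config$use_gyroscope) nm <- c(nm, "gyro_sd_x", "gyro_sd_y", "gyro_sd_z")
  if (config$use_proximity) nm <- c(nm, "prox_mean")
  nm
}

slice_stream <- function(df, start, end) {
  df[df$timestamp >= start & df$timestamp <= end, , drop = FALSE]
}

gps_window_summary <- function(gps) {
  if (is.null(gps) || nrow(gps) == 0L) return(NULL)
  last <- gps[nrow(gps), ]
  list(
    mean_speed_kmh = mean(gps$speed_kmh),
    last_latitude = last$latitude,
    last_longitude = last$longitude,
    min_fix_quality = min(gps$fix_quality),
    max_fix_quality = max(gps$fix_quality),
    n_fixes = nrow(gps)
  )
}

#' Segment a sensor log into fixed-duration windows
#'
#' Windows tile the overall timestamp span `[first_ts, last_ts]` with stride
#' `hop_s`; a trailing partial window is dropped, so a log spanning `T`
#' seconds yields `floor((T - window_s) / hop_s) + 1` windows (zero when
#' `T < window_s`). Sample membership uses the closed interval
#' `[start, start + window_s]`. Windows without any accelerometer sample are
#' marked degenerate.
#'
#' @param log A `sensor_log`.
#' @param window_s,hop_s Window length and hop in seconds.
#' @return A list of `sensor_window` objects (possibly empty), each with
#'   `start_time`, `end_time`, per-kind sample slices, `gps_summary` (or
#'   `NULL` when the window holds no fix) and a `degenerate` flag.
#' @export
segment_windows <- function(log, window_s = 2, hop_s = 1) {
  stopifnot(inherits(log, "sensor_log"))
  cfg <- feature_config(window_s = window_s, hop_s = hop_s)
  all_ts <- c(log$accelerometer$timestamp, log$gyroscope$timestamp,
              log$proximity$timestamp, log$gps$timestamp)
  if (length(all_ts) == 0L) return(list())
  first <- min(all_ts)
  span <- max(all_ts) - first
  if (span < window_s) return(list())
  n_win <- floor((span - window_s) / hop_s) + 1
  lapply(seq_len(n_win) - 1, function(k) {
    s <- first + k * hop_s
    e <- s + window_s
    acc <- slice_stream(log$accelerometer, s, e)
    structure(
      list(start_time = s, end_time = e,
           accelerometer = acc,
           gyroscope = slice_stream(log$gyroscope, s, e),
           proximity = slice_stream(log$proximity, s, e),
           gps_summary = gps_window_summary(slice_stream(log$gps, s, e)),
           degenerate = nrow(acc) == 0L),
      class = "sensor_window"
    )
  })
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Extract the canonical feature vector from one window
#'
#' Constant signals yield zero standard deviations. Missing gyroscope or
#' proximity channels are imputed as zeros and flagged in the result's
#' `imputed` attribute so accelerometer-only logs stay classifiable.
#'
#' @param window A non-degenerate `sensor_window`.
#' @param config A `feature_config`.
#' @return A named numeric feature vector in canonical order, all finite.
#' @export
extract_features <- function(window, config = feature_config()) {
  stopifnot(inherits(window, "sensor_window"))
  if (isTRUE(window$degenerate)) {
    harf_validation_error(sprintf(
      "window [%g, %g] has no accelerometer samples", window$start_time,
      window$end_time
    ))
  }
  a <- cbind(window$accelerometer$x, window$accelerometer$y,
             window$accelerometer$z)
  if (anyNA(a) || any(!is.finite(a))) {
    harf_validation_error(sprintf(
      "NaN/Inf accelerometer sample in window [%g, %g]; window rejected",
      window$start_time, window$end_time
    ))
  }
  mag <- sqrt(rowSums(a^2))
  v <- c(colMeans(a), apply(a, 2, pop_sd), mean(mag), pop_sd(mag))
  imputed <- character(0)
  if (config$use_gyroscope) {
    g <- cbind(window$gyroscope$x, window$gyroscope$y, window$gyroscope$z)
    if (is.null(g) || nrow(window$gyroscope) == 0L) {
      v <- c(v, 0, 0, 0)
      imputed <- c(imputed, "gyroscope")
    } else {
      if (anyNA(g) || any(!is.finite(g))) {
        harf_validation_error("NaN/Inf gyroscope sample; window rejected")
      }
      v <- c(v, apply(g, 2, pop_sd))
    }
  }
  if (config$use_proximity) {
    p <- window$proximity$value
    if (length(p) == 0L) {
      v <- c(v, 0)
      imputed <- c(imputed, "proximity")
    } else {
      if (anyNA(p) || any(!is.finite(p))) {
        harf_validation_error("NaN/Inf proximity sample; window rejected")
      }
      v <- c(v, mean(p))
    }
  }
  names(v) <- harf_feature_names(config)
  if (length(imputed) > 0L) attr(v, "imputed") <- imputed
  v
}

#' Segment a log and extract all window features at once
#'
#' Degenerate windows (no accelerometer samples) are skipped.
#'
#' @param log A `sensor_log`.
#' @param config A `feature_config`.
#' @return A list with `features` (matrix, one row per usable window, named
#'   columns in canonical order), `windows` (data frame of start/end times)
#'   and `gps_summaries` (list parallel to the rows).
#' @export
extract_feature_matrix <- function(log, config = feature_config()) {
  wins <- segment_windows(log, config$window_s, config$hop_s)
  wins <- Filter(function(w) !w$degenerate, wins)
  nm <- harf_feature_names(config)
  if (length(wins) == 0L) {
    return(list(
      features = matrix(numeric(0), ncol = length(nm),
                        dimnames = list(NULL, nm)),
      windows = data.frame(start_time = numeric(0), end_time = numeric(0)),
      gps_summaries = list()
    ))
  }
  feats <- t(vapply(wins, function(w) as.numeric(extract_features(w, config)),
                    numeric(length(nm))))
  colnames(feats) <- nm
  list(
    features = feats,
    windows = data.frame(
      start_time = vapply(wins, `[[`, numeric(1), "start_time"),
      end_time = vapply(wins, `[[`, numeric(1), "end_time")
    ),
    gps_summaries = lapply(wins, `[[`, "gps_summary")
  )
}
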