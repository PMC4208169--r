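# Shared builders for tests: tiny registries, hand-set model sets, window
# and GPS-summary fixtures. Everything is generated in code.

# Independent great-circle oracle: spherical law of cosines on the same
# sphere radius geosphere uses by default.
slc_distance_m <- function(lat1, lon1, lat2, lon2, r = 6378137) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  r * acos(pmin(1, pmax(-1, sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl))))
}

tiny_registry <- function() {
  data.frame(
    label = c("home", "office", "Exercising at gym"),
    latitude = c(37.2400, 37.2480, 37.2300),
    longitude = c(127.0800, 127.0900, 127.0850),
    radius_m = 50,
    category = c("home", "office", "type2"),
    stringsAsFactors = FALSE
  )
}

# GPS window summary with a single synthetic fix.
gsum <- function(lat, lon, speed = 0, quality = 0.9, n = 1L) {
  list(mean_speed_kmh = speed, last_latitude = lat, last_longitude = lon,
       min_fix_quality = quality, max_fix_quality = quality, n_fixes = n)
}

# Model set over all ten type-1 labels with two features; label k gets mean
# (k, -k) (in sorted-label order) and variance at the floor, so a feature
# vector at a label's mean is classified to it with near-certainty.
type1_test_models <- function() {
  labs <- sort(activity_labels()$name[activity_labels()$type == 1L])
  x <- do.call(rbind, lapply(seq_along(labs), function(k) {
    matrix(rep(c(k, -k), 2), nrow = 2, byrow = TRUE)
  }))
  colnames(x) <- c("F1", "F2")
  train_models(x, rep(labs, each = 2), chunk_size = 10)
}

type1_mean <- function(models, label) {
  models$models[[label]]$mu_m
}

# A sensor window built directly from sample vectors (bypassing I/O).
make_window <- function(ax, ay, az, gx = NULL, gy = NULL, gz = NULL,
                        prox = NULL, rate = 50) {
  n <- length(ax)
  ts <- seq(0, by = 1 / rate, length.out = n)
  gyro <- if (is.null(gx)) {
    data.frame(timestamp = numeric(0), x = numeric(0), y = numeric(0),
               z = numeric(0))
  } else {
    data.frame(timestamp = ts, x = gx, y = gy, z = gz)
  }
  proxd <- if (is.null(prox)) {
    data.frame(timestamp = numeric(0), value = numeric(0))
  } else {
    data.frame(timestamp = seq(0, by = 0.2, length.out = length(prox)),
               value = prox)
  }
  structure(
    list(start_time = 0, end_time = max(ts),
         accelerometer = data.frame(timestamp = ts, x = ax, y = ay, z = az),
         gyroscope = gyro, proximity = proxd, gps_summary = NULL,
         degenerate = FALSE),
    class = "sensor_window"
  )
}

# Sensor log whose accelerometer spans exactly [0, span_s] inclusive.
span_log <- function(span_s, rate = 50) {
  ts <- seq(0, span_s, by = 1 / rate)
  log <- empty_sensor_log(rate)
  log$accelerometer <- data.frame(timestamp = ts, x = 0, y = 0, z = 9.81)
  log
}

random_sensor_log <- function(n_each = 20) {
  log <- empty_sensor_log()
  log$accelerometer <- data.frame(timestamp = sort(runif(n_each, 0, 10)),
                                  x = rnorm(n_each), y = rnorm(n_each),
                                  z = rnorm(n_each))
  log$gyroscope <- data.frame(timestamp = sort(runif(n_each, 0, 10)),
                              x = rnorm(n_each), y = rnorm(n_each),
                              z = rnorm(n_each))
  log$proximity <- data.frame(timestamp = sort(runif(5, 0, 10)),
                              value = runif(5, 0, 10))
  log$gps <- data.frame(timestamp = sort(runif(5, 0, 10)),
                        latitude = runif(5, -90, 90),
                        longitude = runif(5, -180, 180),
                        speed_kmh = runif(5, 0, 100),
                        fix_quality = runif(5))
  log
}
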