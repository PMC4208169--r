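#' Seeded multimodal sensor simulator
#'
#' Generates labeled synthetic smartphone sensor logs with known ground
#' truth, at two fidelity levels: signal-level 50 Hz inertial streams with
#' activity-specific archetypes (static gravity-dominated postures, periodic
#' gait oscillations, low-frequency vehicle vibration with a cruise/stop
#' speed profile) plus 1 Hz GPS tracks anchored inside or outside geofences;
#' and feature-level i.i.d. Gaussian draws with stored generative parameters
#' for exact parameter-recovery tests.
#'
#' Archetype parameters are chosen for controllable class separation, not
#' biomechanical realism; noise and amplitude knobs let tests reproduce
#' gait-like confusions when desired.
#'
#' @name simulator
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

activity_pattern <- function(label) {
  if (label == "Riding a car") return("car")
  if (endsWith(label, "/Walking")) return("walking")
  if (endsWith(label, "/Sitting")) return("sitting")
  if (endsWith(label, "/Standing")) return("standing")
  if (endsWith(label, "/Jogging")) return("jogging")
  # location-based venues: people amble around the venue
  "walking"
}

# Inertial/proximity archetypes. accel_base is the gravity-inclusive resting
# orientation (m/s^2); amplitudes in m/s^2 (accel) and rad/s (gyro);
# frequencies in Hz; prox in raw cm; speed in km/h.
archetype_params <- function(pattern) {
  switch(pattern,
    sitting = list(accel_base = c(0.5, 3.0, 9.3), accel_amp = c(0, 0, 0),
                   freq_hz = 0, accel_noise = 0.05,
                   gyro_amp = c(0, 0, 0), gyro_noise = 0.02,
                   prox_cm = 1, speed_kmh = 0),
    standing = list(accel_base = c(0, 0, 9.81), accel_amp = c(0.1, 0.1, 0.1),
                    freq_hz = 0.3, accel_noise = 0.12,
                    gyro_amp = c(0.02, 0.02, 0.02), gyro_noise = 0.04,
                    prox_cm = 9, speed_kmh = 0),
    walking = list(accel_base = c(0, 0, 9.81), accel_amp = c(1.5, 1.0, 3.0),
                   freq_hz = 2, accel_noise = 0.4,
                   gyro_amp = c(0.5, 0.5, 0.3), gyro_noise = 0.05,
                   prox_cm = 5, speed_kmh = 4),
    jogging = list(accel_base = c(0, 0, 9.81), accel_amp = c(3, 2, 6),
                   freq_hz = 3, accel_noise = 0.6,
                   gyro_amp = c(1, 1, 0.6), gyro_noise = 0.08,
                   prox_cm = 5, speed_kmh = 9),
    car = list(accel_base = c(0, 0, 9.81), accel_amp = c(0.3, 0.3, 0.4),
               freq_hz = 4, accel_noise = 0.25,
               gyro_amp = c(0.05, 0.05, 0.05), gyro_noise = 0.08,
               prox_cm = 3, speed_kmh = NA),
    harf_validation_error(sprintf("unknown archetype pattern '%s'", pattern))
  )
}

#' Describe one synthetic activity recording
#'
#' @param label One of the 15 activity labels ([activity_labels()]).
#' @param duration_s Recording length in seconds.
#' @param seed Integer seed; a fixed seed makes the generated log (and its
#'   CSV serialization) identical across runs.
#' @param anchor_lat,anchor_lon GPS anchor position (WGS84 degrees).
#' @param fix_quality Baseline GPS fix quality in `[0, 1]`; indoor (home /
#'   office) recordings default to a weak 0.2, everything else to 0.9.
#' @param anchored If `TRUE` the GPS track stays at the anchor (indoor or
#'   in-venue movement); if `FALSE` the track integrates the speed profile
#'   along `heading_deg`.
#' @param heading_deg Travel bearing for un-anchored tracks.
#' @param overrides Named list of archetype parameter overrides
#'   (`accel_base`, `accel_amp`, `freq_hz`, `accel_noise`, `gyro_amp`,
#'   `gyro_noise`, `prox_cm`, `speed_kmh`).
#' @return An `activity_scenario` object.
#' @export
activity_scenario <- function(label, duration_s = 30, seed = 1,
                              anchor_lat = 37.2200, anchor_lon = 127.1200,
                              fix_quality = NULL, anchored = NULL,
                              heading_deg = 90, overrides = list()) {
  labs <- activity_labels()
  if (!label %in% labs$name) {
    harf_validation_error(sprintf("unknown activity label '%s'", label))
  }
  if (duration_s <= 0) harf_validation_error("duration_s must be > 0")
  pattern <- activity_pattern(label)
  params <- archetype_params(pattern)
  for (nm in names(overrides)) params[[nm]] <- overrides[[nm]]
  if (any(params$freq_hz < 0) || params$accel_noise < 0 ||
      params$gyro_noise < 0) {
    harf_validation_error("frequencies and noise sigmas must be >= 0")
  }
  area <- labs$area[labs$name == label]
  type <- labs$type[labs$name == label]
  if (is.null(fix_quality)) fix_quality <- if (area == "Outdoor") 0.9 else 0.2
  if (is.null(anchored)) anchored <- !(type == 3L || (type == 1L && area == "Outdoor"))
  structure(
    list(label = label, pattern = pattern, duration_s = duration_s,
         seed = as.integer(seed), rate_hz = 50, gps_rate_hz = 1,
         prox_rate_hz = 5, anchor_lat = anchor_lat, anchor_lon = anchor_lon,
         fix_quality = fix_quality, anchored = anchored,
         heading_deg = heading_deg, params = params),
    class = "activity_scenario"
  )
}

# Cruise/stop speed profile for the car archetype: 20 s cruise segments at a
# per-segment uniform 40-80 km/h alternating with 5 s stops.
car_speed_segments <- function(duration_s) {
  segs <- list()
  t0 <- 0
  while (t0 < duration_s) {
    cruise_end <- min(t0 + 20, duration_s)
    segs[[length(segs) + 1L]] <- data.frame(
      start = t0, end = cruise_end, speed_kmh = stats::runif(1, 40, 80)
    )
    t0 <- cruise_end
    if (t0 < duration_s) {
      stop_end <- min(t0 + 5, duration_s)
      segs[[length(segs) + 1L]] <- data.frame(
        start = t0, end = stop_end, speed_kmh = 0
      )
      t0 <- stop_end
    }
  }
  do.call(rbind, segs)
}

segment_speed_at <- function(segments, t) {
  idx <- findInterval(t, segments$start)
  idx[idx < 1L] <- 1L
  segments$speed_kmh[idx]
}

#' Generate a signal-level sensor log for one scenario
#'
#' Inertial channels are `baseline + A sin(2 pi f t + phase) + N(0, sigma)`
#' at 50 Hz; proximity is sampled at 5 Hz around the archetype's raw value;
#' GPS at 1 Hz follows the scenario's speed profile (constant for gait and
#' postures, alternating cruise/stop for the car) with a few metres of
#' position jitter. The generated speed segments are attached as the
#' `speed_segments` attribute for ground-truth use.
#'
#' @param scenario An `activity_scenario`.
#' @return A `sensor_log`; identical for identical scenarios and seeds.
#' @export
generate_signal_log <- function(scenario) {
  stopifnot(inherits(scenario, "activity_scenario"))
  p <- scenario$params
  local_seed(scenario$seed, {
    n <- round(scenario$duration_s * scenario$rate_hz)
    t50 <- seq(0, by = 1 / scenario$rate_hz, length.out = n)
    phases <- c(0, pi / 2, pi)
    mk_axes <- function(base, amp, noise) {
      vapply(1:3, function(i) {
        base[i] + amp[i] * sin(2 * pi * p$freq_hz * t50 + phases[i]) +
          stats::rnorm(n, 0, noise)
      }, numeric(n))
    }
    acc <- mk_axes(p$accel_base, p$accel_amp, p$accel_noise)
    gyr <- mk_axes(c(0, 0, 0), p$gyro_amp, p$gyro_noise)

    n_prox <- max(1L, round(scenario$duration_s * scenario$prox_rate_hz))
    t_prox <- seq(0, by = 1 / scenario$prox_rate_hz, length.out = n_prox)
    prox <- pmax(p$prox_cm + stats::rnorm(n_prox, 0, 0.1), 0)

    n_gps <- max(1L, floor(scenario$duration_s * scenario$gps_rate_hz))
    t_gps <- seq(0, by = 1 / scenario$gps_rate_hz, length.out = n_gps)
    segments <- if (scenario$pattern == "car") {
      car_speed_segments(scenario$duration_s)
    } else {
      data.frame(start = 0, end = scenario$duration_s,
                 speed_kmh = p$speed_kmh)
    }
    speeds <- segment_speed_at(segments, t_gps)
    if (scenario$anchored) {
      lat <- rep(scenario$anchor_lat, n_gps)
      lon <- rep(scenario$anchor_lon, n_gps)
    } else {
      # integrate speed (km/h -> m/s) along the heading
      step_m <- c(0, speeds[-n_gps] / 3.6 * diff(t_gps))
      dist_m <- cumsum(step_m)
      dest <- geosphere::destPoint(
        c(scenario$anchor_lon, scenario$anchor_lat),
        scenario$heading_deg, dist_m
      )
      lon <- dest[, 1]
      lat <- dest[, 2]
    }
    # ~2 m of position jitter, well inside the default 50 m fences
    lat <- lat + stats::rnorm(n_gps, 0, 2e-5)
    lon <- lon + stats::rnorm(n_gps, 0, 2e-5)
    fq <- pmin(pmax(scenario$fix_quality + stats::rnorm(n_gps, 0, 0.02), 0), 1)

    log <- new_sensor_log(
      accelerometer = data.frame(timestamp = t50, x = acc[, 1], y = acc[, 2],
                                 z = acc[, 3]),
      gyroscope = data.frame(timestamp = t50, x = gyr[, 1], y = gyr[, 2],
                             z = gyr[, 3]),
      proximity = data.frame(timestamp = t_prox, value = prox),
      gps = data.frame(timestamp = t_gps, latitude = lat, longitude = lon,
                       speed_kmh = speeds, fix_quality = fq),
      nominal_rate = scenario$rate_hz
    )
    attr(log, "speed_segments") <- segments
    attr(log, "scenario_label") <- scenario$label
    log
  })
}

#' Generate a feature-level Gaussian dataset with stored ground truth
#'
#' @param class_params Named list: one entry per class, each a list with
#'   per-feature vectors `mu` and `sigma2` (`sigma2 > 0`).
#' @param n_per_class Draws per class (>= 1).
#' @param seed Integer seed.
#' @param feature_names Optional feature names (default `F1..Fn`).
#' @return A list with `features` (matrix), `labels` (character vector) and
#'   `truth` (the generative `class_params`, for recovery assertions).
#' @export
generate_feature_dataset <- function(class_params, n_per_class, seed = 1,
                                     feature_names = NULL) {
  if (!is.list(class_params) || is.null(names(class_params)) ||
      length(class_params) == 0L) {
    harf_validation_error("class_params must be a named list of (mu, sigma2)")
  }
  if (n_per_class < 1) harf_validation_error("n_per_class must be >= 1")
  k <- length(class_params[[1L]]$mu)
  for (nm in names(class_params)) {
    cp <- class_params[[nm]]
    if (length(cp$mu) != k || length(cp$sigma2) != k) {
      harf_validation_error(sprintf(
        "class '%s' parameter length differs from %d", nm, k
      ))
    }
    if (any(cp$sigma2 <= 0)) {
      harf_validation_error(sprintf("class '%s' has non-positive sigma2", nm))
    }
  }
  feature_names <- feature_names %||% paste0("F", seq_len(k))
  local_seed(seed, {
    mats <- lapply(names(class_params), function(nm) {
      cp <- class_params[[nm]]
      z <- matrix(stats::rnorm(n_per_class * k), nrow = n_per_class)
      sweep(sweep(z, 2, sqrt(cp$sigma2), "*"), 2, cp$mu, "+")
    })
    features <- do.call(rbind, mats)
    colnames(features) <- feature_names
    list(
      features = features,
      labels = rep(names(class_params), each = n_per_class),
      truth = class_params
    )
  })
}

#' Default registered-location registry for the synthetic study area
#'
#' Six venues (home, office and the four type-2 venues) spread several
#' hundred metres apart with 50 m geofences.
#'
#' @return A registry data frame.
#' @export
default_registry <- function() {
  validate_registry(data.frame(
    label = c("home", "office", "Waiting for bus at bus stop",
              "Having a meal at cafeteria", "Exercising at gym",
              "Visiting a park"),
    latitude = c(37.2400, 37.2480, 37.2350, 37.2500, 37.2300, 37.2430),
    longitude = c(127.0800, 127.0900, 127.0700, 127.0750, 127.0850, 127.0650),
    radius_m = 50,
    category = c("home", "office", rep("type2", 4)),
    stringsAsFactors = FALSE
  ))
}

scenario_anchor <- function(label, registry) {
  labs <- activity_labels()
  area <- labs$area[labs$name == label]
  type <- labs$type[labs$name == label]
  pick <- function(lbl) {
    row <- registry[registry$label == lbl, ]
    c(row$latitude[1], row$longitude[1])
  }
  if (type == 2L) return(pick(label))
  if (area == "Home") return(pick(registry$label[registry$category == "home"][1]))
  if (area == "Office") return(pick(registry$label[registry$category == "office"][1]))
  # outdoor physical activities and the car start well clear of every fence
  c(37.2200, 127.1200)
}

#' Generate a full train/test evaluation suite over all 15 activities
#'
#' Training logs cover the ten type-1 physical activities (the type-2 and
#' heuristic labels need no Gaussian model); test logs cover all 15
#' activities, with GPS anchored inside the correct geofence for home,
#' office and venue recordings and well outside every fence for outdoor
#' ones. Train and test use disjoint seeds derived from `seed`.
#'
#' @param registry Registry containing a home, an office and the four
#'   type-2 venues (default [default_registry()]).
#' @param seed Base integer seed.
#' @param train_duration_s,test_duration_s Per-scenario recording lengths.
#' @return A list with `train` / `test` (lists of `list(label, scenario,
#'   log)`) and `registry`.
#' @export
generate_evaluation_suite <- function(registry = default_registry(), seed = 1,
                                      train_duration_s = 60,
                                      test_duration_s = 40) {
  validate_registry(registry)
  if (sum(registry$category == "home") < 1L ||
      sum(registry$category == "office") < 1L ||
      sum(registry$category == "type2") < 4L) {
    harf_config_error(
      "registry must contain a home, an office and the four type-2 venues"
    )
  }
  labs <- activity_labels()
  seed <- as.integer(seed) %% 100000L
  make <- function(label, i, offset, duration) {
    anchor <- scenario_anchor(label, registry)
    sc <- activity_scenario(label, duration_s = duration,
                            seed = seed * 131L + offset + i,
                            anchor_lat = anchor[1], anchor_lon = anchor[2])
    list(label = label, scenario = sc, log = generate_signal_log(sc))
  }
  type1 <- labs$name[labs$type == 1L]
  train <- lapply(seq_along(type1), function(i) {
    make(type1[i], i, 0L, train_duration_s)
  })
  test <- lapply(seq_len(nrow(labs)), function(i) {
    make(labs$name[i], i, 10000L, test_duration_s)
  })
  list(train = train, test = test, registry = registry)
}
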