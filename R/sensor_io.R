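#' Sensor log, model, registry and confusion-matrix I/O
#'
#' All interchange formats are plain text. Sensor logs are CSV with columns
#' `timestamp,sensor,v1,v2,v3,v4`: accelerometer/gyroscope rows use v1..v3
#' (m/s^2, rad/s), proximity rows use v1 (raw cm), GPS rows use
#' v1 = latitude (deg), v2 = longitude (deg), v3 = speed (km/h),
#' v4 = fix quality in [0, 1]. Models and location registries are JSON with
#' an explicit `schema_version`. Confusion matrices are labeled CSV of
#' row-normalized percentages.
#'
#' @name sensor_io
NULL

SENSOR_KINDS <- c("accelerometer", "gyroscope", "proximity", "gps")
MODEL_SCHEMA_VERSION <- 1L
REGISTRY_CATEGORIES <- c("home", "office", "type2")

empty_df <- function(cols) {
  as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
}

#' Construct an empty sensor log
#'
#' @param nominal_rate Declared inertial sampling rate in Hz (default 50).
#' @return A `sensor_log` object with zero samples of every kind.
#' @export
empty_sensor_log <- function(nominal_rate = 50) {
  new_sensor_log(
    accelerometer = empty_df(c("timestamp", "x", "y", "z")),
    gyroscope = empty_df(c("timestamp", "x", "y", "z")),
    proximity = empty_df(c("timestamp", "value")),
    gps = empty_df(c("timestamp", "latitude", "longitude", "speed_kmh",
                     "fix_quality")),
    nominal_rate = nominal_rate
  )
}

new_sensor_log <- function(accelerometer, gyroscope, proximity, gps,
                           nominal_rate = 50, n_malformed = 0L) {
  if (!is.numeric(nominal_rate) || nominal_rate <= 0) {
    harf_validation_error("nominal_rate must be > 0")
  }
  structure(
    list(accelerometer = accelerometer, gyroscope = gyroscope,
         proximity = proximity, gps = gps, nominal_rate = nominal_rate,
         n_malformed = as.integer(n_malformed)),
    class = "sensor_log"
  )
}

#' @export
print.sensor_log <- function(x, ...) {
  cat(sprintf(
    "sensor_log: %d accel, %d gyro, %d proximity, %d gps samples (nominal %g Hz)\n",
    nrow(x$accelerometer), nrow(x$gyroscope), nrow(x$proximity), nrow(x$gps),
    x$nominal_rate
  ))
  if (x$n_malformed > 0) cat(sprintf("  %d malformed rows dropped\n", x$n_malformed))
  invisible(x)
}

check_monotone <- function(ts, kind) {
  if (length(ts) > 1L) {
    bad <- which(diff(ts) < 0)
    if (length(bad) > 0L) {
      harf_format_error(sprintf(
        "non-monotonic timestamps in %s stream at sample %d", kind, bad[1L] + 1L
      ))
    }
  }
  invisible(TRUE)
}

#' Read a multimodal sensor log from CSV
#'
#' Malformed rows (unparseable numbers, unknown sensor kinds, missing
#' components, out-of-range GPS values) are dropped, counted in the returned
#' log's `n_malformed` field and reported with a warning. Ordering violations
#' within a stream are rejected, never repaired.
#'
#' @param path Path to a sensor-log CSV with header
#'   `timestamp,sensor,v1,v2,v3,v4`.
#' @param nominal_rate Declared inertial sampling rate in Hz.
#' @return A `sensor_log` with per-kind streams sorted by timestamp.
#' @export
read_sensor_log <- function(path, nominal_rate = 50) {
  if (!file.exists(path)) harf_format_error(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) harf_format_error(sprintf("cannot parse CSV %s: %s",
                                                  path, conditionMessage(e)))
  )
  required <- c("timestamp", "sensor", "v1", "v2", "v3", "v4")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    harf_format_error(sprintf("missing required column(s): %s",
                              paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) return(empty_sensor_log(nominal_rate))
  ts <- suppressWarnings(as.numeric(df$timestamp))
  vals <- lapply(df[c("v1", "v2", "v3", "v4")],
                 function(col) suppressWarnings(as.numeric(col)))
  kind <- df$sensor
  bad <- is.na(ts) | !(kind %in% SENSOR_KINDS)
  tri <- kind %in% c("accelerometer", "gyroscope")
  bad <- bad | (tri & (is.na(vals$v1) | is.na(vals$v2) | is.na(vals$v3)))
  bad <- bad | (kind == "proximity" & is.na(vals$v1))
  is_gps <- kind == "gps"
  gps_ok <- !is.na(vals$v1) & !is.na(vals$v2) & !is.na(vals$v3) &
    !is.na(vals$v4) & vals$v1 >= -90 & vals$v1 <= 90 &
    vals$v2 >= -180 & vals$v2 <= 180 & vals$v3 >= 0 &
    vals$v4 >= 0 & vals$v4 <= 1
  bad <- bad | (is_gps & !gps_ok)
  n_malformed <- sum(bad)
  if (n_malformed > 0L) {
    warning(sprintf("%s: dropped %d malformed row(s)", path, n_malformed))
  }
  keep <- !bad
  slice <- function(k, cols) {
    idx <- which(keep & kind == k)
    out <- data.frame(timestamp = ts[idx])
    for (i in seq_along(cols)) out[[cols[i]]] <- vals[[i]][idx]
    check_monotone(out$timestamp, k)
    out
  }
  new_sensor_log(
    accelerometer = slice("accelerometer", c("x", "y", "z")),
    gyroscope = slice("gyroscope", c("x", "y", "z")),
    proximity = slice("proximity", "value"),
    gps = slice("gps", c("latitude", "longitude", "speed_kmh", "fix_quality")),
    nominal_rate = nominal_rate, n_malformed = n_malformed
  )
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

#' Write a sensor log to CSV
#'
#' Rows are interleaved in timestamp order (ties broken by kind:
#' accelerometer, gyroscope, proximity, gps). Numbers are written with 17
#' significant digits so that read-after-write reproduces every double
#' exactly.
#'
#' @param log A `sensor_log`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensor_log <- function(log, path) {
  stopifnot(inherits(log, "sensor_log"))
  rows <- list()
  add <- function(ts, kind, v1, v2 = NA_real_, v3 = NA_real_, v4 = NA_real_) {
    if (length(ts) == 0L) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      timestamp = ts, sensor = kind, v1 = v1, v2 = v2, v3 = v3, v4 = v4,
      stringsAsFactors = FALSE
    )
  }
  add(log$accelerometer$timestamp, "accelerometer",
      log$accelerometer$x, log$accelerometer$y, log$accelerometer$z)
  add(log$gyroscope$timestamp, "gyroscope",
      log$gyroscope$x, log$gyroscope$y, log$gyroscope$z)
  add(log$proximity$timestamp, "proximity", log$proximity$value)
  add(log$gps$timestamp, "gps", log$gps$latitude, log$gps$longitude,
      log$gps$speed_kmh, log$gps$fix_quality)
  header <- "timestamp,sensor,v1,v2,v3,v4"
  if (length(rows) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  all_rows <- do.call(rbind, rows)
  kind_rank <- match(all_rows$sensor, SENSOR_KINDS)
  ord <- order(all_rows$timestamp, kind_rank, method = "radix")
  all_rows <- all_rows[ord, , drop = FALSE]
  lines <- paste(
    fmt_num(all_rows$timestamp), all_rows$sensor,
    fmt_num(all_rows$v1), fmt_num(all_rows$v2),
    fmt_num(all_rows$v3), fmt_num(all_rows$v4),
    sep = ","
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write an activity model set to JSON
#'
#' @param models An `anb_model_set` (see [train_models()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  if (!inherits(models, "anb_model_set") || length(models$models) == 0L) {
    harf_validation_error("models must be a non-empty anb_model_set")
  }
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    feature_names = as.list(models$feature_names),
    mode = models$mode,
    variance_floor = models$variance_floor,
    chunk_size = models$chunk_size,
    models = lapply(unname(models$models), function(m) {
      list(label = m$label, prior = m$prior, mu_m = as.list(m$mu_m),
           mu_v = as.list(m$mu_v), j = m$j, mode = m$mode,
           variance_floor = m$variance_floor)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read an activity model set from JSON
#'
#' @param path Path to a model JSON written by [write_models()].
#' @return An `anb_model_set`.
#' @export
read_models <- function(path) {
  if (!file.exists(path)) harf_format_error(sprintf("file not found: %s", path))
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) harf_format_error(sprintf(
      "model file %s is not valid JSON (truncated or corrupt): %s",
      path, conditionMessage(e)
    ))
  )
  ver <- obj$schema_version
  if (is.null(ver) || !identical(as.integer(ver), MODEL_SCHEMA_VERSION)) {
    harf_format_error(sprintf(
      "unsupported model schema version '%s' (this build reads version %d)",
      if (is.null(ver)) "<absent>" else as.character(ver), MODEL_SCHEMA_VERSION
    ))
  }
  feature_names <- as.character(unlist(obj$feature_names))
  models <- lapply(obj$models, function(m) {
    structure(
      list(label = m$label, prior = as.numeric(m$prior),
           feature_names = feature_names,
           mu_m = as.numeric(unlist(m$mu_m)), mu_v = as.numeric(unlist(m$mu_v)),
           j = as.integer(m$j), mode = m$mode,
           variance_floor = as.numeric(m$variance_floor), chunks = NULL),
      class = "anb_model"
    )
  })
  names(models) <- vapply(models, function(m) m$label, character(1))
  new_model_set(models, feature_names, obj$mode, as.numeric(obj$variance_floor),
                as.integer(obj$chunk_size))
}

#' Read a registered-location registry from JSON
#'
#' The registry is a JSON array of objects with fields `label`, `latitude`,
#' `longitude`, `radius_m` and `category` (one of `home`, `office`, `type2`).
#' `type2` entries must be named after one of the four location-based
#' activities so that geofence matches map one-to-one onto activity labels.
#'
#' @param path Path to the registry JSON.
#' @return A data frame with one row per registered location.
#' @export
read_location_registry <- function(path) {
  if (!file.exists(path)) harf_format_error(sprintf("file not found: %s", path))
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) harf_format_error(sprintf(
      "registry %s is not valid JSON: %s", path, conditionMessage(e)
    ))
  )
  if (!is.list(obj)) harf_format_error("registry must be a JSON array")
  rows <- lapply(obj, function(e) {
    for (f in c("label", "latitude", "longitude", "radius_m", "category")) {
      if (is.null(e[[f]])) {
        harf_validation_error(sprintf(
          "registry entry '%s' is missing field '%s'",
          e$label %||% "<unlabeled>", f
        ))
      }
    }
    data.frame(label = e$label, latitude = as.numeric(e$latitude),
               longitude = as.numeric(e$longitude),
               radius_m = as.numeric(e$radius_m), category = e$category,
               stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, rows)
  validate_registry(reg)
}

#' Validate a location registry data frame
#'
#' @param reg Data frame with columns `label`, `latitude`, `longitude`,
#'   `radius_m`, `category`.
#' @return `reg`, invisibly validated (returned visibly for chaining).
#' @export
validate_registry <- function(reg) {
  bad_cat <- !(reg$category %in% REGISTRY_CATEGORIES)
  if (any(bad_cat)) {
    harf_validation_error(sprintf(
      "unknown category '%s' for registry entry '%s' (allowed: %s)",
      reg$category[bad_cat][1L], reg$label[bad_cat][1L],
      paste(REGISTRY_CATEGORIES, collapse = ", ")
    ))
  }
  if (any(reg$radius_m <= 0)) {
    harf_validation_error(sprintf(
      "registry entry '%s' has non-positive radius_m",
      reg$label[reg$radius_m <= 0][1L]
    ))
  }
  if (anyDuplicated(reg$label)) {
    harf_validation_error(sprintf(
      "duplicate registry label '%s'; labels must be unique",
      reg$label[duplicated(reg$label)][1L]
    ))
  }
  if (any(reg$latitude < -90 | reg$latitude > 90 |
          reg$longitude < -180 | reg$longitude > 180)) {
    harf_validation_error("registry coordinates out of WGS84 range")
  }
  type2_names <- activity_labels()$name[activity_labels()$type == 2L]
  t2 <- reg$label[reg$category == "type2"]
  bad_t2 <- setdiff(t2, type2_names)
  if (length(bad_t2) > 0L) {
    harf_validation_error(sprintf(
      "type2 registry entry '%s' does not name a location-based activity (%s)",
      bad_t2[1L], paste(type2_names, collapse = "; ")
    ))
  }
  reg
}

#' Write a location registry to JSON
#'
#' @param reg Registry data frame (see [read_location_registry()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_location_registry <- function(reg, path) {
  validate_registry(reg)
  entries <- lapply(seq_len(nrow(reg)), function(i) {
    list(label = reg$label[i], latitude = reg$latitude[i],
         longitude = reg$longitude[i], radius_m = reg$radius_m[i],
         category = reg$category[i])
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Write per-window predictions as JSON lines
#'
#' @param preds A list of prediction records (each a list with at least
#'   `label`; see [harf_route()]).
#' @param path Output path (one JSON object per line).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  lines <- vapply(preds, function(p) {
    as.character(jsonlite::toJSON(p, auto_unbox = TRUE, digits = I(17),
                                  null = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#'
#' @param path JSON-lines predictions path.
#' @return A list of prediction records.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) harf_format_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}
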