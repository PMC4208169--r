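#' Hierarchical, location-first activity routing
#'
#' Recognition proceeds location-first. The last GPS fix of a window is
#' compared against the registered-location list (circular geofences,
#' haversine distance). A match on a type-2 venue short-circuits to that
#' venue's location-based activity without invoking the classifier. A match
#' on home or office restricts the naive Bayes candidate set to that area's
#' three physical activities. An unmatched (or fix-less) window is treated
#' as outdoors and classified over the four outdoor physical activities;
#' on that branch only, a windowed mean GPS speed strictly above 25 km/h
#' compulsorily relabels the window as riding a car (the heuristic
#' override).
#'
#' @name hierarchy
NULL

#' The fifteen-activity taxonomy
#'
#' Ten location-qualified physical activities (type 1, classified from
#' multimodal features with location-restricted candidates), four purely
#' location-based activities (type 2, implied by being inside a registered
#' venue), and one heuristic activity (type 3, riding a car, triggered by
#' GPS speed).
#'
#' @return A data frame with columns `name`, `area` (Home/Office/Outdoor)
#'   and `type` (1, 2 or 3); exactly 15 rows partitioned 10/4/1.
#' @export
activity_labels <- function() {
  data.frame(
    name = c("Home/Walking", "Home/Sitting", "Home/Standing",
             "Office/Walking", "Office/Sitting", "Office/Standing",
             "Outdoor/Walking", "Outdoor/Sitting", "Outdoor/Standing",
             "Outdoor/Jogging",
             "Waiting for bus at bus stop", "Having a meal at cafeteria",
             "Exercising at gym", "Visiting a park",
             "Riding a car"),
    area = c(rep("Home", 3), rep("Office", 3), rep("Outdoor", 4),
             rep("Outdoor", 4), "Outdoor"),
    type = c(rep(1L, 10), rep(2L, 4), 3L),
    stringsAsFactors = FALSE
  )
}

check_coords <- function(lat, lon) {
  if (!is.numeric(lat) || !is.numeric(lon) || length(lat) != 1L ||
      length(lon) != 1L || is.na(lat) || is.na(lon) ||
      lat < -90 || lat > 90 || lon < -180 || lon > 180) {
    harf_validation_error("invalid WGS84 coordinates")
  }
  invisible(TRUE)
}

#' Match a position against the registered-location list
#'
#' @param lat,lon Current position in WGS84 decimal degrees.
#' @param registry Registry data frame (see [read_location_registry()]).
#' @return The matched registry row as a one-row data frame (the entry whose
#'   great-circle distance to the point is within its `radius_m`; the
#'   nearest center among multiple matches), or `NULL` when no geofence
#'   contains the point.
#' @export
match_location <- function(lat, lon, registry) {
  check_coords(lat, lon)
  if (is.null(registry) || nrow(registry) == 0L) return(NULL)
  d <- geosphere::distHaversine(
    c(lon, lat), cbind(registry$longitude, registry$latitude)
  )
  hit <- which(d <= registry$radius_m)
  if (length(hit) == 0L) return(NULL)
  best <- hit[order(d[hit], registry$label[hit])][1L]
  out <- registry[best, , drop = FALSE]
  out$distance_m <- d[best]
  out
}

#' Discriminate outdoor from indoor-or-unknown via GPS fix quality
#'
#' A window is deemed outdoors iff it contains at least one fix whose quality
#' reaches the threshold (`>=`, boundary inclusive); absent or uniformly weak
#' GPS yields `indoor_or_unknown`.
#'
#' @param gps_summary A window GPS summary (see [segment_windows()]) or
#'   `NULL`.
#' @param quality_threshold Fix-quality threshold in `[0, 1]`; default 0.5.
#' @return `"outdoor"` or `"indoor_or_unknown"`.
#' @export
detect_environment <- function(gps_summary, quality_threshold = 0.5) {
  if (is.null(gps_summary) || gps_summary$n_fixes < 1L) {
    return("indoor_or_unknown")
  }
  if (gps_summary$max_fix_quality >= quality_threshold) "outdoor"
  else "indoor_or_unknown"
}

#' Riding-a-car speed heuristic
#'
#' @param mean_speed_kmh Windowed mean GPS speed in km/h; must be >= 0.
#' @param threshold_kmh Override threshold; default 25.
#' @return `TRUE` iff the speed is strictly over the threshold.
#' @export
heuristic_speed_override <- function(mean_speed_kmh, threshold_kmh = 25) {
  if (!is.numeric(mean_speed_kmh) || is.na(mean_speed_kmh) ||
      mean_speed_kmh < 0) {
    harf_validation_error("mean speed must be a non-negative number")
  }
  mean_speed_kmh > threshold_kmh
}

area_candidates <- function(area) {
  if (area == "Outdoor") {
    paste0("Outdoor/", c("Walking", "Sitting", "Standing", "Jogging"))
  } else {
    paste0(area, "/", c("Walking", "Sitting", "Standing"))
  }
}

#' Route one window through the hierarchical recognizer
#'
#' Decision order: (a) geofence match on the window's last fix — a type-2
#' venue returns its location-based activity directly (classifier skipped);
#' home/office classify with candidates restricted to that area's walking /
#' sitting / standing; (b) no match (or no fix) classifies over the outdoor
#' candidate set; (c) on the outdoor branch, mean GPS speed strictly over
#' the threshold replaces the label with "Riding a car" and sets the
#' override flag. Every decision is appended to the route trace.
#'
#' @param fv Feature vector for the window (canonical order).
#' @param gps_summary Window GPS summary or `NULL`.
#' @param registry Registered-location data frame.
#' @param models An `anb_model_set` covering the type-1 labels needed by the
#'   branch taken (missing required models raise a configuration error).
#' @param quality_threshold Fix-quality threshold for [detect_environment()].
#' @param speed_threshold_kmh Riding-a-car override threshold (km/h).
#' @return A `harf_prediction`: list with `label`, `tie`, `posteriors` (the
#'   score data frame, or `NULL` when the classifier was skipped), `route`
#'   (character trace) and `heuristic_override`.
#' @export
harf_route <- function(fv, gps_summary, registry, models,
                       quality_threshold = 0.5, speed_threshold_kmh = 25) {
  trace <- character(0)
  env <- detect_environment(gps_summary, quality_threshold)
  trace <- c(trace, paste0("environment:", env))
  loc <- NULL
  if (!is.null(gps_summary) && gps_summary$n_fixes >= 1L) {
    loc <- match_location(gps_summary$last_latitude, gps_summary$last_longitude,
                          registry)
  }
  if (!is.null(loc)) {
    trace <- c(trace, paste0("location:", loc$label))
    if (loc$category == "type2") {
      trace <- c(trace, "type2-shortcut")
      return(new_prediction(loc$label, tie = FALSE, posteriors = NULL,
                            route = trace, heuristic_override = FALSE))
    }
    area <- if (loc$category == "home") "Home" else "Office"
    cands <- area_candidates(area)
    missing <- setdiff(cands, names(models$models))
    if (length(missing) > 0L) {
      harf_config_error(sprintf(
        "matched %s but required model(s) missing: %s",
        tolower(area), paste(missing, collapse = ", ")
      ))
    }
    trace <- c(trace, paste0("candidates:", paste(cands, collapse = "|")))
    cl <- nb_classify(models, fv, cands)
    return(new_prediction(cl$label, tie = cl$tie, posteriors = cl$scores,
                          route = trace, heuristic_override = FALSE))
  }
  trace <- c(trace, "location:unregistered")
  cands <- area_candidates("Outdoor")
  missing <- setdiff(cands, names(models$models))
  if (length(missing) > 0L) {
    harf_config_error(sprintf(
      "outdoor branch requires model(s): %s", paste(missing, collapse = ", ")
    ))
  }
  trace <- c(trace, paste0("candidates:", paste(cands, collapse = "|")))
  cl <- nb_classify(models, fv, cands)
  label <- cl$label
  override <- FALSE
  if (!is.null(gps_summary) && gps_summary$n_fixes >= 1L &&
      heuristic_speed_override(gps_summary$mean_speed_kmh,
                               speed_threshold_kmh)) {
    override <- TRUE
    label <- "Riding a car"
    trace <- c(trace, sprintf("override:speed %.1f km/h > %g km/h",
                              gps_summary$mean_speed_kmh, speed_threshold_kmh))
  }
  new_prediction(label, tie = cl$tie, posteriors = cl$scores, route = trace,
                 heuristic_override = override)
}

new_prediction <- function(label, tie, posteriors, route, heuristic_override) {
  structure(
    list(label = label, tie = tie, posteriors = posteriors, route = route,
         heuristic_override = heuristic_override),
    class = "harf_prediction"
  )
}

#' @export
print.harf_prediction <- function(x, ...) {
  cat(sprintf("prediction: %s%s\n", x$label,
              if (x$heuristic_override) " [speed override]" else ""))
  cat("  route:", paste(x$route, collapse = " -> "), "\n")
  invisible(x)
}
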