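# Location-first routing: taxonomy, geofencing, environment, override.

test_that("the taxonomy has 15 labels partitioned 10/4/1", {
  labs <- activity_labels()
  expect_equal(nrow(labs), 15L)
  expect_equal(as.vector(table(labs$type)[c("1", "2", "3")]), c(10L, 4L, 1L))
  expect_setequal(unique(labs$area), c("Home", "Office", "Outdoor"))
  expect_false(anyDuplicated(labs$name) > 0)
})

test_that("geofence matching agrees with an independent spherical oracle", {
  reg <- tiny_registry()
  # exact center matches its own entry
  hit <- match_location(reg$latitude[1], reg$longitude[1], reg)
  expect_equal(hit$label, "home")
  expect_equal(hit$distance_m, 0, tolerance = 1e-6)
  # 10 km away from everything: no match
  expect_null(match_location(37.33, 127.20, reg))
  # overlapping fences: nearer center wins, distances cross-checked
  reg2 <- data.frame(
    label = c("a", "b"), latitude = c(37.2400, 37.2404),
    longitude = c(127.08, 127.08), radius_m = 500,
    category = c("home", "office"), stringsAsFactors = FALSE
  )
  pt <- c(37.2401, 127.08)
  d_a <- slc_distance_m(pt[1], pt[2], reg2$latitude[1], reg2$longitude[1])
  d_b <- slc_distance_m(pt[1], pt[2], reg2$latitude[2], reg2$longitude[2])
  expect_lt(d_a, d_b)
  hit2 <- match_location(pt[1], pt[2], reg2)
  expect_equal(hit2$label, "a")
  expect_equal(hit2$distance_m, d_a, tolerance = 1e-3)
  expect_error(match_location(95, 0, reg), class = "harf_validation_error")
})

test_that("environment detection keys on fix quality with an inclusive boundary", {
  expect_equal(detect_environment(NULL), "indoor_or_unknown")
  expect_equal(detect_environment(gsum(37, 127, quality = 0.9)), "outdoor")
  expect_equal(detect_environment(gsum(37, 127, quality = 0.5)), "outdoor")
  expect_equal(detect_environment(gsum(37, 127, quality = 0.49)),
               "indoor_or_unknown")
})

test_that("the speed override is strictly greater-than 25 km/h", {
  expect_true(heuristic_speed_override(26))
  expect_false(heuristic_speed_override(25))
  expect_false(heuristic_speed_override(0))
  expect_error(heuristic_speed_override(-1), class = "harf_validation_error")
})

test_that("routing follows the decision tree on constructed fixtures", {
  reg <- tiny_registry()
  ms <- type1_test_models()
  gym <- reg[reg$label == "Exercising at gym", ]

  # type-2 shortcut: any inertial signature, classifier skipped
  pr <- harf_route(c(99, -99), gsum(gym$latitude, gym$longitude), reg, ms)
  expect_equal(pr$label, "Exercising at gym")
  expect_null(pr$posteriors)
  expect_false(pr$heuristic_override)
  expect_true(any(grepl("type2-shortcut", pr$route)))

  # home match restricts candidates to the three home activities
  target <- "Home/Sitting"
  pr2 <- harf_route(type1_mean(ms, target),
                    gsum(reg$latitude[1], reg$longitude[1], quality = 0.2),
                    reg, ms)
  expect_equal(pr2$label, target)
  expect_equal(nrow(pr2$posteriors), 3L)
  expect_true(all(startsWith(pr2$posteriors$label, "Home/")))

  # office symmetric
  target_o <- "Office/Walking"
  pr3 <- harf_route(type1_mean(ms, target_o),
                    gsum(reg$latitude[2], reg$longitude[2]), reg, ms)
  expect_equal(pr3$label, target_o)
  expect_true(all(startsWith(pr3$posteriors$label, "Office/")))

  # unregistered location -> the four outdoor candidates
  pr4 <- harf_route(type1_mean(ms, "Outdoor/Jogging"), gsum(37.3, 127.3),
                    reg, ms)
  expect_equal(pr4$label, "Outdoor/Jogging")
  expect_equal(nrow(pr4$posteriors), 4L)

  # >25 km/h outdoors: sitting-like features compulsorily become the car
  pr5 <- harf_route(type1_mean(ms, "Outdoor/Sitting"),
                    gsum(37.3, 127.3, speed = 60), reg, ms)
  expect_equal(pr5$label, "Riding a car")
  expect_true(pr5$heuristic_override)
  # boundary: exactly 25 km/h does not override
  pr6 <- harf_route(type1_mean(ms, "Outdoor/Sitting"),
                    gsum(37.3, 127.3, speed = 25), reg, ms)
  expect_equal(pr6$label, "Outdoor/Sitting")
  expect_false(pr6$heuristic_override)
  # no GPS at all: outdoor candidate set, no override possible
  pr7 <- harf_route(type1_mean(ms, "Outdoor/Walking"), NULL, reg, ms)
  expect_equal(pr7$label, "Outdoor/Walking")
  expect_false(pr7$heuristic_override)
})

test_that("the override never applies on the home/office branch", {
  reg <- tiny_registry()
  ms <- type1_test_models()
  pr <- harf_route(type1_mean(ms, "Home/Sitting"),
                   gsum(reg$latitude[1], reg$longitude[1], speed = 60),
                   reg, ms)
  expect_equal(pr$label, "Home/Sitting")
  expect_false(pr$heuristic_override)
})

test_that("raising speed across the threshold never un-sets the car label", {
  reg <- tiny_registry()
  ms <- type1_test_models()
  fv <- type1_mean(ms, "Outdoor/Sitting")
  speeds <- seq(0, 80, by = 5)
  labels <- vapply(speeds, function(s) {
    harf_route(fv, gsum(37.3, 127.3, speed = s), reg, ms)$label
  }, character(1))
  is_car <- labels == "Riding a car"
  expect_false(any(is_car[speeds <= 25]))
  expect_true(all(is_car[speeds > 25]))
})

test_that("type-2 output is independent of inertial features", {
  reg <- tiny_registry()
  ms <- type1_test_models()
  gym <- reg[reg$label == "Exercising at gym", ]
  set.seed(31)
  for (i in 1:20) {
    pr <- harf_route(rnorm(2, 0, 50), gsum(gym$latitude, gym$longitude),
                     reg, ms)
    expect_equal(pr$label, "Exercising at gym")
  }
})

test_that("area routing never leaks labels across areas", {
  reg <- tiny_registry()
  ms <- type1_test_models()
  set.seed(13)
  for (i in 1:25) {
    fv <- rnorm(2, 0, 8)
    home <- harf_route(fv, gsum(reg$latitude[1], reg$longitude[1]), reg, ms)
    expect_true(startsWith(home$label, "Home/"))
    office <- harf_route(fv, gsum(reg$latitude[2], reg$longitude[2]), reg, ms)
    expect_true(startsWith(office$label, "Office/"))
    out <- harf_route(fv, gsum(37.3, 127.3, speed = 5), reg, ms)
    expect_true(startsWith(out$label, "Outdoor/"))
  }
})

test_that("routing is deterministic and required models are enforced", {
  reg <- tiny_registry()
  ms <- type1_test_models()
  fv <- c(2.5, -2.5)
  g <- gsum(reg$latitude[1], reg$longitude[1])
  a <- harf_route(fv, g, reg, ms)
  b <- harf_route(fv, g, reg, ms)
  expect_identical(a$label, b$label)
  expect_identical(a$route, b$route)

  ms_missing <- ms
  ms_missing$models[["Home/Sitting"]] <- NULL
  expect_error(harf_route(fv, g, reg, ms_missing),
               "Home/Sitting", class = "harf_config_error")
})
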