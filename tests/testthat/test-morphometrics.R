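# Shape measurements: area, perimeter, dissection index, landmarks,
# serration counting, normalization and population summaries.

test_that("polygon area matches hand values and the analytic circle limit", {
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(polygon_area(rbind(c(0, 0), c(2, 0), c(0, 2))), 2)
  expect_equal(polygon_area(circle_polygon(512)), pi, tolerance = 1e-4)
  # orientation and starting vertex do not matter
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq[4:1, ]), 1)
  expect_equal(polygon_area(sq[c(3, 4, 1, 2), ]), 1)
})

test_that("polygon area agrees with an independent shoelace implementation", {
  skip_if_not_installed("pracma")
  set.seed(7)
  for (i in 1:10) {
    th <- sort(runif(30, 0, 2 * pi))
    r <- runif(30, 0.5, 2)
    xy <- cbind(r * cos(th), r * sin(th)) # star-shaped, hence simple
    expect_equal(polygon_area(xy),
                 abs(pracma::polyarea(xy[, 1], xy[, 2])),
                 tolerance = 1e-12)
  }
})

test_that("open and self-intersecting polygons are rejected", {
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "3 vertices")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygon_area(bowtie), "self-intersecting")
})

test_that("perimeter covers closed squares, open polylines and the circle limit", {
  expect_equal(polygon_perimeter(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 4)
  expect_equal(polygon_perimeter(rbind(c(0, 0), c(3, 4)), closed = FALSE), 5)
  expect_equal(polygon_perimeter(circle_polygon(512)), 2 * pi,
               tolerance = 1e-4)
})

test_that("dissection index hits the isoperimetric equality and the square value", {
  expect_equal(dissection_index(circle_polygon(2048)), 2 * sqrt(pi),
               tolerance = 1e-3)
  expect_equal(dissection_index(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 4)
})

test_that("dissection index is scale invariant and grows with serration", {
  ann0 <- generate_lip_contour(lip_shape_params(serration_amplitude = 0))
  ann1 <- generate_lip_contour(lip_shape_params(serration_count = 20,
                                                serration_amplitude = 0.5))
  w0 <- as.matrix(ann0$left_wing[, c("x_mm", "y_mm")])
  w1 <- as.matrix(ann1$left_wing[, c("x_mm", "y_mm")])
  expect_gt(dissection_index(w1), dissection_index(w0))
  for (s in c(0.1, 3, 40)) {
    expect_equal(dissection_index(w1 * s), dissection_index(w1),
                 tolerance = 1e-9)
  }
})

test_that("body and wing measures read the landmarks", {
  ann <- generate_lip_contour(lip_shape_params(
    body_length = 30, body_width = 10, wing_radius = 20, body_wing_angle = 90
  ))
  expect_equal(measure_body(ann)$body_length, 30)
  expect_equal(measure_body(ann)$body_width, 10)
  expect_equal(measure_wing(ann)$wing_length, 20)
  expect_equal(measure_wing(ann)$angle, 90, tolerance = 1e-8)
  # missing landmark errors by name
  ann2 <- ann
  ann2$landmarks <- ann2$landmarks[ann2$landmarks$landmark != "body_tip", ]
  expect_error(measure_body(ann2), "body_tip")
})

test_that("parallel body and wing axes are a degenerate error", {
  ann <- generate_lip_contour(lip_shape_params())
  ann$landmarks$x_mm[ann$landmarks$landmark == "wing_tip"] <- 0
  ann$landmarks$y_mm[ann$landmarks$landmark == "wing_tip"] <- -5
  expect_error(measure_wing(ann), "parallel")
})

test_that("serration counting is exact for generated teeth and thresholds dominate", {
  smooth <- generate_lip_contour(lip_shape_params(serration_amplitude = 0))
  expect_identical(count_serrations(serrated_margin(smooth)), 0L)
  ann <- generate_lip_contour(lip_shape_params(serration_count = 12,
                                               serration_amplitude = 0.5))
  m <- serrated_margin(ann)
  expect_identical(count_serrations(m, prominence_threshold = 0.2), 12L)
  expect_identical(count_serrations(m, prominence_threshold = 1.0), 0L)
  expect_error(count_serrations(m, prominence_threshold = 0), "> 0")
  expect_error(count_serrations(m[1:3, ]), "5 vertices")
})

test_that("measure_lip recovers generator ground truth end to end", {
  p <- lip_shape_params(body_length = 16, body_width = 7, wing_radius = 22,
                        body_wing_angle = 75, serration_count = 18,
                        serration_amplitude = 0.5)
  m <- measure_lip(generate_lip_contour(p))
  expect_equal(m$body_length, 16)
  expect_equal(m$body_width, 7)
  expect_equal(m$wing_length, 22)
  expect_equal(m$angle, 75, tolerance = 1e-6)
  expect_identical(m$serration_number, 18L)
  expect_gt(m$area, 0)
  expect_gt(m$dissection_index, 2 * sqrt(pi) - 1e-3)
})

test_that("measurements are invariant under rigid motions and reflection", {
  ann <- generate_lip_contour(lip_shape_params(serration_count = 10,
                                               serration_amplitude = 0.5))
  transform_ann <- function(ann, fun) {
    out <- ann
    for (part in c("lip", "left_wing")) {
      xy <- fun(as.matrix(out[[part]][, c("x_mm", "y_mm")]))
      out[[part]]$x_mm <- xy[, 1]; out[[part]]$y_mm <- xy[, 2]
    }
    xy <- fun(as.matrix(out$landmarks[, c("x_mm", "y_mm")]))
    out$landmarks$x_mm <- xy[, 1]; out$landmarks$y_mm <- xy[, 2]
    out
  }
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rigid <- transform_ann(ann, function(xy) {
    sweep(xy %*% t(R), 2, c(13, -4), "+")
  })
  mirror <- transform_ann(ann, function(xy) cbind(-xy[, 1], xy[, 2]))
  m0 <- measure_lip(ann)
  expect_equal(as.data.frame(measure_lip(rigid)), as.data.frame(m0),
               tolerance = 1e-9)
  expect_equal(as.data.frame(measure_lip(mirror)), as.data.frame(m0),
               tolerance = 1e-9)
})

test_that("radar normalization divides by the fixed trait maxima", {
  m <- tibble::tibble(
    area = 1, perimeter = 1, dissection_index = 40, body_length = 30,
    body_width = 10, wing_length = 40, angle = 90, serration_number = 50
  )
  prof <- normalize_profile(m)
  expect_equal(unlist(prof[1, c("DI", "BL", "BW", "WL", "A", "Se")]),
               c(DI = 1, BL = 1, BW = 1, WL = 1, A = 1, Se = 1))
  m$angle <- 45
  expect_equal(normalize_profile(m)$A, 0.5)
  m[1, c("dissection_index", "body_length", "body_width", "wing_length",
         "angle", "serration_number")] <- 0
  expect_equal(sum(unlist(
    normalize_profile(m)[1, c("DI", "BL", "BW", "WL", "A", "Se")]
  )), 0)
  expect_error(normalization_constants(di_max = 0), "> 0")
})

test_that("population radar summaries give means, sample SDs and counts", {
  one <- tibble::tibble(DI = 0.2, BL = 0.5, BW = 0.6, WL = 0.5, A = 0.7,
                        Se = 0.4)
  s1 <- summarize_population(one)
  expect_equal(s1$sd, rep(0, 6))
  expect_equal(s1$n, rep(1L, 6))
  two <- dplyr::bind_rows(one, one + 0.2)
  s2 <- summarize_population(two)
  expect_equal(s2$mean[s2$trait == "DI"], 0.3)
  expect_equal(s2$sd, rep(sqrt(2) * 0.1, 6), tolerance = 1e-12)
  expect_error(summarize_population(one[0, ]), "No profiles")
})

test_that("jittered replicate profiles average back to the noiseless profile", {
  p <- lip_shape_params(serration_count = 15, serration_amplitude = 0.6)
  noiseless <- normalize_profile(measure_lip(generate_lip_contour(p)))
  profs <- purrr::map_dfr(1:40, function(i) {
    pi <- p; pi$seed <- i
    normalize_profile(measure_lip(generate_lip_contour(pi, jitter_sd = 0.002),
                                  check = FALSE))
  })
  sm <- summarize_population(profs)
  for (tr in c("DI", "BL", "BW", "WL", "A", "Se")) {
    row <- sm[sm$trait == tr, ]
    se <- row$sd / sqrt(row$n)
    # perimeter-type quantities pick up a small positive noise bias of
    # order sd^2 / vertex spacing; allow it alongside the sampling error
    expect_lt(abs(row$mean - noiseless[[tr]]), 2 * se + 5e-4)
  }
})
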