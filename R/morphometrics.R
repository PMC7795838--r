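# Lip morphometrics: the seven measured shape factors and their normalized
# radar profile.

#' Area of a closed simple polygon
#'
#' Shoelace area of a closed contour (the closing edge is implicit). The
#' result is independent of orientation, starting vertex and rigid motions.
#'
#' @param contour Two-column matrix or data frame with `x_mm`/`y_mm` columns.
#' @param check Validate simplicity (non-self-intersection) before
#'   computing; disable only for contours known simple by construction.
#' @return Area in mm^2.
#' @export
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
polygon_area <- function(contour, check = TRUE) {
  xy <- as_xy(contour)
  assert_closed_simple(xy, check_simple = check)
  abs(signed_area2(xy)) / 2
}

#' Perimeter of a polygon or polyline
#'
#' Sum of Euclidean segment lengths; for closed contours the implicit
#' closing segment is included.
#'
#' @inheritParams polygon_area
#' @param closed Include the closing segment (default `TRUE`).
#' @return Length in mm.
#' @export
polygon_perimeter <- function(contour, closed = TRUE) {
  xy <- as_xy(contour)
  if (nrow(xy) < 2L) abort("Need at least 2 vertices for a perimeter.")
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  p <- sum(d)
  if (closed) {
    p <- p + sqrt((xy[1, 1] - xy[nrow(xy), 1])^2 +
                  (xy[1, 2] - xy[nrow(xy), 2])^2)
  }
  p
}

#' Dissection index of a closed contour
#'
#' `perimeter / sqrt(area)`: a dimensionless measure of outline complexity,
#' invariant under rigid motions and uniform scaling, minimized by a circle
#' at `2 * sqrt(pi)` (isoperimetric bound, about 3.5449).
#'
#' @inheritParams polygon_area
#' @return Dimensionless dissection index.
#' @export
dissection_index <- function(contour, check = TRUE) {
  a <- polygon_area(contour, check = check)
  if (a <= 0) abort("Zero-area contour: dissection index undefined.")
  polygon_perimeter(contour, closed = TRUE) / sqrt(a)
}

get_landmark <- function(annotation, name) {
  row <- annotation$landmarks[annotation$landmarks$landmark == name, ]
  if (nrow(row) != 1L || anyNA(row[, c("x_mm", "y_mm")])) {
    abort(sprintf("Landmark `%s` is missing from the annotation.", name))
  }
  c(row$x_mm, row$y_mm)
}

#' Body length and width from lip landmarks
#'
#' @param annotation A `lip_annotation`.
#' @return One-row tibble with `body_length` (distance body base to tip,
#'   mm) and `body_width` (length of the body-width segment, mm).
#' @export
measure_body <- function(annotation) {
  base <- get_landmark(annotation, "body_base")
  tip <- get_landmark(annotation, "body_tip")
  w1 <- get_landmark(annotation, "body_width_1")
  w2 <- get_landmark(annotation, "body_width_2")
  tibble::tibble(
    body_length = sqrt(sum((tip - base)^2)),
    body_width = sqrt(sum((w2 - w1)^2))
  )
}

#' Wing length and body-wing angle from lip landmarks
#'
#' The angle is the unsigned angle in (0, 180) degrees between the body axis
#' (base to tip) and the wing axis (base to tip); exactly parallel or
#' antiparallel axes are rejected as degenerate.
#'
#' @param annotation A `lip_annotation`.
#' @return One-row tibble with `wing_length` (mm) and `angle` (degrees).
#' @export
measure_wing <- function(annotation) {
  b <- get_landmark(annotation, "body_tip") -
    get_landmark(annotation, "body_base")
  w <- get_landmark(annotation, "wing_tip") -
    get_landmark(annotation, "wing_base")
  nb <- sqrt(sum(b^2)); nw <- sqrt(sum(w^2))
  if (nb == 0 || nw == 0) abort("Zero-length body or wing axis.")
  cosang <- sum(b * w) / (nb * nw)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (ang <= 0 || ang >= 180) {
    abort("Degenerate body-wing configuration: axes are parallel (angle must lie in the open interval (0, 180)).")
  }
  tibble::tibble(wing_length = nw, angle = ang)
}

# Local maxima of `x` (plateaus count once); returns index (plateau start)
# and topographic prominence of each peak: height above the higher of the
# two cols reached before meeting a taller point (profile ends act as cols).
peak_prominences <- function(x) {
  n <- length(x)
  # collapse plateaus
  keep <- c(TRUE, diff(x) != 0)
  idx <- which(keep)
  v <- x[keep]
  m <- length(v)
  if (m < 3L) return(tibble::tibble(index = integer(), prominence = numeric()))
  is_peak <- c(FALSE, v[2:(m - 1)] > v[1:(m - 2)] & v[2:(m - 1)] > v[3:m],
               FALSE)
  peaks <- which(is_peak)
  prom <- vapply(peaks, function(p) {
    left <- if (p > 1) v[1:(p - 1)] else numeric()
    hi <- which(left >= v[p])
    lo_l <- if (length(hi)) min(left[(max(hi) + 1):(p - 1)]) else min(left)
    right <- if (p < m) v[(p + 1):m] else numeric()
    hi <- which(right >= v[p])
    lo_r <- if (length(hi)) min(right[1:(min(hi) - 1)]) else min(right)
    v[p] - max(lo_l, lo_r)
  }, numeric(1))
  tibble::tibble(index = idx[peaks], prominence = prom)
}

# Least-squares (Kasa) circle fit; NULL when the points are too close to
# collinear for a stable fit.
fit_circle <- function(xy) {
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  b <- xy[, 1]^2 + xy[, 2]^2
  qr_A <- qr(A)
  if (qr_A$rank < 3L) return(NULL)
  sol <- qr.coef(qr_A, b)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  R <- sqrt(r2)
  # reject wildly extrapolated fits (nearly straight margins)
  span <- max(dist(rbind(xy[1, ], xy[nrow(xy) %/% 2, ], xy[nrow(xy), ])))
  if (R > 50 * span) return(NULL)
  list(center = sol[1:2], radius = R)
}

#' Count marginal serrations (teeth) on a wing margin
#'
#' Teeth are local maxima of the margin's deviation from its smooth
#' baseline, retained when their topographic prominence reaches
#' `prominence_threshold`; plateaus count once and the result is
#' deterministic. The baseline is the least-squares circle through the
#' margin vertices (the natural reference for a fan-shaped wing: radial
#' residuals of a smooth arc are ~0, so a plain arc yields zero teeth);
#' for margins too straight for a stable circle fit the baseline falls
#' back to the chord joining the margin's endpoints, making the deviation
#' the classic signed vertex-to-chord distance.
#'
#' @param margin Ordered vertex sub-path (matrix or tibble with
#'   `x_mm`/`y_mm`), at least 5 vertices.
#' @param prominence_threshold Minimum topographic prominence (mm) for a
#'   local maximum to count as a tooth; default 0.2 mm.
#' @return Integer tooth count.
#' @export
count_serrations <- function(margin, prominence_threshold = 0.2) {
  if (prominence_threshold <= 0) {
    abort("`prominence_threshold` must be > 0.")
  }
  xy <- as_xy(margin, name = "margin")
  n <- nrow(xy)
  if (n < 5L) abort("Margin needs at least 5 vertices.")
  circ <- fit_circle(xy)
  if (!is.null(circ)) {
    d <- sqrt((xy[, 1] - circ$center[1])^2 +
              (xy[, 2] - circ$center[2])^2) - circ$radius
  } else {
    a <- xy[1, ]; b <- xy[n, ]
    chord <- b - a
    len <- sqrt(sum(chord^2))
    if (len == 0) abort("Margin endpoints coincide: chord undefined.")
    d <- ((xy[, 1] - a[1]) * chord[2] - (xy[, 2] - a[2]) * chord[1]) / len
    if (sum(d) < 0) d <- -d # orient the bulge upward
  }
  pk <- peak_prominences(d)
  sum(pk$prominence >= prominence_threshold)
}

#' Measure the seven lip shape factors
#'
#' Composes the individual operations: whole-lip area and perimeter,
#' dissection index of the left wing, body length and width, wing length,
#' body-wing angle, and serration number of the left wing's serrated
#' margin.
#'
#' @param annotation A `lip_annotation`.
#' @param prominence_threshold Passed to [count_serrations()].
#' @param check Validate polygon simplicity (see [polygon_area()]).
#' @return One-row tibble with columns `area`, `perimeter`,
#'   `dissection_index`, `body_length`, `body_width`, `wing_length`,
#'   `angle`, `serration_number`.
#' @export
measure_lip <- function(annotation, prominence_threshold = 0.2,
                        check = TRUE) {
  stopifnot(inherits(annotation, "lip_annotation"))
  lip <- as_xy(annotation$lip)
  wing <- as_xy(annotation$left_wing)
  dplyr::bind_cols(
    tibble::tibble(
      area = polygon_area(lip, check = check),
      perimeter = polygon_perimeter(lip),
      dissection_index = dissection_index(wing, check = check)
    ),
    measure_body(annotation),
    measure_wing(annotation),
    tibble::tibble(
      serration_number = count_serrations(
        serrated_margin(annotation),
        prominence_threshold = prominence_threshold
      )
    )
  )
}

#' Normalization maxima for the radar profile
#'
#' The fixed per-trait maxima used to scale measurements into \[0, ~1\]
#' radar values: dissection index 40, body length 30 mm, body width 10 mm,
#' wing length 40 mm, angle 90 degrees, serration number 50.
#'
#' @param di_max,body_length_max,body_width_max,wing_length_max,angle_max,serration_max
#'   Per-trait maxima; all must be positive.
#' @return Named list of the six constants.
#' @export
normalization_constants <- function(di_max = 40, body_length_max = 30,
                                    body_width_max = 10, wing_length_max = 40,
                                    angle_max = 90, serration_max = 50) {
  consts <- list(
    di_max = di_max, body_length_max = body_length_max,
    body_width_max = body_width_max, wing_length_max = wing_length_max,
    angle_max = angle_max, serration_max = serration_max
  )
  if (any(unlist(consts) <= 0)) abort("Normalization constants must be > 0.")
  consts
}

#' Normalized six-trait radar profile
#'
#' Divides six of the measured factors by their fixed maxima
#' ([normalization_constants()]): DI = dissection index / 40, BL = body
#' length / 30, BW = body width / 10, WL = wing length / 40, A = angle / 90,
#' Se = serration number / 50.
#'
#' @param measurements Tibble of measurements as returned by
#'   [measure_lip()] (one or more rows).
#' @param constants A [normalization_constants()] list.
#' @return Tibble with columns `DI`, `BL`, `BW`, `WL`, `A`, `Se` (one row
#'   per input row); any extra identifier columns are carried through.
#' @export
normalize_profile <- function(measurements,
                              constants = normalization_constants()) {
  need <- c("dissection_index", "body_length", "body_width", "wing_length",
            "angle", "serration_number")
  if (!all(need %in% names(measurements))) {
    abort("`measurements` must contain the seven-factor columns from measure_lip().")
  }
  keep <- setdiff(names(measurements),
                  c(need, "area", "perimeter"))
  dplyr::bind_cols(
    measurements[, keep, drop = FALSE],
    tibble::tibble(
      DI = measurements$dissection_index / constants$di_max,
      BL = measurements$body_length / constants$body_length_max,
      BW = measurements$body_width / constants$body_width_max,
      WL = measurements$wing_length / constants$wing_length_max,
      A = measurements$angle / constants$angle_max,
      Se = measurements$serration_number / constants$serration_max
    )
  )
}

#' Per-trait summary of radar profiles
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator; 0 when
#' n = 1) and count per radar trait, optionally within groups -- the
#' radar-chart-ready table.
#'
#' @param profiles Tibble of radar profiles ([normalize_profile()] output).
#' @param group Optional name of a grouping column (e.g. `"population"`).
#' @return Tibble with columns (`group`,) `trait`, `mean`, `sd`, `n`;
#'   traits ordered DI, BL, BW, WL, A, Se. Class `radar_summary`.
#' @export
summarize_population <- function(profiles, group = NULL) {
  traits <- c("DI", "BL", "BW", "WL", "A", "Se")
  if (nrow(profiles) == 0L) abort("No profiles supplied.")
  if (!all(traits %in% names(profiles))) {
    abort("`profiles` must contain the six radar columns DI, BL, BW, WL, A, Se.")
  }
  long <- tidyr::pivot_longer(
    profiles[, c(group, traits)], dplyr::all_of(traits),
    names_to = "trait", values_to = "value"
  )
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group, "trait")))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1L) stats::sd(.data$value) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(trait = factor(.data$trait, levels = traits)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(group, "trait"))))
  class(out) <- c("radar_summary", class(out))
  out
}
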