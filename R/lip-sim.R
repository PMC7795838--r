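#' Parameters for the synthetic egret-lip generator
#'
#' Bundles the geometric ground-truth parameters from which
#' [generate_lip_contour()] builds a synthetic lip (labellum) outline: a
#' drop-shaped central body flanked by two fan-shaped wings, with optional
#' sinusoidal serration of the left wing's distal margin. Defaults describe a
#' typical egret-flower lip at millimetre scale.
#'
#' @param body_length Body length (mm), base to tip.
#' @param body_width Maximum body width (mm).
#' @param wing_radius Wing fan radius (mm); also the wing-axis length.
#' @param wing_angular_extent Angular extent of each wing fan (degrees),
#'   in (0, 180).
#' @param body_wing_angle Unsigned angle between body axis and wing axis
#'   (degrees), in (0, 180).
#' @param serration_count Number of teeth realized on the left wing's distal
#'   margin (0 for a smooth arc).
#' @param serration_amplitude Radial amplitude of the teeth (mm).
#' @param vertices_per_unit Target vertex density along the outline
#'   (vertices per mm). The default keeps the perimeter discretization error
#'   well below 0.1%.
#' @param seed Integer seed used for optional vertex jitter.
#' @return A list of class `lip_shape_params`.
#' @export
#' @examples
#' p <- lip_shape_params(serration_count = 12)
#' ann <- generate_lip_contour(p)
#' measure_lip(ann)
lip_shape_params <- function(body_length = 15,
                             body_width = 6,
                             wing_radius = 20,
                             wing_angular_extent = 100,
                             body_wing_angle = 60,
                             serration_count = 20,
                             serration_amplitude = 0.5,
                             vertices_per_unit = 10,
                             seed = 1L) {
  assert_scalar_number(body_length, "body_length", lower = 0, open_lower = TRUE)
  assert_scalar_number(body_width, "body_width", lower = 0, open_lower = TRUE)
  assert_scalar_number(wing_radius, "wing_radius", lower = 0, open_lower = TRUE)
  assert_scalar_number(wing_angular_extent, "wing_angular_extent",
                       lower = 0, upper = 180,
                       open_lower = TRUE, open_upper = TRUE)
  assert_scalar_number(body_wing_angle, "body_wing_angle",
                       lower = 0, upper = 180,
                       open_lower = TRUE, open_upper = TRUE)
  assert_scalar_number(serration_count, "serration_count", lower = 0)
  if (serration_count != round(serration_count)) {
    abort("`serration_count` must be a whole number.")
  }
  assert_scalar_number(serration_amplitude, "serration_amplitude", lower = 0)
  assert_scalar_number(vertices_per_unit, "vertices_per_unit",
                       lower = 0, open_lower = TRUE)
  structure(
    list(
      body_length = body_length,
      body_width = body_width,
      wing_radius = wing_radius,
      wing_angular_extent = wing_angular_extent,
      body_wing_angle = body_wing_angle,
      serration_count = as.integer(round(serration_count)),
      serration_amplitude = serration_amplitude,
      vertices_per_unit = vertices_per_unit,
      seed = as.integer(seed)
    ),
    class = "lip_shape_params"
  )
}

wrap180 <- function(d) ((d + 180) %% 360) - 180

# Radial distance from the origin to the lower-half ellipse modelling the
# body lobe (semi-axes body_width/2 and body_length/2, centred below the
# origin so the origin sits on its rim). Zero outside the lower half-plane.
body_radius <- function(theta_deg, body_length, body_width) {
  th <- theta_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  a <- body_width / 2; b <- body_length / 2
  r <- numeric(length(th))
  lower <- uy < 0
  denom <- ux[lower]^2 / a^2 + uy[lower]^2 / b^2
  r[lower] <- (-body_length * uy[lower] / b^2) / denom
  r
}

wing_radius_fun <- function(theta_deg, center_deg, extent, radius,
                            teeth = 0L, amplitude = 0) {
  dd <- wrap180(theta_deg - center_deg)
  r <- numeric(length(theta_deg))
  inside <- abs(dd) <= extent / 2
  if (teeth > 0L && amplitude > 0) {
    frac <- (dd[inside] + extent / 2) / extent
    r[inside] <- radius + amplitude * sin(2 * pi * teeth * frac)
  } else {
    r[inside] <- radius
  }
  r
}

#' Generate a synthetic egret-lip contour with known ground truth
#'
#' Builds a closed, simple, counterclockwise lip outline as a star-shaped
#' polygon around the lip base: a drop-shaped body lobe pointing "down" along
#' the body axis and two wing fans at `body_wing_angle` on either side of it.
#' Serrations on the left wing's distal margin are realized as a sinusoidal
#' radial modulation `r = R + a * sin(k * theta')` over the wing arc, so
#' exactly `k` teeth of radial prominence `a` exist. Landmarks (body
#' base/tip, body-width segment, wing base/tip) and the serrated-margin
#' vertex range are returned alongside the polygons.
#'
#' Parameter combinations whose lobes would overlap (wings touching each
#' other or engulfing the body axis, teeth deeper than the wing radius) are
#' rejected with an error rather than silently producing a degenerate
#' outline.
#'
#' @param params A [lip_shape_params()] object.
#' @param jitter_sd Standard deviation (mm) of optional Gaussian vertex
#'   jitter applied to both contours (seeded by `params$seed`); keep well
#'   below the vertex spacing.
#' @return A `lip_annotation` list with elements `lip` and `left_wing`
#'   (vertex tibbles with `vertex_index`, `x_mm`, `y_mm`), `landmarks`
#'   (tibble `landmark`, `x_mm`, `y_mm`), `serrated_margin` (0-based
#'   half-open index range on the left-wing contour) and `params`.
#' @export
generate_lip_contour <- function(params, jitter_sd = 0) {
  stopifnot(inherits(params, "lip_shape_params"))
  L <- params$body_length
  W <- params$body_width
  R <- params$wing_radius
  E <- params$wing_angular_extent
  bwa <- params$body_wing_angle
  k <- params$serration_count
  amp <- params$serration_amplitude

  if (amp >= R / 2) {
    abort("Serration amplitude must be below half the wing radius; the margin would self-intersect.")
  }
  center_left <- 270 - bwa
  center_right <- 270 + bwa
  sep <- min(2 * bwa, 360 - 2 * bwa)
  if (sep <= E + 2) {
    abort("Wing fans overlap each other for this body_wing_angle / wing_angular_extent combination; contour rejected.")
  }
  if (bwa <= E / 2 + 2) {
    abort("Wing fan engulfs the body axis (body_wing_angle too small for this wing_angular_extent); contour rejected.")
  }

  r_sinus <- 0.05 * min(L, R)
  radial <- function(theta) {
    pmax(
      body_radius(theta, L, W),
      wing_radius_fun(theta, center_left, E, R, k, amp),
      wing_radius_fun(theta, center_right, E, R),
      r_sinus
    )
  }

  # the serrated arc must dominate every other lobe, or teeth are obscured
  probe <- seq(center_left - E / 2, center_left + E / 2, length.out = 181)
  others <- pmax(body_radius(probe, L, W),
                 wing_radius_fun(probe, center_right, E, R), r_sinus)
  if (any(others >= R - amp)) {
    abort("Body or opposite wing overlaps the serrated margin; contour rejected.")
  }

  approx_perim <- 2 * pi * max(L, R + amp)
  n_theta <- max(
    ceiling(params$vertices_per_unit * approx_perim),
    if (k > 0) ceiling(24 * k * 360 / E) else 0,
    256
  )
  thetas <- seq(0, 360, length.out = n_theta + 1L)[-(n_theta + 1L)]
  lip_xy <- cbind(radial(thetas) * cos(thetas * pi / 180),
                  radial(thetas) * sin(thetas * pi / 180))

  arc_len <- (R + amp) * E * pi / 180
  m_arc <- max(ceiling(params$vertices_per_unit * arc_len),
               if (k > 0) 24 * k else 0, 48) + 1L
  arc_th <- seq(center_left - E / 2, center_left + E / 2, length.out = m_arc)
  arc_r <- wing_radius_fun(arc_th, center_left, E, R, k, amp)
  wing_xy <- rbind(
    c(0, 0),
    cbind(arc_r * cos(arc_th * pi / 180), arc_r * sin(arc_th * pi / 180))
  )

  u_wing <- c(cos(center_left * pi / 180), sin(center_left * pi / 180))
  landmarks <- tibble::tribble(
    ~landmark, ~x_mm, ~y_mm,
    "body_base", 0, 0,
    "body_tip", 0, -L,
    "body_width_1", -W / 2, -L / 2,
    "body_width_2", W / 2, -L / 2,
    "wing_base", 0, 0,
    "wing_tip", R * u_wing[1], R * u_wing[2]
  )

  if (jitter_sd > 0) {
    with_seed(derive_seed(params$seed, "lip_jitter"), {
      lip_xy <- lip_xy + rnorm(length(lip_xy), sd = jitter_sd)
      wing_xy <- wing_xy + rnorm(length(wing_xy), sd = jitter_sd)
      landmarks$x_mm <- landmarks$x_mm + rnorm(nrow(landmarks), sd = jitter_sd)
      landmarks$y_mm <- landmarks$y_mm + rnorm(nrow(landmarks), sd = jitter_sd)
    })
  }

  lip_xy <- ensure_ccw(lip_xy)
  structure(
    list(
      lip = xy_tibble(lip_xy),
      left_wing = xy_tibble(wing_xy),
      landmarks = landmarks,
      serrated_margin = c(1L, nrow(wing_xy)),
      params = params,
      truth = list(
        serration_count = if (amp > 0) k else 0L,
        body_length = L, body_width = W,
        wing_length = R, body_wing_angle = bwa
      )
    ),
    class = "lip_annotation"
  )
}

#' @export
print.lip_annotation <- function(x, ...) {
  cat(sprintf(
    "<lip_annotation> %d lip vertices, %d left-wing vertices, %d landmarks\n",
    nrow(x$lip), nrow(x$left_wing), nrow(x$landmarks)
  ))
  invisible(x)
}

#' Extract the serrated-margin vertices of an annotated lip
#'
#' @param annotation A `lip_annotation`.
#' @return Tibble of margin vertices (subset of the left-wing contour, in
#'   order), per the annotation's 0-based half-open `serrated_margin` range.
#' @export
serrated_margin <- function(annotation) {
  stopifnot(inherits(annotation, "lip_annotation"))
  rng <- annotation$serrated_margin
  if (rng[1] < 0 || rng[2] > nrow(annotation$left_wing) || rng[1] >= rng[2]) {
    abort("Invalid serrated_margin range for this left-wing contour.")
  }
  annotation$left_wing[(rng[1] + 1L):rng[2], ]
}

#' @describeIn generate_lip_contour Long-format vertex table for one or more
#'   annotations (columns `shape_id`, `role`, `vertex_index`, `x_mm`,
#'   `y_mm`), ready for CSV export.
#' @param annotations A named list of `lip_annotation` objects (names become
#'   `shape_id`).
#' @export
contour_table <- function(annotations) {
  if (inherits(annotations, "lip_annotation")) {
    annotations <- list(shape_1 = annotations)
  }
  if (is.null(names(annotations)) || any(names(annotations) == "")) {
    names(annotations) <- paste0("shape_", seq_along(annotations))
  }
  purrr::imap_dfr(annotations, function(ann, id) {
    dplyr::bind_rows(
      dplyr::mutate(ann$lip, shape_id = id, role = "lip", .before = 1),
      dplyr::mutate(ann$left_wing, shape_id = id, role = "left_wing",
                    .before = 1)
    )
  })
}

#' @describeIn generate_lip_contour Long-format landmark table (columns
#'   `shape_id`, `landmark`, `x_mm`, `y_mm`, `vertex_index`); the
#'   serrated-margin range travels as two index-only rows
#'   (`serration_margin_start`, `serration_margin_end`).
#' @export
landmark_table <- function(annotations) {
  if (inherits(annotations, "lip_annotation")) {
    annotations <- list(shape_1 = annotations)
  }
  if (is.null(names(annotations)) || any(names(annotations) == "")) {
    names(annotations) <- paste0("shape_", seq_along(annotations))
  }
  purrr::imap_dfr(annotations, function(ann, id) {
    dplyr::bind_rows(
      dplyr::mutate(ann$landmarks, shape_id = id,
                    vertex_index = NA_integer_, .before = 1),
      tibble::tibble(
        shape_id = id,
        landmark = c("serration_margin_start", "serration_margin_end"),
        x_mm = NA_real_, y_mm = NA_real_,
        vertex_index = as.integer(ann$serrated_margin)
      )
    )
  })
}
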