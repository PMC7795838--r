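# Contour handling: closed simple polygons in real-valued millimetre
# coordinates, stored counterclockwise with the closing edge implicit.

# Accepts a two-column matrix, or a data frame with x_mm/y_mm (or x/y)
# columns, and returns an n x 2 numeric matrix.
as_xy <- function(contour, name = "contour") {
  if (is.matrix(contour) && ncol(contour) == 2L) {
    xy <- contour
  } else if (is.data.frame(contour)) {
    xcol <- intersect(c("x_mm", "x"), names(contour))[1]
    ycol <- intersect(c("y_mm", "y"), names(contour))[1]
    if (is.na(xcol) || is.na(ycol)) {
      abort(sprintf("`%s` needs x_mm/y_mm (or x/y) columns.", name))
    }
    xy <- cbind(contour[[xcol]], contour[[ycol]])
  } else {
    abort(sprintf("`%s` must be a two-column matrix or a data frame.", name))
  }
  storage.mode(xy) <- "double"
  if (anyNA(xy)) abort(sprintf("`%s` contains missing coordinates.", name))
  unname(xy)
}

xy_tibble <- function(xy) {
  tibble::tibble(
    vertex_index = seq_len(nrow(xy)) - 1L,
    x_mm = xy[, 1],
    y_mm = xy[, 2]
  )
}

# Twice the signed area (positive when counterclockwise).
signed_area2 <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y)
}

ensure_ccw <- function(xy) {
  if (signed_area2(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

# Simplicity test for a closed polygon: no two non-adjacent edges intersect.
# Sweep over edges sorted by their minimum x to keep the candidate set small.
is_simple_polygon <- function(xy, eps = 1e-12) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  i2 <- c(seq_len(n)[-1], 1L)
  ax <- xy[, 1]; ay <- xy[, 2]
  bx <- ax[i2]; by <- ay[i2]
  if (any(abs(ax - bx) < eps & abs(ay - by) < eps)) return(FALSE) # zero edge
  xmin <- pmin(ax, bx); xmax <- pmax(ax, bx)
  ymin <- pmin(ay, by); ymax <- pmax(ay, by)
  ord <- order(xmin)
  cross <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  for (ii in seq_len(n - 1L)) {
    i <- ord[ii]
    jj <- ii + 1L
    while (jj <= n && xmin[ord[jj]] <= xmax[i] + eps) {
      j <- ord[jj]
      jj <- jj + 1L
      # skip adjacent edges (they share one endpoint by construction)
      if (i == j) next
      d <- abs(i - j)
      if (d == 1L || d == n - 1L) next
      if (ymin[i] > ymax[j] + eps || ymin[j] > ymax[i] + eps) next
      d1 <- cross(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])
      d2 <- cross(ax[i], ay[i], bx[i], by[i], bx[j], by[j])
      d3 <- cross(ax[j], ay[j], bx[j], by[j], ax[i], ay[i])
      d4 <- cross(ax[j], ay[j], bx[j], by[j], bx[i], by[i])
      if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
          ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

assert_closed_simple <- function(xy, check_simple = TRUE, name = "contour") {
  if (nrow(xy) < 3L) {
    abort(sprintf("A closed `%s` needs at least 3 vertices.", name))
  }
  if (check_simple && !is_simple_polygon(xy)) {
    abort(sprintf("`%s` is self-intersecting (or has a zero-length edge).",
                  name))
  }
  invisible(xy)
}
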