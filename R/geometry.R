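# Planar geometry primitives shared by the phantom generator, the landmark
# detectors and the measurement layer. All coordinates are (row, col) with row
# increasing downward (superior -> inferior on an upright radiograph),
# 0-based, matching the raster convention used throughout the package.

#' Create a 2-D point
#'
#' @param row,col Coordinates in pixels (full-image frame, 0-based).
#' @return A named numeric vector `c(row, col)`.
#' @export
pt <- function(row, col) {
  stopifnot(is.finite(row), is.finite(col))
  c(row = as.numeric(row), col = as.numeric(col))
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

#' Create an axis line
#'
#' An axis line is an anchored, oriented line: mechanical and anatomical bone
#' axes and joint orientation lines are all represented this way.
#'
#' @param anchor A point `c(row, col)` on the line.
#' @param direction A 2-vector `c(dr, dc)`; normalised internally.
#' @return An object of class `axis_line` with unit `direction`.
#' @export
axis_line <- function(anchor, direction) {
  structure(
    list(anchor = c(row = as.numeric(anchor[[1]]), col = as.numeric(anchor[[2]])),
         direction = unit_vec(as.numeric(direction))),
    class = "axis_line"
  )
}

#' @export
print.axis_line <- function(x, ...) {
  cat(sprintf("<axis_line> anchor (%.2f, %.2f), direction (%.4f, %.4f)\n",
              x$anchor[1], x$anchor[2], x$direction[1], x$direction[2]))
  invisible(x)
}

#' Angle between two axis lines or rays
#'
#' `kind = "acute"` returns the acute angle between the two (undirected)
#' lines, `arccos(|a . b|)`, in `[0, 90]` degrees. `kind = "as_defined"`
#' treats both directions as rays and returns `arccos(a . b)` in `[0, 180]`
#' degrees; clinical joint angles are computed this way from the named-side
#' ray of a joint line and the ray of the axis pointing into the bone.
#'
#' @param a,b `axis_line` objects or plain 2-vectors.
#' @param kind `"acute"` or `"as_defined"`.
#' @return Angle in degrees.
#' @export
angle_between <- function(a, b, kind = c("acute", "as_defined")) {
  kind <- match.arg(kind)
  da <- if (inherits(a, "axis_line")) a$direction else unit_vec(as.numeric(a))
  db <- if (inherits(b, "axis_line")) b$direction else unit_vec(as.numeric(b))
  d <- sum(da * db)
  if (kind == "acute") d <- abs(d)
  d <- min(1, max(-1, d))
  acos(d) * 180 / pi
}

#' Perpendicular distance from a point to an axis line
#'
#' @param p Point `c(row, col)`.
#' @param line An `axis_line`.
#' @return Unsigned distance in the coordinate units of the inputs.
#' @export
point_line_distance <- function(p, line) {
  w <- as.numeric(p) - line$anchor
  unname(abs(w[1] * line$direction[2] - w[2] * line$direction[1]))
}

# Signed version: positive when p lies on the side of the line that a
# +90 degree rotation of the direction points to.
point_line_signed <- function(p, line) {
  w <- as.numeric(p) - line$anchor
  unname(w[1] * line$direction[2] - w[2] * line$direction[1])
}

# Rotate a (row, col) vector by `deg` degrees. The sense is fixed by the
# matrix below and is only ever used with a side-aware sign.
rot2 <- function(v, deg) {
  th <- deg * pi / 180
  c(v[1] * cos(th) - v[2] * sin(th),
    v[1] * sin(th) + v[2] * cos(th))
}

#' Algebraic least-squares circle fit (Kasa method)
#'
#' Fits a circle to 2-D points by minimising
#' `sum((x^2 + y^2 + D x + E y + F)^2)`, a linear least-squares problem that
#' is exact on noise-free circles and is the standard workhorse for locating
#' the femoral head centre from boundary pixels.
#'
#' @param points A numeric matrix with columns `row`, `col` (or a list of
#'   points as returned by [pt()]).
#' @return A list with `center` (named `c(row, col)`) and `radius`.
#' @export
fit_circle <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, points)
  }
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("circle fit needs at least 3 points", call. = FALSE)
  x <- points[, 1]
  y <- points[, 2]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  fit <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(fit) || qr(A)$rank < 3) {
    stop("degenerate circle fit: points are collinear", call. = FALSE)
  }
  D <- fit[1]; E <- fit[2]; FF <- fit[3]
  cx <- -D / 2
  cy <- -E / 2
  r2 <- cx^2 + cy^2 - FF
  if (r2 <= 0) stop("degenerate circle fit: non-positive radius", call. = FALSE)
  list(center = c(row = unname(cx), col = unname(cy)), radius = unname(sqrt(r2)))
}

#' Total-least-squares line fit
#'
#' Fits a line minimising orthogonal distances (first principal component of
#' the centred points). Used for mid-diaphyseal shaft axes.
#'
#' @param points Numeric matrix with columns `row`, `col`.
#' @return An [axis_line()] through the centroid; `direction` follows the
#'   dominant eigenvector, oriented with non-negative row component
#'   (proximal -> distal for an upright leg).
#' @export
fit_line_tls <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("line fit needs at least 2 points", call. = FALSE)
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X, nu = 0, nv = 2)
  dir <- sv$v[, 1]
  if (dir[1] < 0) dir <- -dir
  axis_line(ctr, dir)
}

# Quadratic sub-pixel refinement of a profile extremum. `values[idx]` must be
# the discrete extremum; a parabola is fitted over a +/- `window` sample
# neighbourhood and its vertex returned as (position, value) in the
# coordinates of `positions`. Falls back to the discrete extremum when the
# fit is degenerate (flat or wrong-curvature profile).
refine_extremum <- function(positions, values, idx, window, maximum = TRUE) {
  lo <- max(1, idx - window)
  hi <- min(length(values), idx + window)
  xs <- positions[lo:hi]
  ys <- values[lo:hi]
  keep <- is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 5) {
    return(c(pos = positions[idx], val = values[idx]))
  }
  co <- stats::lm.fit(cbind(1, xs, xs^2), ys)$coefficients
  a <- co[[3]]
  ok <- is.finite(a) && ((maximum && a < -1e-9) || (!maximum && a > 1e-9))
  if (!ok) return(c(pos = positions[idx], val = values[idx]))
  xv <- -co[[2]] / (2 * a)
  if (xv < min(xs) || xv > max(xs)) {
    return(c(pos = positions[idx], val = values[idx]))
  }
  c(pos = unname(xv), val = unname(co[[1]] + co[[2]] * xv + a * xv^2))
}
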