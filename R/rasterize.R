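# Rasterisation of the phantom's piecewise-analytic bone shapes. A mask is a
# logical/0-1 integer matrix whose pixel (i, j) has centre (i-1, j-1) in
# 0-based (row, col) coordinates; a pixel is foreground when its centre lies
# inside the union of the shape primitives (even-odd rule for polygons).

prim_polygon <- function(rows, cols) {
  stopifnot(length(rows) == length(cols), length(rows) >= 3)
  list(type = "polygon", rows = as.numeric(rows), cols = as.numeric(cols))
}

prim_disc <- function(center, radius) {
  stopifnot(radius > 0)
  list(type = "disc", center = as.numeric(center), radius = as.numeric(radius))
}

# Nonzero-winding scanline fill of one polygon into an nr x nc logical
# matrix. The winding rule (rather than even-odd) keeps locally
# self-intersecting boundary polygons - as produced by boundary jitter -
# solid instead of punching spurious interior holes.
fill_polygon <- function(rows, cols, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  n <- length(rows)
  r1 <- rows; c1 <- cols
  r2 <- rows[c(2:n, 1)]; c2 <- cols[c(2:n, 1)]
  rmin <- max(0L, floor(min(rows)))
  rmax <- min(nr - 1L, ceiling(max(rows)))
  if (rmax < rmin) return(m)
  for (r in rmin:rmax) {
    # half-open edge rule: an edge covers scanline r when min <= r < max
    down <- r1 <= r & r < r2
    up <- r2 <= r & r < r1
    hit <- down | up
    if (!any(hit)) next
    t <- (r - r1[hit]) / (r2[hit] - r1[hit])
    xs <- c1[hit] + t * (c2[hit] - c1[hit])
    dirs <- ifelse(down[hit], 1L, -1L)
    ord <- order(xs)
    xs <- xs[ord]; dirs <- dirs[ord]
    wind <- cumsum(dirs)
    inside <- which(wind != 0)
    for (i in inside) {
      if (i == length(xs)) next
      a <- max(ceiling(xs[i]), 0L)
      b <- min(floor(xs[i + 1]), nc - 1L)
      if (a <= b) m[r + 1L, (a + 1L):(b + 1L)] <- TRUE
    }
  }
  m
}

fill_disc <- function(center, radius, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  r0 <- center[1]; c0 <- center[2]
  rmin <- max(0L, ceiling(r0 - radius))
  rmax <- min(nr - 1L, floor(r0 + radius))
  if (rmax < rmin) return(m)
  for (r in rmin:rmax) {
    half <- sqrt(max(0, radius^2 - (r - r0)^2))
    a <- max(ceiling(c0 - half), 0L)
    b <- min(floor(c0 + half), nc - 1L)
    if (a <= b) m[r + 1L, (a + 1L):(b + 1L)] <- TRUE
  }
  m
}

# Rasterise a list of primitives into one binary mask (union).
rasterize_primitives <- function(prims, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  for (p in prims) {
    m <- m | switch(p$type,
      polygon = fill_polygon(p$rows, p$cols, nr, nc),
      disc = fill_disc(p$center, p$radius, nr, nc),
      stop("unknown primitive type: ", p$type)
    )
  }
  m
}

# Resample a primitive to a closed polygon with roughly `step` px between
# vertices, so boundary jitter can displace vertices before re-rasterising.
prim_as_polygon <- function(p, step = 2.5) {
  if (p$type == "disc") {
    n <- max(16L, ceiling(2 * pi * p$radius / step))
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    return(prim_polygon(p$center[1] + p$radius * sin(th),
                        p$center[2] + p$radius * cos(th)))
  }
  n <- length(p$rows)
  rows <- c(); cols <- c()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    seg <- c(p$rows[j] - p$rows[i], p$cols[j] - p$cols[i])
    len <- sqrt(sum(seg^2))
    k <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    rows <- c(rows, p$rows[i] + t * seg[1])
    cols <- c(cols, p$cols[i] + t * seg[2])
  }
  prim_polygon(rows, cols)
}

# Boundary pixels of a mask: foreground with at least one 4-neighbour outside
# the foreground (image border counts as background). Returns a matrix of
# 0-based (row, col) pixel-centre coordinates.
mask_boundary <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  up <- rbind(FALSE, mask[-nr, , drop = FALSE])
  dn <- rbind(mask[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, mask[, -nc, drop = FALSE])
  rt <- cbind(mask[, -1, drop = FALSE], FALSE)
  b <- mask & !(up & dn & lf & rt)
  idx <- which(b, arr.ind = TRUE)
  cbind(row = idx[, 1] - 1, col = idx[, 2] - 1)
}

# Pixel-centre coordinates (0-based) of all foreground pixels.
mask_points <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  cbind(row = idx[, 1] - 1, col = idx[, 2] - 1)
}

# Tight 0-based half-open bounding box [row_min, col_min, row_max, col_max].
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask has no bounding box", call. = FALSE)
  c(row_min = min(idx[, 1]) - 1L, col_min = min(idx[, 2]) - 1L,
    row_max = max(idx[, 1]), col_max = max(idx[, 2]))
}
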