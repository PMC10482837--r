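# Landmark detection from per-class binary masks: femoral head circle fit,
# mid-diaphyseal shaft axes, and joint orientation lines, assembled into a
# full-frame landmark set. Detectors work in mask-local 0-based (row, col)
# coordinates; `assemble_landmarks()` applies the ROI offsets.
#
# Side conventions: medial/lateral labels derive from the `side` flag only.
# For a left limb the lateral structure has the smaller column; extremal-tie
# breaks go toward smaller columns on the left and larger on the right.

as_mask <- function(x) {
  if (is.list(x) && !is.null(x$pixels)) x <- x$pixels
  m <- as.matrix(x) != 0
  storage.mode(m) <- "logical"
  m
}

lateral_col_sign <- function(side) if (side == "left") -1 else 1
medial_col_sign <- function(side) -lateral_col_sign(side)

# Euclidean distance transform of the foreground (px), via EBImage.
mask_distmap <- function(mask) {
  img <- EBImage::Image(t(mask * 1))
  t(EBImage::imageData(EBImage::distmap(img)))
}

#' Fit the mid-diaphyseal axis of a shaft mask
#'
#' For each occupied row in the central portion of the mask's vertical
#' extent, the midpoint of the foreground run is computed; a total-least-
#' squares line through the midpoints is the anatomical axis.
#'
#' @param shaft_mask Binary matrix (nonzero = bone).
#' @param central_fraction Fraction of the vertical extent used (centred);
#'   excludes metaphyseal flare at both ends.
#' @return An [axis_line()] in mask-local coordinates, oriented
#'   proximal -> distal (increasing row).
#' @export
shaft_axis <- function(shaft_mask, central_fraction = 0.6) {
  mask <- as_mask(shaft_mask)
  pts <- mask_points(mask)
  if (!nrow(pts)) stop("shaft mask is empty", call. = FALSE)
  rows <- sort(unique(pts[, "row"]))
  if (length(rows) < 20) {
    stop("shaft mask has fewer than 20 foreground rows", call. = FALSE)
  }
  if (diff(range(rows)) <= diff(range(pts[, "col"]))) {
    stop("shaft mask is not taller than wide", call. = FALSE)
  }
  r0 <- min(rows); r1 <- max(rows)
  lo <- r0 + (1 - central_fraction) / 2 * (r1 - r0)
  hi <- r1 - (1 - central_fraction) / 2 * (r1 - r0)
  sel_rows <- rows[rows >= lo & rows <= hi]
  mids <- matrix(NA_real_, length(sel_rows), 2)
  n_multi <- 0L
  for (i in seq_along(sel_rows)) {
    cols <- sort(pts[pts[, "row"] == sel_rows[i], "col"])
    gaps <- which(diff(cols) > 1)
    if (length(gaps)) {
      n_multi <- n_multi + 1L
      # use the longest run
      bounds <- c(0, gaps, length(cols))
      lens <- diff(bounds)
      k <- which.max(lens)
      cols <- cols[(bounds[k] + 1):bounds[k + 1]]
    }
    mids[i, ] <- c(sel_rows[i], (min(cols) + max(cols)) / 2)
  }
  if (n_multi > 0.2 * length(sel_rows)) {
    stop("fragmented shaft mask: multiple foreground runs in more than 20% of rows",
         call. = FALSE)
  }
  fit_line_tls(mids)
}

#' Proximal femur landmarks from the femoral head mask
#'
#' Locates the femoral head centre and radius by an algebraic circle fit to
#' the superior-medial boundary arc (the infero-lateral half is excluded to
#' keep the neck junction out of the fit), the head apex, the femoral neck
#' axis through the narrowest neck cross-section, and the greater trochanter
#' tip (most superior mask point lateral of the neck axis and clear of the
#' fitted head disc).
#'
#' @param head_mask Binary matrix containing head, neck and trochanter.
#' @param side `"left"` or `"right"`.
#' @return A list: `head_center`, `head_radius`, `head_apex`,
#'   `trochanter_tip`, `neck_axis`, `trochanter_found`. When the mask is a
#'   bare head disc with no neck/trochanter, `trochanter_found` is `FALSE`
#'   and the corresponding fields are `NA`/`NULL` (with a warning).
#' @export
head_landmarks <- function(head_mask, side = c("left", "right")) {
  side <- match.arg(side)
  mask <- as_mask(head_mask)
  pts <- mask_points(mask)
  if (!nrow(pts)) stop("head mask is empty", call. = FALSE)

  dm <- mask_distmap(mask)
  idx <- which.max(dm)
  ctr <- c(row = (idx - 1) %% nrow(dm), col = (idx - 1) %/% nrow(dm))
  r_est <- max(dm)
  if (r_est < 3) stop("no circular component found in head mask", call. = FALSE)

  bnd <- mask_boundary(mask)
  v <- unit_vec(c(-1, medial_col_sign(side)))
  for (it in 1:3) {
    w <- sweep(bnd, 2, c(ctr["row"], ctr["col"]))
    d <- sqrt(rowSums(w^2))
    keep <- d > 0.8 * r_est & d < 1.2 * r_est & (w %*% v) > 0
    if (sum(keep) < 8) break
    fit <- fit_circle(bnd[keep, , drop = FALSE])
    ctr <- fit$center
    r_est <- fit$radius
  }
  head_center <- ctr
  head_radius <- r_est

  # head apex: most superior mask point within the fitted disc, sub-pixel
  # refined on the per-column top profile of the disc cap
  w <- sweep(pts, 2, c(ctr["row"], ctr["col"]))
  in_disc <- sqrt(rowSums(w^2)) <= head_radius + 0.75
  cap <- pts[in_disc, , drop = FALSE]
  cols <- sort(unique(cap[, "col"]))
  top <- vapply(cols, function(cc) min(cap[cap[, "col"] == cc, "row"]), numeric(1))
  j <- which.min(top)
  ref <- refine_extremum(cols, top, j, window = max(4L, round(0.4 * head_radius)),
                         maximum = FALSE)
  head_apex <- pt(ref["val"], ref["pos"])

  # neck: pixels beyond the head disc
  out <- sqrt(rowSums(w^2)) > 1.05 * head_radius
  if (!any(out)) {
    warning("head mask contains no structure beyond the head disc: ",
            "neck and trochanter absent", call. = FALSE)
    return(list(head_center = head_center, head_radius = head_radius,
                head_apex = head_apex, trochanter_tip = c(row = NA_real_, col = NA_real_),
                neck_axis = NULL, trochanter_found = FALSE))
  }
  ring <- sqrt(rowSums(w^2)) > 1.05 * head_radius &
    sqrt(rowSums(w^2)) < 1.6 * head_radius
  if (!any(ring)) ring <- out
  u0 <- unit_vec(colMeans(pts[ring, , drop = FALSE]) -
                   c(ctr["row"], ctr["col"]))
  n0 <- c(-u0[2], u0[1])
  wo <- sweep(pts[out, , drop = FALSE], 2, c(ctr["row"], ctr["col"]))
  t_par <- as.numeric(wo %*% u0)
  t_perp <- as.numeric(wo %*% n0)
  sel <- t_par > head_radius + 2 & t_par < 2.1 * head_radius
  if (sum(sel) > 20) {
    bins <- floor((t_par[sel] - min(t_par[sel])) / 3)
    stats_by <- vapply(sort(unique(bins)), function(b) {
      pp <- t_perp[sel][bins == b]
      tt <- t_par[sel][bins == b]
      c(lo = min(pp), hi = max(pp), mid = (min(pp) + max(pp)) / 2,
        t = mean(tt), n = length(pp))
    }, numeric(5))
    stats_by <- stats_by[, stats_by["n", ] >= 3, drop = FALSE]
    stats_by <- stats_by[, order(stats_by["t", ]), drop = FALSE]
    # the sections nearest the head are bare neck (anything joining the
    # neck - trochanter, calcar - attaches further out); walk distally
    # while the section width stays neck-like and pick the narrowest
    width <- stats_by["hi", ] - stats_by["lo", ]
    w0 <- stats::median(width[seq_len(min(3, length(width)))])
    last <- which(width > w0 + 4)
    last <- if (length(last)) min(last) - 1L else length(width)
    keep <- seq_len(max(1L, last))
    stats_by <- stats_by[, keep, drop = FALSE]
    use <- which.min(width[keep])
    isthmus <- c(
      ctr["row"] + stats_by["t", use] * u0[1] + stats_by["mid", use] * n0[1],
      ctr["col"] + stats_by["t", use] * u0[2] + stats_by["mid", use] * n0[2])
    neck_dir <- unit_vec(isthmus - c(ctr["row"], ctr["col"]))
  } else {
    neck_dir <- u0
  }
  neck_axis <- axis_line(head_center, neck_dir)

  # trochanter tip: most superior point lateral of the neck axis, outside
  # 1.1x the fitted head disc; ties toward the lateral column
  probe <- c(head_center[1], head_center[2] + lateral_col_sign(side))
  s_lat <- sign(point_line_signed(probe, neck_axis))
  dall <- sqrt(rowSums(w^2))
  wa <- sweep(pts, 2, neck_axis$anchor)
  sgn <- wa[, 1] * neck_axis$direction[2] - wa[, 2] * neck_axis$direction[1]
  cand <- dall > 1.1 * head_radius & sign(sgn) == s_lat
  if (!any(cand)) {
    warning("no trochanter found lateral of the neck axis", call. = FALSE)
    return(list(head_center = head_center, head_radius = head_radius,
                head_apex = head_apex, trochanter_tip = c(row = NA_real_, col = NA_real_),
                neck_axis = neck_axis, trochanter_found = FALSE))
  }
  cp <- pts[cand, , drop = FALSE]
  ccols <- sort(unique(cp[, "col"]))
  ctop <- vapply(ccols, function(cc) min(cp[cp[, "col"] == cc, "row"]), numeric(1))
  j <- which.min(ctop)
  if (sum(ctop == ctop[j]) > 1) {
    tie <- which(ctop == ctop[j])
    j <- if (side == "left") min(tie) else max(tie)
  }
  reft <- refine_extremum(ccols, ctop, j, window = 9L, maximum = FALSE)
  trochanter_tip <- pt(reft["val"], reft["pos"])

  list(head_center = head_center, head_radius = head_radius,
       head_apex = head_apex, trochanter_tip = trochanter_tip,
       neck_axis = neck_axis, trochanter_found = TRUE)
}

# Split a knee mask into femoral (above) and tibial (below) parts at the
# joint space: the row with the least foreground in the central band.
knee_split_row <- function(mask) {
  prof <- rowSums(mask)
  occ <- which(prof > 0)
  r0 <- min(occ); r1 <- max(occ)
  band <- seq(r0 + round(0.2 * (r1 - r0)), r0 + round(0.8 * (r1 - r0)))
  cut <- band[which.min(prof[band])]
  if (prof[cut] > 0.5 * max(prof)) {
    stop("knee mask has no discernible joint space", call. = FALSE)
  }
  cut
}

#' Detect a joint orientation line
#'
#' Finds the two articular extremal points of a joint surface: the two most
#' distal condylar points of the distal femur (one per lobe, split at the
#' intercondylar notch), the two most proximal plateau points of the
#' proximal tibia, or the two plafond corners of the distal tibia. Extrema
#' are refined to sub-pixel positions with a local parabola fit.
#'
#' @param joint_mask Binary matrix. For the knee it may contain both the
#'   femoral and tibial articular components; they are separated at the
#'   joint space.
#' @param bone `"femur_distal"`, `"tibia_proximal"` or `"tibia_distal"`.
#' @param side `"left"` or `"right"`.
#' @return A list: `medial`, `lateral` (points), `line` (an [axis_line()]
#'   through them), `center` (segment midpoint), all mask-local.
#' @export
joint_line <- function(joint_mask,
                       bone = c("femur_distal", "tibia_proximal", "tibia_distal"),
                       side = c("left", "right")) {
  bone <- match.arg(bone)
  side <- match.arg(side)
  mask <- as_mask(joint_mask)
  if (!any(mask)) stop("joint mask is empty", call. = FALSE)

  if (bone %in% c("femur_distal", "tibia_proximal")) {
    cut <- knee_split_row(mask)
    keep_rows <- if (bone == "femur_distal") 1:cut else (cut + 1):nrow(mask)
    sub <- matrix(FALSE, nrow(mask), ncol(mask))
    sub[keep_rows, ] <- mask[keep_rows, , drop = FALSE]
    mask <- sub
    if (!any(mask)) stop("no ", bone, " component above/below the joint space",
                         call. = FALSE)
  }
  pts <- mask_points(mask)
  maximum <- bone != "tibia_proximal"  # distal surfaces look for max row
  cols <- sort(unique(pts[, "col"]))
  prof <- vapply(cols, function(cc) {
    rr <- pts[pts[, "col"] == cc, "row"]
    if (maximum) max(rr) else min(rr)
  }, numeric(1))
  sprof <- if (maximum) prof else -prof

  j1 <- which.max(sprof)
  if (sum(sprof == sprof[j1]) > 1) {
    tie <- which(sprof == sprof[j1])
    j1 <- if (side == "left") min(tie) else max(tie)
  }
  excl <- abs(cols - cols[j1]) <= 0.3 * diff(range(cols))
  if (all(excl)) {
    stop("single-lobed ", bone, " contour: cannot find two articular extrema",
         call. = FALSE)
  }
  s2 <- sprof; s2[excl] <- -Inf
  j2 <- which.max(s2)
  ja <- min(j1, j2); jb <- max(j1, j2)
  notch <- min(sprof[ja:jb])
  if (notch > min(sprof[ja], sprof[jb]) - 2) {
    stop("single-lobed ", bone, " contour: no notch between candidate extrema",
         call. = FALSE)
  }

  win <- max(4L, round(0.08 * (cols[jb] - cols[ja])))
  refine <- function(j) {
    rf <- refine_extremum(cols, prof, j, window = win, maximum = maximum)
    pt(rf["val"], rf["pos"])
  }
  p_a <- refine(ja)  # smaller col
  p_b <- refine(jb)  # larger col
  if (side == "left") {
    lateral <- p_a; medial <- p_b
  } else {
    lateral <- p_b; medial <- p_a
  }
  center <- (medial + lateral) / 2
  list(medial = medial, lateral = lateral,
       line = axis_line(medial, lateral - medial), center = pt(center[1], center[2]))
}

required_roi_classes <- c("femoral_head", "femoral_shaft", "tibial_shaft",
                          "knee", "ankle")

#' Assemble a landmark set from a mask set
#'
#' Runs the head, shaft and joint-line detectors on the per-class masks,
#' maps all results into the full-image frame via the ROI offsets, and
#' validates the landmark-set invariants. Right-side masks are mirrored to
#' left orientation first and the detected coordinates un-mirrored
#' afterwards, so one set of left-convention detectors serves both sides
#' and mirror symmetry of the pipeline is exact by construction.
#'
#' @param mask_set A `mask_set` (per-class masks + offsets + side), e.g.
#'   from [generate_phantom()] or [read_mask_set()].
#' @param shaft_fraction Central row fraction used by [shaft_axis()].
#' @return A `landmark_set` in full-image coordinates.
#' @export
assemble_landmarks <- function(mask_set, shaft_fraction = 0.6) {
  stopifnot(inherits(mask_set, "mask_set"))
  missing <- setdiff(required_roi_classes, names(mask_set$masks))
  if (length(missing)) {
    stop("mask set is missing ROI class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  true_side <- mask_set$side
  masks <- mask_set$masks
  widths <- lapply(masks, ncol)
  if (true_side == "right") {
    masks <- lapply(masks, function(m) m[, ncol(m):1, drop = FALSE])
  }
  side <- "left"
  off <- mask_set$offsets
  unmirror_pt <- function(p, cls) {
    if (true_side == "right" && !any(is.na(p))) {
      p[2] <- (widths[[cls]] - 1) - p[2]
    }
    p
  }
  unmirror_line <- function(l, cls) {
    if (true_side == "right") {
      axis_line(c(l$anchor[1], (widths[[cls]] - 1) - l$anchor[2]),
                c(l$direction[1], -l$direction[2]))
    } else l
  }
  shift_pt <- function(p, cls) {
    p <- unmirror_pt(p, cls)
    if (any(is.na(p))) return(p)
    pt(p[1] + off[[cls]]["row"], p[2] + off[[cls]]["col"])
  }
  shift_line <- function(l, cls) {
    l <- unmirror_line(l, cls)
    axis_line(l$anchor + c(off[[cls]]["row"], off[[cls]]["col"]), l$direction)
  }

  hd <- head_landmarks(masks$femoral_head, side)
  if (!hd$trochanter_found) {
    stop("cannot assemble landmarks: trochanter/neck absent from the femoral head mask",
         call. = FALSE)
  }
  fem_axis <- shaft_axis(masks$femoral_shaft, shaft_fraction)
  tib_axis <- shaft_axis(masks$tibial_shaft, shaft_fraction)
  knee_f <- joint_line(masks$knee, "femur_distal", side)
  knee_t <- joint_line(masks$knee, "tibia_proximal", side)
  ank <- joint_line(masks$ankle, "tibia_distal", side)

  new_landmark_set(
    head_center = shift_pt(hd$head_center, "femoral_head"),
    head_radius = hd$head_radius,
    head_apex = shift_pt(hd$head_apex, "femoral_head"),
    trochanter_tip = shift_pt(hd$trochanter_tip, "femoral_head"),
    neck_axis = shift_line(hd$neck_axis, "femoral_head"),
    femoral_anat_axis = shift_line(fem_axis, "femoral_shaft"),
    femoral_condyle_medial = shift_pt(knee_f$medial, "knee"),
    femoral_condyle_lateral = shift_pt(knee_f$lateral, "knee"),
    knee_center_femoral = shift_pt(knee_f$center, "knee"),
    plateau_medial = shift_pt(knee_t$medial, "knee"),
    plateau_lateral = shift_pt(knee_t$lateral, "knee"),
    knee_center_tibial = shift_pt(knee_t$center, "knee"),
    tibial_anat_axis = shift_line(tib_axis, "tibial_shaft"),
    plafond_medial = shift_pt(ank$medial, "ankle"),
    plafond_lateral = shift_pt(ank$lateral, "ankle"),
    ankle_center = shift_pt(ank$center, "ankle"),
    side = true_side
  )
}
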