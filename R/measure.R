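# Alignment measurement: axes from landmarks, the sixteen Paley-style
# parameters, and normal-range classification.
#
# Angle conventions. Every named joint angle is the angle between (a) the
# ray of the joint orientation line pointing to the named side
# (lateral/medial), and (b) the ray of the bone axis pointing into the bone
# as drawn on the radiograph (proximally for a bone proximal to the joint,
# distally for a bone distal to it). Because joint-line rays are derived
# from the medial/lateral landmark labels - which follow the `side` flag and
# never the image content - every report field is invariant under horizontal
# mirroring of the input.

#' Construct a landmark set
#'
#' Named 2-D points (full-image pixel frame, 0-based `(row, col)`) and
#' joint/axis lines for one limb. Use [assemble_landmarks()] to detect one
#' from a mask set.
#'
#' @param head_center,head_apex,trochanter_tip,femoral_condyle_medial,femoral_condyle_lateral,knee_center_femoral,plateau_medial,plateau_lateral,knee_center_tibial,plafond_medial,plafond_lateral,ankle_center Points `c(row, col)`.
#' @param head_radius Fitted femoral head radius, px.
#' @param neck_axis,femoral_anat_axis,tibial_anat_axis [axis_line()] objects;
#'   anatomical axes are oriented proximal to distal, the neck axis points
#'   from the head centre toward the shaft.
#' @param side `"left"` or `"right"`.
#' @return An object of class `landmark_set`.
#' @export
new_landmark_set <- function(head_center, head_radius, head_apex,
                             trochanter_tip, neck_axis, femoral_anat_axis,
                             femoral_condyle_medial, femoral_condyle_lateral,
                             knee_center_femoral, plateau_medial,
                             plateau_lateral, knee_center_tibial,
                             tibial_anat_axis, plafond_medial,
                             plafond_lateral, ankle_center, side) {
  lm <- structure(
    list(head_center = head_center, head_radius = head_radius,
         head_apex = head_apex, trochanter_tip = trochanter_tip,
         neck_axis = neck_axis, femoral_anat_axis = femoral_anat_axis,
         femoral_condyle_medial = femoral_condyle_medial,
         femoral_condyle_lateral = femoral_condyle_lateral,
         knee_center_femoral = knee_center_femoral,
         plateau_medial = plateau_medial, plateau_lateral = plateau_lateral,
         knee_center_tibial = knee_center_tibial,
         tibial_anat_axis = tibial_anat_axis,
         plafond_medial = plafond_medial, plafond_lateral = plafond_lateral,
         ankle_center = ankle_center,
         side = match.arg(side, c("left", "right"))),
    class = "landmark_set")
  validate_landmark_set(lm)
  lm
}

validate_landmark_set <- function(lm, tol = 1.5) {
  pts <- c("head_center", "head_apex", "trochanter_tip",
           "femoral_condyle_medial", "femoral_condyle_lateral",
           "knee_center_femoral", "plateau_medial", "plateau_lateral",
           "knee_center_tibial", "plafond_medial", "plafond_lateral",
           "ankle_center")
  for (nm in pts) {
    if (!all(is.finite(lm[[nm]]))) {
      stop("landmark `", nm, "` is not finite", call. = FALSE)
    }
  }
  for (nm in c("neck_axis", "femoral_anat_axis", "tibial_anat_axis")) {
    if (abs(vec_norm(lm[[nm]]$direction) - 1) > 1e-9) {
      stop("axis `", nm, "` direction is not unit length", call. = FALSE)
    }
  }
  lat_left_of_med <- function(lat, med) {
    if (lm$side == "left") lat["col"] < med["col"] else lat["col"] > med["col"]
  }
  pairs <- list(
    c("femoral_condyle_lateral", "femoral_condyle_medial"),
    c("plateau_lateral", "plateau_medial"),
    c("plafond_lateral", "plafond_medial"))
  for (pr in pairs) {
    a <- lm[[pr[1]]]; b <- lm[[pr[2]]]
    if (vec_norm(a - b) < 1e-6) {
      stop("landmarks `", pr[1], "` and `", pr[2], "` coincide", call. = FALSE)
    }
    if (!lat_left_of_med(a, b)) {
      stop("medial/lateral ordering of `", pr[1], "`/`", pr[2],
           "` violates the ", lm$side, "-side convention", call. = FALSE)
    }
  }
  on_segment <- function(p, a, b, nm) {
    line <- axis_line(a, b - a)
    if (point_line_distance(p, line) > tol) {
      stop("landmark `", nm, "` does not lie on its joint segment", call. = FALSE)
    }
  }
  on_segment(lm$knee_center_femoral, lm$femoral_condyle_lateral,
             lm$femoral_condyle_medial, "knee_center_femoral")
  on_segment(lm$knee_center_tibial, lm$plateau_lateral, lm$plateau_medial,
             "knee_center_tibial")
  on_segment(lm$ankle_center, lm$plafond_lateral, lm$plafond_medial,
             "ankle_center")
  invisible(lm)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %s limb\n", x$side))
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) == 2) {
      cat(sprintf("  %-24s (%8.2f, %8.2f)\n", nm, v[1], v[2]))
    }
  }
  invisible(x)
}

#' Build the mechanical and anatomical axis bundle
#'
#' @param lm A `landmark_set`.
#' @return A list of [axis_line()]s, all oriented proximal to distal:
#'   `femoral_mech` (head centre to femoral knee centre), `tibial_mech`
#'   (tibial knee centre to ankle centre), `hip_ankle` (head centre to ankle
#'   centre), and the anatomical `femoral_anat`, `tibial_anat`.
#' @export
build_axes <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  seg_axis <- function(a, b, nm) {
    if (vec_norm(b - a) < 1e-9) {
      stop("degenerate axis `", nm, "`: endpoints coincide", call. = FALSE)
    }
    axis_line(a, b - a)
  }
  list(
    femoral_mech = seg_axis(lm$head_center, lm$knee_center_femoral, "femoral_mech"),
    tibial_mech = seg_axis(lm$knee_center_tibial, lm$ankle_center, "tibial_mech"),
    hip_ankle = seg_axis(lm$head_center, lm$ankle_center, "hip_ankle"),
    femoral_anat = lm$femoral_anat_axis,
    tibial_anat = lm$tibial_anat_axis
  )
}

#' Normal ranges of the alignment parameters
#'
#' Closed normal intervals for the thirteen flagged parameters; the three
#' lengths carry no range. `aLDTA` uses the standard Paley range 86-92
#' degrees (identical to mLDTA, as the tibial anatomical and mechanical axes
#' are nearly coincident).
#'
#' @return A tibble with `parameter`, `units`, `lo`, `hi`.
#' @export
normal_ranges <- function() {
  tibble::tribble(
    ~parameter, ~units, ~lo, ~hi,
    "mLPFA", "deg", 85, 95,
    "mLDFA", "deg", 85, 90,
    "mMPTA", "deg", 85, 90,
    "mLDTA", "deg", 86, 92,
    "MAD",   "mm",   0,  3,
    "mJLCA", "deg",  0,  2,
    "mTFA",  "deg",  0,  3,
    "aMPFA", "deg", 80, 89,
    "aLDFA", "deg", 79, 83,
    "NSA",   "deg", 124, 136,
    "aMPTA", "deg", 85, 90,
    "aLDTA", "deg", 86, 92,
    "aTFA",  "deg",  0,  3,
    "full_leg_length", "mm", NA_real_, NA_real_,
    "femoral_length",  "mm", NA_real_, NA_real_,
    "tibial_length",   "mm", NA_real_, NA_real_
  )
}

#' Compute the sixteen alignment parameters
#'
#' Thirteen angles/deviations (mLPFA, mLDFA, mMPTA, mLDTA, MAD, mJLCA, mTFA,
#' aMPFA, aLDFA, NSA, aMPTA, aLDTA, aTFA) and three lengths, with
#' normal-range flags. Lengths are pixel distances multiplied by the pixel
#' spacing; MAD is the perpendicular distance from the tibial knee centre to
#' the hip-to-ankle line.
#'
#' @param lm A `landmark_set`.
#' @param spacing Pixel spacing in mm/px (> 0).
#' @param signed_mad If `TRUE`, MAD carries a sign: positive when the knee
#'   centre lies medial to the hip-ankle line, negative when lateral.
#' @return A one-row tibble of class `limb_report`.
#' @export
compute_report <- function(lm, spacing, signed_mad = FALSE) {
  stopifnot(inherits(lm, "landmark_set"))
  if (!is.finite(spacing) || spacing <= 0) {
    stop("pixel spacing must be > 0", call. = FALSE)
  }
  ax <- build_axes(lm)
  ray <- function(from, to) unit_vec(to - from)

  lat_cond <- ray(lm$femoral_condyle_medial, lm$femoral_condyle_lateral)
  med_plat <- ray(lm$plateau_lateral, lm$plateau_medial)
  lat_plaf <- ray(lm$plafond_medial, lm$plafond_lateral)
  lat_troch <- ray(lm$head_center, lm$trochanter_tip)
  med_troch <- -lat_troch

  d_fm <- ax$femoral_mech$direction   # proximal -> distal
  d_tm <- ax$tibial_mech$direction
  d_fa <- ax$femoral_anat$direction
  d_ta <- ax$tibial_anat$direction
  ang <- function(u, v) angle_between(u, v, kind = "as_defined")

  mLPFA <- ang(lat_troch, d_fm)
  mLDFA <- ang(lat_cond, -d_fm)
  mMPTA <- ang(med_plat, d_tm)
  mLDTA <- ang(lat_plaf, -d_tm)
  mJLCA <- angle_between(lat_cond, med_plat, kind = "acute")
  mTFA <- angle_between(d_fm, d_tm, kind = "acute")
  aMPFA <- ang(med_troch, d_fa)
  aLDFA <- ang(lat_cond, -d_fa)
  NSA <- ang(-lm$neck_axis$direction, d_fa)
  aMPTA <- ang(med_plat, d_ta)
  aLDTA <- ang(lat_plaf, -d_ta)
  aTFA <- angle_between(d_fa, d_ta, kind = "acute")

  mad_px <- point_line_distance(lm$knee_center_tibial, ax$hip_ankle)
  if (signed_mad) {
    s <- point_line_signed(lm$knee_center_tibial, ax$hip_ankle)
    # sign chosen so that a knee centre medial to the hip-ankle line gives a
    # positive MAD, lateral a negative one, irrespective of side
    medial_sign <- if (lm$side == "left") -1 else 1
    mad_px <- abs(mad_px) * sign(s) * medial_sign
    if (mad_px == 0) mad_px <- 0
  }

  dist_mm <- function(a, b) vec_norm(a - b) * spacing
  report <- tibble::tibble(
    mLPFA = mLPFA, mLDFA = mLDFA, mMPTA = mMPTA, mLDTA = mLDTA,
    MAD = mad_px * spacing,
    mJLCA = mJLCA, mTFA = mTFA,
    aMPFA = aMPFA, aLDFA = aLDFA, NSA = NSA, aMPTA = aMPTA, aLDTA = aLDTA,
    aTFA = aTFA,
    full_leg_length = dist_mm(lm$head_apex, lm$ankle_center),
    femoral_length = dist_mm(lm$head_apex, lm$knee_center_femoral),
    tibial_length = dist_mm(lm$knee_center_tibial, lm$ankle_center),
    side = lm$side, pixel_spacing = spacing
  )
  class(report) <- c("limb_report", class(report))
  attr(report, "normal_flags") <- classify_normality(report)
  report
}

#' Classify parameters against their normal ranges
#'
#' Boundaries are inclusive (closed intervals); lengths carry no flag.
#' Classification uses the absolute value for MAD when a signed MAD was
#' requested.
#'
#' @param report A `limb_report` (or any one-row data frame with the
#'   parameter columns).
#' @return A named logical vector over the thirteen flagged parameters.
#' @export
classify_normality <- function(report) {
  rng <- normal_ranges()
  rng <- rng[!is.na(rng$lo), ]
  flags <- vapply(seq_len(nrow(rng)), function(i) {
    v <- report[[rng$parameter[i]]][1]
    if (rng$parameter[i] == "MAD") v <- abs(v)
    v >= rng$lo[i] & v <= rng$hi[i]
  }, logical(1))
  names(flags) <- rng$parameter
  flags
}

#' @export
print.limb_report <- function(x, ...) {
  cat(sprintf("<limb_report> %s limb at %.2f mm/px\n",
              x$side[1], x$pixel_spacing[1]))
  print(tidy.limb_report(x), n = 16)
  invisible(x)
}

#' Tidy a measurement report
#'
#' @param x A `limb_report`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `parameter`, `value`,
#'   `units`, `lo`, `hi`, `normal`.
#' @export
tidy.limb_report <- function(x, ...) {
  rng <- normal_ranges()
  flags <- attr(x, "normal_flags")
  vals <- vapply(rng$parameter, function(p) x[[p]][1], numeric(1))
  tibble::tibble(
    parameter = rng$parameter,
    value = unname(vals),
    units = rng$units,
    lo = rng$lo, hi = rng$hi,
    normal = ifelse(rng$parameter %in% names(flags),
                    unname(flags[rng$parameter]), NA)
  )
}

#' One-line summary of a report
#'
#' @param x A `limb_report`.
#' @param ... Unused.
#' @return A one-row tibble: side, mTFA, MAD, number of abnormal flags.
#' @export
glance.limb_report <- function(x, ...) {
  flags <- attr(x, "normal_flags")
  tibble::tibble(side = x$side[1], mTFA = x$mTFA[1], MAD = x$MAD[1],
                 n_abnormal = sum(!flags), n_flagged = length(flags))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
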