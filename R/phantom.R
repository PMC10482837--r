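# Synthetic full-leg phantom with closed-form ground truth.
#
# Each bone is a union of analytic primitives (discs, rectangles, trapezoids)
# arranged so that every anatomical landmark the measurement pipeline must
# find has an exact continuous-coordinate location: the femoral head is a
# disc, joint surfaces carry small circular bulges whose extremal points ARE
# the joint-line endpoints, and shafts are rectangles centred on their
# anatomical axes. Ground truth is evaluated from the continuous geometry
# before any rasterisation, so pipeline error measured against it includes
# discretisation error by design.

PHANTOM_CANVAS <- c(1920L, 768L)  # rows x cols at 0.48 mm/px (~369 x 922 mm)
KNEE_GAP_MM <- 10                 # femorotibial joint space of the phantom

#' Parametric description of a synthetic leg
#'
#' All lengths are millimetres and all angles degrees. The geometry is
#' gauge-fixed with a vertical femoral mechanical axis; every clinical angle
#' of the phantom is then determined by the joint-line tilts this spec
#' encodes.
#'
#' @param side `"left"` or `"right"`.
#' @param pixel_spacing Pixel spacing in mm/px.
#' @param femoral_length Head apex to femoral knee centre, mm.
#' @param tibial_length Tibial knee centre to ankle centre, mm.
#' @param neck_shaft_angle Femoral neck vs anatomical axis, degrees.
#' @param neck_length Head centre to trochanteric shaft junction, mm.
#' @param head_radius Femoral head radius, mm.
#' @param mLPFA_true,mLDFA_true,mMPTA_true,mLDTA_true Target joint angles.
#' @param jlca_true Joint line convergence angle, degrees.
#' @param anat_offset_angle Femoral anatomical-vs-mechanical axis angle.
#' @param shaft_width,condyle_width,plafond_width Bone widths, mm.
#' @param boundary_jitter_sd Boundary noise, px (0 = clean masks).
#' @param seed Integer recorded for provenance.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(side = "left",
                         pixel_spacing = 0.48,
                         femoral_length = 458,
                         tibial_length = 364,
                         neck_shaft_angle = 130,
                         neck_length = 50,
                         head_radius = 24,
                         mLPFA_true = 90,
                         mLDFA_true = 87.5,
                         mMPTA_true = 87.5,
                         mLDTA_true = 89,
                         jlca_true = 1,
                         anat_offset_angle = 6,
                         shaft_width = 30,
                         condyle_width = 80,
                         plafond_width = 50,
                         boundary_jitter_sd = 0,
                         seed = 1L) {
  side <- match.arg(side, c("left", "right"))
  spec <- list(side = side, pixel_spacing = pixel_spacing,
               femoral_length = femoral_length, tibial_length = tibial_length,
               neck_shaft_angle = neck_shaft_angle, neck_length = neck_length,
               head_radius = head_radius, mLPFA_true = mLPFA_true,
               mLDFA_true = mLDFA_true, mMPTA_true = mMPTA_true,
               mLDTA_true = mLDTA_true, jlca_true = jlca_true,
               anat_offset_angle = anat_offset_angle,
               shaft_width = shaft_width, condyle_width = condyle_width,
               plafond_width = plafond_width,
               boundary_jitter_sd = boundary_jitter_sd,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  lens <- c("pixel_spacing", "femoral_length", "tibial_length", "neck_length",
            "head_radius", "shaft_width", "condyle_width", "plafond_width")
  for (f in lens) {
    if (!is.finite(spec[[f]]) || spec[[f]] <= 0) {
      stop("phantom_spec: `", f, "` must be strictly positive", call. = FALSE)
    }
  }
  angs <- c("neck_shaft_angle", "mLPFA_true", "mLDFA_true", "mMPTA_true",
            "mLDTA_true")
  for (f in angs) {
    if (!is.finite(spec[[f]]) || spec[[f]] <= 0 || spec[[f]] >= 180) {
      stop("phantom_spec: `", f, "` must lie in (0, 180) degrees", call. = FALSE)
    }
  }
  if (spec$jlca_true < 0 || spec$jlca_true >= 30) {
    stop("phantom_spec: `jlca_true` must lie in [0, 30) degrees", call. = FALSE)
  }
  if (spec$boundary_jitter_sd < 0) {
    stop("phantom_spec: `boundary_jitter_sd` must be >= 0", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s leg, %.2f mm/px | femur %.0f mm, tibia %.0f mm\n",
    x$side, x$pixel_spacing, x$femoral_length, x$tibial_length))
  cat(sprintf(
    "  NSA %.1f  mLPFA %.1f  mLDFA %.1f  mMPTA %.1f  mLDTA %.1f  JLCA %.1f\n",
    x$neck_shaft_angle, x$mLPFA_true, x$mLDFA_true, x$mMPTA_true,
    x$mLDTA_true, x$jlca_true))
  invisible(x)
}

#' Sample a phantom spec from a study-like population
#'
#' The normal population draws every parameterised joint angle uniformly
#' inside its published normal range and bone lengths from the study
#' population's magnitudes; `varus` and `valgus` push the knee angles outside
#' their ranges in the respective direction, and `lld` shortens the tibia to
#' create a leg-length discrepancy with normal angles.
#'
#' @param rng_seed Integer seed; identical seeds give identical specs.
#' @param population One of `"normal"`, `"varus"`, `"valgus"`, `"lld"`.
#' @return A [phantom_spec()].
#' @export
sample_phantom_spec <- function(rng_seed,
                                population = c("normal", "varus", "valgus", "lld")) {
  if (!is.character(population) || !population[1] %in%
      c("normal", "varus", "valgus", "lld")) {
    stop("unknown population label: ", population[1],
         " (expected normal, varus, valgus or lld)", call. = FALSE)
  }
  population <- population[1]
  with_local_seed(rng_seed, {
    u <- function(a, b) stats::runif(1, a, b)
    femoral <- u(435, 480)
    tibial <- u(345, 380)
    mLDFA <- u(85, 90); mMPTA <- u(85, 90); jlca <- u(0, 2)
    if (population == "varus") {
      mLDFA <- u(90.5, 93); mMPTA <- u(82, 84.5); jlca <- u(2.5, 4)
    } else if (population == "valgus") {
      mLDFA <- u(82, 84.5); mMPTA <- u(90.5, 93)
    } else if (population == "lld") {
      tibial <- u(300, 340)
    }
    phantom_spec(
      side = sample(c("left", "right"), 1),
      pixel_spacing = 0.48,
      femoral_length = femoral,
      tibial_length = tibial,
      neck_shaft_angle = u(124, 136),
      neck_length = u(45, 55),
      head_radius = u(22, 27),
      mLPFA_true = u(85, 95),
      mLDFA_true = mLDFA,
      mMPTA_true = mMPTA,
      mLDTA_true = u(86, 92),
      jlca_true = jlca,
      shaft_width = u(26, 34),
      condyle_width = u(75, 88),
      plafond_width = u(45, 58),
      boundary_jitter_sd = 0,
      seed = as.integer(rng_seed)
    )
  })
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Closed-form phantom geometry for a LEFT leg in mm, origin at canvas
# top-left, (row, col), row down, medial = +col. Returns landmarks (mm) and
# shape primitives (mm) per ROI class. Right-side phantoms are produced by
# mirroring afterwards, which leaves every angle and length invariant.
phantom_geometry_mm <- function(spec, canvas_mm) {
  med <- function(tau) c(sin(tau * pi / 180), cos(tau * pi / 180))
  lat <- function(tau) -med(tau)
  distal <- function(th) c(cos(th * pi / 180), -sin(th * pi / 180))

  # joint-line tilts and axis tilts from the target clinical angles
  # (femoral mechanical axis vertical by gauge)
  tau_C <- 90 - spec$mLDFA_true
  tau_P <- tau_C - spec$jlca_true
  th_T <- spec$mMPTA_true - 90 + tau_P
  tau_A <- th_T + 90 - spec$mLDTA_true
  tau_H <- spec$mLPFA_true - 90
  th_Fa <- -spec$anat_offset_angle

  r <- spec$head_radius
  sw <- spec$shaft_width
  cw <- spec$condyle_width
  pw <- 0.95 * cw
  pfw <- spec$plafond_width
  r_l <- 0.16 * cw    # condylar bulge radius
  r_lp <- 0.16 * pw   # plateau bulge radius
  r_a <- 0.13 * pfw   # plafond bulge radius
  r_t <- 7            # trochanteric cap radius

  margin_top <- 15
  KF <- c(margin_top + spec$femoral_length, canvas_mm[2] / 2)
  L_Fm <- spec$femoral_length - r
  H <- KF + c(-L_Fm, 0)
  apex <- H + c(-r, 0)
  C_lat <- KF + (cw / 2) * lat(tau_C)
  C_med <- KF + (cw / 2) * med(tau_C)
  KT <- KF + c(KNEE_GAP_MM, 0)
  P_lat <- KT + (pw / 2) * lat(tau_P)
  P_med <- KT + (pw / 2) * med(tau_P)
  A <- KT + spec$tibial_length * distal(th_T)
  F_lat <- A + (pfw / 2) * lat(tau_A)
  F_med <- A + (pfw / 2) * med(tau_A)
  d_HT <- 2.5 * r
  TT <- H + d_HT * lat(tau_H)

  d_a <- distal(th_Fa)
  u_neck <- rot2(d_a, spec$neck_shaft_angle)   # points supero-medial
  S_top <- H - spec$neck_length * u_neck
  condyle_clear <- r_l + 8
  t_shaft <- (KF[1] - condyle_clear - S_top[1]) / d_a[1]
  B_f <- S_top + t_shaft * d_a

  d_t <- distal(th_T)
  tib_anat_off <- c(0, 3)  # anatomical axis runs ~3 mm medial of mechanical

  landmarks <- list(
    head_center = H, head_apex = apex, trochanter_tip = TT,
    neck_axis = list(anchor = H, direction = -u_neck),
    femoral_anat_axis = list(anchor = (S_top + B_f) / 2, direction = d_a),
    femoral_condyle_lateral = C_lat, femoral_condyle_medial = C_med,
    knee_center_femoral = KF,
    plateau_lateral = P_lat, plateau_medial = P_med,
    knee_center_tibial = KT,
    tibial_anat_axis = list(anchor = (KT + A) / 2 + tib_anat_off,
                            direction = d_t),
    plafond_lateral = F_lat, plafond_medial = F_med,
    ankle_center = A,
    head_radius = r
  )

  n_a <- c(-d_a[2], d_a[1])
  n_neck <- c(-u_neck[2], u_neck[1])
  hw_n <- 0.44 * r
  rect <- function(p1, p2, n, hw) {
    prim_polygon(c(p1[1] + hw * n[1], p2[1] + hw * n[1],
                   p2[1] - hw * n[1], p1[1] - hw * n[1]),
                 c(p1[2] + hw * n[2], p2[2] + hw * n[2],
                   p2[2] - hw * n[2], p1[2] - hw * n[2]))
  }

  # trochanteric mass: superior cap (tip = TT exactly) plus a quad tying the
  # cap into the lateral strip of the neck, kept off the neck centreline so
  # the isthmus cross-section of the mask stays symmetric about the true axis
  n_lat_neck <- c(-u_neck[2], u_neck[1])
  if (n_lat_neck[2] > 0) n_lat_neck <- -n_lat_neck  # lateral = -col (left)
  attach_t <- max(0.7 * spec$neck_length, r + 7)
  N1 <- H + attach_t * (-u_neck) + 0.85 * 0.44 * r * n_lat_neck
  N2 <- H + 0.98 * spec$neck_length * (-u_neck) + 0.85 * 0.44 * r * n_lat_neck
  tro_quad <- prim_polygon(
    c(TT[1] + 2, TT[1] + 1.8 * r, N2[1], N1[1]),
    c(TT[2] - 6, TT[2] - 4, N2[2], N1[2])
  )

  D_lat <- C_lat + c(-r_l, 0); D_med <- C_med + c(-r_l, 0)
  U_lat <- P_lat + c(r_lp, 0); U_med <- P_med + c(r_lp, 0)
  G_lat <- F_lat + c(-r_a, 0); G_med <- F_med + c(-r_a, 0)

  tib_top <- KT + tib_anat_off + 20 * d_t
  tib_bot <- A + tib_anat_off - 15 * d_t
  n_t <- c(-d_t[2], d_t[1])

  prims <- list(
    femoral_head = list(
      prim_disc(H, r),
      rect(H, S_top, n_neck, hw_n),
      prim_disc(TT + c(r_t, 0), r_t),
      tro_quad
    ),
    femoral_shaft = list(rect(S_top, B_f, n_a, sw / 2)),
    tibial_shaft = list(rect(tib_top, tib_bot, n_t, 0.45 * sw)),
    knee = list(
      prim_polygon(c(B_f[1], D_lat[1], D_med[1], B_f[1]),
                   c(B_f[2] - 0.6 * sw, D_lat[2], D_med[2], B_f[2] + 0.6 * sw)),
      prim_disc(D_lat, r_l), prim_disc(D_med, r_l),
      prim_polygon(c(U_lat[1], U_med[1], KT[1] + 55, KT[1] + 55),
                   c(U_lat[2], U_med[2], KT[2] + 0.6 * sw, KT[2] - 0.6 * sw)),
      prim_disc(U_lat, r_lp), prim_disc(U_med, r_lp)
    ),
    ankle = list(
      prim_polygon(c(A[1] - 45, G_lat[1], G_med[1], A[1] - 45),
                   c(A[2] - 0.45 * pfw, G_lat[2], G_med[2], A[2] + 0.45 * pfw)),
      prim_disc(G_lat, r_a), prim_disc(G_med, r_a)
    )
  )

  list(landmarks = landmarks, prims = prims)
}

scale_point <- function(p, s) p / s
mirror_col <- function(p, ncol_px) c(p[1], (ncol_px - 1) - p[2])

# mm geometry -> pixel-frame landmark_set, with optional horizontal mirror
geometry_to_landmarks <- function(geo, spec, canvas_px) {
  s <- spec$pixel_spacing
  mirror <- spec$side == "right"
  cvt_pt <- function(p) {
    p <- p / s
    if (mirror) p <- mirror_col(p, canvas_px[2])
    pt(p[1], p[2])
  }
  cvt_line <- function(l) {
    a <- l$anchor / s
    d <- l$direction
    if (mirror) {
      a <- mirror_col(a, canvas_px[2])
      d <- c(d[1], -d[2])
    }
    axis_line(a, d)
  }
  lm <- geo$landmarks
  new_landmark_set(
    head_center = cvt_pt(lm$head_center),
    head_radius = lm$head_radius / s,
    head_apex = cvt_pt(lm$head_apex),
    trochanter_tip = cvt_pt(lm$trochanter_tip),
    neck_axis = cvt_line(lm$neck_axis),
    femoral_anat_axis = cvt_line(lm$femoral_anat_axis),
    femoral_condyle_medial = cvt_pt(lm$femoral_condyle_medial),
    femoral_condyle_lateral = cvt_pt(lm$femoral_condyle_lateral),
    knee_center_femoral = cvt_pt(lm$knee_center_femoral),
    plateau_medial = cvt_pt(lm$plateau_medial),
    plateau_lateral = cvt_pt(lm$plateau_lateral),
    knee_center_tibial = cvt_pt(lm$knee_center_tibial),
    tibial_anat_axis = cvt_line(lm$tibial_anat_axis),
    plafond_medial = cvt_pt(lm$plafond_medial),
    plafond_lateral = cvt_pt(lm$plafond_lateral),
    ankle_center = cvt_pt(lm$ankle_center),
    side = spec$side
  )
}

geometry_to_prims_px <- function(geo, spec, canvas_px) {
  s <- spec$pixel_spacing
  mirror <- spec$side == "right"
  lapply(geo$prims, function(class_prims) {
    lapply(class_prims, function(p) {
      if (p$type == "disc") {
        ctr <- p$center / s
        if (mirror) ctr <- mirror_col(ctr, canvas_px[2])
        prim_disc(ctr, p$radius / s)
      } else {
        rows <- p$rows / s
        cols <- p$cols / s
        if (mirror) cols <- (canvas_px[2] - 1) - cols
        prim_polygon(rows, cols)
      }
    })
  })
}

crop_mask <- function(full, pad = 4L) {
  bb <- mask_bbox(full)
  r0 <- max(0L, bb["row_min"] - pad); c0 <- max(0L, bb["col_min"] - pad)
  r1 <- min(nrow(full), bb["row_max"] + pad); c1 <- min(ncol(full), bb["col_max"] + pad)
  list(mask = full[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE],
       offset = c(row = as.integer(r0), col = as.integer(c0)))
}

rasterize_mask_set <- function(prims_px, spec, canvas_px) {
  nr <- canvas_px[1]; nc <- canvas_px[2]
  masks <- list(); offsets <- list()
  for (cls in names(prims_px)) {
    full <- rasterize_primitives(prims_px[[cls]], nr, nc)
    cr <- crop_mask(full)
    masks[[cls]] <- cr$mask
    offsets[[cls]] <- cr$offset
  }
  structure(list(masks = masks, offsets = offsets,
                 pixel_spacing = spec$pixel_spacing, side = spec$side,
                 canvas = as.integer(canvas_px)),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %s side, %.2f mm/px, canvas %d x %d px\n",
              x$side, x$pixel_spacing, x$canvas[1], x$canvas[2]))
  for (cls in names(x$masks)) {
    cat(sprintf("  %-14s %5d px foreground at offset (%d, %d)\n", cls,
                sum(x$masks[[cls]]), x$offsets[[cls]][1], x$offsets[[cls]][2]))
  }
  invisible(x)
}

#' Generate a synthetic leg phantom
#'
#' Builds the continuous bone geometry implied by `spec`, evaluates its
#' ground-truth landmarks and measurement report in closed form, and then
#' rasterises one binary mask per ROI class (femoral shaft, tibial shaft,
#' femoral head, knee, ankle). If `spec$boundary_jitter_sd > 0` the masks are
#' additionally jittered with [add_boundary_jitter()] (seeded from
#' `spec$seed`); the truth fields always describe the clean geometry.
#'
#' @param spec A [phantom_spec()].
#' @param canvas Canvas size `c(rows, cols)` in px.
#' @return An object of class `phantom_case`: `mask_set`, `truth_landmarks`,
#'   `truth_report`, `spec`, and the full-frame primitives used.
#' @export
generate_phantom <- function(spec, canvas = PHANTOM_CANVAS) {
  validate_phantom_spec(spec)
  canvas <- as.integer(canvas)
  canvas_mm <- canvas * spec$pixel_spacing
  if (spec$femoral_length + spec$tibial_length >= canvas_mm[1]) {
    stop("phantom exceeds canvas: femoral + tibial length (",
         round(spec$femoral_length + spec$tibial_length), " mm) does not fit ",
         round(canvas_mm[1]), " mm of canvas height", call. = FALSE)
  }
  geo <- phantom_geometry_mm(spec, canvas_mm)
  # overall fit check on the continuous geometry (2 mm margin)
  ext <- range_of_prims(geo$prims)
  if (ext["row_min"] < 2 || ext["col_min"] < 2 ||
      ext["row_max"] > canvas_mm[1] - 2 || ext["col_max"] > canvas_mm[2] - 2) {
    stop("phantom exceeds canvas: bone extent [",
         paste(round(ext), collapse = ", "), "] mm vs canvas ",
         round(canvas_mm[1]), " x ", round(canvas_mm[2]), " mm", call. = FALSE)
  }
  lms <- geometry_to_landmarks(geo, spec, canvas)
  prims_px <- geometry_to_prims_px(geo, spec, canvas)
  truth_report <- compute_report(lms, spec$pixel_spacing)
  mask_set <- rasterize_mask_set(prims_px, spec, canvas)
  case <- structure(list(mask_set = mask_set, truth_landmarks = lms,
                         truth_report = truth_report, spec = spec,
                         primitives = prims_px),
                    class = "phantom_case")
  if (spec$boundary_jitter_sd > 0) {
    case <- add_boundary_jitter(case, spec$boundary_jitter_sd,
                                seed = spec$seed + 1e6)
  }
  case
}

range_of_prims <- function(prims) {
  rows <- c(); cols <- c()
  for (cls in prims) for (p in cls) {
    if (p$type == "disc") {
      rows <- c(rows, p$center[1] + c(-1, 1) * p$radius)
      cols <- c(cols, p$center[2] + c(-1, 1) * p$radius)
    } else {
      rows <- c(rows, range(p$rows)); cols <- c(cols, range(p$cols))
    }
  }
  c(row_min = min(rows), row_max = max(rows),
    col_min = min(cols), col_max = max(cols))
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s leg phantom (seed %d)\n",
              x$spec$side, x$spec$seed))
  print(x$mask_set)
  invisible(x)
}

# Zero-mean boundary displacement with a short correlation length along the
# polygon: iid Gaussian draws smoothed by a circular moving average and
# rescaled to the requested marginal sd. Segmentation error is spatially
# coherent; uncorrelated per-vertex noise would instead make the outline
# fold over itself at realistic amplitudes.
smooth_noise <- function(n, sd, window = 9L) {
  window <- min(window, max(1L, n - 1L))
  z <- stats::rnorm(n)
  s <- stats::filter(z, rep(1 / window, window), circular = TRUE)
  as.numeric(s) * sd * sqrt(window)
}

#' Perturb phantom mask boundaries
#'
#' Re-rasterises every shape primitive after displacing its boundary polygon
#' vertices (one vertex every ~2.5 px) by zero-mean Gaussian offsets with a
#' short along-boundary correlation length, emulating segmentation noise.
#' Ground-truth landmarks and report are left untouched.
#'
#' @param case A `phantom_case`.
#' @param sd Displacement standard deviation in px; `0` returns the input.
#' @param seed Integer seed for the displacement noise.
#' @return A `phantom_case` with jittered masks and unchanged truth.
#' @export
add_boundary_jitter <- function(case, sd, seed = case$spec$seed + 1e6) {
  stopifnot(inherits(case, "phantom_case"))
  if (sd < 0) stop("jitter sd must be >= 0", call. = FALSE)
  if (sd == 0) return(case)
  seed <- as.integer(seed %% .Machine$integer.max)
  jittered <- with_local_seed(seed, {
    lapply(case$primitives, function(class_prims) {
      lapply(class_prims, function(p) {
        poly <- prim_as_polygon(p, step = 2.5)
        n <- length(poly$rows)
        prim_polygon(poly$rows + smooth_noise(n, sd),
                     poly$cols + smooth_noise(n, sd))
      })
    })
  })
  case$mask_set <- rasterize_mask_set(jittered, case$spec,
                                      case$mask_set$canvas)
  case
}
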