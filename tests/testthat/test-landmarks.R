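rect_mask <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(FALSE, nr, nc)
  m[r0:r1, c0:c1] <- TRUE
  m
}

test_that("shaft axis of an axis-aligned rectangle is its column centre line", {
  m <- rect_mask(100, 40, 5, 95, 11, 29)
  ax <- shaft_axis(m)
  expect_lt(angle_between(ax$direction, c(1, 0), "acute"), 1e-6)
  expect_lt(abs(ax$anchor["col"] - 19), 1e-6)  # centre of 0-based cols 10..28
})

test_that("shaft axis recovers a rotated rectangle to 0.2 degrees", {
  # rasterise a 10-degree rotated rectangle
  th <- 10 * pi / 180
  nr <- 400; nc <- 200
  ctr <- c(200, 100)
  m <- matrix(FALSE, nr, nc)
  idx <- which(matrix(TRUE, nr, nc), arr.ind = TRUE) - 1
  u <- cbind(idx[, 1] - ctr[1], idx[, 2] - ctr[2])
  along <- u[, 1] * cos(th) + u[, 2] * sin(th)
  across <- -u[, 1] * sin(th) + u[, 2] * cos(th)
  m[abs(along) <= 150 & abs(across) <= 20] <- TRUE
  ax <- shaft_axis(m)
  got <- angle_between(ax$direction, c(cos(th), sin(th)), "acute")
  expect_lt(got, 0.2)
})

test_that("a bowed shaft yields the chord direction of its central arc", {
  # circular-arc shaft: centreline col = 60 + 400 - sqrt(400^2 - (row-150)^2)
  nr <- 300; nc <- 140
  m <- matrix(FALSE, nr, nc)
  for (r in 10:290) {
    cc <- 60 + 400 - sqrt(400^2 - (r - 150)^2)
    m[r + 1, max(1, round(cc - 12)):min(nc, round(cc + 12))] <- TRUE
  }
  ax <- shaft_axis(m)
  # analytic chord over the central 60% of rows [66, 234]
  ccol <- function(r) 60 + 400 - sqrt(400^2 - (r - 150)^2)
  chord <- c(234 - 66, ccol(234) - ccol(66))
  expect_lt(angle_between(ax$direction, chord, "acute"), 0.2)
})

test_that("shaft axis rejects short and fragmented masks", {
  expect_error(shaft_axis(rect_mask(30, 10, 5, 15, 3, 7)), "20 foreground rows")
  expect_error(shaft_axis(rect_mask(50, 80, 5, 34, 3, 77)), "taller than wide")
  frag <- rect_mask(100, 60, 5, 95, 10, 20) | rect_mask(100, 60, 5, 95, 40, 50)
  expect_error(shaft_axis(frag), "fragmented")
})

test_that("head landmarks recover the phantom's proximal femur", {
  case <- phantom_fixture(2)
  truth <- case$truth_landmarks
  off <- case$mask_set$offsets$femoral_head
  hd <- head_landmarks(case$mask_set$masks$femoral_head, truth$side)
  expect_lt(vec_norm(hd$head_center + off - truth$head_center), 0.5)
  expect_lt(abs(hd$head_radius - truth$head_radius), 1)
  expect_lt(vec_norm(hd$head_apex + off - truth$head_apex), 1)
  expect_lt(vec_norm(hd$trochanter_tip + off - truth$trochanter_tip), 1)
  expect_lt(angle_between(hd$neck_axis, truth$neck_axis, "acute"), 0.5)
})

test_that("a bare disc reports trochanter absence explicitly", {
  m <- fill_disc(c(60, 60), 40, 121, 121)
  expect_warning(hd <- head_landmarks(m, "left"), "absent")
  expect_false(hd$trochanter_found)
  expect_true(all(is.na(hd$trochanter_tip)))
  expect_lt(vec_norm(hd$head_center - c(60, 60)), 0.5)
  expect_lt(abs(hd$head_radius - 40), 1)
})

test_that("mirrored head masks give mirrored landmarks", {
  case <- phantom_fixture(2)
  m <- case$mask_set$masks$femoral_head
  side <- case$mask_set$side
  other <- if (side == "left") "right" else "left"
  W <- ncol(m)
  hd <- head_landmarks(m, side)
  hd_m <- head_landmarks(m[, W:1], other)
  expect_lt(abs(hd_m$head_center["col"] - (W - 1 - hd$head_center["col"])), 0.1)
  expect_lt(abs(hd_m$trochanter_tip["col"] - (W - 1 - hd$trochanter_tip["col"])), 0.1)
  expect_lt(abs(hd_m$head_center["row"] - hd$head_center["row"]), 0.1)
})

test_that("joint lines recover the phantom knee to the stated tolerances", {
  spec <- phantom_spec(jlca_true = 0)
  case0 <- generate_phantom(spec)
  kf <- joint_line(case0$mask_set$masks$knee, "femur_distal", "left")
  kt <- joint_line(case0$mask_set$masks$knee, "tibia_proximal", "left")
  expect_lt(angle_between(kf$line, kt$line, "acute"), 0.3)

  spec2 <- phantom_spec(jlca_true = 2)
  case2 <- generate_phantom(spec2)
  kf2 <- joint_line(case2$mask_set$masks$knee, "femur_distal", "left")
  kt2 <- joint_line(case2$mask_set$masks$knee, "tibia_proximal", "left")
  expect_lt(abs(angle_between(kf2$line, kt2$line, "acute") - 2), 0.3)
})

test_that("a flat horizontal articular edge gives a horizontal joint line", {
  m <- rect_mask(60, 100, 10, 40, 11, 91)
  # two shallow bulges so the lobe finder has distinct extrema
  m <- m | fill_disc(c(44, 20), 5, 60, 100) | fill_disc(c(44, 80), 5, 60, 100)
  jl <- joint_line(m, "tibia_distal", "left")
  expect_lt(angle_between(jl$line$direction, c(0, 1), "acute"), 0.5)
  expect_lt(abs(jl$center["col"] - 50), 1)
  expect_equal(unname(jl$lateral["col"] < jl$medial["col"]), TRUE)
})

test_that("single-lobed contours raise a degeneracy error naming the bone", {
  m <- rect_mask(60, 100, 10, 40, 11, 91)
  expect_error(joint_line(m, "tibia_distal", "left"), "tibia_distal")
})

test_that("assembled landmarks match closed-form truth within a pixel", {
  for (s in c(3, 8)) {
    case <- phantom_fixture(s)
    lm <- assemble_landmarks(case$mask_set)
    truth <- case$truth_landmarks
    for (nm in c("head_center", "head_apex", "trochanter_tip",
                 "femoral_condyle_medial", "femoral_condyle_lateral",
                 "knee_center_femoral", "plateau_medial", "plateau_lateral",
                 "knee_center_tibial", "plafond_medial", "plafond_lateral",
                 "ankle_center")) {
      expect_lt(vec_norm(lm[[nm]] - truth[[nm]]), 1)
    }
    for (nm in c("femoral_anat_axis", "tibial_anat_axis", "neck_axis")) {
      expect_lt(angle_between(lm[[nm]], truth[[nm]], "acute"), 0.5)
    }
  }
})

test_that("landmarks are exactly equivariant under mask translation", {
  case <- phantom_fixture(3)
  ms <- case$mask_set
  shifted <- ms
  for (cls in names(shifted$offsets)) {
    shifted$offsets[[cls]] <- shifted$offsets[[cls]] + c(row = 7L, col = 11L)
  }
  lm0 <- assemble_landmarks(ms)
  lm1 <- assemble_landmarks(shifted)
  expect_equal(unname(lm1$head_center - lm0$head_center), c(7, 11),
               tolerance = 1e-12)
  expect_equal(unname(lm1$ankle_center - lm0$ankle_center), c(7, 11),
               tolerance = 1e-12)
  expect_equal(lm1$femoral_anat_axis$direction, lm0$femoral_anat_axis$direction,
               tolerance = 1e-12)
})

test_that("a missing ROI class is reported by name", {
  case <- phantom_fixture(3)
  ms <- case$mask_set
  ms$masks$ankle <- NULL
  expect_error(assemble_landmarks(ms), "ankle")
})

test_that("small rotations of the phantom rotate the fitted shaft axes", {
  case <- phantom_fixture(5)
  m <- case$mask_set$masks$femoral_shaft
  ax0 <- shaft_axis(m)
  # rotate the shaft mask by 3 degrees about its centre
  th <- 3 * pi / 180
  pts <- mask_points(m)
  ctr <- colMeans(pts)
  nr <- nrow(m) + 80; nc <- ncol(m) + 80
  rot <- matrix(FALSE, nr, nc)
  rr <- round(ctr[1] + cos(th) * (pts[, 1] - ctr[1]) -
                sin(th) * (pts[, 2] - ctr[2])) + 40
  cc <- round(ctr[2] + sin(th) * (pts[, 1] - ctr[1]) +
                cos(th) * (pts[, 2] - ctr[2])) + 40
  ok <- rr >= 0 & rr < nr & cc >= 0 & cc < nc
  rot[cbind(rr[ok] + 1, cc[ok] + 1)] <- TRUE
  # fill pinholes from the forward mapping
  rot <- t(EBImage::imageData(EBImage::closing(
    EBImage::Image(t(rot * 1)), EBImage::makeBrush(3, "box")))) > 0.5
  ax1 <- shaft_axis(rot)
  got <- angle_between(ax0$direction, ax1$direction, "acute")
  expect_lt(abs(got - 3), 0.3)
})
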