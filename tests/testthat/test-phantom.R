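test_that("normal-population specs stay inside the published angle ranges", {
  for (s in 1:20) {
    spec <- sample_phantom_spec(s, "normal")
    expect_true(spec$neck_shaft_angle >= 124 && spec$neck_shaft_angle <= 136)
    expect_true(spec$mLDFA_true >= 85 && spec$mLDFA_true <= 90)
    expect_true(spec$mMPTA_true >= 85 && spec$mMPTA_true <= 90)
    expect_true(spec$mLDTA_true >= 86 && spec$mLDTA_true <= 92)
    expect_true(spec$mLPFA_true >= 85 && spec$mLPFA_true <= 95)
    expect_true(spec$jlca_true >= 0 && spec$jlca_true <= 2)
  }
})

test_that("spec sampling is deterministic and rejects unknown populations", {
  expect_identical(sample_phantom_spec(3, "normal"),
                   sample_phantom_spec(3, "normal"))
  expect_error(sample_phantom_spec(1, "bowlegs"), "unknown population")
})

test_that("deformity populations push knee angles outside their ranges", {
  v <- sample_phantom_spec(2, "varus")
  expect_gt(v$mLDFA_true, 90)
  expect_lt(v$mMPTA_true, 85)
  g <- sample_phantom_spec(2, "valgus")
  expect_lt(g$mLDFA_true, 85)
  expect_gt(g$mMPTA_true, 90)
  l <- sample_phantom_spec(2, "lld")
  expect_lt(l$tibial_length, 345)
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(head_radius = -1), "strictly positive")
  expect_error(phantom_spec(neck_shaft_angle = 190), "\\(0, 180\\)")
  expect_error(phantom_spec(boundary_jitter_sd = -0.1), ">= 0")
})

test_that("closed-form truth copies the spec's target angles exactly", {
  spec <- phantom_spec(neck_shaft_angle = 130, mLPFA_true = 91,
                       mLDFA_true = 88, mMPTA_true = 86.5, mLDTA_true = 90,
                       jlca_true = 1.5)
  tr <- generate_phantom(spec)$truth_report
  expect_equal(tr$NSA, 130, tolerance = 1e-9)
  expect_equal(tr$mLPFA, 91, tolerance = 1e-9)
  expect_equal(tr$mLDFA, 88, tolerance = 1e-9)
  expect_equal(tr$mMPTA, 86.5, tolerance = 1e-9)
  expect_equal(tr$mLDTA, 90, tolerance = 1e-9)
  expect_equal(tr$mJLCA, 1.5, tolerance = 1e-9)
})

test_that("matched knee angles with zero convergence give a straight limb", {
  spec <- phantom_spec(mLDFA_true = 87.5, mMPTA_true = 87.5, jlca_true = 0)
  tr <- generate_phantom(spec)$truth_report
  expect_equal(tr$mTFA, 0, tolerance = 1e-9)
  expect_equal(tr$MAD, 0, tolerance = 1e-6)
})

test_that("truth lengths follow the construction geometry", {
  spec <- phantom_spec(femoral_length = 460, tibial_length = 363,
                       mLDFA_true = 87.5, mMPTA_true = 87.5, jlca_true = 0)
  tr <- generate_phantom(spec)$truth_report
  expect_equal(tr$femoral_length, 460, tolerance = 1e-9)
  expect_equal(tr$tibial_length, 363, tolerance = 1e-9)
  # coaxial construction: apex to ankle = femur + joint gap + tibia
  expect_lt(abs(tr$full_leg_length - (460 + 363 + 10)), 1)
})

test_that("every truth landmark lies inside the foreground masks", {
  case <- phantom_fixture(4)
  ms <- case$mask_set
  lm <- case$truth_landmarks
  pts <- c("head_center", "head_apex", "trochanter_tip",
           "femoral_condyle_medial", "femoral_condyle_lateral",
           "plateau_medial", "plateau_lateral",
           "plafond_medial", "plafond_lateral")
  covered <- function(p, tol) {
    for (cls in names(ms$masks)) {
      loc <- round(p) - ms$offsets[[cls]]
      m <- ms$masks[[cls]]
      for (dr in -tol:tol) for (dc in -tol:tol) {
        r <- loc[1] + dr + 1; c <- loc[2] + dc + 1
        if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) && m[r, c]) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (nm in pts) expect_true(covered(lm[[nm]], 1L), label = nm)
  # joint centres sit in the articular void between the condylar bulges (as
  # on a real radiograph); they must still be close to bone
  bulge <- ceiling(0.16 * case$spec$condyle_width / case$spec$pixel_spacing)
  for (nm in c("knee_center_femoral", "knee_center_tibial", "ankle_center")) {
    expect_true(covered(lm[[nm]], bulge), label = nm)
  }
})

test_that("an oversized limb triggers an explicit canvas error", {
  spec <- phantom_spec(femoral_length = 700, tibial_length = 500)
  expect_error(generate_phantom(spec), "exceeds canvas")
})

test_that("mirroring the side flag leaves the closed-form report invariant", {
  base <- sample_phantom_spec(9, "normal")
  left <- base; left$side <- "left"
  right <- base; right$side <- "right"
  tl <- generate_phantom(left)$truth_report
  tr <- generate_phantom(right)$truth_report
  for (p in setdiff(normal_ranges()$parameter, character(0))) {
    expect_lt(abs(tl[[p]] - tr[[p]]) / max(1, abs(tl[[p]])), 1e-6)
  }
})

test_that("rescaling pixel spacing leaves the mm-valued truth invariant", {
  base <- sample_phantom_spec(5, "normal")
  fine <- base; fine$pixel_spacing <- 0.24
  t1 <- generate_phantom(base)$truth_report
  t2 <- generate_phantom(fine, canvas = c(3840, 1536))$truth_report
  for (p in c("full_leg_length", "femoral_length", "tibial_length", "MAD")) {
    expect_lt(abs(t1[[p]] - t2[[p]]), 1 * 0.48)
  }
  for (p in c("mLDFA", "mMPTA", "NSA", "mTFA")) {
    expect_lt(abs(t1[[p]] - t2[[p]]), 1e-9)
  }
})

test_that("zero jitter is the identity and jitter leaves truth unchanged", {
  case <- phantom_fixture(6)
  expect_identical(add_boundary_jitter(case, 0), case)
  j1 <- add_boundary_jitter(case, 1, seed = 100)
  j2 <- add_boundary_jitter(case, 1, seed = 200)
  expect_identical(j1$truth_report, case$truth_report)
  expect_identical(j1$truth_landmarks, case$truth_landmarks)
  expect_false(identical(j1$mask_set$masks$femoral_shaft,
                         j2$mask_set$masks$femoral_shaft))
})

test_that("1 px jitter keeps shaft masks close to the clean masks", {
  case <- phantom_fixture(6)
  clean <- case$mask_set
  to_canvas <- function(ms, cls) {
    full <- matrix(FALSE, ms$canvas[1], ms$canvas[2])
    om <- ms$offsets[[cls]]; m <- ms$masks[[cls]]
    full[om[1] + seq_len(nrow(m)), om[2] + seq_len(ncol(m))] <- m
    full
  }
  scores <- sapply(1:10, function(s) {
    j <- add_boundary_jitter(case, 1, seed = s)
    sapply(c("femoral_shaft", "tibial_shaft"), function(cls) {
      dsc(to_canvas(clean, cls), to_canvas(j$mask_set, cls))
    })
  })
  expect_true(all(scores > 0.9))
})
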