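test_that("Dice handles identical, disjoint and partial overlaps", {
  a <- matrix(FALSE, 8, 8); a[2:3, 2:3] <- TRUE
  expect_identical(dsc(a, a), 1)
  b <- matrix(FALSE, 8, 8); b[6:7, 6:7] <- TRUE
  expect_identical(dsc(a, b), 0)
  shifted <- matrix(FALSE, 8, 8); shifted[2:3, 3:4] <- TRUE
  expect_identical(dsc(a, shifted), 0.5)  # overlap 2 of 4: 2*2/(4+4)
  expect_identical(dsc(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 1)
  expect_error(dsc(a, matrix(FALSE, 4, 4)), "mismatch")
})

test_that("Hausdorff handles identical masks and two-point cases", {
  a <- matrix(FALSE, 20, 20); a[5:10, 5:10] <- TRUE
  expect_identical(hausdorff(a, a), 0)
  p1 <- matrix(FALSE, 20, 20); p1[3, 3] <- TRUE
  p2 <- matrix(FALSE, 20, 20); p2[3, 15] <- TRUE
  expect_identical(hausdorff(p1, p2, spacing = 0.5), 12 * 0.5)
  expect_error(hausdorff(a, matrix(FALSE, 20, 20)), "non-empty")
})

test_that("dsc and hausdorff are symmetric and match brute force", {
  set.seed(99)
  for (i in 1:25) {
    a <- random_mask(24, 24)
    b <- random_mask(24, 24)
    expect_identical(dsc(a, b), dsc(b, a))
    expect_identical(dsc(a, b), oracle_dsc(a, b))
    h <- hausdorff(a, b)
    expect_identical(h, hausdorff(b, a))
    expect_identical(h, oracle_hausdorff(a, b))
  }
})

make_boxes <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    tibble::tibble(class = r[[1]], score = as.numeric(r[[2]]),
                   row_min = r[[3]], col_min = r[[4]],
                   row_max = r[[5]], col_max = r[[6]])
  }))
}

test_that("mAP is 1 for perfect self-detections and 0 for none", {
  gt <- make_boxes(list("a", 1, 0, 0, 10, 10), list("b", 1, 20, 20, 40, 50))
  expect_identical(mean_average_precision(gt, gt[, -2]), 1)
  none <- gt[0, ]
  expect_identical(mean_average_precision(none, gt[, -2]), 0)
})

test_that("a single detection at known IoU scores k/10", {
  # truth 10x10 at origin; detection shifted 2 cols: IoU = 80/120 = 2/3
  gt <- make_boxes(list("a", 1, 0, 0, 10, 10))[, -2]
  det <- make_boxes(list("a", 0.9, 0, 2, 10, 12))
  iou <- 80 / 120
  k <- sum(seq(0.5, 0.95, by = 0.05) <= iou)
  expect_identical(mean_average_precision(det, gt), k / 10)
  expect_identical(k, 4L)  # thresholds 0.50, 0.55, 0.60, 0.65
})

test_that("mAP is translation invariant and warns on orphan classes", {
  gt <- make_boxes(list("a", 1, 0, 0, 10, 10), list("a", 1, 30, 30, 44, 44))[, -2]
  det <- make_boxes(list("a", 0.8, 0, 1, 10, 11), list("a", 0.6, 31, 30, 45, 44))
  m0 <- mean_average_precision(det, gt)
  shift <- function(df) {
    df$row_min <- df$row_min + 13; df$row_max <- df$row_max + 13
    df$col_min <- df$col_min + 7; df$col_max <- df$col_max + 7
    df
  }
  expect_identical(mean_average_precision(shift(det), shift(gt)), m0)
  # shrinking all detections toward their centres cannot raise the score
  shrink <- det
  shrink$row_min <- shrink$row_min + 2; shrink$row_max <- shrink$row_max - 2
  expect_lte(mean_average_precision(shrink, gt), m0)
  orphan <- rbind(det, make_boxes(list("zz", 0.5, 0, 0, 5, 5)))
  expect_warning(mean_average_precision(orphan, gt), "zz")
})

test_that("identity series yield perfect agreement and zero errors", {
  d <- data.frame(x = c(85.2, 87.1, 90.4, 86.3, 88.8), y = c(85.2, 87.1, 90.4, 86.3, 88.8))
  a <- agreement(d, x, y)
  expect_equal(a$ccc, 1, tolerance = 1e-12)
  expect_equal(a$pcc, 1, tolerance = 1e-12)
  expect_equal(a$icc, 1, tolerance = 1e-12)
  expect_identical(a$mae, 0)
  expect_identical(a$rmse, 0)
  expect_identical(c(a$loa_low, a$loa_high), c(0, 0))
})

test_that("a constant shift degrades CCC but not PCC", {
  x <- c(85.2, 87.1, 90.4, 86.3, 88.8, 91.5)
  d <- data.frame(x = x, y = x + 1)
  a <- agreement(d, x, y)
  s2 <- mean((x - mean(x))^2)  # Lin's 1/n variance
  expect_equal(a$pcc, 1, tolerance = 1e-12)
  expect_equal(a$ccc, 2 * s2 / (2 * s2 + 1), tolerance = 1e-12)
  expect_equal(a$mean_diff, 1, tolerance = 1e-12)
  expect_identical(a$mad_abs_dev, 0)
  expect_lt(a$ccc, a$pcc)
})

test_that("agreement matches independent ANOVA and Lin oracles", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(8, 88, 3)
    y <- x + rnorm(8, 0.3, 0.8)
    d <- data.frame(x = x, y = y)
    a <- agreement(d, x, y)
    expect_equal(a$icc, oracle_icc21(x, y), tolerance = 1e-10)
    expect_equal(a$ccc, oracle_ccc(x, y), tolerance = 1e-12)
    expect_equal(a$pcc, cor(x, y), tolerance = 1e-12)
    expect_equal(a$rmse^2, a$mse, tolerance = 1e-12)
    expect_lte(abs(a$ccc), abs(a$pcc) + 1e-12)
  }
})

test_that("agreement matches a reference implementation on a fixture", {
  # ICC/CCC/PCC for this 6x2 table cross-checked against pingouin (Python)
  d <- data.frame(ref = c(87.2, 88.5, 86.9, 90.1, 85.4, 89.0),
                  sys = c(87.6, 88.1, 87.4, 90.5, 85.0, 88.6))
  a <- agreement(d, ref, sys)
  expect_equal(a$icc, 0.970828471411901, tolerance = 1e-10)
  expect_equal(a$ccc, 0.965197215777262, tolerance = 1e-10)
  expect_equal(a$pcc, 0.967167195700734, tolerance = 1e-10)
  a3 <- agreement(d, ref, sys, icc_form = "ICC3_1")
  expect_equal(a3$icc, 0.965250538644272, tolerance = 1e-10)
})

test_that("agreement statistics scale correctly under unit changes", {
  set.seed(5)
  x <- rnorm(12, 50, 4); y <- x + rnorm(12, 1, 1)
  a1 <- agreement(data.frame(x, y), x, y)
  k <- 10
  a2 <- agreement(data.frame(x = k * x, y = k * y), x, y)
  expect_equal(a2$pcc, a1$pcc, tolerance = 1e-12)
  expect_equal(a2$ccc, a1$ccc, tolerance = 1e-12)
  expect_equal(a2$icc, a1$icc, tolerance = 1e-9)
  expect_equal(a2$mae, k * a1$mae, tolerance = 1e-9)
  expect_equal(a2$rmse, k * a1$rmse, tolerance = 1e-9)
  expect_equal(a2$loa_high, k * a1$loa_high, tolerance = 1e-9)
})

test_that("zero-variance series are reported as undefined, not a crash", {
  d <- data.frame(x = rep(5, 4), y = c(5.1, 4.9, 5.2, 5.0))
  expect_warning(a <- agreement(d, x, y), "zero variance")
  expect_true(is.na(a$pcc) && is.na(a$ccc) && is.na(a$icc))
  expect_false(is.na(a$rmse))
})

test_that("agreement_table maps groups to rows", {
  set.seed(2)
  long <- data.frame(
    parameter = rep(c("mLDFA", "mMPTA"), each = 6),
    ref = rnorm(12, 87, 2)
  )
  long$sys <- long$ref + rnorm(12, 0, 0.5)
  tab <- agreement_table(long, ref, sys, parameter)
  expect_equal(sort(tab$label), c("mLDFA", "mMPTA"))
  expect_equal(tab$n, c(6, 6))
})
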