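# Evaluation statistics: segmentation overlap (Dice, Hausdorff), detection
# quality (COCO-style mAP over IoU 0.50:0.05:0.95), and the method-comparison
# suite used to compare system measurements against a human reference
# (Lin's CCC, Pearson r, ICC(2,1), Bland-Altman, MAE/MSE/RMSE, mean absolute
# deviation of the differences).

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks agree perfectly (1).
#'
#' @param a,b Binary masks (matrices of identical dimensions).
#' @return A scalar in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!all(dim(a) == dim(b))) {
    stop("mask shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

directed_hausdorff_px <- function(P, Q) {
  # max over P of min distance to Q, chunked to bound memory
  worst <- 0
  chunk <- 2048L
  for (i in seq(1, nrow(P), by = chunk)) {
    ii <- i:min(i + chunk - 1L, nrow(P))
    d2 <- outer(P[ii, 1], Q[, 1], "-")^2 + outer(P[ii, 2], Q[, 2], "-")^2
    worst <- max(worst, max(sqrt(apply(d2, 1, min))))
  }
  worst
}

#' Hausdorff distance between two masks
#'
#' Undirected maximum Hausdorff distance over the boundary pixel sets, in
#' millimetres. `variant = "p95"` gives the 95th-percentile variant.
#'
#' @param a,b Non-empty binary masks of identical dimensions.
#' @param spacing Pixel spacing in mm/px.
#' @param variant `"max"` (default) or `"p95"`.
#' @return Distance in mm.
#' @export
hausdorff <- function(a, b, spacing = 1, variant = c("max", "p95")) {
  variant <- match.arg(variant)
  a <- as_mask(a); b <- as_mask(b)
  if (!all(dim(a) == dim(b))) {
    stop("mask shape mismatch", call. = FALSE)
  }
  if (!any(a) || !any(b)) stop("hausdorff distance needs non-empty masks", call. = FALSE)
  P <- mask_boundary(a); Q <- mask_boundary(b)
  if (variant == "max") {
    return(max(directed_hausdorff_px(P, Q), directed_hausdorff_px(Q, P)) * spacing)
  }
  min_d <- function(X, Y) {
    out <- numeric(nrow(X))
    chunk <- 2048L
    for (i in seq(1, nrow(X), by = chunk)) {
      ii <- i:min(i + chunk - 1L, nrow(X))
      d2 <- outer(X[ii, 1], Y[, 1], "-")^2 + outer(X[ii, 2], Y[, 2], "-")^2
      out[ii] <- sqrt(apply(d2, 1, min))
    }
    out
  }
  max(stats::quantile(min_d(P, Q), 0.95), stats::quantile(min_d(Q, P), 0.95)) *
    spacing
}

# IoU between one box and a matrix of boxes; boxes are 0-based half-open
# (row_min, col_min, row_max, col_max).
box_iou <- function(box, boxes) {
  ih <- pmax(0, pmin(box[3], boxes[, 3]) - pmax(box[1], boxes[, 1]))
  iw <- pmax(0, pmin(box[4], boxes[, 4]) - pmax(box[2], boxes[, 2]))
  inter <- ih * iw
  a1 <- (box[3] - box[1]) * (box[4] - box[2])
  a2 <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
  inter / (a1 + a2 - inter)
}

ap_single_class <- function(scores, tp, n_truth, interpolation) {
  if (n_truth == 0) return(NA_real_)
  if (!length(scores)) return(0)
  ord <- order(scores, decreasing = TRUE)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_truth
  precision <- cum_tp / (cum_tp + cum_fp)
  # precision envelope (monotone non-increasing from the right)
  penv <- rev(cummax(rev(precision)))
  if (interpolation == "101") {
    rs <- seq(0, 1, by = 0.01)
    pr <- vapply(rs, function(r) {
      i <- which(recall >= r)
      if (length(i)) penv[min(i)] else 0
    }, numeric(1))
    return(mean(pr))
  }
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * penv)
}

#' Mean average precision over IoU thresholds
#'
#' COCO-style detection metric: per class, average precision (area under the
#' interpolated precision-recall envelope) is averaged over IoU thresholds
#' 0.50 to 0.95 in steps of 0.05, then averaged over classes. Detections are
#' matched greedily to ground truth in order of decreasing score.
#'
#' @param detections Data frame with columns `class`, `score`, `row_min`,
#'   `col_min`, `row_max`, `col_max` (0-based, half-open).
#' @param truths Data frame with `class` and the same box columns.
#' @param thresholds IoU thresholds to average over.
#' @param interpolation `"all"` (all-point envelope area) or `"101"`
#'   (101-point COCO sampling).
#' @return mAP in `[0, 1]`.
#' @export
mean_average_precision <- function(detections, truths,
                                   thresholds = seq(0.5, 0.95, by = 0.05),
                                   interpolation = c("all", "101")) {
  interpolation <- match.arg(interpolation)
  box_cols <- c("row_min", "col_min", "row_max", "col_max")
  stopifnot(all(c("class", box_cols) %in% names(truths)))
  if (nrow(detections)) {
    stopifnot(all(c("class", "score", box_cols) %in% names(detections)))
    if (!all(is.finite(detections$score))) {
      stop("detection scores must be finite", call. = FALSE)
    }
  }
  orphan <- setdiff(unique(detections$class), unique(truths$class))
  if (length(orphan)) {
    warning("no ground truth for class(es) ", paste(orphan, collapse = ", "),
            "; excluded from mAP", call. = FALSE)
  }
  classes <- unique(truths$class)
  aps <- numeric(0)
  for (cl in classes) {
    gt <- as.matrix(truths[truths$class == cl, box_cols, drop = FALSE])
    det <- detections[which(detections$class == cl), , drop = FALSE]
    det <- det[order(det$score, decreasing = TRUE), , drop = FALSE]
    dbox <- as.matrix(det[, box_cols, drop = FALSE])
    for (thr in thresholds) {
      matched <- rep(FALSE, nrow(gt))
      tp <- rep(FALSE, nrow(det))
      if (nrow(det)) {
        for (i in seq_len(nrow(det))) {
          ious <- box_iou(dbox[i, ], gt)
          ious[matched] <- -1
          j <- which.max(ious)
          if (length(j) && ious[j] >= thr) {
            matched[j] <- TRUE
            tp[i] <- TRUE
          }
        }
      }
      aps <- c(aps, ap_single_class(det$score, tp, nrow(gt), interpolation))
    }
  }
  if (!length(aps)) return(NA_real_)
  mean(aps)
}

# ICC(2,1): two-way random effects, absolute agreement, single measurement,
# from the mean squares of the two-way ANOVA (subjects x raters).
icc_two_way <- function(x, y, form = c("ICC2_1", "ICC3_1")) {
  form <- match.arg(form)
  n <- length(x); k <- 2
  df <- data.frame(value = c(x, y),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  fit <- stats::aov(value ~ subject + rater, data = df)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (form == "ICC3_1") {
    return((msr - mse) / (msr + (k - 1) * mse))
  }
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Agreement statistics for a paired measurement series
#'
#' Computes the full method-comparison suite between a reference series
#' (e.g. radiologist) and a system series: Pearson correlation (with a
#' two-sided t-test p-value), Lin's concordance correlation coefficient
#' (1/n moments), ICC(2,1) (two-way random effects, absolute agreement,
#' single rater; `icc_form = "ICC3_1"` for the consistency variant),
#' MAE/MSE/RMSE, Bland-Altman bias and 95% limits of agreement, and the mean
#' absolute deviation of the paired differences around their mean.
#'
#' @param data A data frame.
#' @param reference,system Columns of `data` (tidy-eval) holding the paired
#'   values.
#' @param icc_form ICC variant.
#' @param label Optional parameter name stored alongside the results.
#' @return A one-row tibble of class `limb_agreement` with columns `label`,
#'   `n`, `pcc`, `pcc_p`, `ccc`, `icc`, `mae`, `mse`, `rmse`, `mean_diff`,
#'   `loa_low`, `loa_high`, `mad_abs_dev`.
#' @export
agreement <- function(data, reference, system, icc_form = "ICC2_1",
                      label = NULL) {
  x <- rlang::eval_tidy(rlang::enquo(reference), data)
  y <- rlang::eval_tidy(rlang::enquo(system), data)
  if (length(x) != length(y)) stop("paired series differ in length", call. = FALSE)
  if (length(x) < 2) stop("agreement needs at least 2 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("paired series must be finite", call. = FALSE)
  }
  n <- length(x)
  d <- y - x
  mae <- mean(abs(d))
  mse <- mean(d^2)
  rmse <- sqrt(mse)
  mean_diff <- mean(d)
  sd_d <- stats::sd(d)
  loa <- mean_diff + c(-1, 1) * 1.96 * sd_d
  mad_abs_dev <- mean(abs(d - mean_diff))

  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (degenerate) {
    warning("zero variance in a series: correlation coefficients undefined",
            call. = FALSE)
    pcc <- NA_real_; pcc_p <- NA_real_; ccc <- NA_real_; icc <- NA_real_
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    pcc <- unname(ct$estimate)
    pcc_p <- ct$p.value
    mx <- mean(x); my <- mean(y)
    sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
    sxy <- mean((x - mx) * (y - my))
    ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
    icc <- icc_two_way(x, y, icc_form)
  }

  out <- tibble::tibble(
    label = label %||% NA_character_, n = n,
    pcc = pcc, pcc_p = pcc_p, ccc = ccc, icc = icc,
    mae = mae, mse = mse, rmse = rmse,
    mean_diff = mean_diff, loa_low = loa[1], loa_high = loa[2],
    mad_abs_dev = mad_abs_dev
  )
  class(out) <- c("limb_agreement", class(out))
  attr(out, "pairs") <- tibble::tibble(reference = x, system = y)
  out
}

#' Per-parameter agreement table
#'
#' Applies [agreement()] to each group of a long paired-measurement table,
#' producing one row per parameter in the shape of a published
#' method-comparison table.
#'
#' @param data Data frame with one row per (case, parameter) pair.
#' @param reference,system Paired value columns (tidy-eval).
#' @param by Grouping column naming the parameter (tidy-eval).
#' @param icc_form ICC variant passed through.
#' @return A tibble with one `limb_agreement` row per group.
#' @export
agreement_table <- function(data, reference, system, by, icc_form = "ICC2_1") {
  ref_q <- rlang::enquo(reference)
  sys_q <- rlang::enquo(system)
  by_q <- rlang::enquo(by)
  groups <- rlang::eval_tidy(by_q, data)
  out <- lapply(split(seq_len(nrow(data)), groups), function(idx) {
    res <- rlang::inject(
      agreement(data[idx, , drop = FALSE], !!ref_q, !!sys_q,
                icc_form = icc_form, label = as.character(groups[idx[1]])))
    class(res) <- setdiff(class(res), "limb_agreement")
    attr(res, "pairs") <- NULL
    res
  })
  dplyr::bind_rows(out)
}

#' @export
glance.limb_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, pcc = x$pcc, ccc = x$ccc, icc = x$icc,
                 rmse = x$rmse, mean_diff = x$mean_diff)
}

#' @export
print.limb_agreement <- function(x, ...) {
  cat(sprintf("<limb_agreement>%s n = %d pairs\n",
              if (!is.na(x$label)) paste0(" ", x$label) else "", x$n))
  NextMethod()
}
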