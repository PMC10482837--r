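# ggplot2 visualisations: Bland-Altman agreement plots, report-vs-normal-
# range summaries, and alignment overlays of axes and joint lines on masks.

#' Bland-Altman plot of an agreement result
#'
#' @param object A `limb_agreement` (from [agreement()]).
#' @param ... Unused.
#' @return A ggplot: per-pair mean vs difference, with the bias line (solid)
#'   and 95% limits of agreement (dashed).
#' @exportS3Method ggplot2::autoplot
autoplot.limb_agreement <- function(object, ...) {
  pairs <- attr(object, "pairs")
  if (is.null(pairs)) stop("agreement object carries no pair data", call. = FALSE)
  df <- tibble::tibble(
    avg = (pairs$reference + pairs$system) / 2,
    diff = pairs$system - pairs$reference
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::labs(
      x = "Mean of reference and system",
      y = "System - reference",
      title = if (!is.na(object$label)) object$label else "Bland-Altman",
      subtitle = sprintf("bias %.3f, LoA [%.3f, %.3f]", object$mean_diff,
                         object$loa_low, object$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a measurement report against its normal ranges
#'
#' @param object A `limb_report`.
#' @param ... Unused.
#' @return A ggplot showing each flagged parameter's value (point) over its
#'   normal range (segment); abnormal values are highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.limb_report <- function(object, ...) {
  td <- tidy.limb_report(object)
  td <- td[!is.na(td$lo), ]
  td$parameter <- factor(td$parameter, levels = rev(td$parameter))
  ggplot2::ggplot(td, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$parameter),
                          linewidth = 3, colour = "grey80") +
    ggplot2::geom_point(ggplot2::aes(x = .data$value, colour = .data$normal),
                        size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "firebrick"),
                                 name = "within range") +
    ggplot2::facet_wrap(~units, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Alignment parameters (%s limb)",
                                  object$side[1])) +
    ggplot2::theme_minimal()
}

#' Overlay landmarks and axes on a mask set
#'
#' Renders the mask boundaries with the detected (or true) mechanical and
#' anatomical axes, joint orientation lines, and named landmark points, in
#' radiographic orientation.
#'
#' @param mask_set A `mask_set`.
#' @param landmarks A `landmark_set` in the same full-image frame.
#' @return A ggplot.
#' @export
plot_alignment <- function(mask_set, landmarks) {
  stopifnot(inherits(mask_set, "mask_set"), inherits(landmarks, "landmark_set"))
  bnd <- dplyr::bind_rows(lapply(names(mask_set$masks), function(cls) {
    b <- mask_boundary(mask_set$masks[[cls]])
    off <- mask_set$offsets[[cls]]
    tibble::tibble(class = cls, row = b[, 1] + off[["row"]],
                   col = b[, 2] + off[["col"]])
  }))
  lm <- landmarks
  seg <- function(a, b, what) {
    tibble::tibble(what = what, row = a[1], col = a[2],
                   row_end = b[1], col_end = b[2])
  }
  ax <- dplyr::bind_rows(
    seg(lm$head_center, lm$knee_center_femoral, "femoral mechanical"),
    seg(lm$knee_center_tibial, lm$ankle_center, "tibial mechanical"),
    seg(lm$head_center, lm$ankle_center, "hip-ankle"),
    seg(lm$femoral_condyle_lateral, lm$femoral_condyle_medial, "joint line"),
    seg(lm$plateau_lateral, lm$plateau_medial, "joint line"),
    seg(lm$plafond_lateral, lm$plafond_medial, "joint line"),
    seg(lm$head_center, lm$trochanter_tip, "proximal femoral")
  )
  pts <- dplyr::bind_rows(lapply(
    c("head_center", "head_apex", "trochanter_tip", "knee_center_femoral",
      "knee_center_tibial", "ankle_center"),
    function(nm) tibble::tibble(name = nm, row = lm[[nm]][1], col = lm[[nm]][2])))
  ggplot2::ggplot() +
    ggplot2::geom_point(data = bnd, ggplot2::aes(x = .data$col, y = .data$row),
                        size = 0.1, colour = "grey70") +
    ggplot2::geom_segment(data = ax,
                          ggplot2::aes(x = .data$col, y = .data$row,
                                       xend = .data$col_end, yend = .data$row_end,
                                       colour = .data$what),
                          linewidth = 0.5) +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$col, y = .data$row),
                        size = 1, colour = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)", colour = NULL,
                  title = sprintf("%s limb", lm$side)) +
    ggplot2::theme_minimal()
}
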