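# Pipeline orchestration and file IO: run configuration, mask-set and
# landmark readers/writers, report serialisation, and the end-to-end
# masks -> landmarks -> report runner.
#
# On-disk case layout: one directory per case holding `{side}_{class}.png`
# binary masks, a `rois.json` sidecar (per-class offsets/boxes, canvas size,
# pixel spacing, laterality), and optionally `truth_landmarks.json`,
# `truth_report.csv`, `spec.json` for phantom cases.

#' Pipeline run configuration
#'
#' Bundles every tunable of the measurement pipeline. Defaults mirror the
#' package's standard operating point: 0.48 mm/px, CLAHE tiles (8,8) with
#' clip 2.0, mid-60% shaft-axis fraction, ICC(2,1), max-Hausdorff.
#'
#' @param pixel_spacing mm/px, > 0.
#' @param side `"left"`, `"right"` or `"both"`.
#' @param canvas Phantom canvas `c(rows, cols)` in px.
#' @param clahe_block,clahe_clip CLAHE tile grid and clip limit.
#' @param shaft_fraction Central row fraction for shaft axes, in (0, 1).
#' @param icc_form `"ICC2_1"` or `"ICC3_1"`.
#' @param hd_variant `"max"` or `"p95"`.
#' @param seed Integer seed governing any phantom generation.
#' @param verbose Emit per-step timing messages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pixel_spacing = 0.48, side = "left",
                       canvas = PHANTOM_CANVAS, clahe_block = c(8, 8),
                       clahe_clip = 2, shaft_fraction = 0.6,
                       icc_form = "ICC2_1", hd_variant = "max",
                       seed = 1L, verbose = FALSE) {
  side <- match.arg(side, c("left", "right", "both"))
  stopifnot(pixel_spacing > 0, length(canvas) == 2, all(canvas > 0),
            length(clahe_block) == 2, all(clahe_block >= 1), clahe_clip > 0,
            shaft_fraction > 0, shaft_fraction < 1)
  icc_form <- match.arg(icc_form, c("ICC2_1", "ICC3_1"))
  hd_variant <- match.arg(hd_variant, c("max", "p95"))
  structure(list(pixel_spacing = pixel_spacing, side = side,
                 canvas = as.integer(canvas), clahe_block = as.integer(clahe_block),
                 clahe_clip = clahe_clip, shaft_fraction = shaft_fraction,
                 icc_form = icc_form, hd_variant = hd_variant,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Write a mask set to a case directory
#'
#' @param mask_set A `mask_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mask_set <- function(mask_set, dir) {
  stopifnot(inherits(mask_set, "mask_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rois <- list()
  for (cls in names(mask_set$masks)) {
    m <- mask_set$masks[[cls]]
    png::writePNG(m * 1, file.path(dir, paste0(mask_set$side, "_", cls, ".png")))
    off <- mask_set$offsets[[cls]]
    rois[[cls]] <- c(off["row"], off["col"], off["row"] + nrow(m),
                     off["col"] + ncol(m))
  }
  meta <- list(side = mask_set$side, pixel_spacing = mask_set$pixel_spacing,
               canvas = mask_set$canvas, rois = rois)
  jsonlite::write_json(meta, file.path(dir, "rois.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a mask set from a case directory
#'
#' @param dir Directory written by [write_mask_set()] (or laid out the same
#'   way by hand).
#' @return A `mask_set`.
#' @export
read_mask_set <- function(dir) {
  meta_path <- file.path(dir, "rois.json")
  if (!file.exists(meta_path)) {
    stop("no rois.json in ", dir, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  masks <- list(); offsets <- list()
  for (cls in names(meta$rois)) {
    path <- file.path(dir, paste0(meta$side, "_", cls, ".png"))
    if (!file.exists(path)) stop("missing mask file: ", path, call. = FALSE)
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    masks[[cls]] <- px > 0.5
    box <- as.numeric(meta$rois[[cls]])
    offsets[[cls]] <- c(row = as.integer(box[1]), col = as.integer(box[2]))
  }
  structure(list(masks = masks, offsets = offsets,
                 pixel_spacing = meta$pixel_spacing, side = meta$side,
                 canvas = as.integer(meta$canvas)),
            class = "mask_set")
}

#' Serialise a landmark set to JSON
#'
#' Points are written as `[row, col]` floats and axes as
#' `{point: [row, col], direction: [dr, dc]}` with unit directions.
#'
#' @param lm A `landmark_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  is_line <- vapply(lm, inherits, logical(1), what = "axis_line")
  pts <- lm[!is_line & vapply(lm, function(x) is.numeric(x) && length(x) == 2,
                              logical(1))]
  lines <- lapply(lm[is_line], function(l) {
    list(point = unname(l$anchor), direction = unname(l$direction))
  })
  out <- list(side = lm$side, head_radius = lm$head_radius,
              points = lapply(pts, unname), lines = lines)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landmark set from JSON
#'
#' @param path File written by [write_landmarks()].
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- function(nm) pt(j$points[[nm]][1], j$points[[nm]][2])
  l <- function(nm) axis_line(j$lines[[nm]]$point, j$lines[[nm]]$direction)
  new_landmark_set(
    head_center = p("head_center"), head_radius = j$head_radius,
    head_apex = p("head_apex"), trochanter_tip = p("trochanter_tip"),
    neck_axis = l("neck_axis"), femoral_anat_axis = l("femoral_anat_axis"),
    femoral_condyle_medial = p("femoral_condyle_medial"),
    femoral_condyle_lateral = p("femoral_condyle_lateral"),
    knee_center_femoral = p("knee_center_femoral"),
    plateau_medial = p("plateau_medial"),
    plateau_lateral = p("plateau_lateral"),
    knee_center_tibial = p("knee_center_tibial"),
    tibial_anat_axis = l("tibial_anat_axis"),
    plafond_medial = p("plafond_medial"),
    plafond_lateral = p("plafond_lateral"),
    ankle_center = p("ankle_center"),
    side = j$side
  )
}

#' Write a measurement report as CSV
#'
#' One row per parameter: `parameter, value, units, normal_range,
#' normal_flag`, values rounded to 0.01 degree / 0.01 mm, period decimal
#' separator.
#'
#' @param report A `limb_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  td <- tidy.limb_report(report)
  out <- data.frame(
    parameter = td$parameter,
    value = sprintf("%.2f", td$value),
    units = td$units,
    normal_range = ifelse(is.na(td$lo), "-", paste0(td$lo, "-", td$hi)),
    normal_flag = ifelse(is.na(td$normal), "",
                         ifelse(td$normal, "normal", "abnormal"))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ground-truth ROI bounding boxes of a mask set
#'
#' Tight boxes of each class mask in full-image coordinates (0-based,
#' half-open), usable as ground truth or as perfect self-detections for the
#' detection metric.
#'
#' @param mask_set A `mask_set`.
#' @param score Score attached to each box (for use as detections).
#' @return A tibble with `class`, `score`, `row_min`, `col_min`, `row_max`,
#'   `col_max`.
#' @export
roi_boxes <- function(mask_set, score = 1) {
  stopifnot(inherits(mask_set, "mask_set"))
  rows <- lapply(names(mask_set$masks), function(cls) {
    bb <- mask_bbox(mask_set$masks[[cls]])
    off <- mask_set$offsets[[cls]]
    tibble::tibble(class = cls, score = score,
                   row_min = bb[["row_min"]] + off[["row"]],
                   col_min = bb[["col_min"]] + off[["col"]],
                   row_max = bb[["row_max"]] + off[["row"]],
                   col_max = bb[["col_max"]] + off[["col"]])
  })
  dplyr::bind_rows(rows)
}

#' Run the measurement pipeline
#'
#' Takes masks (a `mask_set`, a `phantom_case`, or a case directory path),
#' detects landmarks, computes the sixteen-parameter report, and optionally
#' writes report CSV/JSON, landmark JSON and the mask set to `out_dir`.
#' Deterministic given the config and input; per-step wall times are
#' reported in the result (and as messages when `config$verbose`).
#'
#' @param input A `mask_set`, `phantom_case`, or directory path. With
#'   `input = NULL` a phantom is generated from `config$seed`.
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A list: `report`, `landmarks`, `timings` (named seconds),
#'   `config_hash`, and `truth` (phantom inputs only).
#' @export
run_pipeline <- function(input = NULL, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  timings <- c()
  tick <- function(nm, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    dt <- as.numeric(Sys.time() - t0, units = "secs")
    timings[[nm]] <<- dt
    if (config$verbose) message(sprintf("[%s] %.2f s", nm, dt))
    out
  }
  truth <- NULL
  masks <- tick("ingest", {
    if (is.null(input)) {
      case <- generate_phantom(sample_phantom_spec(config$seed, "normal"),
                               canvas = config$canvas)
      truth <- case$truth_report
      case$mask_set
    } else if (inherits(input, "phantom_case")) {
      truth <- input$truth_report
      input$mask_set
    } else if (inherits(input, "mask_set")) {
      input
    } else if (is.character(input) && dir.exists(input)) {
      read_mask_set(input)
    } else {
      stop("unsupported pipeline input (expected mask_set, phantom_case or ",
           "case directory)", call. = FALSE)
    }
  })
  lm <- tick("landmarks", assemble_landmarks(masks, config$shaft_fraction))
  spacing <- masks$pixel_spacing %||% config$pixel_spacing
  report <- tick("measure", compute_report(lm, spacing))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(out_dir, "report.csv"))
    jsonlite::write_json(
      c(as.list(tibble::as_tibble(report)[1, ]),
        list(normal_flags = as.list(attr(report, "normal_flags")),
             config_hash = config_hash(config))),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    write_landmarks(lm, file.path(out_dir, "landmarks.json"))
  }
  list(report = report, landmarks = lm, timings = timings,
       config_hash = config_hash(config), truth = truth)
}

#' Write a full phantom case to disk
#'
#' Masks plus `truth_landmarks.json`, `truth_report.csv` and `spec.json`.
#'
#' @param case A `phantom_case`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  write_mask_set(case$mask_set, dir)
  write_landmarks(case$truth_landmarks, file.path(dir, "truth_landmarks.json"))
  write_report(case$truth_report, file.path(dir, "truth_report.csv"))
  jsonlite::write_json(unclass(case$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Phantom-recovery self-test
#'
#' Generates `n` seeded phantoms, runs the full pipeline on each, and
#' tabulates recovered-vs-truth errors for every report parameter.
#'
#' @param n Number of phantoms.
#' @param jitter Boundary jitter sd in px applied to each case.
#' @param population Passed to [sample_phantom_spec()].
#' @param seed Base seed; case i uses `seed + i - 1`.
#' @return A tibble with one row per case and one error column per
#'   parameter, plus `seed` and `side`.
#' @export
selftest <- function(n = 10, jitter = 0, population = "normal", seed = 1L) {
  params <- setdiff(normal_ranges()$parameter, character(0))
  rows <- lapply(seq_len(n), function(i) {
    s <- seed + i - 1L
    spec <- sample_phantom_spec(s, population)
    case <- generate_phantom(spec)
    if (jitter > 0) case <- add_boundary_jitter(case, jitter, seed = s + 5000L)
    lm <- assemble_landmarks(case$mask_set)
    rep <- compute_report(lm, spec$pixel_spacing)
    errs <- vapply(params, function(p) rep[[p]] - case$truth_report[[p]],
                   numeric(1))
    tibble::as_tibble(c(list(seed = s, side = spec$side), as.list(errs)))
  })
  dplyr::bind_rows(rows)
}
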