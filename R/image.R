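# Deterministic image operators applied ahead of landmark detection:
# pad-to-square, fixed-size resize, CLAHE, ROI cropping and right-side
# horizontal flipping. Every geometric operator keeps an affine coordinate
# transform (orig = a * current + b, per axis) so points measured in any
# processed frame map back to the original full-image frame.

#' Create an image buffer
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]` (rows x cols).
#' @param offset Position `c(row, col)` of this buffer inside the full-image
#'   frame, 0-based.
#' @return An object of class `limb_image`.
#' @export
limb_image <- function(pixels, offset = c(0, 0)) {
  pixels <- as.matrix(pixels)
  if (!length(pixels)) stop("empty image buffer", call. = FALSE)
  if (any(offset < 0)) stop("offset components must be >= 0", call. = FALSE)
  structure(
    list(pixels = pixels,
         offset = c(row = as.numeric(offset[1]), col = as.numeric(offset[2])),
         transform = list(a = c(1, 1),
                          b = c(as.numeric(offset[1]), as.numeric(offset[2]))),
         flipped = FALSE),
    class = "limb_image")
}

#' @export
print.limb_image <- function(x, ...) {
  cat(sprintf("<limb_image> %d x %d px, offset (%g, %g)%s\n",
              nrow(x$pixels), ncol(x$pixels), x$offset[1], x$offset[2],
              if (x$flipped) ", flipped" else ""))
  invisible(x)
}

#' Read a grayscale image
#'
#' Reads PNG/JPEG/TIFF; colour images are converted to grayscale by channel
#' averaging (full-leg radiographs are typically gray-valued RGB).
#'
#' @param path File path.
#' @return A [limb_image()] with intensities in `[0, 1]`.
#' @export
read_gray <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) dat <- apply(dat, c(1, 2), mean)
  limb_image(t(dat))
}

#' Map points from a processed frame back to the full-image frame
#'
#' @param img A `limb_image` carrying the accumulated transform.
#' @param points Matrix (n x 2) or vector of `(row, col)` coordinates in
#'   `img`'s current frame.
#' @return Coordinates in the original full-image frame.
#' @export
map_to_full_frame <- function(img, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  a <- img$transform$a; b <- img$transform$b
  out <- cbind(a[1] * p[, 1] + b[1], a[2] * p[, 2] + b[2])
  colnames(out) <- c("row", "col")
  if (is.null(dim(points))) out[1, ] else out
}

#' Map full-frame points into the current processed frame
#'
#' Exact inverse of [map_to_full_frame()].
#' @inheritParams map_to_full_frame
#' @export
map_from_full_frame <- function(img, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  a <- img$transform$a; b <- img$transform$b
  out <- cbind((p[, 1] - b[1]) / a[1], (p[, 2] - b[2]) / a[2])
  colnames(out) <- c("row", "col")
  if (is.null(dim(points))) out[1, ] else out
}

compose_transform <- function(img, a2, b2) {
  # current frame y relates to previous frame x by x = a2 * y + b2
  a <- img$transform$a; b <- img$transform$b
  img$transform$a <- a * a2
  img$transform$b <- a * b2 + b
  img
}

#' Pad an image to a square
#'
#' Pads with a constant fill to `max(height, width)` on both axes, centring
#' the original content; the padding is recorded in the coordinate
#' transform so points map back exactly.
#'
#' @param img A `limb_image`.
#' @param fill Fill intensity (default black).
#' @return A square `limb_image`.
#' @export
pad_to_square <- function(img, fill = 0) {
  stopifnot(inherits(img, "limb_image"))
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  side <- max(nr, nc)
  if (nr == side && nc == side) return(img)
  top <- floor((side - nr) / 2)
  left <- floor((side - nc) / 2)
  out <- matrix(fill, side, side)
  out[top + seq_len(nr), left + seq_len(nc)] <- img$pixels
  img$pixels <- out
  compose_transform(img, a2 = c(1, 1), b2 = c(-top, -left))
}

#' Resize to a fixed pixel size
#'
#' Bilinear resampling via EBImage; the scale factors enter the coordinate
#' transform (pixel-centre convention) for back-mapping.
#'
#' @param img A `limb_image`.
#' @param target `c(rows, cols)` of the output.
#' @return A resized `limb_image`.
#' @export
resize_fixed <- function(img, target) {
  stopifnot(inherits(img, "limb_image"), length(target) == 2, all(target > 0))
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  eb <- EBImage::Image(t(img$pixels))
  out <- EBImage::resize(eb, w = target[2], h = target[1], filter = "bilinear")
  img$pixels <- t(EBImage::imageData(out))
  s <- c(target[1] / nr, target[2] / nc)
  compose_transform(img, a2 = 1 / s, b2 = (1 / s - 1) / 2)
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Per-tile histogram equalisation with clip-limited histograms and bilinear
#' tile interpolation (via EBImage). Dimensions that are not multiples of
#' the tile grid are padded by edge replication and cropped back, so edge
#' tiles effectively absorb the remainder pixels. Constant images are
#' returned unchanged.
#'
#' @param img A `limb_image` with intensities in `[0, 1]` (8-bit semantics).
#' @param block Tile grid `c(rows, cols)`, default `c(8, 8)`.
#' @param clip Clip limit (multiples of the uniform histogram level),
#'   default 2.
#' @return A `limb_image` with equalised intensities.
#' @export
clahe <- function(img, block = c(8, 8), clip = 2) {
  stopifnot(inherits(img, "limb_image"))
  px <- img$pixels
  if (length(dim(px)) != 2) stop("CLAHE needs a single-channel image", call. = FALSE)
  if (min(px) < 0 || max(px) > 1) {
    stop("CLAHE expects grayscale intensities in [0, 1]", call. = FALSE)
  }
  if (any(block < 1) || clip <= 0) {
    stop("block must be >= (1,1) and clip > 0", call. = FALSE)
  }
  if (diff(range(px)) == 0) return(img)
  nr <- nrow(px); nc <- ncol(px)
  pr <- (block[1] - nr %% block[1]) %% block[1]
  pc <- (block[2] - nc %% block[2]) %% block[2]
  if (pr > 0) px <- rbind(px, px[rep(nr, pr), , drop = FALSE])
  if (pc > 0) px <- cbind(px, px[, rep(nc, pc), drop = FALSE])
  eb <- EBImage::Image(t(px))
  out <- EBImage::clahe(eb, nx = block[2], ny = block[1], limit = clip)
  res <- t(EBImage::imageData(out))[seq_len(nr), seq_len(nc), drop = FALSE]
  img$pixels <- pmin(pmax(res, 0), 1)
  img
}

#' Crop a region of interest
#'
#' @param img A `limb_image`.
#' @param box `c(row_min, col_min, row_max, col_max)`, 0-based half-open, in
#'   `img`'s current frame.
#' @return A `limb_image` holding a copy of the region; its offset/transform
#'   place it at the box origin.
#' @export
crop_roi <- function(img, box) {
  stopifnot(inherits(img, "limb_image"), length(box) == 4)
  box <- as.integer(box)
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (box[1] < 0 || box[2] < 0 || box[3] > nr || box[4] > nc ||
      box[1] >= box[3] || box[2] >= box[4]) {
    stop("ROI box [", paste(box, collapse = ", "),
         ") is out of bounds for a ", nr, " x ", nc, " image", call. = FALSE)
  }
  img$pixels <- img$pixels[(box[1] + 1):box[3], (box[2] + 1):box[4], drop = FALSE]
  img$offset <- img$offset + c(box[1], box[2])
  compose_transform(img, a2 = c(1, 1), b2 = c(box[1], box[2]))
}

#' Mirror a right-side image to left orientation
#'
#' Right-side ROIs are horizontally flipped so one set of left-convention
#' detectors serves both sides; the transform un-mirrors detected
#' coordinates (a column `c` in a flipped W-wide buffer maps back to
#' `W - 1 - c`). Left-side input is returned unchanged.
#'
#' @param img A `limb_image`.
#' @param side `"left"` or `"right"`.
#' @return A `limb_image`, mirrored iff `side == "right"`.
#' @export
flip_right_to_left <- function(img, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(img, "limb_image"))
  if (side == "left") return(img)
  w <- ncol(img$pixels)
  img$pixels <- img$pixels[, w:1, drop = FALSE]
  img$flipped <- !img$flipped
  compose_transform(img, a2 = c(1, -1), b2 = c(0, w - 1))
}

#' Rescale intensities to the unit interval
#'
#' 8-bit integer input (values in 0..255) is divided by 255; unit-interval
#' input is returned unchanged. Purely an intensity operator: the coordinate
#' transform is untouched.
#'
#' @param img A `limb_image` or numeric matrix.
#' @return Same type as the input, intensities in `[0, 1]`.
#' @export
normalize_unit <- function(img) {
  px <- if (inherits(img, "limb_image")) img$pixels else img
  if (max(px) > 1) px <- px / 255
  if (inherits(img, "limb_image")) {
    img$pixels <- px
    img
  } else px
}
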