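#' Synthetic fluorescence image stack of a shortening myocyte
#'
#' Renders a bright ellipse (the dye-loaded cell) on a dark background
#' whose area follows a contraction transient dipping to
#' `(1 - peak_shortening)` of the resting area: the long semi-axis is
#' scaled by the transient (cardiomyocytes shorten lengthwise) while the
#' short axis is fixed. Intended as a ground-truth fixture for
#' [cell_area_shortening()]; write to multi-page TIFF with
#' [write_image_stack()].
#'
#' @param n_frames Number of frames.
#' @param rest_area_px Resting cell area in pixels.
#' @param peak_shortening Fractional area reduction at contraction peak, in
#'   `[0, 1)`.
#' @param dims Image height/width in pixels, `c(h, w)`.
#' @param fg,bg Foreground (cell) and background intensities in `[0, 1]`.
#' @param peak_frame Frame index of peak contraction; default mid-stack.
#' @param tau_frames Exponential relaxation time constant of the
#'   transient's decay, in frames (the upstroke is a one-frame step).
#' @param distractor If `TRUE`, adds a second, smaller bright blob so that
#'   largest-component tracking can be exercised.
#' @return A numeric array `dims[1] x dims[2] x n_frames` with values in
#'   `[0, 1]` and attribute `area_true` (pixel area per frame).
#' @export
make_shortening_stack <- function(n_frames = 40, rest_area_px = 4000,
                                  peak_shortening = 0.1, dims = c(96, 128),
                                  fg = 0.9, bg = 0.1, peak_frame = NULL,
                                  tau_frames = 6, distractor = FALSE) {
  if (peak_shortening < 0 || peak_shortening >= 1)
    stop("make_shortening_stack: peak_shortening must be in [0, 1)")
  if (is.null(peak_frame)) peak_frame <- max(2L, floor(n_frames / 2))
  # contraction transient g(t): 0 at rest, 1 at peak
  fr_idx <- seq_len(n_frames)
  g <- ifelse(fr_idx < peak_frame, 0,
              exp(-(fr_idx - peak_frame) / tau_frames))
  # ellipse with 3:1 aspect; scale long axis by (1 - ps*g)
  b0 <- sqrt(rest_area_px / (3 * pi))
  a0 <- 3 * b0
  h <- dims[1]; w <- dims[2]
  yc <- (h + 1) / 2; xc <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - yc
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - xc
  stack <- array(bg, dim = c(h, w, n_frames))
  area_true <- numeric(n_frames)
  for (f in fr_idx) {
    a <- a0 * (1 - peak_shortening * g[f])
    mask <- (xx / a)^2 + (yy / b0)^2 <= 1
    if (distractor) {
      mask2 <- ((xx - w / 3)^2 + (yy - h / 3)^2) <= (b0 / 2)^2
      mask <- mask | mask2
    }
    frame <- matrix(bg, h, w)
    frame[mask] <- fg
    stack[, , f] <- frame
    area_true[f] <- sum((xx / a)^2 + (yy / b0)^2 <= 1)
  }
  attr(stack, "area_true") <- area_true
  stack
}

#' Write / read a multi-page TIFF image stack
#'
#' Thin wrappers over the tiff package storing each frame as one page.
#'
#' @param stack A numeric array `h x w x n_frames` with values in `[0, 1]`.
#' @param path Output `.tif` path.
#' @return `write_image_stack` returns `path` invisibly; `read_image_stack`
#'   returns the array.
#' @export
write_image_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("write_image_stack: the 'tiff' package is required")
  frames <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f])
  tiff::writeTIFF(frames, path)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("read_image_stack: the 'tiff' package is required")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}

#' Cell shortening from thresholded area of a fluorescence image stack
#'
#' Each frame is thresholded to identify the myocyte; only the largest
#' connected component is kept (so bright debris does not contaminate the
#' area), its pixel area is measured, and the area timecourse is
#' normalised to the mean area over the diastolic (resting) frames.
#' Shortening is `1 - min(normalised area)`.
#'
#' The automatic threshold is the midpoint between the background and cell
#' modal intensities (medians of the two intensity populations split at
#' the range midpoint). Frames with an empty mask yield a missing value
#' with a warning.
#'
#' @param stack A numeric array `h x w x n_frames` (or a TIFF path).
#' @param threshold Intensity threshold, or `"auto"`.
#' @param diastolic_frames Indices of resting frames used for
#'   normalisation; default: frames whose area is within 1% of the maximum.
#' @return A list with `area_px`, `area_norm` (per frame), `shortening`
#'   (fraction), and `threshold` used.
#' @export
cell_area_shortening <- function(stack, threshold = "auto",
                                 diastolic_frames = NULL) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("cell_area_shortening: the 'EBImage' package is required")
  if (is.character(stack)) stack <- read_image_stack(stack)
  stopifnot(length(dim(stack)) == 3)
  n_frames <- dim(stack)[3]
  if (identical(threshold, "auto")) {
    v <- as.vector(stack)
    mid <- (min(v) + max(v)) / 2
    threshold <- (stats::median(v[v < mid]) + stats::median(v[v >= mid])) / 2
  }
  area <- rep(NA_real_, n_frames)
  for (f in seq_len(n_frames)) {
    mask <- stack[, , f] > threshold
    if (!any(mask)) {
      warning(sprintf("cell_area_shortening: empty mask in frame %d", f))
      next
    }
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(as.integer(lab[lab > 0]))
    area[f] <- max(sizes)
  }
  if (all(is.na(area)))
    stop(empty_signal_error("cell_area_shortening: all frames have empty masks"))
  if (is.null(diastolic_frames)) {
    mx <- max(area, na.rm = TRUE)
    diastolic_frames <- which(!is.na(area) & area >= 0.99 * mx)
  }
  rest_area <- mean(area[diastolic_frames], na.rm = TRUE)
  area_norm <- area / rest_area
  list(area_px = area, area_norm = area_norm,
       shortening = 1 - min(area_norm, na.rm = TRUE),
       threshold = threshold)
}
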