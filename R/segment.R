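# Image-processing stages of the counting pipeline: stack projection,
# auto-contrast, 8-bit conversion and histogram auto-thresholding.

#' Construct a two-channel field image
#'
#' @param nuclei_channel,vwf_channel 3-D arrays (height, width, n_slices) of
#'   non-negative intensities; a matrix is treated as a single slice.
#' @param pixel_size_um,z_step_um physical calibration (> 0).
#' @param field_id,slide_id,condition_id identifiers.
#' @return an object of class `field_image`.
#' @export
field_image <- function(nuclei_channel, vwf_channel, pixel_size_um, z_step_um,
                        field_id = "field1", slide_id = "slide1",
                        condition_id = "cond1") {
  as_stack <- function(x) {
    if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
    if (!is.array(x) || length(dim(x)) != 3L)
      stop("channels must be (height, width, n_slices) arrays")
    x
  }
  nuclei_channel <- as_stack(nuclei_channel)
  vwf_channel <- as_stack(vwf_channel)
  if (!identical(dim(nuclei_channel), dim(vwf_channel)))
    stop("nuclei and VWF channels must share identical dimensions")
  finite_ok <- function(x) all(is.finite(range(x)))  # no 0/1 mask allocation
  if (!finite_ok(nuclei_channel) || !finite_ok(vwf_channel))
    stop("channel intensities must be finite")
  assert_scalar(pixel_size_um, "pixel_size_um", 0, TRUE)
  assert_scalar(z_step_um, "z_step_um", 0, TRUE)
  structure(list(nuclei_channel = nuclei_channel, vwf_channel = vwf_channel,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 field_id = field_id, slide_id = slide_id,
                 condition_id = condition_id),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$nuclei_channel)
  cat(sprintf("<field_image> %s / %s / %s: %d x %d px, %d slices @ %.3g um/px\n",
              x$condition_id, x$slide_id, x$field_id, d[2], d[1], d[3],
              x$pixel_size_um))
  invisible(x)
}

#' Project a z-stack
#'
#' `max` returns the pixelwise maximum-intensity projection; `per_slice`
#' returns the list of unmodified slices (for pipelines that analyze every
#' slice separately).
#'
#' @param channel 3-D array (height, width, n_slices) or a single matrix.
#' @param mode `"max"` or `"per_slice"`.
#' @return a matrix (`max`) or list of matrices (`per_slice`).
#' @export
project_stack <- function(channel, mode = c("max", "per_slice")) {
  mode <- match.arg(mode)
  if (is.matrix(channel)) channel <- array(channel, c(dim(channel), 1L))
  stopifnot(is.array(channel), length(dim(channel)) == 3L)
  nz <- dim(channel)[3]
  if (nz == 0L) stop("empty stack")
  if (mode == "per_slice")
    return(lapply(seq_len(nz), function(s) channel[, , s]))
  out <- channel[, , 1]
  for (s in seq_len(nz)[-1]) out <- pmax(out, channel[, , s])
  out
}

#' Auto-contrast an image by percentile stretching
#'
#' Linearly rescales intensities so that the `saturated_fraction / 2` lowest
#' and highest pixels clip to 0 and 1 (the ImageJ enhance-contrast
#' convention, where the stated fraction counts both tails). The mapping is
#' order-preserving on unclipped pixels; a constant image is returned
#' unchanged.
#'
#' @param image numeric matrix.
#' @param saturated_fraction total fraction of pixels allowed to saturate,
#'   in `[0, 0.5)`. Default 0.0035 (ImageJ's 0.35%).
#' @return a matrix with values in `[0, 1]` (or the input if constant).
#' @export
auto_contrast <- function(image, saturated_fraction = 0.0035) {
  stopifnot(is.numeric(image), is.matrix(image))
  if (saturated_fraction < 0 || saturated_fraction >= 0.5)
    stop("saturated_fraction must be in [0, 0.5)")
  q <- quantile(image, c(saturated_fraction / 2, 1 - saturated_fraction / 2),
                names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    if (max(image) == min(image)) return(image)
    q <- range(image)
  }
  out <- (image - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Convert an image to 8-bit
#'
#' Linear min-max scaling to integers in `[0, 255]` with rounding; a
#' constant image maps to all zeros.
#'
#' @param image numeric matrix with finite values.
#' @return an integer matrix in `[0, 255]`.
#' @export
to_8bit <- function(image) {
  stopifnot(is.numeric(image), is.matrix(image), all(is.finite(image)))
  lo <- min(image); hi <- max(image)
  out <- if (hi == lo) {
    matrix(0L, nrow(image), ncol(image))
  } else {
    matrix(as.integer(round((image - lo) / (hi - lo) * 255)),
           nrow(image), ncol(image))
  }
  out
}

#' Automatic histogram thresholding of an 8-bit image
#'
#' `isodata` is the Ridler-Calvard iterative intermeans algorithm (the
#' isodata family behind ImageJ/FIJI's default auto-threshold): starting
#' from the midpoint of the occupied intensity range, the threshold is
#' moved to the midpoint of the two class means until it stabilizes. The
#' midpoint start makes the iteration land on the fixed point that
#' separates the two modes even when foreground pixels are rare. `otsu` maximizes the
#' between-class variance; ties are broken toward the lowest threshold. In
#' both cases the foreground mask is `image > threshold`. A constant image
#' yields an all-background mask with the constant reported as the
#' threshold.
#'
#' @param image integer matrix with values in `[0, 255]` (see [to_8bit()]).
#' @param method `"isodata"` or `"otsu"`.
#' @return a list with `threshold` (integer) and `mask` (logical matrix,
#'   `image > threshold`).
#' @export
auto_threshold <- function(image, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  v <- as.integer(image)
  if (any(is.na(v)) || any(v < 0L) || any(v > 255L))
    stop("auto_threshold expects an 8-bit image with values in [0, 255]")
  h <- as.numeric(tabulate(v + 1L, nbins = 256L))
  levels <- 0:255
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    return(list(threshold = lo,
                mask = matrix(FALSE, nrow(image), ncol(image))))
  }
  thr <- if (method == "isodata") {
    # Ridler-Calvard iterative intermeans, initialized at the midpoint of
    # the occupied dynamic range; the midpoint start selects the fixed
    # point separating the two modes even when foreground is rare
    t_cur <- floor((lo + hi) / 2)
    repeat {
      below <- h[seq_len(t_cur + 1L)]
      above <- h[(t_cur + 2L):256L]
      m0 <- if (sum(below) > 0) sum(below * 0:t_cur) / sum(below) else 0
      m1 <- if (sum(above) > 0) {
        sum(above * (t_cur + 1L):255L) / sum(above)
      } else 255
      t_new <- floor((m0 + m1) / 2)
      if (t_new == t_cur) break
      t_cur <- t_new
    }
    t_cur
  } else {
    n <- sum(h)
    w0 <- cumsum(h)[1:255]              # class sizes for t = 0..254
    mu0 <- cumsum(h * levels)[1:255]
    w1 <- n - w0
    muT <- sum(h * levels)
    valid <- w0 > 0 & w1 > 0
    bcv <- rep(-Inf, 255)
    bcv[valid] <- (muT * w0[valid] - n * mu0[valid])^2 /
      (w0[valid] * w1[valid])           # proportional to w0 w1 (m0 - m1)^2
    which.max(bcv) - 1L                 # first maximum = lowest threshold
  }
  list(threshold = as.integer(thr), mask = image > thr)
}
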