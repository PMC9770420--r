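# Synthetic field rendering: object placement and channel rasterization.
#
# Coordinates: (y, x) = (row, col), 0-based pixel centers, so a rendered
# object's true centroid is directly comparable with particle centroids
# measured by the segmentation module.

# --- placement ---------------------------------------------------------------

# Object z-centers sit away from the stack faces when the stack allows it;
# degenerate one- or two-slice stacks fall back to the full slice range.
draw_z_centers <- function(n, n_slices) {
  if (n_slices >= 3) runif(n, 1.5, n_slices - 0.5)
  else runif(n, 1, n_slices)
}

# Nuclei are placed on a jittered grid: one nucleus per randomly chosen grid
# cell, with radii capped so the footprint plus the separation margin fits
# inside the cell. This guarantees non-overlap up to high packing fractions
# and mimics how contact-inhibited cells pack at confluence (nuclei in dense
# fields are drawn at the smaller end of the radius range).
place_nuclei <- function(spec) {
  n <- spec$nucleus_count
  empty <- data.frame(y_px = numeric(0), x_px = numeric(0), a_px = numeric(0),
                      b_px = numeric(0), orientation_rad = numeric(0),
                      z_center = numeric(0))
  if (n == 0L) return(empty)
  H <- spec$field_height_px; W <- spec$field_width_px
  px <- spec$pixel_size_um
  rmin <- spec$nucleus_radius_um[1] / px
  rmax <- spec$nucleus_radius_um[2] / px
  margin <- spec$nucleus_separation_um / px

  ky <- ceiling(sqrt(n * H / W))
  kx <- ceiling(n / ky)
  while (kx * ky < n) kx <- kx + 1L
  cell_h <- H / ky
  cell_w <- W / kx
  avail <- min(cell_h, cell_w) / 2 - margin / 2
  if (avail < rmin)
    stop(sprintf(paste0("cannot place %d nuclei of radius >= %.3g um in a ",
                        "%d x %d px field without overlap"),
                 n, spec$nucleus_radius_um[1], W, H))

  cells <- sample.int(kx * ky, n)
  ci <- (cells - 1L) %% kx        # grid column
  ri <- (cells - 1L) %/% kx       # grid row
  a <- pmin(runif(n, rmin, rmax), avail)
  b <- pmin(runif(n, rmin, rmax), avail)
  theta <- runif(n, 0, pi)
  m <- pmax(a, b)
  jy <- pmax(cell_h / 2 - margin / 2 - m, 0)
  jx <- pmax(cell_w / 2 - margin / 2 - m, 0)
  cy <- (ri + 0.5) * cell_h - 0.5 + runif(n, -1, 1) * jy
  cx <- (ci + 0.5) * cell_w - 0.5 + runif(n, -1, 1) * jx
  zmid <- (spec$n_slices + 1) / 2
  zc <- runif(n, zmid - 1.5, zmid + 1.5)
  data.frame(y_px = cy, x_px = cx, a_px = a, b_px = b,
             orientation_rad = theta, z_center = zc)
}

# WPB rods: rejection sampling of capsule core segments with a minimum
# surface-to-surface clearance (min_separation_um) against all previously
# accepted rods.
place_wpbs <- function(spec) {
  n <- spec$wpb_count
  empty <- data.frame(y_px = numeric(0), x_px = numeric(0),
                      length_px = numeric(0), width_px = numeric(0),
                      orientation_rad = numeric(0), z_center = numeric(0))
  if (n == 0L) return(empty)
  H <- spec$field_height_px; W <- spec$field_width_px
  px <- spec$pixel_size_um
  margin <- spec$min_separation_um / px
  len <- runif(n, spec$wpb_length_um[1], spec$wpb_length_um[2]) / px
  hw <- runif(n, spec$wpb_width_um[1], spec$wpb_width_um[2]) / 2 / px
  half <- pmax(len / 2 - hw, 0)
  zc <- draw_z_centers(n, spec$n_slices)

  P1 <- matrix(NA_real_, n, 2)
  P2 <- matrix(NA_real_, n, 2)
  HW <- numeric(n)
  HALF <- numeric(n)
  ok <- 0L
  for (i in seq_len(n)) {
    ext <- len[i] / 2 + margin
    if (2 * ext >= min(H, W))
      stop(sprintf("WPB of length %.3g um does not fit in the field",
                   len[i] * px))
    placed <- FALSE
    for (try in seq_len(spec$max_place_retries)) {
      th <- runif(1, 0, pi)
      cy <- runif(1, ext - 0.5, H - 0.5 - ext)
      cx <- runif(1, ext - 0.5, W - 0.5 - ext)
      u <- c(sin(th), cos(th))
      p1 <- c(cy, cx) - half[i] * u
      p2 <- c(cy, cx) + half[i] * u
      if (ok > 0L) {
        idx <- seq_len(ok)
        clear <- hw[i] + HW[idx] + margin
        reach <- half[i] + HALF[idx] + clear
        cyx <- (P1[idx, , drop = FALSE] + P2[idx, , drop = FALSE]) / 2
        near <- which(abs(cyx[, 1] - cy) <= reach & abs(cyx[, 2] - cx) <= reach)
        if (length(near)) {
          d <- min_dist_segment_to_segments(
            p1, p2, P1[near, , drop = FALSE], P2[near, , drop = FALSE])
          if (any(d < clear[near])) next
        }
      }
      ok <- ok + 1L
      P1[ok, ] <- p1
      P2[ok, ] <- p2
      HW[ok] <- hw[i]
      HALF[ok] <- half[i]
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(paste0("could not place WPB %d of %d after %d retries: ",
                          "requested density exceeds placement capacity"),
                   i, n, spec$max_place_retries))
  }
  ctr <- (P1 + P2) / 2
  data.frame(y_px = ctr[, 1], x_px = ctr[, 2], length_px = len,
             width_px = 2 * hw, orientation_rad = atan2(
               (P2[, 1] - P1[, 1]), (P2[, 2] - P1[, 2])) %% pi,
             z_center = zc)
}

# Immature vesicles: small discs, non-overlapping against rods and each other.
place_immature <- function(spec, wpbs) {
  n <- spec$immature_count
  empty <- data.frame(y_px = numeric(0), x_px = numeric(0),
                      radius_px = numeric(0), z_center = numeric(0))
  if (n == 0L) return(empty)
  H <- spec$field_height_px; W <- spec$field_width_px
  px <- spec$pixel_size_um
  margin <- spec$min_separation_um / px
  r <- runif(n, spec$immature_radius_um[1], spec$immature_radius_um[2]) / px
  zc <- draw_z_centers(n, spec$n_slices)

  nw <- nrow(wpbs)
  if (nw > 0L) {
    u <- cbind(sin(wpbs$orientation_rad), cos(wpbs$orientation_rad))
    half <- pmax(wpbs$length_px / 2 - wpbs$width_px / 2, 0)
    A <- cbind(wpbs$y_px, wpbs$x_px) - half * u
    B <- cbind(wpbs$y_px, wpbs$x_px) + half * u
    whw <- wpbs$width_px / 2
  }
  cy <- numeric(n); cx <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    ext <- r[i] + margin
    for (try in seq_len(spec$max_place_retries)) {
      y <- runif(1, ext - 0.5, H - 0.5 - ext)
      x <- runif(1, ext - 0.5, W - 0.5 - ext)
      if (nw > 0L) {
        d <- dist_point_to_segments(c(y, x), A, B)
        if (any(d < r[i] + whw + margin)) next
      }
      if (i > 1L) {
        j <- seq_len(i - 1L)
        if (any(sqrt((cy[j] - y)^2 + (cx[j] - x)^2) < r[i] + r[j] + margin))
          next
      }
      cy[i] <- y; cx[i] <- x
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(paste0("could not place immature vesicle %d of %d after ",
                          "%d retries: requested density exceeds placement ",
                          "capacity"), i, n, spec$max_place_retries))
  }
  data.frame(y_px = cy, x_px = cx, radius_px = r, z_center = zc)
}

# --- rasterization -----------------------------------------------------------

# Each patch is a small intensity matrix plus the R row/col indices it covers.
# Intensity is peak-normalized: the in-focus centerline of an object is ~1.
# sigma = 0 gives hard-edged indicator footprints (used by ground-truth
# oracles and footprint-area tests).

patch_window <- function(c0, extent, limit) {
  lo <- max(floor(c0 - extent), 0)
  hi <- min(ceiling(c0 + extent), limit - 1)
  lo:hi
}

patch_ellipse <- function(cy, cx, a, b, theta, sigma, H, W) {
  pad <- 3 * sigma + 1
  rows <- patch_window(cy, max(a, b) + pad, H)
  cols <- patch_window(cx, max(a, b) + pad, W)
  dy <- rows - cy
  dx <- cols - cx
  U <- outer(dy, dx, function(y, x) y * sin(theta) + x * cos(theta))
  V <- outer(dy, dx, function(y, x) y * cos(theta) - x * sin(theta))
  rn <- sqrt((U / a)^2 + (V / b)^2)
  d <- (rn - 1) * min(a, b)           # approximate signed distance, px
  I <- if (sigma > 0) stats::pnorm(-d / sigma) else (d <= 0) * 1
  list(rows = rows + 1L, cols = cols + 1L, I = I)
}

patch_capsule <- function(cy, cx, half, hwidth, theta, sigma, H, W) {
  pad <- 3 * sigma + 1
  ext <- half + hwidth + pad
  rows <- patch_window(cy, ext, H)
  cols <- patch_window(cx, ext, W)
  dy <- rows - cy
  dx <- cols - cx
  U <- outer(dy, dx, function(y, x) y * sin(theta) + x * cos(theta))
  V <- outer(dy, dx, function(y, x) y * cos(theta) - x * sin(theta))
  dseg <- sqrt(pmax(abs(U) - half, 0)^2 + V^2)
  I <- if (sigma > 0) {
    stats::pnorm((hwidth - dseg) / sigma) / stats::pnorm(hwidth / sigma)
  } else (dseg <= hwidth) * 1
  list(rows = rows + 1L, cols = cols + 1L, I = pmin(I, 1))
}

patch_disc <- function(cy, cx, r, sigma, H, W) {
  patch_capsule(cy, cx, 0, r, 0, sigma, H, W)
}

# Gaussian axial weight of an object centered at z_center (slice units)
z_weights <- function(n_slices, z_center, z_sigma_um, z_step_um) {
  exp(-(((seq_len(n_slices) - z_center) * z_step_um)^2) / (2 * z_sigma_um^2))
}

# Accumulate a list of patches (each: rows, cols, I, zw) into a stack in a
# single call, so the (potentially large) array is copied once, not once
# per object.
accumulate_patches <- function(arr, patches, keep = 0.005) {
  for (p in patches) {
    ss <- which(p$zw > keep)
    if (!length(ss)) next
    # one indexed assignment per object: patch (x) z-profile outer product;
    # as.vector avoids dim mismatches when an index has extent 1
    arr[p$rows, p$cols, ss] <- arr[p$rows, p$cols, ss] +
      as.vector(outer(p$I, p$zw[ss]))
  }
  arr
}

#' Render a synthetic two-channel field with ground truth
#'
#' Generates one imaged location: a nuclei channel (filled ellipses) and a
#' VWF channel (capsule-shaped WPB rods plus small immature discs), each as a
#' z-stack in which every object is brightest at its own `z_center` slice
#' with Gaussian axial fall-off. Objects are placed without overlap (see
#' [scene_spec()] for the separation margins); additive background and
#' per-slice Gaussian noise complete the model, and intensities are clamped
#' at zero. Rendering is fully deterministic given the spec (seed included).
#'
#' @param spec a [scene_spec()].
#' @param field_id,slide_id,condition_id identifiers attached to the image.
#' @return a list with elements `image` (a `field_image`: channels
#'   `nuclei_channel` and `vwf_channel`, arrays of dim (height, width,
#'   n_slices), plus calibration) and `truth` (a `ground_truth`: data frames
#'   `nuclei`, `wpbs`, `immature` holding the exact object inventory in
#'   0-based pixel coordinates).
#' @examples
#' sc <- scene_spec(field_width_px = 128, field_height_px = 128,
#'                  pixel_size_um = 0.25, nucleus_count = 2, wpb_count = 5,
#'                  seed = 1)
#' f <- render_field(sc)
#' dim(f$image$vwf_channel)
#' nrow(f$truth$wpbs)
#' @export
render_field <- function(spec, field_id = "field1", slide_id = "slide1",
                         condition_id = "cond1") {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$field_height_px; W <- spec$field_width_px; Z <- spec$n_slices
  px <- spec$pixel_size_um
  sigma <- spec$psf_sigma_um / px

  out <- withr::with_seed(spec$seed, {
    nuclei <- place_nuclei(spec)
    wpbs <- place_wpbs(spec)
    imm <- place_immature(spec, wpbs)

    nuc_patches <- lapply(seq_len(nrow(nuclei)), function(i) {
      p <- patch_ellipse(nuclei$y_px[i], nuclei$x_px[i], nuclei$a_px[i],
                         nuclei$b_px[i], nuclei$orientation_rad[i], sigma,
                         H, W)
      p$zw <- z_weights(Z, nuclei$z_center[i], spec$nucleus_z_sigma_um,
                        spec$z_step_um)
      p
    })
    nuc_ch <- accumulate_patches(array(spec$background_level, c(H, W, Z)),
                                 nuc_patches)

    vwf_patches <- c(
      lapply(seq_len(nrow(wpbs)), function(i) {
        half <- max(wpbs$length_px[i] / 2 - wpbs$width_px[i] / 2, 0)
        p <- patch_capsule(wpbs$y_px[i], wpbs$x_px[i], half,
                           wpbs$width_px[i] / 2, wpbs$orientation_rad[i],
                           sigma, H, W)
        p$zw <- z_weights(Z, wpbs$z_center[i], spec$z_sigma_um,
                          spec$z_step_um)
        p
      }),
      lapply(seq_len(nrow(imm)), function(i) {
        p <- patch_disc(imm$y_px[i], imm$x_px[i], imm$radius_px[i], sigma,
                        H, W)
        p$zw <- z_weights(Z, imm$z_center[i], spec$z_sigma_um, spec$z_step_um)
        p
      }))
    vwf_ch <- accumulate_patches(array(spec$background_level, c(H, W, Z)),
                                 vwf_patches)

    if (spec$noise_sd > 0) {
      for (s in seq_len(Z)) {
        v <- nuc_ch[, , s] + rnorm(H * W, 0, spec$noise_sd)
        v[v < 0] <- 0
        nuc_ch[, , s] <- v
        v <- vwf_ch[, , s] + rnorm(H * W, 0, spec$noise_sd)
        v[v < 0] <- 0
        vwf_ch[, , s] <- v
      }
    }
    list(nuclei = nuclei, wpbs = wpbs, immature = imm,
         nuc_ch = nuc_ch, vwf_ch = vwf_ch)
  })

  image <- field_image(out$nuc_ch, out$vwf_ch, pixel_size_um = px,
                       z_step_um = spec$z_step_um, field_id = field_id,
                       slide_id = slide_id, condition_id = condition_id)
  truth <- structure(list(nuclei = out$nuclei, wpbs = out$wpbs,
                          immature = out$immature, spec = spec),
                     class = "ground_truth")
  list(image = image, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d nuclei, %d WPBs, %d immature vesicles\n",
              nrow(x$nuclei), nrow(x$wpbs), nrow(x$immature)))
  invisible(x)
}
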