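#' Average an image stack over frames
#'
#' @param stack An [image_stack()] (or a bare 3-D array).
#' @return A 2-D matrix of per-pixel means.
#' @export
average_stack <- function(stack) {
  data <- if (inherits(stack, "image_stack")) stack$data else stack
  stopifnot(is.array(data), length(dim(data)) == 3L, dim(data)[1] >= 1L)
  colMeans(matrix(data, nrow = dim(data)[1]), dims = 1) |>
    matrix(nrow = dim(data)[2], ncol = dim(data)[3])
}

# Separable Gaussian blur with replicate padding; unlike EBImage::gblur it
# supports kernels larger than the image (needed for the wide background
# sigma of the difference-of-Gaussians bandpass on small fields).
.gblur_mat <- function(m, sigma) {
  if (is.null(sigma) || sigma <= 0) return(m)
  half <- ceiling(3 * sigma)
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    stats::convolve(vp, rev(k), type = "filter")
  }
  m <- apply(m, 2, conv1)          # along rows (each column vector)
  t(apply(m, 1, conv1))            # along cols
}

# 8-connected component labeling by BFS (row, col) matrix in, label matrix out.
.label8 <- function(fg) {
  lab <- matrix(0L, nrow(fg), ncol(fg))
  nr <- nrow(fg); nc <- ncol(fg)
  k <- 0L
  off <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  for (start in which(fg)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue) > 0L) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r0 <- (p - 1L) %% nr + 1L
      c0 <- (p - 1L) %/% nr + 1L
      r <- r0 + off[, 1]; c <- c0 + off[, 2]
      ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
      q <- (c[ok] - 1L) * nr + r[ok]
      q <- q[fg[q] & lab[q] == 0L]
      lab[q] <- k
      queue <- c(queue, q)
    }
  }
  lab
}

#' Segment diffraction-limited particles
#'
#' The image is bandpass filtered with a difference of Gaussians (removing
#' camera noise and slow background modulation), blurred, and thresholded at
#' `threshold_frac` (default 2%) of the background, where the background is
#' the median of the whole input image. Foreground pixels are grouped into
#' 8-connected components; components smaller than `min_px` pixels are
#' dropped. Thresholding is invariant to rescaling the image by any c > 0.
#'
#' @param image 2-D numeric matrix, finite.
#' @param bandpass_sigmas Difference-of-Gaussians sigmas `c(low, high)` in
#'   px; `NULL` disables the bandpass (pure median thresholding).
#' @param blur_sigma_px Gaussian blur applied before thresholding (> 0, or
#'   `NULL`/0 to skip).
#' @param threshold_frac Foreground criterion: filtered intensity above
#'   background exceeding this fraction of the background median.
#' @param min_px Minimum particle size in pixels.
#' @return A list of particle masks; each is a list with `pixels` (matrix of
#'   (row, col)), `background_level` (image median), and `boundary`
#'   (outline pixels, 4-neighborhood erosion definition).
#' @export
segment_particles <- function(image, bandpass_sigmas = c(1, 20),
                              blur_sigma_px = 1, threshold_frac = 0.02,
                              min_px = 3) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (!is.null(blur_sigma_px) && blur_sigma_px < 0)
    stop("non-positive blur sigma")
  bg <- stats::median(image)
  filt <- image - bg
  if (!is.null(bandpass_sigmas)) {
    filt <- .gblur_mat(image, bandpass_sigmas[1]) -
      .gblur_mat(image, bandpass_sigmas[2])
  }
  if (!is.null(blur_sigma_px) && blur_sigma_px > 0)
    filt <- .gblur_mat(filt, blur_sigma_px)
  fg <- filt > threshold_frac * bg & filt > 0
  lab <- .label8(fg)
  out <- list()
  if (max(lab) > 0) {
    for (k in seq_len(max(lab))) {
      px <- which(lab == k, arr.ind = TRUE)
      if (nrow(px) < min_px) next
      out[[length(out) + 1L]] <-
        list(pixels = unname(px), background_level = bg,
             boundary = .mask_boundary(px, dim(image)))
    }
  }
  out
}

# Boundary = mask pixels with at least one 4-neighbor outside the mask.
.mask_boundary <- function(px, dims) {
  inmask <- matrix(FALSE, dims[1], dims[2])
  inmask[px] <- TRUE
  on_bd <- logical(nrow(px))
  for (i in seq_len(nrow(px))) {
    r <- px[i, 1]; c <- px[i, 2]
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2]
    on_bd[i] <- any(!ok) || any(!inmask[nb[ok, , drop = FALSE]])
  }
  unname(px[on_bd, , drop = FALSE])
}

#' Particle length by boundary thinning
#'
#' The mask is thinned to a one-pixel-wide skeleton and the length is the
#' longest geodesic path along it, counting 8-connectivity step distances
#' (1 px axial, sqrt(2) px diagonal), converted to nm. A single-pixel
#' skeleton has length 0. The total skeleton length (sum over all skeleton
#' edges) is returned as an attribute `"total_nm"`.
#'
#' @param mask A particle mask from [segment_particles()], or a logical
#'   matrix.
#' @param pixel_size_nm Pixel pitch in nm (default 107.2).
#' @return Length in nm.
#' @export
particle_length <- function(mask, pixel_size_nm = 107.2) {
  bin <- .mask_to_matrix(mask)
  if (sum(bin) == 0L) stop("mask non-empty required")
  skel <- thin_binary(bin)
  len <- skeleton_longest_path(skel) * pixel_size_nm
  attr(len, "total_nm") <- skeleton_total_length(skel) * pixel_size_nm
  len
}

.mask_to_matrix <- function(mask) {
  if (is.matrix(mask) && (is.logical(mask) || all(mask %in% c(0, 1))))
    return(mask != 0)
  px <- mask$pixels
  stopifnot(is.matrix(px), nrow(px) >= 1L)
  # crop to bounding box with 1 px pad
  r <- px[, 1] - min(px[, 1]) + 2L
  c <- px[, 2] - min(px[, 2]) + 2L
  bin <- matrix(FALSE, max(r) + 1L, max(c) + 1L)
  bin[cbind(r, c)] <- TRUE
  bin
}

#' Moment-based particle length
#'
#' Sub-pixel apparent length from intensity second moments: for a line
#' segment of length L convolved with an isotropic Gaussian PSF, the
#' principal second moments of the background-subtracted intensity are
#' `lambda1 = L^2/12 + sigma^2` and `lambda2 = sigma^2`, so
#' `L = sqrt(12 (lambda1 - lambda2))` — self-calibrating against the PSF
#' width. For isotropic (blob-like) particles the estimate is ~0. This
#' measure resolves lengths well below the pixel-quantized skeleton measure
#' of [particle_length()], whose thinning step erodes about one pixel per
#' rounded end (see the methods vignette for the bias characterization).
#'
#' @param mask A particle mask from [segment_particles()].
#' @param image The 2-D image the mask was segmented from.
#' @param pixel_size_nm Pixel pitch in nm (default 107.2).
#' @return Length in nm.
#' @export
moment_length <- function(mask, image, pixel_size_nm = 107.2) {
  px <- mask$pixels
  w <- pmax(image[px] - mask$background_level, 0)
  if (sum(w) <= 0) return(0)
  mu <- c(sum(px[, 1] * w), sum(px[, 2] * w)) / sum(w)
  cxx <- sum(w * (px[, 1] - mu[1])^2) / sum(w)
  cyy <- sum(w * (px[, 2] - mu[2])^2) / sum(w)
  cxy <- sum(w * (px[, 1] - mu[1]) * (px[, 2] - mu[2])) / sum(w)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE,
              only.values = TRUE)$values
  sqrt(max(12 * (ev[1] - ev[2]), 0)) * pixel_size_nm
}

#' Signal-to-background corrected particle intensity
#'
#' Per-pixel SBR = (intensity - background) / background, summed over the
#' particle's pixels; the background is the median of the whole image
#' (carried by the mask). Additive over disjoint masks.
#'
#' @param mask A particle mask from [segment_particles()].
#' @param image The 2-D image the mask was segmented from.
#' @return Corrected intensity (dimensionless).
#' @export
sbr_intensity <- function(mask, image) {
  bg <- mask$background_level
  if (is.null(bg) || bg <= 0) stop("undefined SBR: background level is 0")
  vals <- image[mask$pixels]
  sum((vals - bg) / bg)
}

#' Per-field particle summary
#'
#' @param particles List of particle masks from [segment_particles()], or a
#'   numeric vector of lengths in nm.
#' @param pixel_size_nm Pixel pitch for length measurement.
#' @param breaks_nm Histogram bin edges; the defaults include the 500 and
#'   1000 nm thresholds used for aggregate size classification.
#' @return A list with `count`, `mean_length_nm` (NA when no particles),
#'   `lengths_nm`, and `histogram` (data frame of bin, count, fraction).
#' @export
field_summary <- function(particles, pixel_size_nm = 107.2,
                          breaks_nm = c(0, 500, 1000, Inf)) {
  lengths <- if (is.numeric(particles)) particles
  else vapply(particles, function(m) as.numeric(particle_length(m, pixel_size_nm)),
              numeric(1))
  n <- length(lengths)
  cuts <- cut(lengths, breaks = breaks_nm, right = FALSE)
  counts <- as.integer(table(cuts))
  list(count = n,
       mean_length_nm = if (n > 0) mean(lengths) else NA_real_,
       lengths_nm = lengths,
       histogram = data.frame(bin = levels(cuts), count = counts,
                              fraction = if (n > 0) counts / n else
                                rep(NA_real_, length(counts))))
}

#' Analyze a diffraction-limited image stack
#'
#' Convenience wrapper: average the stack, segment particles, and measure
#' per-particle lengths and SBR-corrected intensities.
#'
#' @param stack An [image_stack()].
#' @param config An [analysis_config()].
#' @return A list with `particles` (data frame: length_nm, total_skeleton_nm,
#'   corrected_intensity, n_pixels) and `summary` (from [field_summary()]).
#' @export
dl_analyze <- function(stack, config = analysis_config()) {
  img <- average_stack(stack)
  p <- config$dl
  masks <- segment_particles(img, bandpass_sigmas = p$bandpass_sigmas,
                             blur_sigma_px = p$blur_sigma_px,
                             threshold_frac = p$threshold_frac,
                             min_px = p$min_px)
  ps <- stack$pixel_size_nm
  if (length(masks) == 0L) {
    tab <- data.frame(length_nm = numeric(), length_moment_nm = numeric(),
                      total_skeleton_nm = numeric(),
                      corrected_intensity = numeric(), n_pixels = integer())
  } else {
    lens <- lapply(masks, particle_length, pixel_size_nm = ps)
    tab <- data.frame(
      length_nm = vapply(lens, as.numeric, numeric(1)),
      length_moment_nm = vapply(masks, moment_length, numeric(1),
                                image = img, pixel_size_nm = ps),
      total_skeleton_nm = vapply(lens, function(l) attr(l, "total_nm"),
                                 numeric(1)),
      corrected_intensity = vapply(masks, sbr_intensity, numeric(1),
                                   image = img),
      n_pixels = vapply(masks, function(m) nrow(m$pixels), integer(1)))
  }
  list(particles = tab,
       summary = field_summary(tab$length_moment_nm, pixel_size_nm = ps,
                               breaks_nm = p$length_breaks_nm))
}
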