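#' Fourier ring correlation resolution estimate
#'
#' Localizations are split randomly into two half-datasets, each half is
#' rendered into a count histogram on a common grid, and the Fourier ring
#' correlation curve FRC(q) (ring-averaged normalized cross-spectrum of the
#' two half-images) is computed with single-frequency-bin rings. The image
#' resolution is 1 / q* where q* is the first spatial frequency at which the
#' curve drops below the 1/7 threshold (linearly interpolated between
#' adjacent bins); if the curve never crosses, the resolution is reported as
#' not determined (`NA`).
#'
#' @param locs A [localization_table()] with at least 2 rows.
#' @param pixel_nm Rendering pixel size in nm (default 10).
#' @param split_seed Seed for the random half-split (determinism).
#' @param threshold Crossing threshold (default 1/7).
#' @param halves Optional list of two pre-rendered half-images (matrices of
#'   equal size), overriding the split-and-render step; used e.g. to verify
#'   that an image correlated with itself gives FRC = 1 at all frequencies.
#' @return An object of class `frc_result`: list with `curve` (data frame:
#'   freq_inv_nm, frc), `resolution_nm` (NA if not determined),
#'   `determined`, and `threshold`.
#' @export
frc_resolution <- function(locs, pixel_nm = 10, split_seed = 1,
                           threshold = 1 / 7, halves = NULL) {
  if (is.null(halves)) {
    if (nrow(locs) < 2L) stop("fewer than 2 localizations")
    ext <- c(min(locs$x_nm), max(locs$x_nm) + pixel_nm,
             min(locs$y_nm), max(locs$y_nm) + pixel_nm)
    half <- with_seed(split_seed,
                      sample(c(TRUE, FALSE), nrow(locs), replace = TRUE))
    h1 <- render_superres(locs[half, , drop = FALSE], pixel_nm, extent_nm = ext)
    h2 <- render_superres(locs[!half, , drop = FALSE], pixel_nm, extent_nm = ext)
    # pad to a common square for isotropic rings
    n <- max(dim(h1))
    pad <- function(m) {
      out <- matrix(0, n, n)
      out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
      out
    }
    h1 <- pad(h1); h2 <- pad(h2)
  } else {
    h1 <- halves[[1]]; h2 <- halves[[2]]
    stopifnot(is.matrix(h1), all(dim(h1) == dim(h2)))
    n <- max(dim(h1))
    if (nrow(h1) != ncol(h1)) {
      pad <- function(m) {
        out <- matrix(0, n, n)
        out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
        out
      }
      h1 <- pad(h1); h2 <- pad(h2)
    }
  }
  f1 <- stats::fft(h1)
  f2 <- stats::fft(h2)
  # integer frequency coordinates with wrap-around
  k <- ((0:(n - 1) + n %/% 2) %% n) - n %/% 2
  kr <- matrix(k, n, n)
  kc <- matrix(k, n, n, byrow = TRUE)
  ring <- pmin(as.integer(round(sqrt(kr^2 + kc^2))), n)  # bin index
  num <- Re(f1 * Conj(f2))
  d1 <- Mod(f1)^2
  d2 <- Mod(f2)^2
  nbins <- n %/% 2
  sums_num <- vapply(0:(nbins - 1), function(r) sum(num[ring == r]), numeric(1))
  sums_d1 <- vapply(0:(nbins - 1), function(r) sum(d1[ring == r]), numeric(1))
  sums_d2 <- vapply(0:(nbins - 1), function(r) sum(d2[ring == r]), numeric(1))
  denom <- sqrt(sums_d1 * sums_d2)
  frc <- ifelse(denom > 0, sums_num / denom, 0)
  freq <- (0:(nbins - 1)) / (n * pixel_nm)   # cycles per nm
  below <- which(frc < threshold)
  below <- below[below > 1]   # ignore the zero-frequency bin
  if (length(below) == 0L) {
    res <- NA_real_; determined <- FALSE
  } else {
    i <- below[1]
    # linear interpolation between bin i-1 (above) and bin i (below)
    f0 <- frc[i - 1]; f1v <- frc[i]
    q <- freq[i - 1] + (f0 - threshold) / (f0 - f1v) * (freq[i] - freq[i - 1])
    res <- 1 / q; determined <- TRUE
  }
  structure(list(curve = data.frame(freq_inv_nm = freq, frc = frc),
                 resolution_nm = res, determined = determined,
                 threshold = threshold),
            class = "frc_result")
}

#' @export
print.frc_result <- function(x, ...) {
  cat("Fourier ring correlation:",
      if (x$determined) sprintf("resolution %.1f nm", x$resolution_nm)
      else "resolution not determined (no crossing)",
      sprintf("(threshold %.3f)\n", x$threshold))
  invisible(x)
}

#' @export
plot.frc_result <- function(x, ...) {
  graphics::plot(x$curve$freq_inv_nm, x$curve$frc, type = "l",
                 xlab = "spatial frequency (1/nm)", ylab = "FRC", ...)
  graphics::abline(h = x$threshold, lty = 2)
  if (x$determined) graphics::abline(v = 1 / x$resolution_nm, lty = 3)
  invisible(x)
}
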