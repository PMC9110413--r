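#' Image stack container
#'
#' A 3-D intensity array (frame, row, col) with acquisition metadata.
#' Coordinate convention used throughout the package: x = column, y = row,
#' both in nm with the origin at the center of pixel (1, 1); frames are
#' 0-based; the time of frame f is `f * frame_interval_ms`.
#'
#' @param data Numeric array, dim (frames, rows, cols), all finite and >= 0,
#'   or a matrix (interpreted as a single frame).
#' @param pixel_size_nm Length of one pixel in nm (default 107.2).
#' @param frame_interval_ms Time between frames in ms.
#' @param channel_label Free-text channel description.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_nm = 107.2, frame_interval_ms = 20,
                        channel_label = "") {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a (frame, row, col) array")
  if (dim(data)[1] < 1L) stop("zero frames")
  if (!all(is.finite(data)) || any(data < 0))
    stop("intensities must be finite and >= 0")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be > 0")
  if (!is.numeric(frame_interval_ms) || frame_interval_ms <= 0)
    stop("frame_interval_ms must be > 0")
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 frame_interval_ms = frame_interval_ms,
                 channel_label = channel_label),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d frame(s) of %d x %d px (%.1f nm/px, %g ms/frame)%s\n",
              d[1], d[2], d[3], x$pixel_size_nm, x$frame_interval_ms,
              if (nzchar(x$channel_label)) paste0(" [", x$channel_label, "]") else ""))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Read a multi-page TIFF as an image stack
#'
#' Pixel values are returned as stored (16-bit integer TIFFs read back as
#' integer counts). Metadata absent from the file is filled from `config`.
#'
#' @param path Path to a TIFF file.
#' @param config An [analysis_config()] supplying default metadata.
#' @param channel_label Channel description.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, config = analysis_config(),
                             channel_label = "") {
  if (!file.exists(path)) stop("missing file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable stack: ", path))
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("unreadable stack: zero frames in ", path)
  if (!all(vapply(pages, is.matrix, logical(1))))
    stop("unreadable stack: non-raster content in ", path)
  data <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) data[f, , ] <- pages[[f]]
  image_stack(data,
              pixel_size_nm = config$imaging$pixel_size_nm,
              frame_interval_ms = config$imaging$frame_interval_ms,
              channel_label = channel_label)
}

#' Write an image stack to a multi-page 16-bit TIFF
#'
#' Intensities are rounded and clamped to the 16-bit range; integer-valued
#' stacks within range round-trip bit-identically through
#' [read_image_stack()].
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(dim(stack$data)[1]), function(f) {
    m <- pmin(pmax(round(stack$data[f, , ]), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Localization table container
#'
#' Per-emission-event records feeding the SMLM pipeline. One row is one
#' localization: a 2D-Gaussian fit of a fluorescence signal in one frame.
#'
#' @param frame 0-based frame indices.
#' @param x_nm,y_nm Positions in nm (x = column direction, y = row direction).
#' @param intensity Fit signal strength (arbitrary units).
#' @param precision_nm Localization precision (s.d., nm), > 0.
#' @param frame_interval_ms Time between frames; `t_ms = frame * interval`.
#' @return A data frame of class `localization_table`, sorted by frame then x.
#' @export
localization_table <- function(frame = integer(), x_nm = numeric(),
                               y_nm = numeric(), intensity = numeric(),
                               precision_nm = numeric(),
                               frame_interval_ms = 20) {
  n <- length(frame)
  if (n > 0 && length(intensity) == 0) intensity <- rep(1, n)
  if (n > 0 && length(precision_nm) == 0) precision_nm <- rep(NA_real_, n)
  df <- data.frame(frame = as.integer(frame), x_nm = x_nm, y_nm = y_nm,
                   intensity = intensity, precision_nm = precision_nm)
  if (nrow(df) > 0) {
    if (any(df$frame < 0)) stop("frames must be non-negative")
    if (any(!is.na(df$precision_nm) & df$precision_nm < 0))
      stop("negative precision")
    df <- df[order(df$frame, df$x_nm), , drop = FALSE]
    rownames(df) <- NULL
  }
  df$t_ms <- df$frame * frame_interval_ms
  attr(df, "frame_interval_ms") <- frame_interval_ms
  class(df) <- c("localization_table", "data.frame")
  df
}

# Column mappings for supported localization-file dialects.
.loc_dialects <- list(
  tauaggr = c(frame = "frame", x_nm = "x_nm", y_nm = "y_nm",
              intensity = "intensity", precision_nm = "precision_nm"),
  generic = c(frame = "frame", x_nm = "x", y_nm = "y",
              intensity = "intensity", precision_nm = "precision")
)

#' Read a localization table from delimited text
#'
#' @param path CSV file with a header row.
#' @param dialect Named column mapping: `"tauaggr"` (this package's writer)
#'   or `"generic"` (`frame,x,y,intensity,precision`).
#' @param mapping Optional named character vector overriding the dialect,
#'   names = canonical fields, values = file column names.
#' @param default_precision_nm Fill-in when the file has no precision column.
#' @param frame_interval_ms Frame time used to derive `t_ms`.
#' @return A [localization_table()].
#' @export
read_localizations <- function(path, dialect = c("tauaggr", "generic"),
                               mapping = NULL, default_precision_nm = 20,
                               frame_interval_ms = 20) {
  if (!file.exists(path)) stop("missing file: ", path)
  map <- if (!is.null(mapping)) mapping else .loc_dialects[[match.arg(dialect)]]
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- c("frame", "x_nm", "y_nm")
  for (f in need)
    if (!map[[f]] %in% names(raw))
      stop("unmappable columns: missing '", map[[f]], "' in ", path)
  if (nrow(raw) == 0L)
    return(localization_table(frame_interval_ms = frame_interval_ms))
  getcol <- function(f, default = NULL) {
    if (map[[f]] %in% names(raw)) raw[[map[[f]]]] else default
  }
  prec <- getcol("precision_nm")
  if (is.null(prec)) {
    warning("no precision column; filling with default ",
            default_precision_nm, " nm")
    prec <- rep(default_precision_nm, nrow(raw))
  }
  if (any(prec < 0, na.rm = TRUE)) stop("negative precision in ", path)
  localization_table(frame = getcol("frame"),
                     x_nm = getcol("x_nm"), y_nm = getcol("y_nm"),
                     intensity = getcol("intensity", rep(1, nrow(raw))),
                     precision_nm = prec,
                     frame_interval_ms = frame_interval_ms)
}

#' Write a localization table as CSV (canonical dialect)
#'
#' @param locs A [localization_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  utils::write.csv(
    as.data.frame(locs)[, c("frame", "x_nm", "y_nm", "intensity",
                            "precision_nm")],
    path, row.names = FALSE)
  invisible(path)
}

#' Deconvolved native mass spectrum container
#'
#' @param mass_da Strictly increasing mass axis (Da).
#' @param intensity Non-negative intensities.
#' @param mass_range Analysis window, Da (default 40--44 kDa).
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mass_da, intensity, mass_range = c(40000, 44000)) {
  if (length(mass_da) != length(intensity))
    stop("mass and intensity lengths differ")
  if (length(mass_da) > 1 && any(diff(mass_da) <= 0))
    stop("non-monotone mass axis")
  if (any(!is.finite(mass_da)) || any(!is.finite(intensity)))
    stop("non-finite values in spectrum")
  if (any(intensity < 0)) stop("negative intensity")
  structure(list(mass_da = as.numeric(mass_da),
                 intensity = as.numeric(intensity),
                 mass_range = mass_range),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("mass_spectrum: %d points, %.1f-%.1f Da (analysis window %.0f-%.0f Da)\n",
              length(x$mass_da), min(x$mass_da), max(x$mass_da),
              x$mass_range[1], x$mass_range[2]))
  invisible(x)
}

#' Read a two-column mass spectrum (mass Da, intensity)
#'
#' Accepts whitespace- or comma-delimited numeric text, with or without a
#' header line.
#'
#' @param path Input file.
#' @param mass_range Analysis window passed to [mass_spectrum()].
#' @return A [mass_spectrum()].
#' @export
read_spectrum <- function(path, mass_range = c(40000, 44000)) {
  if (!file.exists(path)) stop("missing file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- !grepl("^[-+0-9.eE \t,]+$", first)
  tab <- utils::read.table(path, sep = sep, header = has_header)
  if (ncol(tab) < 2L) stop("expected two columns (mass, intensity) in ", path)
  mass_spectrum(tab[[1]], tab[[2]], mass_range = mass_range)
}

#' @rdname read_spectrum
#' @param spectrum A [mass_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(mass_da = spectrum$mass_da, intensity = spectrum$intensity),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
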