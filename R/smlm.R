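#' Quality-filter a localization table
#'
#' Keeps localizations whose fit signal strength is at least
#' `min_signal_strength` and whose precision is at most `max_precision_nm`;
#' row order is preserved. Rows with missing precision are kept.
#'
#' @param locs A [localization_table()].
#' @param min_signal_strength Minimum signal strength (default 3).
#' @param max_precision_nm Maximum localization precision in nm (default 30).
#' @return The filtered [localization_table()].
#' @export
quality_filter <- function(locs, min_signal_strength = 3,
                           max_precision_nm = 30) {
  keep <- locs$intensity >= min_signal_strength &
    (is.na(locs$precision_nm) | locs$precision_nm <= max_precision_nm)
  out <- locs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect and remove fiducial markers
#'
#' A fiducial is a spatially tight site occupied in more than `min_frames`
#' distinct frames: localizations are linked at `radius_nm`, and a linked
#' site counts as "the same location" only if its r.m.s. radius is at most
#' `radius_nm` — a densely labeled aggregate chains into an extended
#' cluster and is never mistaken for a marker, whereas a marker's jitter is
#' far below the localization precision. All of a fiducial's localizations
#' are removed from the returned table.
#'
#' @param locs A [localization_table()].
#' @param min_frames Frame-count threshold (default 500).
#' @param radius_nm Co-location radius (default 15, the spatial DBSCAN
#'   epsilon).
#' @return List with `fiducials` (data frame: x_nm, y_nm, n_frames) and
#'   `locs` (the cleaned table).
#' @export
detect_fiducials <- function(locs, min_frames = 500, radius_nm = 15) {
  if (nrow(locs) == 0L)
    return(list(fiducials = data.frame(x_nm = numeric(), y_nm = numeric(),
                                       n_frames = integer()),
                locs = locs))
  lab <- dbscan_labels(cbind(locs$x_nm, locs$y_nm), eps = radius_nm,
                       minpts = 1L)
  fid <- data.frame(x_nm = numeric(), y_nm = numeric(), n_frames = integer())
  drop <- logical(nrow(locs))
  for (k in seq_len(max(lab))) {
    sel <- lab == k
    nf <- length(unique(locs$frame[sel]))
    rms <- sqrt(stats::var(locs$x_nm[sel]) + stats::var(locs$y_nm[sel]))
    if (sum(sel) < 2 || is.na(rms)) rms <- 0
    if (nf > min_frames && rms <= radius_nm) {
      fid <- rbind(fid, data.frame(x_nm = mean(locs$x_nm[sel]),
                                   y_nm = mean(locs$y_nm[sel]),
                                   n_frames = nf))
      drop[sel] <- TRUE
    }
  }
  out <- locs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(fiducials = fid, locs = out)
}

#' Group localizations into blinking bursts
#'
#' Two-stage DBSCAN: stage 1 clusters localizations spatially (epsilon 15 nm,
#' minimum 3 points); stage 2 splits each spatial cluster along the time axis
#' (epsilon 21 ms, minimum 2 localizations), so that adjacent-frame
#' localizations (20 ms frames) are neighbors while gaps of two or more
#' frames separate bursts, removing single-frame localizations.
#' Localizations noise-labeled at either stage are discarded.
#'
#' @param locs A [localization_table()], cleaned of fiducials.
#' @param spatial_eps_nm,spatial_minpts Stage-1 DBSCAN parameters.
#' @param temporal_eps_ms,temporal_min_frames Stage-2 DBSCAN parameters.
#' @return A data frame of bursts (id, x_nm, y_nm, start_frame, end_frame,
#'   n_locs) with the member localization row indices as attribute
#'   `"members"`.
#' @export
group_bursts <- function(locs, spatial_eps_nm = 15, spatial_minpts = 3,
                         temporal_eps_ms = 21, temporal_min_frames = 2) {
  empty <- data.frame(id = integer(), x_nm = numeric(), y_nm = numeric(),
                      start_frame = integer(), end_frame = integer(),
                      n_locs = integer())
  attr(empty, "members") <- list()
  if (nrow(locs) == 0L) return(empty)
  slab <- dbscan_labels(cbind(locs$x_nm, locs$y_nm),
                        eps = spatial_eps_nm, minpts = spatial_minpts)
  rows <- list(); members <- list(); id <- 0L
  for (k in seq_len(max(slab, 0L))) {
    sel <- which(slab == k)
    tlab <- dbscan_labels(matrix(locs$t_ms[sel], ncol = 1),
                          eps = temporal_eps_ms,
                          minpts = temporal_min_frames)
    for (b in seq_len(max(tlab, 0L))) {
      m <- sel[tlab == b]
      id <- id + 1L
      rows[[id]] <- data.frame(id = id,
                               x_nm = mean(locs$x_nm[m]),
                               y_nm = mean(locs$y_nm[m]),
                               start_frame = min(locs$frame[m]),
                               end_frame = max(locs$frame[m]),
                               n_locs = length(m))
      members[[id]] <- m
    }
  }
  if (id == 0L) return(empty)
  out <- do.call(rbind, rows)
  attr(out, "members") <- members
  out
}

#' Group bursts into aggregate clusters
#'
#' Final DBSCAN on burst centroids (epsilon 200 nm, minimum 20 bursts);
#' noise-labeled bursts are discarded. Each retained cluster is interpreted
#' as the detection of one super-resolved protein aggregate.
#'
#' @param bursts Burst table from [group_bursts()].
#' @param eps_nm DBSCAN epsilon (default 200).
#' @param min_bursts Minimum burst count (default 20).
#' @return A list of clusters; each has `id`, `burst_ids`, `n_bursts`, and
#'   the member burst centroid coordinates `x_nm`, `y_nm`.
#' @export
cluster_bursts <- function(bursts, eps_nm = 200, min_bursts = 20) {
  if (nrow(bursts) == 0L) return(list())
  lab <- dbscan_labels(cbind(bursts$x_nm, bursts$y_nm),
                       eps = eps_nm, minpts = min_bursts)
  out <- list()
  for (k in seq_len(max(lab, 0L))) {
    sel <- lab == k
    out[[length(out) + 1L]] <-
      list(id = length(out) + 1L, burst_ids = bursts$id[sel],
           n_bursts = sum(sel),
           x_nm = bursts$x_nm[sel], y_nm = bursts$y_nm[sel])
  }
  out
}

#' Measure the skeleton length of an aggregate cluster
#'
#' Burst centroids are mapped to an integer super-resolution grid: spatial
#' coordinates in units of `superres_pixel_nm` are scaled by `scale_factor`
#' and rounded, giving a grid spacing of `superres_pixel_nm / scale_factor`
#' nm. The binary occupancy image is morphologically closed (disc of radius
#' `closing_radius` grid units) to bridge inter-burst gaps, thinned to a
#' one-pixel-wide skeleton, and the length is the longest geodesic path with
#' 8-connectivity step distances, converted back to nm. The total skeleton
#' length is attached as attribute `"total_nm"`. A degenerate cluster whose
#' bursts all map to one grid point has length 0.
#'
#' @param cluster One cluster from [cluster_bursts()] (or any list with
#'   `x_nm`, `y_nm`).
#' @param scale_factor Grid refinement factor (default 8).
#' @param superres_pixel_nm Base pixel of the spatial domain before scaling
#'   (default 107.2, the camera pixel pitch).
#' @param closing_radius Disc radius of the closing structuring element, in
#'   grid units (default 2).
#' @return Length in nm.
#' @export
cluster_length <- function(cluster, scale_factor = 8,
                           superres_pixel_nm = 107.2, closing_radius = 2) {
  grid_nm <- superres_pixel_nm / scale_factor
  gx <- round(cluster$x_nm / grid_nm)
  gy <- round(cluster$y_nm / grid_nm)
  pad <- closing_radius + 2L
  r <- as.integer(gy - min(gy)) + pad + 1L
  c <- as.integer(gx - min(gx)) + pad + 1L
  img <- matrix(FALSE, max(r) + pad, max(c) + pad)
  img[cbind(r, c)] <- TRUE
  if (sum(img) <= 1L) {
    len <- 0
    attr(len, "total_nm") <- 0
    return(len)
  }
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
    img <- as.matrix(EBImage::closing(EBImage::Image(img * 1), brush)) > 0.5
  }
  skel <- thin_binary(img)
  len <- skeleton_longest_path(skel) * grid_nm
  attr(len, "total_nm") <- skeleton_total_length(skel) * grid_nm
  len
}

#' Render localizations into a super-resolution histogram image
#'
#' @param locs A [localization_table()].
#' @param pixel_nm Rendering pixel size in nm.
#' @param clusters Optional cluster list from [cluster_bursts()]; when
#'   given, a per-pixel integer label image of cluster footprints is
#'   attached as attribute `"labels"`.
#' @param extent_nm Optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   data range.
#' @return Count matrix (rows = y bins, cols = x bins). Total counts equal
#'   the number of localizations inside the extent.
#' @export
render_superres <- function(locs, pixel_nm = 10, clusters = NULL,
                            extent_nm = NULL) {
  if (is.null(extent_nm)) {
    if (nrow(locs) == 0L) stop("empty table and no extent given")
    extent_nm <- c(min(locs$x_nm), max(locs$x_nm) + pixel_nm,
                   min(locs$y_nm), max(locs$y_nm) + pixel_nm)
  }
  nx <- max(1L, ceiling((extent_nm[2] - extent_nm[1]) / pixel_nm))
  ny <- max(1L, ceiling((extent_nm[4] - extent_nm[3]) / pixel_nm))
  bx <- pmin(pmax(floor((locs$x_nm - extent_nm[1]) / pixel_nm), 0), nx - 1L)
  by <- pmin(pmax(floor((locs$y_nm - extent_nm[3]) / pixel_nm), 0), ny - 1L)
  img <- matrix(0L, ny, nx)
  if (nrow(locs) > 0) {
    tab <- table(by * nx + bx)
    idx <- as.integer(names(tab))
    img[cbind(idx %/% nx + 1L, idx %% nx + 1L)] <- as.integer(tab)
  }
  if (!is.null(clusters)) {
    labimg <- matrix(0L, ny, nx)
    for (cl in clusters) {
      cx <- pmin(pmax(floor((cl$x_nm - extent_nm[1]) / pixel_nm), 0), nx - 1L)
      cy <- pmin(pmax(floor((cl$y_nm - extent_nm[3]) / pixel_nm), 0), ny - 1L)
      labimg[cbind(cy + 1L, cx + 1L)] <- cl$id
    }
    attr(img, "labels") <- labimg
  }
  attr(img, "pixel_nm") <- pixel_nm
  attr(img, "extent_nm") <- extent_nm
  img
}

#' Aggregate size fractions below and above length thresholds
#'
#' @param lengths_nm Numeric vector of cluster lengths (nm), or a list of
#'   clusters carrying `length_nm`.
#' @param thresholds_nm Length thresholds (default 500 and 1000 nm).
#' @return Named list: for each threshold, the fraction of clusters strictly
#'   below it, plus `partition` (fractions over the full set of bins, which
#'   sum to 1).
#' @export
cluster_size_fractions <- function(lengths_nm, thresholds_nm = c(500, 1000)) {
  if (is.list(lengths_nm))
    lengths_nm <- vapply(lengths_nm, function(cl) cl$length_nm, numeric(1))
  if (length(lengths_nm) == 0L) stop("empty cluster list")
  out <- list()
  for (th in thresholds_nm)
    out[[paste0("below_", th, "_nm")]] <- mean(lengths_nm < th)
  cuts <- cut(lengths_nm, breaks = c(0, thresholds_nm, Inf), right = FALSE)
  out$partition <- as.numeric(table(cuts)) / length(lengths_nm)
  names(out$partition) <- levels(cuts)
  out
}

#' Run the full SMLM analysis pipeline
#'
#' Quality filter, fiducial removal, burst grouping, burst clustering, and
#' per-cluster skeleton length measurement, at the parameters in `config`.
#'
#' @param locs A raw [localization_table()].
#' @param config An [analysis_config()].
#' @return An object of class `smlm_result`: list with `locs` (cleaned),
#'   `fiducials`, `bursts`, `clusters` (data frame: id, n_bursts, length_nm,
#'   total_skeleton_nm), and `cluster_objects`.
#' @export
smlm_analyze <- function(locs, config = analysis_config()) {
  p <- config$smlm
  locs <- quality_filter(locs, p$min_signal_strength, p$max_precision_nm)
  fid <- detect_fiducials(locs, p$fiducial_min_frames, p$fiducial_radius_nm)
  bursts <- group_bursts(fid$locs, p$spatial_eps_nm, p$spatial_minpts,
                         p$temporal_eps_ms, p$temporal_min_frames)
  clusters <- cluster_bursts(bursts, p$cluster_eps_nm, p$cluster_min_bursts)
  if (length(clusters) > 0) {
    lens <- lapply(clusters, cluster_length, scale_factor = p$scale_factor,
                   superres_pixel_nm = p$superres_pixel_nm,
                   closing_radius = p$closing_radius)
    tab <- data.frame(
      id = vapply(clusters, function(cl) cl$id, integer(1)),
      n_bursts = vapply(clusters, function(cl) cl$n_bursts, integer(1)),
      length_nm = vapply(lens, as.numeric, numeric(1)),
      total_skeleton_nm = vapply(lens, function(l) attr(l, "total_nm"),
                                 numeric(1)))
    for (i in seq_along(clusters)) clusters[[i]]$length_nm <- tab$length_nm[i]
  } else {
    tab <- data.frame(id = integer(), n_bursts = integer(),
                      length_nm = numeric(), total_skeleton_nm = numeric())
  }
  structure(list(locs = fid$locs, fiducials = fid$fiducials, bursts = bursts,
                 clusters = tab, cluster_objects = clusters),
            class = "smlm_result")
}

#' @export
print.smlm_result <- function(x, ...) {
  cat(sprintf("smlm_result: %d localizations, %d fiducial(s), %d bursts, %d clusters\n",
              nrow(x$locs), nrow(x$fiducials), nrow(x$bursts),
              nrow(x$clusters)))
  if (nrow(x$clusters) > 0)
    cat(sprintf("  cluster lengths: %.0f-%.0f nm (mean %.0f nm)\n",
                min(x$clusters$length_nm), max(x$clusters$length_nm),
                mean(x$clusters$length_nm)))
  invisible(x)
}
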