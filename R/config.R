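#' Default analysis parameters
#'
#' Returns the full nested list of stage parameters with their defaults.
#' Values that the underlying acquisition and analysis protocol fixes
#' (camera pixel pitch, DBSCAN radii, quality-filter cutoffs, MCMC chain
#' settings, ...) default to those protocol values; purely implementation
#' level knobs (bandpass sigmas, closing radius, background percentile)
#' default to the choices documented in the methods vignette.
#'
#' @return Named nested list of parameter groups.
#' @export
ta_defaults <- function() {
  list(
    seed = 1L,
    imaging = list(
      pixel_size_nm    = 107.2,
      frame_interval_ms = 20
    ),
    dl = list(
      bandpass_sigmas = c(1, 20),  # DoG sigmas, px
      blur_sigma_px   = 1,
      threshold_frac  = 0.02,      # 2% above the image median
      min_px          = 3,
      length_breaks_nm = c(0, 500, 1000, Inf)
    ),
    smlm = list(
      min_signal_strength = 3,
      max_precision_nm    = 30,
      fiducial_min_frames = 500,
      fiducial_radius_nm  = 15,
      spatial_eps_nm      = 15,
      spatial_minpts      = 3,
      temporal_eps_ms     = 21,
      temporal_min_frames = 2,
      cluster_eps_nm      = 200,
      cluster_min_bursts  = 20,
      scale_factor        = 8,
      superres_pixel_nm   = 107.2,
      closing_radius      = 2
    ),
    frc = list(
      pixel_nm  = 10,
      threshold = 1 / 7
    ),
    ms = list(
      base_mass_da = 39900,
      phosphate_da = 80,
      adduct_da    = 23,
      max_phos     = 50,
      max_adduct   = 50,
      window_da    = 10,
      chains       = 6,
      steps        = 3000,
      burn_in      = 800,
      thin         = 100,
      floor_frac   = 1e-6
    ),
    traces = list(
      bg_percentile  = 0.05,
      blur_sigma_px  = 1,
      trace_smooth_sd = 1.5,     # frames
      cell_radius_px = 5,
      min_track_frac = 0.25,
      refractory_frames = 3,
      ros_window     = 50
    )
  )
}

#' Build an analysis configuration
#'
#' Merges user overrides into [ta_defaults()]. Overrides are given as nested
#' lists, e.g. `analysis_config(smlm = list(spatial_eps_nm = 20))`.
#'
#' @param ... Named parameter groups overriding the defaults.
#' @return An object of class `analysis_config` (a nested list).
#' @export
analysis_config <- function(...) {
  cfg <- ta_defaults()
  over <- list(...)
  for (grp in names(over)) {
    if (!grp %in% names(cfg)) {
      cfg[[grp]] <- over[[grp]]
    } else if (is.list(over[[grp]])) {
      for (key in names(over[[grp]])) cfg[[grp]][[key]] <- over[[grp]][[key]]
    } else {
      cfg[[grp]] <- over[[grp]]
    }
  }
  class(cfg) <- c("analysis_config", "list")
  cfg
}

#' Read / write an analysis configuration
#'
#' Configurations serialize to YAML and round-trip losslessly.
#'
#' @param path File path.
#' @param config An `analysis_config` object.
#' @return `read_config` returns an `analysis_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  do.call(analysis_config, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("tauaggr analysis configuration\n")
  for (grp in names(x)) {
    if (is.list(x[[grp]])) {
      cat(" ", grp, ": ",
          paste(names(x[[grp]]),
                vapply(x[[grp]], function(v) paste(format(v), collapse = ","),
                       character(1)),
                sep = "=", collapse = "  "), "\n", sep = "")
    } else {
      cat(" ", grp, " = ", format(x[[grp]]), "\n", sep = "")
    }
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
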