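# Shared fixtures and independent oracles used across test files.

# Brute-force density clustering oracle: full distance matrix, core points
# by neighbor count, clusters = connected components of the core-core graph
# (igraph), borders assigned to their lowest-index core neighbor, cluster
# ids ordered by lowest member core index. Independent of the package's
# grid-bucketed BFS implementation.
oracle_dbscan <- function(coords, eps, minpts) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(coords))
  adj <- d <= eps
  core <- rowSums(adj) >= minpts    # closed neighborhood includes self
  labels <- integer(n)
  if (any(core)) {
    g <- igraph::graph_from_adjacency_matrix(adj[core, core, drop = FALSE],
                                             mode = "undirected")
    comp <- igraph::components(g)$membership
    core_idx <- which(core)
    # renumber components by their lowest core index
    first <- tapply(core_idx, comp, min)
    renum <- match(seq_along(first), order(first))
    labels[core_idx] <- renum[comp]
    for (i in which(!core)) {
      cn <- core_idx[adj[i, core_idx]]
      if (length(cn) > 0) labels[i] <- labels[min(cn)]
    }
  }
  labels
}

# Staged-grouping oracle: spatial density clustering, then temporal within
# each spatial cluster, returning per-localization burst keys.
oracle_bursts <- function(locs, spatial_eps = 15, spatial_minpts = 3,
                          temporal_eps = 21, temporal_min = 2) {
  slab <- oracle_dbscan(cbind(locs$x_nm, locs$y_nm), spatial_eps,
                        spatial_minpts)
  key <- rep(NA_character_, nrow(locs))
  for (k in seq_len(max(slab, 0))) {
    sel <- which(slab == k)
    tlab <- oracle_dbscan(matrix(locs$t_ms[sel], ncol = 1), temporal_eps,
                          temporal_min)
    ok <- tlab > 0
    key[sel[ok]] <- paste(k, tlab[ok])
  }
  key
}

# Membership signature of the package's burst grouping, comparable with
# oracle_bursts(): the set of bursts as sorted member index sets.
burst_member_sets <- function(bursts) {
  m <- attr(bursts, "members")
  sets <- lapply(m, sort)
  sets[order(vapply(sets, function(s) s[1], numeric(1)))]
}

key_member_sets <- function(key) {
  sets <- unname(split(seq_along(key)[!is.na(key)], key[!is.na(key)]))
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, function(s) s[1], numeric(1)))]
}

# One fibril (or blob) rendered to a localization stream; burst count
# proportional to length as in the dense-labeling regime the pipeline
# assumes (see the methods vignette).
sim_aggregate_locs <- function(size_nm, shape = "segment",
                               orientation = pi / 7, precision_nm = 20,
                               density_per_nm = 0.5, n_frames = 10000,
                               seed = 1) {
  nb <- max(30L, round(density_per_nm * size_nm))
  truth <- ground_truth(
    aggregates = data.frame(shape = shape, x_nm = 3500, y_nm = 3500,
                            size_nm = size_nm, orientation = orientation),
    seed = seed)
  gen_smlm_stream(truth, emitter_model(precision_nm = precision_nm),
                  n_frames = n_frames, n_bursts = nb)
}

# Measured skeleton length of the largest cluster recovered from a stream.
recovered_length <- function(locs) {
  b <- group_bursts(locs)
  cl <- cluster_bursts(b)
  if (length(cl) == 0) return(NA_real_)
  max(vapply(cl, function(x) as.numeric(cluster_length(x)), numeric(1)))
}

# A dense multi-fibril scene for FRC studies.
sim_frc_locs <- function(precision_nm, seed = 3) {
  truth <- ground_truth(aggregates = data.frame(
    shape = "segment",
    x_nm = c(1000, 2000, 3000, 1500, 2500),
    y_nm = c(1000, 1500, 2500, 3000, 2000),
    size_nm = 1500,
    orientation = c(0.3, 1.2, 2.0, 2.6, 0.8)), seed = seed)
  gen_smlm_stream(truth, emitter_model(precision_nm = precision_nm),
                  n_frames = 10000, n_bursts = rep(1500L, 5))
}

# Simulated diffraction-limited field of n aggregates at the study's
# acquisition conditions (EMCCD background 500, read noise 3, PSF 120 nm).
sim_dl_field <- function(size_nm, n = 50, shape = "segment", seed = 1,
                         fov_px = 256, n_frames = 50) {
  set.seed(seed)
  margin <- 1500
  g <- expand.grid(x = seq(margin, fov_px * 107.2 - margin, length.out = 8),
                   y = seq(margin, fov_px * 107.2 - margin, length.out = 8))
  g <- g[seq_len(n), ]
  truth <- ground_truth(
    aggregates = data.frame(shape = shape, x_nm = g$x, y_nm = g$y,
                            size_nm = size_nm,
                            orientation = stats::runif(n, 0, pi)),
    seed = seed)
  render_dl_stack(truth, psf_sigma_nm = 120, amplitude = 150,
                  noise = list(gain = 1, read_sd = 3, background = 500),
                  n_frames = n_frames, fov_px = fov_px)
}

# Per-trace spike study: normalized noisy trace plus ground-truth onsets.
sim_spike_trace <- function(spike_frames, n_frames = 400, amplitude = 1,
                            noise_sd = 0.04, seed = 1) {
  tr <- gen_calcium_trace(n_frames, spike_frames, amplitude = amplitude,
                          rise = 1, decay = 20, baseline = 1,
                          noise_sd = noise_sd, seed = seed)
  normalize_trace(tauaggr:::.gauss_smooth_1d(tr, 1.5), 1:50)
}

# Spike onsets with a minimum separation, so transients are resolvable.
draw_spike_frames <- function(n, lo = 60, hi = 350, min_sep = 30) {
  repeat {
    s <- sort(sample(lo:hi, n))
    if (n < 2 || all(diff(s) >= min_sep)) return(s)
  }
}
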