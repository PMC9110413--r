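# Exact DBSCAN with grid-bucketed neighbor search.
#
# Standard semantics: a point is core if its closed eps-neighborhood
# (including itself) holds >= minpts points; clusters grow by BFS from core
# points in ascending index order, so border points join the cluster of the
# first-discovered core neighbor and ties break by lowest point index.
# Returns 0 for noise, 1..k for clusters. Works for 1-D or 2-D coordinates.
dbscan_labels <- function(coords, eps, minpts) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1L)
  n <- nrow(coords)
  labels <- integer(n)
  if (n == 0L) return(labels)
  d <- ncol(coords)
  stopifnot(d <= 2L, eps > 0)

  # bucket points into eps-sized cells; neighbors live in adjacent cells
  cell <- matrix(0L, n, d)
  for (j in seq_len(d)) cell[, j] <- as.integer(floor(coords[, j] / eps))
  key <- if (d == 1L) as.character(cell[, 1]) else paste(cell[, 1], cell[, 2])
  buckets <- split(seq_len(n), key)

  offsets <- if (d == 1L) -1:1 else as.matrix(expand.grid(-1:1, -1:1))
  neighbors <- function(i) {
    cand <- integer(0)
    if (d == 1L) {
      for (o in offsets) {
        b <- buckets[[as.character(cell[i, 1] + o)]]
        if (!is.null(b)) cand <- c(cand, b)
      }
      cand[abs(coords[cand, 1] - coords[i, 1]) <= eps]
    } else {
      for (r in seq_len(nrow(offsets))) {
        b <- buckets[[paste(cell[i, 1] + offsets[r, 1],
                            cell[i, 2] + offsets[r, 2])]]
        if (!is.null(b)) cand <- c(cand, b)
      }
      dx <- coords[cand, 1] - coords[i, 1]
      dy <- coords[cand, 2] - coords[i, 2]
      cand[dx * dx + dy * dy <= eps * eps]
    }
  }

  nb <- vector("list", n)
  core <- logical(n)
  for (i in seq_len(n)) {
    nb[[i]] <- sort(neighbors(i))
    core[i] <- length(nb[[i]]) >= minpts
  }

  # cluster the core points (BFS over core-core adjacency, seeds in
  # ascending index order, so cluster ids follow lowest core index)
  visited <- logical(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    k <- k + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- k
    while (length(queue) > 0L) {
      p <- queue[1L]
      queue <- queue[-1L]
      for (q in nb[[p]]) {
        if (core[q] && !visited[q]) {
          visited[q] <- TRUE
          labels[q] <- k
          queue <- c(queue, q)
        }
      }
    }
  }
  # border points join the cluster of their lowest-index core neighbor
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn) > 0L) labels[i] <- labels[min(cn)]
  }
  labels
}
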