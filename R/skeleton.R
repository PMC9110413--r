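# Binary thinning and skeleton path measurement.
#
# thin_binary(): Zhang-Suen two-subiteration thinning to a one-pixel-wide
# skeleton, vectorized over the whole image per pass.
# skeleton_longest_path(): longest geodesic path through the skeleton with
# 8-connectivity step distances (1 for axial, sqrt(2) for diagonal steps).

thin_binary <- function(mask) {
  stopifnot(is.matrix(mask))
  img <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask != 0)
  nr <- nrow(img); nc <- ncol(img)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      # clockwise neighbors starting north: p2..p9
      p2 <- shift(img, -1,  0); p3 <- shift(img, -1,  1)
      p4 <- shift(img,  0,  1); p5 <- shift(img,  1,  1)
      p6 <- shift(img,  1,  0); p7 <- shift(img,  1, -1)
      p8 <- shift(img,  0, -1); p9 <- shift(img, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 0) {
        cond <- img == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- img == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        img[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] > 0
}

# Adjacency of skeleton pixels: returns for each pixel the indices of its
# 8-connected skeleton neighbors plus the step weights.
.skel_graph <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  if (n == 0L) return(list(n = 0L))
  idx <- matrix(0L, nrow(skel), ncol(skel))
  idx[px] <- seq_len(n)
  nbrs <- vector("list", n)
  wts <- vector("list", n)
  off <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1,  0,  1, -1, 1, -1, 0, 1))
  w8 <- ifelse(off[, 1] != 0 & off[, 2] != 0, sqrt(2), 1)
  for (i in seq_len(n)) {
    r <- px[i, 1] + off[, 1]
    c <- px[i, 2] + off[, 2]
    ok <- r >= 1 & r <= nrow(skel) & c >= 1 & c <= ncol(skel)
    j <- idx[cbind(r[ok], c[ok])]
    keep <- j > 0L
    nbrs[[i]] <- j[keep]
    wts[[i]] <- w8[ok][keep]
  }
  list(n = n, px = px, nbrs = nbrs, wts = wts)
}

# Dijkstra over the (small) skeleton graph; returns distances from `from`.
.skel_dists <- function(g, from) {
  dist <- rep(Inf, g$n)
  dist[from] <- 0
  done <- logical(g$n)
  for (iter in seq_len(g$n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- g$nbrs[[u]]
    nd <- dist[u] + g$wts[[u]]
    upd <- nd < dist[nb]
    dist[nb[upd]] <- nd[upd]
  }
  dist
}

# Longest geodesic path length (in pixel steps) through a skeleton, by a
# double Dijkstra sweep per connected component (exact on trees, which
# thinning output is up to rare small cycles). Returns 0 for <= 1 pixel.
skeleton_longest_path <- function(skel) {
  g <- .skel_graph(skel)
  if (g$n <= 1L) return(0)
  best <- 0
  remaining <- rep(TRUE, g$n)
  while (any(remaining)) {
    s <- which(remaining)[1]
    d0 <- .skel_dists(g, s)
    comp <- is.finite(d0)
    u <- which(comp)[which.max(d0[comp])]
    d1 <- .skel_dists(g, u)
    best <- max(best, max(d1[is.finite(d1)]))
    remaining[comp] <- FALSE
  }
  best
}

# Total skeleton length in pixel steps: sum of all unique 8-neighbor edges.
skeleton_total_length <- function(skel) {
  g <- .skel_graph(skel)
  if (g$n <= 1L) return(0)
  tot <- 0
  for (i in seq_len(g$n)) {
    sel <- g$nbrs[[i]] > i   # count each edge once
    tot <- tot + sum(g$wts[[i]][sel])
  }
  tot
}
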