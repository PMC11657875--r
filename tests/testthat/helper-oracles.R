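# Independent oracles and fixture builders. These deliberately avoid the
# package's own geometry/clustering code paths.

# Even-odd point-in-polygon, written independently of the package internals.
oracle_pip <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cond <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cond)
    j <- i
  }
  inside
}

# 1 nm rasterization chord oracle: probe the perpendicular line at 1 nm
# steps and count the contiguous inside run containing the skeleton point.
oracle_chord <- function(px, py, nx, ny, vertices, tmax = 1000, step = 1) {
  t <- seq(-tmax, tmax, by = step)
  inside <- oracle_pip(px + t * nx, py + t * ny, vertices[, 1], vertices[, 2])
  i0 <- which.min(abs(t))
  if (!inside[i0]) return(NA_real_)
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  ri <- which(ends >= i0)[1]
  runs$lengths[ri] * step
}

# Rasterized width profile of a (single-plane, in-plane) annotation.
oracle_profile <- function(annotation, step_nm = 20, tmax = 1000) {
  sk <- annotation$skeleton
  nodes <- sk$nodes
  seg <- diff(nodes)
  seg_len <- sqrt(rowSums(seg^2))
  s_nodes <- c(0, cumsum(seg_len))
  total <- s_nodes[length(s_nodes)]
  s <- seq(0, total, by = step_nm)
  if (total - s[length(s)] > 1e-9) s <- c(s, total)
  seg_idx <- pmin(findInterval(s, s_nodes, rightmost.closed = TRUE),
                  nrow(seg))
  frac <- (s - s_nodes[seg_idx]) / seg_len[seg_idx]
  px <- nodes[seg_idx, 1] + frac * seg[seg_idx, 1]
  py <- nodes[seg_idx, 2] + frac * seg[seg_idx, 2]
  pz <- nodes[seg_idx, 3] + frac * seg[seg_idx, 3]
  in_plane <- abs(seg[seg_idx, 3]) <= 1e-6
  d <- rep(NA_real_, length(s))
  for (o in annotation$outlines) {
    sel <- which(in_plane & abs(pz - o$z) <= 1e-6)
    for (i in sel) {
      txy <- seg[seg_idx[i], 1:2]
      tl <- sqrt(sum(txy^2))
      if (tl == 0) next
      d[i] <- oracle_chord(px[i], py[i], -txy[2] / tl, txy[1] / tl,
                           o$vertices, tmax = tmax)
    }
  }
  list(s = s, d = d)
}

# O(n^3) brute-force Ward agglomeration computing the within-cluster
# sum-of-squares increase directly from the points (no Lance-Williams
# shortcut, no shared code with stats::hclust). Returns the merge sequence
# as a list of sorted member-index vectors, one per merge.
oracle_ward_merges <- function(X) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  merges <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL; best_cost <- Inf
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        ci <- clusters[[i]]; cj <- clusters[[j]]
        mi <- colMeans(X[ci, , drop = FALSE])
        mj <- colMeans(X[cj, , drop = FALSE])
        cost <- length(ci) * length(cj) / (length(ci) + length(cj)) *
          sum((mi - mj)^2)
        if (cost < best_cost - 1e-12) {
          best_cost <- cost; best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# hclust merge matrix -> list of sorted member-index vectors per step
hclust_merge_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    members <- unlist(lapply(tree$merge[k, ], function(m)
      if (m < 0) -m else sets[[m]]))
    sets[[k]] <- sort(members)
  }
  sets
}

# same partition up to label renaming?
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    nrow(unique(cbind(a, b))) == length(unique(a))
}

# --- small fixtures -------------------------------------------------------

# axis-aligned rectangular "cylinder" spine: skeleton along x, constant
# width, one plane
cylinder_annotation <- function(length_nm = 2000, width_nm = 400,
                                labels = NULL) {
  nodes <- cbind(seq(0, length_nm, length.out = 11), 0, 0)
  sk <- spine_skeleton(nodes, labels, spine_id = "cyl")
  poly <- rbind(c(-50, -width_nm / 2), c(length_nm + 50, -width_nm / 2),
                c(length_nm + 50, width_nm / 2), c(-50, width_nm / 2))
  spine_annotation(sk, list(plane_outline(0, poly)))
}

# linear cone from width0 at s=0 to ~0 at s=length
cone_annotation <- function(length_nm = 2000, width0 = 600) {
  nodes <- cbind(seq(0, length_nm, length.out = 11), 0, 0)
  sk <- spine_skeleton(nodes, spine_id = "cone")
  xs <- seq(-20, length_nm, length.out = 50)
  w <- pmax(width0 * (1 - xs / length_nm), 2) / 2
  poly <- rbind(cbind(xs, -w), cbind(rev(xs), rev(w)))
  spine_annotation(sk, list(plane_outline(0, poly)))
}

default_dendrite_table <- function(n_dendrites = 4, n_spines = 100) {
  p <- matrix(0.1, n_dendrites, 4)
  for (i in seq_len(n_dendrites)) p[i, ((i - 1) %% 4) + 1] <- 0.7
  data.frame(neuron_id = "n1", dendrite_id = paste0("d", seq_len(n_dendrites)),
             n_spines = n_spines, p1 = p[, 1], p2 = p[, 2], p3 = p[, 3],
             p4 = p[, 4])
}

minimal_nml <- function(path) {
  writeLines(c(
    '<things>',
    ' <parameters><scale x="20" y="20" z="300"/></parameters>',
    ' <thing id="1" name="n1/d1/s1">',
    '  <nodes>',
    '   <node id="1" x="0" y="0" z="0"/>',
    '   <node id="2" x="20" y="0" z="1"/>',
    '  </nodes>',
    '  <edges><edge source="1" target="2"/></edges>',
    ' </thing>',
    '</things>'), path)
  path
}
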