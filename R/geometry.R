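# Internal 2D polygon geometry used by the width profiler and the generator.
# All coordinates are in nm. Polygons are simple (non-self-intersecting),
# given as ordered vertex matrices without a repeated closing vertex.

#' @noRd
poly_edges <- function(vertices) {
  n <- nrow(vertices)
  list(
    ax = vertices[, 1], ay = vertices[, 2],
    ex = vertices[c(2:n, 1), 1] - vertices[, 1],
    ey = vertices[c(2:n, 1), 2] - vertices[, 2]
  )
}

# Even-odd point-in-polygon, vectorized over points.
#' @noRd
points_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  jx <- vx[c(n, 1:(n - 1))]; jy <- vy[c(n, 1:(n - 1))]
  inside <- logical(length(px))
  for (k in seq_len(n)) {
    cross <- ((vy[k] > py) != (jy[k] > py)) &
      (px < (jx[k] - vx[k]) * (py - vy[k]) / (jy[k] - vy[k]) + vx[k])
    inside <- xor(inside, cross)
  }
  inside
}

# Simplicity check: no two non-adjacent edges intersect.
#' @noRd
polygon_is_simple <- function(vertices) {
  n <- nrow(vertices)
  if (n < 3) return(FALSE)
  e <- poly_edges(vertices)
  # zero-length edges make adjacency reasoning unreliable
  if (any(e$ex == 0 & e$ey == 0)) return(FALSE)
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  adjacent <- (j - i == 1) | (i == 1 & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (length(i) == 0) return(TRUE)
  # segment intersection via orientation signs
  d1 <- (e$ex[i]) * (e$ay[j] - e$ay[i]) - (e$ey[i]) * (e$ax[j] - e$ax[i])
  d2 <- (e$ex[i]) * (e$ay[j] + e$ey[j] - e$ay[i]) -
    (e$ey[i]) * (e$ax[j] + e$ex[j] - e$ax[i])
  d3 <- (e$ex[j]) * (e$ay[i] - e$ay[j]) - (e$ey[j]) * (e$ax[i] - e$ax[j])
  d4 <- (e$ex[j]) * (e$ay[i] + e$ey[i] - e$ay[j]) -
    (e$ey[j]) * (e$ax[i] + e$ex[i] - e$ax[j])
  crossing <- (d1 * d2 < 0) & (d3 * d4 < 0)
  # collinear overlap of non-adjacent edges also breaks simplicity
  touch <- (d1 == 0 & d2 == 0 & d3 == 0 & d4 == 0)
  !any(crossing | touch)
}

# Intersection parameters of the infinite line p + t*dir with all polygon
# edges, half-open in the edge parameter to count shared vertices once.
#' @noRd
line_polygon_ts <- function(px, py, dx, dy, edges, eps = 1e-12) {
  denom <- dx * edges$ey - dy * edges$ex
  dax <- edges$ax - px
  day <- edges$ay - py
  tt <- (dax * edges$ey - day * edges$ex) / denom
  uu <- (dax * dy - day * dx) / denom
  keep <- abs(denom) > eps & uu >= 0 & uu < 1
  sort(tt[keep])
}

# Chord of the polygon along direction (dx, dy) through (px, py), i.e. the
# inside interval of the crossing line that contains the point. Returns NA
# when the point lies in no inside interval. Grazing contacts (odd crossing
# count) are resolved by slightly rotating the probe direction.
#' @noRd
polygon_chord <- function(px, py, dx, dy, vertices, tol = 1e-6) {
  edges <- poly_edges(vertices)
  for (jit in c(0, 1e-4, -1e-4, 3e-4)) {
    ca <- cos(jit); sa <- sin(jit)
    ts <- line_polygon_ts(px, py, dx * ca - dy * sa, dx * sa + dy * ca, edges)
    # lines through a polygon vertex can report the crossing twice
    if (length(ts) > 1) ts <- ts[c(TRUE, diff(ts) > tol)]
    if (length(ts) >= 2 && length(ts) %% 2 == 0) {
      lo <- ts[seq(1, length(ts), 2)]
      hi <- ts[seq(2, length(ts), 2)]
      hit <- which(lo <= tol & hi >= -tol)
      if (length(hit) > 0) return(hi[hit[1]] - lo[hit[1]])
    }
  }
  NA_real_
}
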