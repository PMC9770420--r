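# Planar distance helpers used by non-overlapping object placement.
# Points are (y, x) in 0-based pixel-center coordinates.

# distance from one point p = c(y, x) to many segments (A[i,] -> B[i,])
dist_point_to_segments <- function(p, A, B) {
  v <- B - A
  wy <- p[1] - A[, 1]
  wx <- p[2] - A[, 2]
  vv <- v[, 1]^2 + v[, 2]^2
  t <- (wy * v[, 1] + wx * v[, 2]) / ifelse(vv > 0, vv, 1)
  t[vv == 0] <- 0
  t <- pmin(pmax(t, 0), 1)
  dy <- p[1] - (A[, 1] + t * v[, 1])
  dx <- p[2] - (A[, 2] + t * v[, 2])
  sqrt(dy^2 + dx^2)
}

# distance from many points P[i,] to one segment a -> b
dist_points_to_segment <- function(P, a, b) {
  v <- b - a
  vv <- sum(v^2)
  if (vv == 0) return(sqrt((P[, 1] - a[1])^2 + (P[, 2] - a[2])^2))
  t <- ((P[, 1] - a[1]) * v[1] + (P[, 2] - a[2]) * v[2]) / vv
  t <- pmin(pmax(t, 0), 1)
  dy <- P[, 1] - (a[1] + t * v[1])
  dx <- P[, 2] - (a[2] + t * v[2])
  sqrt(dy^2 + dx^2)
}

orient2 <- function(ay, ax, by, bx, cy, cx) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# does segment p1->p2 intersect each of the segments Q1[i,] -> Q2[i,]?
segments_intersect <- function(p1, p2, Q1, Q2) {
  o1 <- orient2(p1[1], p1[2], p2[1], p2[2], Q1[, 1], Q1[, 2])
  o2 <- orient2(p1[1], p1[2], p2[1], p2[2], Q2[, 1], Q2[, 2])
  o3 <- orient2(Q1[, 1], Q1[, 2], Q2[, 1], Q2[, 2], p1[1], p1[2])
  o4 <- orient2(Q1[, 1], Q1[, 2], Q2[, 1], Q2[, 2], p2[1], p2[2])
  (o1 * o2 <= 0) & (o3 * o4 <= 0)
}

# minimum distance between segment p1->p2 and each segment Q1[i,] -> Q2[i,];
# in 2-D the minimum is attained at an endpoint unless the segments cross
min_dist_segment_to_segments <- function(p1, p2, Q1, Q2) {
  d <- pmin(dist_point_to_segments(p1, Q1, Q2),
            dist_point_to_segments(p2, Q1, Q2),
            dist_points_to_segment(Q1, p1, p2),
            dist_points_to_segment(Q2, p1, p2))
  d[segments_intersect(p1, p2, Q1, Q2)] <- 0
  d
}
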