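# Internal geometry, polygon and RNG helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## 2x2 rotation matrix (counter-clockwise by theta, y-up convention)
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

## apply rotation (points as rows) about an optional center
rotate_points <- function(pts, theta, center = c(0, 0)) {
  ctr <- matrix(center, nrow(pts), 2, byrow = TRUE)
  (pts - ctr) %*% t(rot2(theta)) + ctr
}

## pairwise squared Euclidean distances between row sets
pdist2 <- function(A, B = A) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

## signed shoelace area; positive for counter-clockwise (y-up)
polygon_signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

polygon_perimeter <- function(pts) {
  d <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE]) - pts
  sum(sqrt(rowSums(d^2)))
}

## cumulative arc-length position of each vertex, starting at 0
polygon_arc_positions <- function(pts) {
  d <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE]) - pts
  seg <- sqrt(rowSums(d^2))
  c(0, cumsum(seg))[seq_len(nrow(pts))]
}

## segment midpoints and tangent (difference) vectors of a closed polygon
polygon_segments <- function(pts) {
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  list(center = (pts + nxt) / 2, tangent = nxt - pts)
}

## even-odd (crossing number) point-in-polygon test, vectorized over queries
points_in_polygon <- function(px, py, poly) {
  n <- length(px)
  inside <- rep(FALSE, n)
  m <- nrow(poly)
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

## TRUE if the closed polygon has a proper (interior) self-crossing.
## Degenerate repeated vertices and shared endpoints are tolerated.
polygon_self_intersects <- function(pts) {
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) > 0)
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n < 4) return(FALSE)
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  p1x <- pts[, 1]; p1y <- pts[, 2]; p2x <- nxt[, 1]; p2y <- nxt[, 2]
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    js <- seq.int(i + 2, n)
    ## segment n closes onto segment 1; skip that adjacency
    if (i == 1) js <- js[js != n]
    dx1 <- p2x[i] - p1x[i]; dy1 <- p2y[i] - p1y[i]
    d1 <- cross2(dx1, dy1, p1x[js] - p1x[i], p1y[js] - p1y[i])
    d2 <- cross2(dx1, dy1, p2x[js] - p1x[i], p2y[js] - p1y[i])
    dx2 <- p2x[js] - p1x[js]; dy2 <- p2y[js] - p1y[js]
    d3 <- cross2(dx2, dy2, p1x[i] - p1x[js], p1y[i] - p1y[js])
    d4 <- cross2(dx2, dy2, p2x[i] - p1x[js], p2y[i] - p1y[js])
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(TRUE)
  }
  FALSE
}

## Deterministic per-subject RNG stream seed below 2^31, keyed by
## (cohort seed, subject id [, role]) so generation is order-independent.
subject_stream_seed <- function(seed, subject_id, role = "") {
  key <- paste0(subject_id, "|", role)
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 214748329
  as.integer((h + (as.numeric(seed) %% 214748329) * 7919) %% 2147483562) + 1L
}

## cyclic (wrap-aware) distance between arc fractions in [0, 1)
cyclic_frac_dist <- function(u, v) {
  d <- abs(u - v) %% 1
  pmin(d, 1 - d)
}

## distance from arc fractions u to an arc interval [u0, u1) that may wrap
cyclic_interval_dist <- function(u, support) {
  u0 <- support[1] %% 1
  len <- (support[2] - support[1]) %% 1
  rel <- (u - u0) %% 1
  ifelse(rel < len, 0, pmin(rel - len, 1 - rel))
}

## md5 of an arbitrary R object via its serialization (version 3, fixed)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 3)
  close(con)
  unname(tools::md5sum(f))
}

file_hash <- function(path) unname(tools::md5sum(path))
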