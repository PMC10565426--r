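# Internal planar geometry on polygon ring lists.
#
# A geometry is a list of rings; a ring is an n x 2 numeric matrix of
# vertices (open: the closing edge is implicit). Multipolygons and holes
# are both expressed as additional rings under the even-odd rule: a point
# is inside the geometry when it falls inside an odd number of rings.
# All coordinates are planar metres (projected CRS); nothing here is
# valid for geographic coordinates.

.ringOpen <- function(ring) {
  ring <- as.matrix(ring)
  storage.mode(ring) <- "double"
  n <- nrow(ring)
  if (n > 1 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  ring
}

.asGeom <- function(g) {
  if (is.matrix(g)) g <- list(g)
  lapply(g, .ringOpen)
}

# Signed shoelace area of one ring (positive when counter-clockwise).
.ringSignedArea <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Even-odd containment parity sign of each ring: +1 for rings nested in an
# even number of sibling rings (outer shells), -1 for holes.
.ringParity <- function(rings) {
  k <- length(rings)
  if (k == 1L) return(1)
  signs <- numeric(k)
  for (i in seq_len(k)) {
    depth <- 0L
    p <- rings[[i]][1, , drop = FALSE]
    for (j in seq_len(k)) {
      if (j != i && .pointsInRing(p[1], p[2], rings[[j]])) depth <- depth + 1L
    }
    signs[i] <- if (depth %% 2L == 0L) 1 else -1
  }
  signs
}

.geomArea <- function(g) {
  rings <- .asGeom(g)
  signs <- .ringParity(rings)
  sum(signs * abs(vapply(rings, .ringSignedArea, numeric(1))))
}

# Even-odd point-in-ring test, vectorised over points (px, py).
.pointsInRing <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  if (n < 3) return(inside)
  x <- ring[, 1]; y <- ring[, 2]
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py))
    if (any(crosses)) {
      xin <- (x[j] - x[i]) * (py[crosses] - y[i]) / (y[j] - y[i]) + x[i]
      hit <- px[crosses] < xin
      inside[crosses] <- xor(inside[crosses], hit)
    }
    j <- i
  }
  inside
}

.pointsInGeom <- function(px, py, g) {
  rings <- .asGeom(g)
  inside <- logical(length(px))
  for (r in rings) inside <- xor(inside, .pointsInRing(px, py, r))
  inside
}

.geomBBox <- function(g) {
  rings <- .asGeom(g)
  xy <- do.call(rbind, rings)
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
    xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

# Minimum distance between two bounding boxes (0 when they overlap).
.bboxDist <- function(a, b) {
  dx <- max(0, max(a["xmin"], b["xmin"]) - min(a["xmax"], b["xmax"]))
  dy <- max(0, max(a["ymin"], b["ymin"]) - min(a["ymax"], b["ymax"]))
  sqrt(dx * dx + dy * dy)
}

# Ring edges as a segment matrix (x1, y1, x2, y2).
.ringSegments <- function(ring) {
  n <- nrow(ring)
  j <- c(seq_len(n)[-1], 1L)
  cbind(ring[, 1], ring[, 2], ring[j, 1], ring[j, 2])
}

.geomSegments <- function(g) {
  do.call(rbind, lapply(.asGeom(g), .ringSegments))
}

# Distance from one point to many segments, vectorised over segments.
.pointToSegments <- function(px, py, segs) {
  dx <- segs[, 3] - segs[, 1]
  dy <- segs[, 4] - segs[, 2]
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 == 0, 0,
              ((px - segs[, 1]) * dx + (py - segs[, 2]) * dy) / len2)
  t <- pmin(1, pmax(0, t))
  qx <- segs[, 1] + t * dx
  qy <- segs[, 2] + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

.orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# Minimum distance between segment s (length-4) and a segment matrix.
.segToSegments <- function(s, segs) {
  d <- pmin(
    .pointToSegments(s[1], s[2], segs),
    .pointToSegments(s[3], s[4], segs),
    mapply(function(x, y) .pointToSegments(x, y, matrix(s, 1)),
           segs[, 1], segs[, 2]),
    mapply(function(x, y) .pointToSegments(x, y, matrix(s, 1)),
           segs[, 3], segs[, 4])
  )
  # proper crossings have distance zero
  o1 <- .orient(s[1], s[2], s[3], s[4], segs[, 1], segs[, 2])
  o2 <- .orient(s[1], s[2], s[3], s[4], segs[, 3], segs[, 4])
  o3 <- .orient(segs[, 1], segs[, 2], segs[, 3], segs[, 4], s[1], s[2])
  o4 <- .orient(segs[, 1], segs[, 2], segs[, 3], segs[, 4], s[3], s[4])
  crossing <- (o1 * o2 < 0) & (o3 * o4 < 0)
  d[crossing] <- 0
  d
}

# Boundary-to-boundary distance between two geometries; 0 when they
# intersect (boundary crossing or full containment).
.geomDist <- function(ga, gb) {
  ga <- .asGeom(ga); gb <- .asGeom(gb)
  if (.pointsInGeom(ga[[1]][1, 1], ga[[1]][1, 2], gb) ||
      .pointsInGeom(gb[[1]][1, 1], gb[[1]][1, 2], ga)) {
    return(0)
  }
  sa <- .geomSegments(ga)
  sb <- .geomSegments(gb)
  best <- Inf
  for (i in seq_len(nrow(sa))) {
    best <- min(best, .segToSegments(sa[i, ], sb))
    if (best == 0) break
  }
  best
}

# Sutherland-Hodgman clip of one ring by a convex ring. Returns the
# clipped ring (possibly with zero rows). The clip ring is forced CCW.
.clipRingConvex <- function(subject, clip) {
  clip <- .ringOpen(clip)
  if (.ringSignedArea(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- .ringOpen(subject)
  nc <- nrow(clip)
  jc <- c(nc, seq_len(nc - 1))
  for (e in seq_len(nc)) {
    ax <- clip[jc[e], 1]; ay <- clip[jc[e], 2]
    bx <- clip[e, 1]; by <- clip[e, 2]
    inp <- out
    n <- nrow(inp)
    if (n == 0) break
    out <- matrix(numeric(0), ncol = 2)
    side <- .orient(ax, ay, bx, by, inp[, 1], inp[, 2]) >= 0
    jprev <- c(n, seq_len(n - 1))
    for (i in seq_len(n)) {
      p <- inp[i, ]; q <- inp[jprev[i], ]
      pin <- side[i]; qin <- side[jprev[i]]
      if (pin != qin) {
        # edge pq crosses the clip line: add the intersection point
        den <- (bx - ax) * (p[2] - q[2]) - (by - ay) * (p[1] - q[1])
        t <- ((bx - ax) * (p[2] - ay) - (by - ay) * (p[1] - ax)) / den
        ix <- p[1] + t * (q[1] - p[1])
        iy <- p[2] + t * (q[2] - p[2])
        out <- rbind(out, c(ix, iy))
      }
      if (pin) out <- rbind(out, p)
    }
  }
  out
}

# Area of geometry intersected with a convex clip ring.
.geomClipArea <- function(g, clip) {
  rings <- .asGeom(g)
  signs <- .ringParity(rings)
  total <- 0
  for (i in seq_along(rings)) {
    cl <- .clipRingConvex(rings[[i]], clip)
    if (nrow(cl) >= 3) total <- total + signs[i] * abs(.ringSignedArea(cl))
  }
  total
}

# Axis-aligned rectangle ring helper.
.rectRing <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

.geomCentroid <- function(g) {
  rings <- .asGeom(g)
  signs <- .ringParity(rings)
  cx <- 0; cy <- 0; atot <- 0
  for (i in seq_along(rings)) {
    r <- rings[[i]]
    n <- nrow(r)
    if (n < 3) next
    j <- c(n, seq_len(n - 1))
    cross <- r[j, 1] * r[, 2] - r[, 1] * r[j, 2]
    a <- sum(cross) / 2
    if (a == 0) next
    gx <- sum((r[j, 1] + r[, 1]) * cross) / (6 * a)
    gy <- sum((r[j, 2] + r[, 2]) * cross) / (6 * a)
    w <- signs[i] * abs(a)
    cx <- cx + gx * w; cy <- cy + gy * w; atot <- atot + w
  }
  if (atot == 0) colMeans(rings[[1]]) else c(cx, cy) / atot
}
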