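# Internal geometry helpers shared across modules. Masks are logical matrices
# indexed [row, col]; coordinates are 1-based with x = column, y = row and
# pixel centers at integers.

as_mask <- function(x) {
  stopifnot(is.matrix(x))
  storage.mode(x) <- "logical"
  x
}

# Component masks may be stored cropped to a padded bounding box, with an
# "offset" attribute c(ox, oy) such that global = local + offset. All
# coordinate-producing helpers honour it, so cropped and full-frame masks
# are interchangeable.
mask_offset <- function(mask) {
  off <- attr(mask, "offset")
  if (is.null(off)) c(0, 0) else off
}

# foreground pixel coordinates as an n x 2 matrix (x = col, y = row),
# in global image coordinates
mask_coords <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  nr <- nrow(mask)
  off <- mask_offset(mask)
  cbind(x = ((idx - 1L) %/% nr) + 1L + off[1],
        y = ((idx - 1L) %% nr) + 1L + off[2])
}

# per-pixel image values (n x 3) under a possibly-cropped mask; linear
# indexing into the array avoids materializing full channel planes
mask_image_values <- function(image, mask) {
  xy <- mask_coords(mask)
  H <- dim(image)[1]
  np <- H * dim(image)[2]
  idx <- (xy[, 1] - 1) * H + xy[, 2]
  cbind(image[idx], image[idx + np], image[idx + 2 * np])
}

mask_centroid <- function(mask) {
  xy <- mask_coords(mask)
  c(x = mean(xy[, 1]), y = mean(xy[, 2]))
}

# shoelace signed area of a closed polygon (n x 2, columns x, y)
polygon_signed_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_length <- function(p, closed = TRUE) {
  n <- nrow(p)
  if (n < 2) return(0)
  d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  tot <- sum(d)
  if (closed && n > 2) {
    tot <- tot + sqrt((p[1, 1] - p[n, 1])^2 + (p[1, 2] - p[n, 2])^2)
  }
  unname(tot)
}

# Ramer-Douglas-Peucker simplification of an open polyline, returning kept
# vertex indices. Iterative stack formulation to avoid deep recursion.
rdp_indices <- function(p, tol) {
  n <- nrow(p)
  if (n <= 2 || tol <= 0) return(seq_len(n))
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    a <- p[i, ]; b <- p[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ks <- (i + 1L):(j - 1L)
    if (len2 == 0) {
      d <- sqrt((p[ks, 1] - a[1])^2 + (p[ks, 2] - a[2])^2)
    } else {
      # perpendicular distance to the segment's supporting line
      d <- abs(ab[2] * (p[ks, 1] - a[1]) - ab[1] * (p[ks, 2] - a[2])) / sqrt(len2)
    }
    kmax <- which.max(d)
    if (d[kmax] > tol) {
      k <- ks[kmax]
      keep[k] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  which(keep)
}

# Simplify a closed contour polygon: split at the vertex farthest from the
# first, simplify both halves, and rejoin.
simplify_contour <- function(p, tol) {
  n <- nrow(p)
  if (n <= 3 || tol <= 0) return(p)
  d <- (p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2
  s <- which.max(d)
  i1 <- rdp_indices(p[1:s, , drop = FALSE], tol)
  i2 <- rdp_indices(p[s:n, , drop = FALSE], tol) + s - 1L
  idx <- unique(c(i1, i2))
  p[idx[idx <= n], , drop = FALSE]
}

# Minimum enclosing circle (Welzl's algorithm with move-to-front ordering).
# Points: n x 2. Returns list(center = c(x, y), radius).
min_enclosing_circle <- function(pts) {
  pts <- unique(round(pts, 9))
  n <- nrow(pts)
  if (n == 0) stop("no points for enclosing circle", call. = FALSE)
  if (n == 1) return(list(center = as.numeric(pts[1, ]), radius = 0))
  circ2 <- function(a, b) {
    c0 <- (a + b) / 2
    list(center = c0, radius = sqrt(sum((a - c0)^2)))
  }
  circ3 <- function(a, b, c) {
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
  }
  inside <- function(circ, p, eps = 1e-7) {
    sqrt(sum((p - circ$center)^2)) <= circ$radius + eps
  }
  trivial <- function(R) {
    m <- length(R)
    if (m == 0) return(list(center = c(0, 0), radius = 0))
    if (m == 1) return(list(center = R[[1]], radius = 0))
    if (m == 2) return(circ2(R[[1]], R[[2]]))
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      cc <- circ2(R[[pair[1]]], R[[pair[2]]])
      if (all(vapply(R, function(p) inside(cc, p), logical(1)))) return(cc)
    }
    circ3(R[[1]], R[[2]], R[[3]]) %||% circ2(R[[1]], R[[2]])
  }
  # deterministic pseudo-shuffle (no RNG state touched)
  ord <- order((seq_len(n) * 2654435761) %% 4294967296)
  P <- pts[ord, , drop = FALSE]
  circ <- list(center = as.numeric(P[1, ]), radius = 0)
  for (i in seq_len(n)) {
    pi_ <- as.numeric(P[i, ])
    if (inside(circ, pi_)) next
    circ <- list(center = pi_, radius = 0)
    for (j in seq_len(i - 1L)) {
      pj <- as.numeric(P[j, ])
      if (inside(circ, pj)) next
      circ <- circ2(pi_, pj)
      for (k in seq_len(j - 1L)) {
        pk <- as.numeric(P[k, ])
        if (inside(circ, pk)) next
        circ <- trivial(list(pi_, pj, pk))
      }
    }
  }
  circ
}

# Rotate points (n x 2) about a center by theta radians (x toward y)
rotate_points <- function(p, theta, center = c(0, 0)) {
  ct <- cos(theta); st <- sin(theta)
  dx <- p[, 1] - center[1]; dy <- p[, 2] - center[2]
  cbind(x = center[1] + ct * dx - st * dy,
        y = center[2] + st * dx + ct * dy)
}

# Count pixels whose centers fall inside (or on) the convex hull of a point set
convex_hull_pixel_area <- function(pts) {
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[h, , drop = FALSE]
  if (nrow(hull) < 3) return(nrow(unique(round(pts))))
  xr <- floor(min(hull[, 1])):ceiling(max(hull[, 1]))
  yr <- floor(min(hull[, 2])):ceiling(max(hull[, 2]))
  gx <- rep(xr, times = length(yr))
  gy <- rep(yr, each = length(xr))
  inside <- pracma::inpolygon(gx, gy, hull[, 1], hull[, 2], boundary = TRUE)
  sum(inside)
}

# clamp numeric vector
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# lower median of an integer-valued sample (tie rule: take the lower of the
# two central order statistics so channel medians stay integers)
median_lower <- function(x) {
  n <- length(x)
  sort(x, partial = (n + 1L) %/% 2L)[(n + 1L) %/% 2L]
}
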