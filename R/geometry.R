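# planar computational geometry for range estimation
#
# All coordinates are planar. Lon/lat input should be pre-projected with
# project_lonlat(); range-overlap proportions are area ratios and are
# insensitive to the projection at the spatial extents involved here.

#' Construct a convex polygon
#'
#' @param vertices two-column numeric matrix (x, y) of vertices in
#'   counter-clockwise order, without a repeated closing vertex.
#' @return an object of class `convex_polygon`.
#' @export
convex_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L || !all(is.finite(vertices))) {
    stop("a convex polygon needs >= 3 finite (x, y) vertices", call. = FALSE)
  }
  colnames(vertices) <- c("x", "y")
  vertices <- prune_collinear(vertices)
  if (nrow(vertices) < 3L) stop("degenerate hull", call. = FALSE)
  if (shoelace(vertices) <= 0) {
    stop("vertices must be in counter-clockwise order with positive area",
         call. = FALSE)
  }
  structure(list(vertices = vertices), class = "convex_polygon")
}

#' @export
print.convex_polygon <- function(x, ...) {
  cat(sprintf("<convex polygon: %d vertices, area %.6g>\n",
              nrow(x$vertices), polygon_area(x)))
  invisible(x)
}

# cross product (b - a) x (c - a); > 0 means c is left of a->b
cross2 <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

# drop vertices collinear with their neighbours (keeps strict convexity)
prune_collinear <- function(v, tol = 0) {
  repeat {
    n <- nrow(v)
    if (n < 3L) return(v)
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      a <- v[if (i == 1L) n else i - 1L, ]
      b <- v[i, ]
      c <- v[if (i == n) 1L else i + 1L, ]
      if (abs(cross2(a, b, c)) <= tol) keep[i] <- FALSE
    }
    if (all(keep)) return(v)
    v <- v[keep, , drop = FALSE]
  }
}

shoelace <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

#' Convex hull of a planar point set
#'
#' Andrew's monotone-chain algorithm with lexicographic (x, then y) ordering;
#' points collinear on the hull boundary are pruned so the result is strictly
#' convex.
#'
#' @param points two-column matrix or data frame of (x, y) coordinates.
#' @return a [convex_polygon] whose vertices are a subset of the input
#'   points, in counter-clockwise order.
#' @export
convex_hull <- function(points) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  if (!all(is.finite(p))) stop("non-finite coordinates", call. = FALSE)
  p <- unique(p)
  if (nrow(p) < 3L) stop("degenerate hull", call. = FALSE)
  ord <- order(p[, 1], p[, 2])
  p <- p[ord, , drop = FALSE]
  n <- nrow(p)

  build <- function(idx) {
    st <- integer(0)
    for (i in idx) {
      while (length(st) >= 2L &&
             cross2(p[st[length(st) - 1L], ], p[st[length(st)], ], p[i, ]) <= 0) {
        st <- st[-length(st)]
      }
      st <- c(st, i)
    }
    st
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- p[c(lower[-length(lower)], upper[-length(upper)]), , drop = FALSE]
  if (nrow(hull) < 3L) stop("degenerate hull", call. = FALSE)
  colnames(hull) <- c("x", "y")
  structure(list(vertices = hull), class = "convex_polygon")
}

#' Polygon area (shoelace formula)
#'
#' @param poly a [convex_polygon].
#' @return area in squared planar units.
#' @export
polygon_area <- function(poly) {
  shoelace(poly$vertices)
}

#' Intersection of two convex polygons
#'
#' Successive half-plane clipping (Sutherland–Hodgman); convexity of both
#' inputs guarantees the result is their true intersection. Degenerate
#' intersections (shared edge or point only) are reported as empty, since
#' measure-zero sets cannot affect area ratios.
#'
#' @param a,b [convex_polygon] objects.
#' @return a [convex_polygon], or `NULL` when the interiors are disjoint.
#' @export
convex_intersection <- function(a, b) {
  subject <- a$vertices
  clip <- b$vertices
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(subject) == 0L) break
    p1 <- clip[i, ]
    p2 <- clip[if (i == nc) 1L else i + 1L, ]
    subject <- clip_halfplane(subject, p1, p2)
  }
  if (nrow(subject) < 3L) return(NULL)
  subject <- prune_collinear(subject, tol = 1e-12 * max(1, max(abs(subject)))^2)
  if (nrow(subject) < 3L || shoelace(subject) <= 0) return(NULL)
  structure(list(vertices = subject), class = "convex_polygon")
}

# keep the part of polygon v on the left of directed edge p1 -> p2
clip_halfplane <- function(v, p1, p2) {
  n <- nrow(v)
  if (n == 0L) return(v)
  side <- (p2[1] - p1[1]) * (v[, 2] - p1[2]) - (p2[2] - p1[2]) * (v[, 1] - p1[1])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cur_in <- side[i] >= 0
    nxt_in <- side[j] >= 0
    if (cur_in) out <- rbind(out, v[i, ])
    if (cur_in != nxt_in) {
      t <- side[i] / (side[i] - side[j])
      out <- rbind(out, v[i, ] + t * (v[j, ] - v[i, ]))
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Directional range overlap
#'
#' Fraction of `target`'s area covered by `other`:
#' `area(target intersect other) / area(target)`.
#'
#' @param target,other [convex_polygon] objects.
#' @return a proportion in \[0, 1\].
#' @export
directional_overlap <- function(target, other) {
  inter <- convex_intersection(target, other)
  if (is.null(inter)) return(0)
  min(1, polygon_area(inter) / polygon_area(target))
}

#' Symmetric range overlap
#'
#' The average of the two directional overlaps: the proportion of A's range
#' overlapping B plus the proportion of B's range overlapping A, divided by
#' two.
#'
#' @param a,b [convex_polygon] objects.
#' @return a proportion in \[0, 1\].
#' @export
symmetric_overlap <- function(a, b) {
  (directional_overlap(a, b) + directional_overlap(b, a)) / 2
}

#' Test whether points fall inside (or on) a convex polygon
#'
#' @param poly a [convex_polygon].
#' @param points two-column matrix of (x, y).
#' @param tol boundary tolerance (absolute, in cross-product units).
#' @return logical vector.
#' @export
points_in_polygon <- function(poly, points, tol = 1e-9) {
  v <- poly$vertices
  n <- nrow(v)
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  inside <- rep(TRUE, nrow(p))
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[if (i == n) 1L else i + 1L, ]
    s <- (b[1] - a[1]) * (p[, 2] - a[2]) - (b[2] - a[2]) * (p[, 1] - a[1])
    inside <- inside & (s >= -tol)
  }
  inside
}

#' Equirectangular pre-projection for longitude/latitude records
#'
#' Maps lon/lat to planar coordinates `x = lon * cos(mean latitude)`,
#' `y = lat` (degrees). Adequate for area ratios over regional extents;
#' not a substitute for a true map projection.
#'
#' @param lon,lat numeric vectors in degrees.
#' @return two-column matrix of planar (x, y).
#' @export
project_lonlat <- function(lon, lat) {
  cbind(x = lon * cos(mean(lat) * pi / 180), y = lat)
}
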