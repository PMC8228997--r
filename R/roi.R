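#' Corneal region of interest
#'
#' A cornea ROI is the pair of polygons an experienced user draws on a
#' flat-mount image: the outer limbal-edge border, which defines the total
#' cornea area, and an optional inner exclusion border around the central
#' portion of the cornea (staining artifacts there are excluded from both
#' the segmentation and the area denominator).
#'
#' Polygons are given in pixel coordinates with origin at the top-left,
#' `x` = column and `y` = row; pixel centers sit at integer coordinates.
#'
#' @param outer numeric matrix (or two-column data frame) of outer polygon
#'   vertices, columns x and y; must be simple (non-self-intersecting) with
#'   positive area.
#' @param inner optional inner exclusion polygon, same format; must lie
#'   strictly inside the outer polygon. `NULL` for none.
#' @return an object of class `cornea_roi` with elements `outer` and
#'   `inner` (each an n x 2 matrix, or `NULL`).
#' @examples
#' sq <- cbind(c(1, 10, 10, 1), c(1, 1, 10, 10))
#' roi <- cornea_roi(sq)
#' @export
cornea_roi <- function(outer, inner = NULL) {
  outer <- as_poly(outer, "outer")
  if (!is_simple_polygon(outer))
    stopf("outer polygon is self-intersecting")
  if (abs(shoelace_area(outer)) <= 0)
    stopf("outer polygon has zero area: degenerate ROI")
  if (!is.null(inner)) {
    inner <- as_poly(inner, "inner")
    if (!is_simple_polygon(inner))
      stopf("inner polygon is self-intersecting")
    if (!all(point_in_polygon(inner[, 1], inner[, 2], outer)) ||
        polygons_intersect(outer, inner))
      stopf("inner polygon must lie strictly inside the outer polygon")
  }
  structure(list(outer = outer, inner = inner), class = "cornea_roi")
}

as_poly <- function(p, name) {
  p <- as.matrix(p)
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 3L || anyNA(p))
    stopf("'%s' polygon must be a numeric n x 2 matrix with n >= 3", name)
  # drop a repeated closing vertex
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  dimnames(p) <- list(NULL, c("x", "y"))
  p
}

# signed area by the shoelace formula
shoelace_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# proper-crossing test for two closed segments (shared endpoints between
# adjacent polygon edges do not count)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

poly_edges <- function(p) {
  n <- nrow(p)
  list(a = p, b = p[c(2:n, 1), , drop = FALSE])
}

is_simple_polygon <- function(p) {
  n <- nrow(p)
  e <- poly_edges(p)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(e$a[i, ], e$b[i, ], e$a[j, ], e$b[j, ])) return(FALSE)
    }
  }
  TRUE
}

polygons_intersect <- function(p, q) {
  ep <- poly_edges(p); eq <- poly_edges(q)
  for (i in seq_len(nrow(p)))
    for (j in seq_len(nrow(q)))
      if (segments_cross(ep$a[i, ], ep$b[i, ], eq$a[j, ], eq$b[j, ]))
        return(TRUE)
  FALSE
}

# vectorised even-odd (crossing number) point-in-polygon test
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    crosses <- (y[i] > py) != (yn[i] > py)
    if (any(crosses)) {
      xi <- (xn[i] - x[i]) * (py[crosses] - y[i]) / (yn[i] - y[i]) + x[i]
      idx <- which(crosses)[px[crosses] < xi]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

#' Rasterize a cornea ROI to a binary mask
#'
#' Pixels whose centers fall inside the outer polygon and outside the inner
#' exclusion polygon are set. The pixel count of this mask is the total
#' cornea area used as the denominator of vessel densities.
#'
#' @param roi a [cornea_roi()].
#' @param shape integer vector `c(height, width)` of the target raster.
#' @return logical `height x width` matrix.
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "cornea_roi"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stopf("'shape' must be positive c(height, width)")
  h <- shape[1]; w <- shape[2]
  px <- rep(seq_len(w), each = h)   # column-major: x varies with column
  py <- rep(seq_len(h), times = w)  # y = row index
  m <- point_in_polygon(px, py, roi$outer)
  if (!is.null(roi$inner))
    m <- m & !point_in_polygon(px, py, roi$inner)
  matrix(m, nrow = h, ncol = w)
}

#' Read and write ROI polygons as JSON
#'
#' The on-disk format is a JSON object with an `"outer"` (and optionally
#' `"inner"`) list of `[x, y]` pixel-coordinate vertex pairs, origin
#' top-left. ROI invariants are validated at read time.
#'
#' @param path file path.
#' @return `read_roi` returns a [cornea_roi()]; `write_roi` returns `path`
#'   invisibly.
#' @export
read_roi <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj$outer)) stopf("ROI JSON must contain an \"outer\" polygon")
  inner <- obj$inner
  if (!is.null(inner) && length(inner) == 0L) inner <- NULL
  cornea_roi(obj$outer, inner)
}

#' @param roi a [cornea_roi()].
#' @rdname read_roi
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "cornea_roi"))
  obj <- list(outer = unname(roi$outer))
  if (!is.null(roi$inner)) obj$inner <- unname(roi$inner)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Regular-polygon approximation of a circular cornea ROI
#'
#' Convenience constructor for synthetic data: an outer limbal circle and an
#' optional concentric inner exclusion circle, both as regular polygons.
#'
#' @param shape raster `c(height, width)` the ROI is meant for.
#' @param outer_radius outer circle radius in pixels (default 45% of the
#'   smaller image dimension, leaving a margin outside the limbus).
#' @param inner_radius inner exclusion radius in pixels; 0 or `NULL` for no
#'   inner border.
#' @param center circle center `c(x, y)`; default image center.
#' @param n_vertices polygon vertex count (default 72).
#' @return a [cornea_roi()].
#' @export
circular_roi <- function(shape, outer_radius = 0.45 * min(shape),
                         inner_radius = 0.12 * min(shape),
                         center = NULL, n_vertices = 72) {
  if (is.null(center)) center <- c((shape[2] + 1) / 2, (shape[1] + 1) / 2)
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  circ <- function(r) cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
  inner <- NULL
  if (!is.null(inner_radius) && inner_radius > 0) inner <- circ(inner_radius)
  cornea_roi(circ(outer_radius), inner)
}
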