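#' Planar study-region polygons
#'
#' A study region is a simple polygon in planar metric coordinates, with an
#' optional hole (e.g. an island inside a reef survey area). All downstream
#' analyses (L-functions, prevalence surfaces) work in this planar frame and
#' take the region's area as the reference area \eqn{A}.
#'
#' @param outer two-column matrix (or data.frame) of vertex coordinates in
#'   metres; the ring need not be explicitly closed.
#' @param hole optional inner ring cut out of the region, same format.
#' @return an object of class \code{survey_region} with components
#'   \code{outer}, \code{hole} and \code{area} (square metres).
#' @examples
#' r <- region_polygon(cbind(c(0, 100, 100, 0), c(0, 0, 50, 50)))
#' r$area  # 5000
#' @export
region_polygon <- function(outer, hole = NULL) {
  outer <- as_ring(outer)
  if (!is.null(hole)) hole <- as_ring(hole)
  area <- polygon_area(outer) - if (is.null(hole)) 0 else polygon_area(hole)
  if (!is.finite(area) || area <= 0)
    stop("region has non-positive area; check vertex order and coordinates")
  structure(list(outer = outer, hole = hole, area = area),
            class = "survey_region")
}

#' Rectangular study region
#'
#' @param x_min,x_max,y_min,y_max rectangle bounds in metres.
#' @return a \code{survey_region}.
#' @export
region_rectangle <- function(x_min, x_max, y_min, y_max) {
  stopifnot(x_max > x_min, y_max > y_min)
  region_polygon(cbind(c(x_min, x_max, x_max, x_min),
                       c(y_min, y_min, y_max, y_max)))
}

as_ring <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L || nrow(m) < 3L)
    stop("a polygon ring needs a two-column matrix with >= 3 vertices")
  if (any(!is.finite(m))) stop("polygon vertices must be finite")
  # drop an explicit closing vertex
  if (all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

# shoelace formula, absolute value so ring orientation does not matter
polygon_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

# even-odd ray casting; points on an edge count as inside (boundary tolerance
# is handled upstream by the callers that need one)
points_in_ring <- function(x, y, ring) {
  n <- nrow(ring)
  px <- ring[, 1L]; py <- ring[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
  inside <- logical(length(x))
  on_edge <- logical(length(x))
  for (k in seq_len(n)) {
    crosses <- ((py[k] > y) != (qy[k] > y))
    if (any(crosses)) {
      xint <- px[k] + (y[crosses] - py[k]) * (qx[k] - px[k]) / (qy[k] - py[k])
      flip <- logical(length(x)); flip[crosses] <- x[crosses] < xint
      inside <- xor(inside, flip)
      on_edge[crosses] <- on_edge[crosses] |
        abs(x[crosses] - xint) < 1e-9
    }
    # horizontal / degenerate edges: check collinearity within the segment
    dx <- qx[k] - px[k]; dy <- qy[k] - py[k]
    cross <- (x - px[k]) * dy - (y - py[k]) * dx
    dot <- (x - px[k]) * dx + (y - py[k]) * dy
    len2 <- dx * dx + dy * dy
    on_edge <- on_edge | (abs(cross) < 1e-6 * max(1, sqrt(len2)) &
                            dot >= 0 & dot <= len2)
  }
  inside | on_edge
}

#' Test whether points lie inside a study region
#'
#' @param region a \code{survey_region}.
#' @param x,y point coordinates in metres.
#' @return logical vector; points in the hole (if any) are outside.
#' @export
region_contains <- function(region, x, y) {
  stopifnot(inherits(region, "survey_region"))
  inside <- points_in_ring(x, y, region$outer)
  if (!is.null(region$hole))
    inside <- inside & !points_in_ring(x, y, region$hole)
  inside
}

region_bbox <- function(region) {
  c(x_min = min(region$outer[, 1L]), x_max = max(region$outer[, 1L]),
    y_min = min(region$outer[, 2L]), y_max = max(region$outer[, 2L]))
}

# uniform draws inside a region by rejection from the bounding box
runif_region <- function(n, region) {
  bb <- region_bbox(region)
  out_x <- numeric(n); out_y <- numeric(n)
  got <- 0L
  frac <- region$area / ((bb["x_max"] - bb["x_min"]) * (bb["y_max"] - bb["y_min"]))
  if (frac < 1e-6) stop("region is degenerate relative to its bounding box")
  while (got < n) {
    m <- ceiling((n - got) / frac) + 16L
    cx <- stats::runif(m, bb["x_min"], bb["x_max"])
    cy <- stats::runif(m, bb["y_min"], bb["y_max"])
    keep <- region_contains(region, cx, cy)
    k <- min(sum(keep), n - got)
    if (k > 0L) {
      idx <- which(keep)[seq_len(k)]
      out_x[got + seq_len(k)] <- cx[idx]
      out_y[got + seq_len(k)] <- cy[idx]
      got <- got + k
    }
  }
  cbind(x = out_x, y = out_y)
}

#' @export
print.survey_region <- function(x, ...) {
  bb <- region_bbox(x)
  cat(sprintf("Study region: %d outer vertices%s\n", nrow(x$outer),
              if (is.null(x$hole)) "" else sprintf(", hole with %d vertices", nrow(x$hole))))
  cat(sprintf("  extent: %.0f x %.0f m, area %.4f km^2\n",
              bb["x_max"] - bb["x_min"], bb["y_max"] - bb["y_min"], x$area / 1e6))
  invisible(x)
}
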