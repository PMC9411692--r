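#' Construct a vertex-view skull contour
#'
#' A skull contour is an ordered, closed, simple polygon tracing the outer
#' skull outline as seen from directly above the head (vertex view). Model
#' coordinates are unit-agnostic: `x` points toward the subject's right,
#' `y` anterior (toward the nose).
#'
#' On construction the polygon is normalised: a duplicated closing vertex is
#' dropped, consecutive vertices closer than `1e-9` times the contour
#' diameter are merged, and the vertex order is re-oriented counterclockwise.
#' The polygon must remain simple (non-self-intersecting), enclose positive
#' area, and keep at least 32 vertices.
#'
#' @param vertices numeric matrix (or data frame) with two columns, `x` and
#'   `y`; one row per vertex, last vertex implicitly joined to the first.
#' @param units_label free-text label for the length units (default `""`).
#' @return An object of class `skull_contour`: a list with elements
#'   `vertices` (n x 2 matrix, counterclockwise), `units_label`, and cached
#'   `diameter` (bounding-box diagonal).
#' @export
skull_contour <- function(vertices, units_label = "") {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L)
    stop("contour vertices must be a numeric matrix with columns x, y")
  if (!all(is.finite(v)))
    stop("contour vertices must be finite")
  colnames(v) <- c("x", "y")

  # drop explicit closing vertex, then merge near-duplicate neighbours
  diam <- sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
  if (diam <= 0) stop("contour is degenerate: zero diameter")
  tol <- 1e-9 * diam
  if (nrow(v) > 1 && sqrt(sum((v[1, ] - v[nrow(v), ])^2)) < tol)
    v <- v[-nrow(v), , drop = FALSE]
  keep <- c(TRUE, sqrt(rowSums((v[-1, , drop = FALSE] -
                                v[-nrow(v), , drop = FALSE])^2)) >= tol)
  v <- v[keep, , drop = FALSE]

  if (nrow(v) < 32L)
    stop("contour must have at least 32 vertices, got ", nrow(v))

  area <- pracma::polyarea(v[, 1], v[, 2])
  if (abs(area) <= 0) stop("contour encloses zero area")
  if (area < 0) v <- v[nrow(v):1, , drop = FALSE]  # pracma: CCW -> positive

  if (!.polygon_is_simple(v))
    stop("contour is self-intersecting; a simple polygon is required")

  structure(list(vertices = v, units_label = units_label, diameter = diam),
            class = "skull_contour")
}

#' @export
print.skull_contour <- function(x, ...) {
  cat("skull_contour:", nrow(x$vertices), "vertices, diameter",
      format(x$diameter, digits = 6),
      if (nzchar(x$units_label)) x$units_label else "(unitless)", "\n")
  invisible(x)
}

# Simple-polygon check: no two non-adjacent edges intersect.
# Vectorised over all edge pairs; n is a few hundred in practice.
.polygon_is_simple <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  adj <- (j == i + 1L) | (i == 1L & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(TRUE)
  d1 <- .orient(a[i, ], b[i, ], a[j, ])
  d2 <- .orient(a[i, ], b[i, ], b[j, ])
  d3 <- .orient(a[j, ], b[j, ], a[i, ])
  d4 <- .orient(a[j, ], b[j, ], b[i, ])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

.orient <- function(p, q, r) {
  (q[, 1] - p[, 1]) * (r[, 2] - p[, 2]) - (q[, 2] - p[, 2]) * (r[, 1] - p[, 1])
}

#' Construct a landmark set
#'
#' Three anatomical landmarks anchor the measurement frame: the highest point
#' of the nasal dorsum and the anterior helical border of each ear.
#'
#' @param nose,ear_left,ear_right numeric length-2 vectors `(x, y)`.
#'   `ear_left`/`ear_right` are the subject's left/right ears.
#' @param contour optional `skull_contour`; when given, all three landmarks
#'   are checked to lie inside (or on) the contour, and the nose is required
#'   to be off the ear line by more than 1% of the inter-ear distance.
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(nose, ear_left, ear_right, contour = NULL) {
  pts <- list(nose = nose, ear_left = ear_left, ear_right = ear_right)
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 2L || !all(is.finite(p)))
      stop("landmark '", nm, "' must be a finite (x, y) pair")
    pts[[nm]] <- p
  }
  ee <- sqrt(sum((pts$ear_right - pts$ear_left)^2))
  if (ee <= 0) stop("invalid landmarks: ear points coincide")
  # perpendicular distance from nose to the ear line
  u <- (pts$ear_right - pts$ear_left) / ee
  w <- pts$nose - pts$ear_left
  dist_nose <- abs(u[1] * w[2] - u[2] * w[1])
  if (dist_nose <= 0.01 * ee)
    stop("invalid landmarks: nose is (nearly) collinear with the ear pair")

  lm <- structure(pts, class = "landmark_set")
  if (!is.null(contour)) .check_landmarks_inside(lm, contour)
  lm
}

.check_landmarks_inside <- function(landmarks, contour) {
  v <- contour$vertices
  for (nm in c("nose", "ear_left", "ear_right")) {
    p <- landmarks[[nm]]
    inp <- pracma::inpolygon(p[1], p[2], v[, 1], v[, 2], boundary = TRUE)
    if (!inp)
      stop("landmark '", nm, "' lies outside the contour")
  }
  invisible(TRUE)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set: nose (", x$nose[1], ",", x$nose[2],
      ") ears L(", x$ear_left[1], ",", x$ear_left[2],
      ") R(", x$ear_right[1], ",", x$ear_right[2], ")\n")
  invisible(x)
}

# Strict interior test (boundary not accepted)
.point_in_contour <- function(p, contour) {
  v <- contour$vertices
  isTRUE(pracma::inpolygon(p[1], p[2], v[, 1], v[, 2], boundary = FALSE))
}
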