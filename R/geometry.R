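#' Full skull chord through an interior point
#'
#' Intersects the infinite line through `point` along `direction` with the
#' contour polygon and returns the two outermost crossings, one on each side
#' of `point`. For a non-convex contour with more than two crossings, the
#' crossing farthest from `point` on each side is taken: the measured chord
#' always ends on the outside of the skull. The result does not depend on the
#' sign of `direction`.
#'
#' @param contour a `skull_contour`.
#' @param point numeric `(x, y)`, strictly inside the contour.
#' @param direction numeric `(x, y)` direction vector (any non-zero length).
#' @return list with `p1`, `p2` (the endpoints, `p1` on the `+direction`
#'   side), and `length` (their separation).
#' @export
chord_through <- function(contour, point, direction) {
  point <- as.numeric(point); direction <- as.numeric(direction)
  nd <- sqrt(sum(direction^2))
  if (nd <= 0) stop("direction must be non-zero")
  d <- direction / nd
  if (!.point_in_contour(point, contour))
    stop("chord origin point is not strictly inside the contour")

  v <- contour$vertices
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  # signed perpendicular coordinate of each vertex w.r.t. the line;
  # vertices exactly on the line count as the positive side, so a line
  # through a vertex yields exactly one crossing and a tangential touch none
  u <- d[1] * (v[, 2] - point[2]) - d[2] * (v[, 1] - point[1])
  side <- u >= 0
  hit <- side != side[nxt]
  if (!any(hit)) stop("geometry error: line does not cross the contour")
  i <- which(hit)
  frac <- u[i] / (u[i] - u[nxt][i])
  px <- v[i, 1] + frac * (v[nxt, 1][i] - v[i, 1])
  py <- v[i, 2] + frac * (v[nxt, 2][i] - v[i, 2])
  tvals <- (px - point[1]) * d[1] + (py - point[2]) * d[2]

  # merge crossings closer than 1e-12 * diameter (shared-vertex duplicates)
  tvals <- sort(tvals)
  tol <- 1e-12 * contour$diameter
  tvals <- tvals[c(TRUE, diff(tvals) >= tol)]

  pos <- tvals[tvals > 0]
  neg <- tvals[tvals < 0]
  if (!length(pos) || !length(neg))
    stop("geometry error: line does not cross the contour on both sides of the point")
  t1 <- max(pos)   # farthest crossing, +direction side
  t2 <- min(neg)   # farthest crossing, -direction side
  list(p1 = point + t1 * d, p2 = point + t2 * d, length = t1 - t2)
}

#' Build the measurement frame from contour and landmarks
#'
#' Implements the vertex-view construction: a mediolateral line is drawn
#' through the anterior helical border points of the two ears and extended to
#' the outside of the skull (the EarEar chord); `m1` is the midpoint of that
#' chord. The anteroposterior line runs through the nasal-dorsum landmark and
#' `m1`, again extended to the skull outline (the NoseOcciput chord, anterior
#' endpoint on the nose side); `m2` is its midpoint. The anteroposterior axis
#' is not forced perpendicular to the ear line; it follows the landmarks.
#'
#' @param contour a `skull_contour`.
#' @param landmarks a `landmark_set`.
#' @return Object of class `head_frame`: list with unit vectors
#'   `ear_line_dir` and `ap_dir` (pointing toward the nose), midpoints `m1`
#'   and `m2`, and chords `ear_chord`, `ap_chord` (each a list `p1`, `p2`,
#'   `length`; for `ap_chord`, `p1` is the anterior endpoint).
#' @export
build_frame <- function(contour, landmarks) {
  if (!inherits(contour, "skull_contour")) stop("contour must be a skull_contour")
  if (!inherits(landmarks, "landmark_set")) stop("landmarks must be a landmark_set")
  .check_landmarks_inside(landmarks, contour)

  el <- landmarks$ear_right - landmarks$ear_left
  ee_len <- sqrt(sum(el^2))
  if (ee_len <= 0) stop("invalid landmarks: ear points coincide")
  ear_dir <- el / ee_len

  ear_origin <- (landmarks$ear_left + landmarks$ear_right) / 2
  ear_chord <- tryCatch(chord_through(contour, ear_origin, ear_dir),
                        error = function(e) stop("ear line: ", conditionMessage(e)))
  m1 <- (ear_chord$p1 + ear_chord$p2) / 2

  ap <- landmarks$nose - m1
  ap_len <- sqrt(sum(ap^2))
  if (ap_len <= 1e-12 * contour$diameter)
    stop("invalid landmarks: nose coincides with the ear-chord midpoint")
  ap_dir <- ap / ap_len

  ap_chord <- tryCatch(chord_through(contour, m1, ap_dir),
                       error = function(e) stop("nose-occiput line: ", conditionMessage(e)))
  # chord_through puts p1 on the +ap_dir (nose) side already
  m2 <- (ap_chord$p1 + ap_chord$p2) / 2

  structure(list(ear_line_dir = ear_dir, ap_dir = ap_dir,
                 m1 = m1, m2 = m2,
                 ear_chord = ear_chord, ap_chord = ap_chord),
            class = "head_frame")
}

#' @export
print.head_frame <- function(x, ...) {
  cat("head_frame: EarEar", format(x$ear_chord$length, digits = 6),
      " NoseOcciput", format(x$ap_chord$length, digits = 6), "\n")
  invisible(x)
}

#' Measure the oblique diagonal pair at a given angle
#'
#' From `m2` (the midpoint of the nose-occiput skull chord) two full skull
#' chords are measured at `+angle_deg` and `-angle_deg` from the
#' anteroposterior axis, rotating toward the subject's right and left
#' respectively. CVAI uses 30 degrees; the digitally emulated ODDI uses 40.
#'
#' @param contour a `skull_contour`.
#' @param frame a `head_frame` from [build_frame()].
#' @param angle_deg angle from the anteroposterior axis, in (0, 90).
#' @return Object of class `diagonal_pair`: `angle_deg`, `chord_right`,
#'   `chord_left`, `long`, `short`.
#' @export
measure_diagonals <- function(contour, frame, angle_deg) {
  if (!(angle_deg > 0 && angle_deg < 90))
    stop("angle_deg must be strictly between 0 and 90")
  th <- angle_deg * pi / 180
  d <- frame$ap_dir
  # subject's right = ap_dir rotated by -90 deg (x right when y anterior)
  right <- c(d[2], -d[1])
  dir_right <- cos(th) * d + sin(th) * right
  dir_left  <- cos(th) * d - sin(th) * right
  cr <- chord_through(contour, frame$m2, dir_right)$length
  cl <- chord_through(contour, frame$m2, dir_left)$length
  structure(list(angle_deg = angle_deg, chord_right = cr, chord_left = cl,
                 long = max(cr, cl), short = min(cr, cl)),
            class = "diagonal_pair")
}

#' Cranial vault asymmetry index (CVAI)
#'
#' `(long - short) / short * 100`; zero for a symmetric head.
#'
#' @param pair a `diagonal_pair` (conventionally measured at 30 degrees).
#' @return CVAI in percent, `>= 0`.
#' @export
compute_cvai <- function(pair) {
  stopifnot(inherits(pair, "diagonal_pair"))
  (pair$long - pair$short) / pair$short * 100
}

#' Cranial index (CI)
#'
#' Skull width over skull length: `EarEar / NoseOcciput * 100`.
#'
#' @param ear_ear,nose_occiput positive chord lengths (same units).
#' @return CI in percent.
#' @export
compute_ci <- function(ear_ear, nose_occiput) {
  if (!(ear_ear > 0 && nose_occiput > 0))
    stop("chord lengths must be positive")
  ear_ear / nose_occiput * 100
}

#' Oblique diameter difference index (ODDI)
#'
#' Ratio form `long / short * 100`, measured on the 40-degree diagonal pair;
#' equals 100 for a symmetric head. This is the digital emulation of the
#' plagiocephalometry asymmetry parameter, consistent with its published
#' severity thresholds (104 / 108 / 112).
#'
#' @param pair a `diagonal_pair` measured at 40 degrees.
#' @return ODDI in percent, `>= 100`.
#' @export
compute_oddi <- function(pair) {
  stopifnot(inherits(pair, "diagonal_pair"))
  pair$long / pair$short * 100
}

#' Measure all four cranial indices
#'
#' Runs the full pipeline: frame construction, diagonal measurement at 30 and
#' 40 degrees, and computation of CVAI, CI, ODDI and CPI. CPI (the
#' plagiocephalometry width/length parameter) is computed by the same
#' formula as CI on the same frame, since both indices share their published
#' thresholds; on identical geometry `cpi == ci`.
#'
#' @param contour a `skull_contour`.
#' @param landmarks a `landmark_set`.
#' @return Object of class `index_result`: `cvai`, `ci`, `oddi`, `cpi`
#'   (percent), `ear_ear`, `nose_occiput` (lengths), and the measured
#'   `diag30`, `diag40` pairs.
#' @export
measure_all <- function(contour, landmarks) {
  frame <- tryCatch(build_frame(contour, landmarks),
                    error = function(e) stop("frame construction failed: ",
                                             conditionMessage(e)))
  d30 <- tryCatch(measure_diagonals(contour, frame, 30),
                  error = function(e) stop("30-degree diagonals failed: ",
                                           conditionMessage(e)))
  d40 <- tryCatch(measure_diagonals(contour, frame, 40),
                  error = function(e) stop("40-degree diagonals failed: ",
                                           conditionMessage(e)))
  ee <- frame$ear_chord$length
  no <- frame$ap_chord$length
  ci <- compute_ci(ee, no)
  structure(list(cvai = compute_cvai(d30), ci = ci,
                 oddi = compute_oddi(d40), cpi = ci,
                 ear_ear = ee, nose_occiput = no,
                 diag30 = d30, diag40 = d40),
            class = "index_result")
}

#' @export
print.index_result <- function(x, digits = 4, ...) {
  cat(sprintf("index_result: CVAI %.*f  CI %.*f  ODDI %.*f  CPI %.*f\n",
              digits, x$cvai, digits, x$ci, digits, x$oddi, digits, x$cpi))
  cat(sprintf("  EarEar %.*f  NoseOcciput %.*f\n",
              digits, x$ear_ear, digits, x$nose_occiput))
  invisible(x)
}
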