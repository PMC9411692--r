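#' Parameters for a synthetic vertex-view head contour
#'
#' The generator models an infant head outline in polar form around an
#' ellipse: `r(theta) = r_ellipse(theta; a, b) * (1 - d * exp(-angdist(theta,
#' theta0)^2 / (2 sigma^2))) + noise`, with `theta` measured from the
#' anterior axis toward the subject's right. The Gaussian angular dent
#' produces unilateral posterior-lateral flattening (plagiocephaly, driving
#' CVAI/ODDI); the `a/b` semi-axis ratio produces head widening
#' (brachycephaly, driving CI/CPI). Radial noise emulates contour
#' segmentation jitter.
#'
#' @param a half-width (mediolateral semi-axis), > 0.
#' @param b half-length (anteroposterior semi-axis), > 0.
#' @param flat_depth flattening depth `d` as a fraction of local radius, in
#'   `[0, 0.5)`.
#' @param flat_center_deg flattening centre `theta0` in degrees from the
#'   anterior axis (posterior-lateral is typically 130-230).
#' @param flat_width angular standard deviation `sigma` in radians, > 0.
#' @param noise_amp radial noise amplitude as a fraction of local radius,
#'   `< 0.02`.
#' @param n_vertices number of equally spaced contour vertices, >= 64.
#' @param seed integer seed for the radial noise.
#' @return Object of class `skull_params`.
#' @export
skull_params <- function(a = 70, b = 85, flat_depth = 0,
                         flat_center_deg = 140, flat_width = 0.5,
                         noise_amp = 0, n_vertices = 512L, seed = 1L) {
  if (!(a > 0 && b > 0)) stop("semi-axes a, b must be positive")
  if (!(flat_depth >= 0 && flat_depth < 0.5))
    stop("flat_depth must lie in [0, 0.5)")
  if (!(flat_width > 0)) stop("flat_width must be positive")
  if (!(noise_amp >= 0 && noise_amp < 0.02))
    stop("noise_amp must lie in [0, 0.02)")
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 64L) stop("n_vertices must be >= 64")
  structure(list(a = a, b = b, flat_depth = flat_depth,
                 flat_center_deg = flat_center_deg, flat_width = flat_width,
                 noise_amp = noise_amp, n_vertices = n_vertices,
                 seed = as.integer(seed)),
            class = "skull_params")
}

# wrapped angular distance on the circle, result in [-pi, pi]
.angdist <- function(theta, theta0) {
  ((theta - theta0 + pi) %% (2 * pi)) - pi
}

# noise-free polar radius of the model
.skull_radius <- function(theta, params) {
  re <- 1 / sqrt(sin(theta)^2 / params$a^2 + cos(theta)^2 / params$b^2)
  th0 <- params$flat_center_deg * pi / 180
  dent <- params$flat_depth *
    exp(-.angdist(theta, th0)^2 / (2 * params$flat_width^2))
  re * (1 - dent)
}

#' Generate a synthetic skull case
#'
#' Samples the polar model at `n_vertices` equally spaced angles, adds
#' seeded uniform radial noise, and places the landmarks on the deformed
#' contour: nose at the vertex nearest `theta = 0` (anterior), ears at the
#' vertices nearest `theta = +/-90` degrees. Output is deterministic given
#' the seed.
#'
#' @param params a `skull_params`.
#' @param truth compute the ground-truth indices with the independent
#'   dense ray-marching oracle ([true_indices()])? Default `TRUE`.
#' @return Object of class `synthetic_case`: `params`, `contour`
#'   (`skull_contour`), `landmarks` (`landmark_set`), and `truth`
#'   (`index_result` from the oracle, or `NULL`).
#' @export
generate_contour <- function(params, truth = TRUE) {
  stopifnot(inherits(params, "skull_params"))
  n <- params$n_vertices
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  r0 <- .skull_radius(theta, params)
  r <- r0
  if (params$noise_amp > 0) {
    rng <- .seeded_rng(params$seed)
    r <- r + rng(n, -params$noise_amp, params$noise_amp) * r
  }
  v <- cbind(x = r * sin(theta), y = r * cos(theta))
  contour <- skull_contour(v, units_label = "model units")

  # landmarks sit on the deformed (dented) but noise-free outline: radial
  # noise emulates segmentation jitter and does not move the landmarks
  idx_at <- function(target) which.min(abs(.angdist(theta, target)))
  lm_at <- function(target) {
    i <- idx_at(target)
    # pulled fractionally inside so noisy contours still contain them
    0.995 * r0[i] * c(sin(theta[i]), cos(theta[i]))
  }
  landmarks <- landmark_set(nose = lm_at(0),
                            ear_right = lm_at(pi / 2),
                            ear_left = lm_at(-pi / 2),
                            contour = contour)
  tr <- if (isTRUE(truth)) true_indices(params) else NULL
  structure(list(params = params, contour = contour, landmarks = landmarks,
                 truth = tr),
            class = "synthetic_case")
}

# local RNG: uniform draws that do not disturb the global .Random.seed
.seeded_rng <- function(seed) {
  function(n, lo, hi) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    stats::runif(n, lo, hi)
  }
}

#' Ground-truth indices by dense ray marching
#'
#' Independent oracle for the synthetic model: each skull chord is found by
#' marching a ray from the chord origin outward across a dense (1e5-sample)
#' rendering of the noise-free polar radius function and bisecting the
#' outermost inside-to-outside crossing on each side. No polygon is built
#' and none of the production chord-intersection code is reused. Landmarks
#' are the exact model points at `theta = 0, +/-90` degrees.
#'
#' @param params a `skull_params` (noise is ignored: the oracle is
#'   noise-free by construction).
#' @param n_samples ray-march samples per ray (default 1e5).
#' @return An `index_result` with oracle values.
#' @export
true_indices <- function(params, n_samples = 1e5) {
  stopifnot(inherits(params, "skull_params"))
  rfun <- function(th) .skull_radius(th, params)
  rmax <- 2.5 * max(params$a, params$b)

  # signed outside-ness of p + t*dir
  gfun <- function(p, dir, t) {
    x <- p[1] + t * dir[1]; y <- p[2] + t * dir[2]
    sqrt(x^2 + y^2) - rfun(atan2(x, y))
  }
  # farthest inside->outside crossing along +dir from p
  march <- function(p, dir) {
    tt <- seq(0, rmax, length.out = n_samples)
    g <- gfun(p, dir, tt)
    cross <- which(g[-length(g)] < 0 & g[-1] >= 0)
    if (!length(cross)) stop("oracle ray found no boundary crossing")
    i <- cross[length(cross)]
    lo <- tt[i]; hi <- tt[i + 1]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (gfun(p, dir, mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  chord <- function(p, dir) {
    t1 <- march(p, dir); t2 <- march(p, -dir)
    list(p1 = p + t1 * dir, p2 = p - t2 * dir, length = t1 + t2)
  }

  # same landmark convention as generate_contour: on the dented noise-free
  # outline, pulled 0.5% inside
  nose <- 0.995 * c(0, rfun(0))
  ear_r <- 0.995 * c(rfun(pi / 2), 0)
  ear_l <- 0.995 * c(-rfun(-pi / 2), 0)

  ear_dir <- (ear_r - ear_l) / sqrt(sum((ear_r - ear_l)^2))
  ec <- chord((ear_r + ear_l) / 2, ear_dir)
  m1 <- (ec$p1 + ec$p2) / 2
  ap <- nose - m1
  ap_dir <- ap / sqrt(sum(ap^2))
  ac <- chord(m1, ap_dir)
  m2 <- (ac$p1 + ac$p2) / 2

  right <- c(ap_dir[2], -ap_dir[1])
  pair_at <- function(deg) {
    th <- deg * pi / 180
    cr <- chord(m2, cos(th) * ap_dir + sin(th) * right)$length
    cl <- chord(m2, cos(th) * ap_dir - sin(th) * right)$length
    structure(list(angle_deg = deg, chord_right = cr, chord_left = cl,
                   long = max(cr, cl), short = min(cr, cl)),
              class = "diagonal_pair")
  }
  d30 <- pair_at(30)
  d40 <- pair_at(40)
  ci <- compute_ci(ec$length, ac$length)
  structure(list(cvai = compute_cvai(d30), ci = ci,
                 oddi = compute_oddi(d40), cpi = ci,
                 ear_ear = ec$length, nose_occiput = ac$length,
                 diag30 = d30, diag40 = d40),
            class = "index_result")
}

#' Rasterize a synthetic case to a binary mask
#'
#' Scanline-fills the contour polygon into a binary image at the requested
#' resolution, padded so the head never touches the image border. The
#' returned transform maps pixel centers back to model units, and the
#' landmarks are also exported in (column, row) pixel coordinates.
#'
#' @param case a `synthetic_case` (or any list with `contour` and
#'   `landmarks`).
#' @param pixels_per_unit raster resolution; must yield an image of at
#'   least 128 x 128 pixels.
#' @return list with `mask` (integer 0/1 matrix, image convention: row 1 is
#'   the top), `transform` (list `x0`, `y0`, `ppu`, `nrow`, `ncol`; model
#'   x = x0 + (col - 0.5)/ppu, model y = y0 + (nrow - row + 0.5)/ppu), and
#'   `landmarks_px` (3 x 2 matrix of column/row coordinates).
#' @export
rasterize_mask <- function(case, pixels_per_unit) {
  v <- case$contour$vertices
  ppu <- pixels_per_unit
  pad <- 0.05 * case$contour$diameter
  x0 <- min(v[, 1]) - pad; y0 <- min(v[, 2]) - pad
  ncol_px <- ceiling((max(v[, 1]) + pad - x0) * ppu)
  nrow_px <- ceiling((max(v[, 2]) + pad - y0) * ppu)
  if (nrow_px < 128 || ncol_px < 128)
    stop("resolution too low: mask must be at least 128 x 128 pixels, got ",
         nrow_px, " x ", ncol_px)

  mask <- matrix(0L, nrow_px, ncol_px)
  n <- nrow(v)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- v[c(2:n, 1L), 1]; y2 <- v[c(2:n, 1L), 2]
  for (i in seq_len(nrow_px)) {
    yc <- y0 + (nrow_px - i + 0.5) / ppu
    hit <- (y1 <= yc & y2 > yc) | (y2 <= yc & y1 > yc)
    if (!any(hit)) next
    xc <- sort(x1[hit] + (yc - y1[hit]) * (x2[hit] - x1[hit]) /
                 (y2[hit] - y1[hit]))
    for (s in seq(1, length(xc) - 1, by = 2)) {
      j1 <- ceiling((xc[s] - x0) * ppu + 0.5)
      j2 <- floor((xc[s + 1] - x0) * ppu + 0.5)
      if (j2 >= j1) mask[i, max(1, j1):min(ncol_px, j2)] <- 1L
    }
  }

  lm <- rbind(nose = case$landmarks$nose, ear_left = case$landmarks$ear_left,
              ear_right = case$landmarks$ear_right)
  landmarks_px <- cbind(col = (lm[, 1] - x0) * ppu + 0.5,
                        row = nrow_px + 0.5 - (lm[, 2] - y0) * ppu)
  list(mask = mask,
       transform = list(x0 = x0, y0 = y0, ppu = ppu,
                        nrow = nrow_px, ncol = ncol_px),
       landmarks_px = landmarks_px)
}
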