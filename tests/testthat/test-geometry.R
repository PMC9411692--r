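test_that("chord_through finds full skull chords", {
  circ <- ngon(256)
  # diameter along x
  ch <- chord_through(circ, c(0, 0), c(1, 0))
  expect_equal(ch$length, 2, tolerance = 1e-9)
  expect_equal(sort(c(ch$p1[1], ch$p2[1])), c(-1, 1), tolerance = 1e-9)

  # off-center chord: circle chord formula 2*sqrt(1 - 0.25)
  ch2 <- chord_through(circ, c(0.5, 0), c(0, 1))
  expect_equal(ch2$length, 2 * sqrt(0.75), tolerance = 1e-3)  # 256-gon

  # square diagonal
  sq <- skull_contour(t(sapply(seq(0, 4, length.out = 65)[-65], function(s) {
    side <- floor(s); f <- s - side
    switch(side + 1,
           c(-1 + 2 * f, -1), c(1, -1 + 2 * f),
           c(1 - 2 * f, 1), c(-1, 1 - 2 * f))
  })))
  ch3 <- chord_through(sq, c(0, 0), c(cos(pi / 4), sin(pi / 4)))
  expect_equal(ch3$length, 2 * sqrt(2), tolerance = 1e-9)

  # direction sign does not matter
  ch4 <- chord_through(circ, c(0.2, 0.1), c(0.3, -0.7))
  ch5 <- chord_through(circ, c(0.2, 0.1), -c(0.3, -0.7))
  expect_equal(ch4$length, ch5$length, tolerance = 1e-12)

  # errors: point outside
  expect_error(chord_through(circ, c(2, 0), c(1, 0)), "inside")
})

test_that("chord_through takes the outermost crossing on non-convex contours", {
  # unit disc with a pocket carved into the right side whose mouth sits just
  # above the x axis: the horizontal line through the origin crosses the
  # right side three times (x = 0.5, 0.9, ~1); the farthest must be taken
  arc <- seq(0.09, 2 * pi + 0.05, length.out = 160)
  pocket <- rbind(c(0.9, 0.05), c(0.9, -0.1), c(0.5, -0.1),
                  c(0.5, 0.1), c(0.9, 0.1), c(0.9, 0.09))
  ct <- skull_contour(rbind(cbind(cos(arc), sin(arc)), pocket))
  ch <- chord_through(ct, c(0, 0), c(1, 0))
  expect_equal(max(ch$p1[1], ch$p2[1]), 1, tolerance = 1e-3)
  expect_equal(ch$length, 2, tolerance = 1e-3)
})

test_that("build_frame reproduces the published construction", {
  circ <- ngon(256)
  lm <- symmetric_landmarks(1, 1, circ)
  fr <- build_frame(circ, lm)
  expect_equal(fr$m1, c(0, 0), tolerance = 1e-9)
  expect_equal(fr$m2, c(0, 0), tolerance = 1e-9)
  expect_equal(fr$ear_chord$length, 2, tolerance = 1e-4)
  expect_equal(fr$ap_chord$length, 2, tolerance = 1e-4)
  expect_equal(fr$ap_dir, c(0, 1), tolerance = 1e-9)
  # anterior endpoint of the AP chord is on the nose side
  expect_gt(fr$ap_chord$p1[2], 0)

  # ellipse axes are recovered exactly through the landmark construction
  ell <- ellipse_contour(60, 75, 512)
  fre <- build_frame(ell, symmetric_landmarks(60, 75, ell))
  expect_equal(fre$ear_chord$length, 120, tolerance = 1e-6)
  expect_equal(fre$ap_chord$length, 150, tolerance = 1e-6)
})

test_that("frame chords are invariant under rigid motion", {
  ell <- ellipse_contour(60, 75, 256)
  lm <- symmetric_landmarks(60, 75, ell)
  fr0 <- build_frame(ell, lm)
  tc <- transform_case(ell, lm, angle_deg = 37, shift = c(10, 5))
  fr1 <- build_frame(tc$contour, tc$landmarks)
  expect_equal(fr1$ear_chord$length, fr0$ear_chord$length, tolerance = 1e-9)
  expect_equal(fr1$ap_chord$length, fr0$ap_chord$length, tolerance = 1e-9)
})

test_that("measure_diagonals matches the ellipse central-chord closed form", {
  for (n in c(512, 2048)) {
    ell <- ellipse_contour(60, 75, n)
    fr <- build_frame(ell, symmetric_landmarks(60, 75, ell))
    for (ang in c(30, 40)) {
      dp <- measure_diagonals(ell, fr, ang)
      want <- ellipse_chord(60, 75, ang)
      expect_equal(dp$chord_right, want, tolerance = 1e-3)
      expect_equal(dp$chord_left, want, tolerance = 1e-3)
    }
  }
  # denser polygons converge: error shrinks with vertex count
  err_at <- function(n) {
    ell <- ellipse_contour(60, 75, n)
    fr <- build_frame(ell, symmetric_landmarks(60, 75, ell))
    abs(measure_diagonals(ell, fr, 30)$long - ellipse_chord(60, 75, 30))
  }
  expect_lt(err_at(4096), err_at(256))
})

test_that("mirrored contours swap chord sides but not indices", {
  p <- skull_params(a = 65, b = 80, flat_depth = 0.2, flat_center_deg = 150,
                    flat_width = 0.5, n_vertices = 512, seed = 5)
  sc <- generate_contour(p, truth = FALSE)
  m <- measure_all(sc$contour, sc$landmarks)

  mirror <- function(p) c(-p[1], p[2])
  vm <- cbind(-sc$contour$vertices[, 1], sc$contour$vertices[, 2])
  cm <- skull_contour(vm)
  lmm <- landmark_set(mirror(sc$landmarks$nose),
                      ear_left = mirror(sc$landmarks$ear_right),
                      ear_right = mirror(sc$landmarks$ear_left))
  mm <- measure_all(cm, lmm)
  expect_equal(mm$diag30$chord_right, m$diag30$chord_left, tolerance = 1e-9)
  expect_equal(mm$diag30$chord_left, m$diag30$chord_right, tolerance = 1e-9)
  for (f in c("cvai", "ci", "oddi", "cpi"))
    expect_equal(mm[[f]], m[[f]], tolerance = 1e-9)
})

test_that("index formulas follow their definitions", {
  mkpair <- function(long, short, ang) {
    structure(list(angle_deg = ang, chord_right = long, chord_left = short,
                   long = long, short = short), class = "diagonal_pair")
  }
  expect_equal(compute_cvai(mkpair(100, 100, 30)), 0)
  expect_equal(compute_cvai(mkpair(104, 100, 30)), 4)
  expect_equal(compute_cvai(mkpair(111, 100, 30)), 11)  # very-severe boundary
  expect_equal(compute_oddi(mkpair(100, 100, 40)), 100)
  expect_equal(compute_oddi(mkpair(108, 100, 40)), 108) # moderate boundary
  expect_equal(compute_oddi(mkpair(103.9, 100, 40)), 103.9)
  expect_equal(compute_ci(90, 100), 90)
  expect_equal(compute_ci(100, 100), 100)
  expect_equal(compute_ci(120, 150), 80)
  expect_error(compute_ci(0, 10), "positive")
})

test_that("measure_all is exact on symmetric shapes and scale invariant", {
  circ <- ngon(128)
  m <- measure_all(circ, symmetric_landmarks(1, 1, circ))
  expect_equal(m$cvai, 0, tolerance = 1e-9)
  expect_equal(m$oddi, 100, tolerance = 1e-9)
  expect_equal(m$ci, 100, tolerance = 1e-9)
  expect_equal(m$cpi, m$ci)

  p <- skull_params(a = 60, b = 75, flat_depth = 0.12, flat_center_deg = 200,
                    n_vertices = 512, seed = 11)
  sc <- generate_contour(p, truth = FALSE)
  m1 <- measure_all(sc$contour, sc$landmarks)
  tc <- transform_case(sc$contour, sc$landmarks, scale = 3.7)
  m2 <- measure_all(tc$contour, tc$landmarks)
  for (f in c("cvai", "ci", "oddi", "cpi"))
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-9)
  expect_equal(m2$ear_ear, 3.7 * m1$ear_ear, tolerance = 1e-9)
})

test_that("all indices are rigid- and scale-invariant on random skulls", {
  set.seed(7)
  for (k in 1:8) {
    p <- skull_params(a = runif(1, 55, 90), b = runif(1, 70, 95),
                      flat_depth = runif(1, 0, 0.3),
                      flat_center_deg = runif(1, 130, 230),
                      flat_width = 0.5, noise_amp = 0.004,
                      n_vertices = 256, seed = k)
    sc <- generate_contour(p, truth = FALSE)
    m0 <- measure_all(sc$contour, sc$landmarks)
    tc <- transform_case(sc$contour, sc$landmarks,
                         angle_deg = runif(1, 0, 360),
                         shift = runif(2, -100, 100),
                         scale = runif(1, 0.3, 4))
    m1 <- measure_all(tc$contour, tc$landmarks)
    for (f in c("cvai", "ci", "oddi", "cpi"))
      expect_equal(m1[[f]], m0[[f]], tolerance = 1e-9)
  }
})

test_that("circle limit holds for regular n-gons of any size", {
  for (n in c(64, 128, 256, 500)) {
    ct <- ngon(n)
    m <- measure_all(ct, symmetric_landmarks(1, 1, ct))
    expect_equal(m$cvai, 0, tolerance = 1e-9)
    expect_equal(m$oddi, 100, tolerance = 1e-9)
    expect_equal(m$ci, 100, tolerance = 1e-9)
    expect_equal(m$cpi, 100, tolerance = 1e-9)
  }
})

test_that("degenerate measurement inputs raise stage-named errors", {
  circ <- ngon(64)
  lm <- symmetric_landmarks(1, 1, circ)
  expect_error(measure_diagonals(circ, build_frame(circ, lm), 0), "angle")
  expect_error(measure_diagonals(circ, build_frame(circ, lm), 90), "angle")
  # nose collinear with ears is caught at landmark construction
  expect_error(landmark_set(c(0.5, 0.0001), c(-0.9, 0), c(0.9, 0)),
               "collinear")
})
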