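# Shape fixtures built in code.

# regular n-gon (vertex at angle 0), CCW
ngon <- function(n = 128, r = 1, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  skull_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

# axis-aligned ellipse sampled at equal angles; a = half-width (x),
# b = half-length (y); vertex at the anterior pole
ellipse_contour <- function(a, b, n = 512) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  skull_contour(cbind(a * sin(th), b * cos(th)))
}

# symmetric landmarks for a shape centered at the origin with half-width a
# and half-length b (pulled slightly inside the outline)
symmetric_landmarks <- function(a, b, contour = NULL) {
  landmark_set(nose = c(0, 0.995 * b), ear_left = c(-0.995 * a, 0),
               ear_right = c(0.995 * a, 0), contour = contour)
}

# closed-form central chord of an ellipse at angle phi from the AP (y) axis
ellipse_chord <- function(a, b, phi_deg) {
  phi <- phi_deg * pi / 180
  2 / sqrt(sin(phi)^2 / a^2 + cos(phi)^2 / b^2)
}

# rigid motion of a contour + landmarks
transform_case <- function(contour, landmarks, angle_deg = 0,
                           shift = c(0, 0), scale = 1) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tf <- function(p) as.numeric(scale * (R %*% p) + shift)
  v <- t(apply(contour$vertices, 1, tf))
  list(contour = skull_contour(v, units_label = contour$units_label),
       landmarks = landmark_set(tf(landmarks$nose), tf(landmarks$ear_left),
                                tf(landmarks$ear_right)))
}

# the 50-case synthetic study set used by the recovery properties
recovery_cases <- function(n = 50, noise_amp = 0.005, n_vertices = 512) {
  set.seed(42)
  data.frame(
    d = runif(n, 0, 0.3),
    ab = runif(n, 0.7, 1.1),
    th0 = runif(n, 130, 230),
    b = runif(n, 75, 95),
    noise_amp = noise_amp, n_vertices = n_vertices, seed = seq_len(n)
  )
}

params_from_row <- function(row) {
  skull_params(a = row$ab * row$b, b = row$b, flat_depth = row$d,
               flat_center_deg = row$th0, flat_width = 0.5,
               noise_amp = row$noise_amp, n_vertices = row$n_vertices,
               seed = row$seed)
}
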