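# Shared analytic fixtures for the geometry tests.

# n points on the canonical annular saddle:
#   x = a cos(theta), y = b sin(theta), z = -h cos(2 theta)
# so the horns (theta = +/- pi/2, the septolateral axis) sit high.
saddle_points <- function(n = 8, a = 16, b = 11.2, h = 2, jitter = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  if (jitter > 0) th <- th + stats::rnorm(n, 0, jitter)
  cbind(a * cos(th), b * sin(th), -h * cos(2 * th))
}

# closed-form NPA of that saddle (degrees)
saddle_npa <- function(b = 11.2, h = 2) 2 * atan2(b, h) * 180 / pi

# uniform random 3x3 rotation matrix (QR of a Gaussian matrix)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# noiseless, motion-free paired simulation used by several tests
clean_protocol <- function(protocol = "baseline", n_beats = 12L, seed = 1) {
  simulate_protocol(
    annulus_sim_config(noise_sd_mm = 0, rot_deg = 0, trans_mm = 0,
                       n_beats = n_beats),
    lv_sim_config(n_beats = n_beats),
    protocol = protocol, seed = seed
  )
}
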