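# shared fixtures, all built in code

# index-matched transparent-or-turbid slab: no Fresnel step at the faces
matched_slab <- function(mu_s_shg = 0, g = 0.9, mu_s_ex = 0,
                         thickness_cm = 0.01, n = 1.33,
                         ex_nm = 988) {
  tissue_slab(thickness_cm,
              list(optical_properties(ex_nm, n + 1e-9, mu_s_ex, g),
                   optical_properties(ex_nm / 2, n + 1e-9, mu_s_shg, g)),
              n_top = n, n_bottom = n)
}

# wide symmetric detection: acceptance cones cover the emission cone
wide_geometry <- function() detection_geometry(0.9, 0.9, 1.33)

# rectangular-bar phantom for the fiber-diameter estimator
bar_phantom <- function(width_px, angle_deg = 0, size = 64) {
  ctr <- (size + 1) / 2
  th <- angle_deg * pi / 180
  m <- matrix(0, size, size)
  for (y in seq_len(size)) for (x in seq_len(size)) {
    d <- abs(-(x - ctr) * sin(th) + (y - ctr) * cos(th) * 0 +
               (x - ctr) * 0 + (y - ctr) * 0)
    # signed distance from the bar's axis (line through centre at angle th)
    d <- abs((x - ctr) * (-sin(th)) + (y - ctr) * cos(th))
    if (d <= width_px / 2) m[y, x] <- 1
  }
  m
}

# constant-F/B preset for parameter-recovery experiments
flat_fb_preset <- function(fb, efficiency = 0.5, mus_prime_390 = 30,
                           g = 0.9, m_shape = 1.2, name = "flat") {
  wl <- c(780, 890, 988, 1070, 1160)
  tissue_preset(name, m_shape = m_shape, mus_prime_390 = mus_prime_390,
                g = g, n = 1.40,
                fb_curve = stats::setNames(rep(fb, 5), wl),
                efficiency_curve = stats::setNames(rep(efficiency, 5), wl))
}

# one log-step of the default F/B candidate grid
default_grid_log_step <- function() {
  g <- default_fb_grid()
  log(g[2] / g[1])
}
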