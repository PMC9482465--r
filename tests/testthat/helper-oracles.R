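# Shared fixtures and independent oracles.

# homonuclear diatomic along z
diatomic <- function(element = "H", r = 0.74) {
  molecular_geometry(c(element, element),
                     rbind(c(0, 0, 0), c(0, 0, r)),
                     name = sprintf("%s2", element))
}

# random small geometry with a minimum-separation guarantee
random_geometry <- function(n, elements = c("H", "C", "O"), box = 6,
                            min_sep = 0.8) {
  repeat {
    coords <- matrix(runif(3 * n, 0, box), ncol = 3)
    if (n < 2 || min(dist(coords)) >= min_sep) break
  }
  molecular_geometry(sample(elements, n, replace = TRUE), coords)
}

# independent Debye oracle: plain double loop over ordered pairs, scalar
# arithmetic only (no shared code with molecular_intensity)
debye_double_loop <- function(geom, s, table = scattering_table()) {
  n <- nrow(geom$coords)
  out <- numeric(length(s))
  for (k in seq_along(s)) {
    sk <- s[k]
    acc <- 0
    for (i in seq_len(n)) {
      fi <- scattering_amplitude(table, geom$elements[i], sk)
      for (j in seq_len(n)) {
        if (i == j) next
        fj <- scattering_amplitude(table, geom$elements[j], sk)
        rij <- sqrt(sum((geom$coords[i, ] - geom$coords[j, ])^2))
        x <- sk * rij
        acc <- acc + fi * fj * (if (x == 0) 1 else sin(x) / x)
      }
    }
    out[k] <- acc
  }
  out
}

# small detector that still spans the full default s grid
small_detector <- function(n = 256L, accel_voltage = 100) {
  detector_geometry(n_pixels = c(n, n), pixel_pitch = 0.0575 * 1024 / n,
                    camera_length = 500, accel_voltage = accel_voltage)
}

# smooth positive test curve covering the default s range
smooth_curve <- function(s = s_grid(10.5, 0.02)) {
  diffraction_curve(s, 5 + exp(-s / 3) + 0.5 * exp(-(s - 3)^2 / 2))
}

rel_rms <- function(est, truth) {
  sqrt(mean((est - truth)^2)) / sqrt(mean(truth^2))
}

# relative RMS in the damping-weighted metric: sM errors matter in proportion
# to the Gaussian window the sine transform applies
rel_rms_damped <- function(est, truth, s, k = -log(0.1) / max(s)^2) {
  d <- exp(-k * s^2)
  sqrt(mean(((est - truth) * d)^2)) / sqrt(mean((truth * d)^2))
}
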