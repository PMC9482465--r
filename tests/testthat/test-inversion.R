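test_that("extract_sm recovers the true sM in forward-model round trips", {
  tab <- scattering_table()
  s <- s_grid()
  gly <- build_glycerol()
  at <- atomic_intensity(gly, s, tab)
  mol <- molecular_intensity(gly, s, tab)
  sm_true <- modified_scattering(mol, at)

  # background-free total, order-0 baseline
  tot <- total_intensity(gly, s, tab)
  sm0 <- extract_sm(tot, at, background_order = 0L)
  expect_lt(rel_rms_damped(sm0$values, sm_true$values, s), 0.01)

  # cubic synthetic background, order-3 baseline
  bg <- diffraction_curve(s, 2 + 0.8 * s - 0.15 * s^2 + 0.008 * s^3,
                          role = "background")
  tot_bg <- total_intensity(gly, s, tab, background = bg)
  sm3 <- extract_sm(tot_bg, at, background_order = 3L)
  expect_lt(rel_rms_damped(sm3$values, sm_true$values, s), 0.02)

  # the recovered sM preserves the real-space peaks that matter downstream
  fr_true <- sine_transform(sm_true, inversion_settings())
  fr_est <- sine_transform(sm3, inversion_settings())
  for (win in list(c(1, 2), c(2, 3))) {
    expect_equal(find_peaks(fr_est, win)$position[1],
                 find_peaks(fr_true, win)$position[1], tolerance = 0.03)
  }

  # total identical to atomic: nothing molecular to recover
  sm_null <- extract_sm(at_total <- diffraction_curve(s, at$values), at,
                        background_order = 2L)
  expect_lt(max(abs(sm_null$values)), 1e-10)

  expect_error(extract_sm(tot, at, background_order = length(s)), "below")
})

test_that("low-s splicing blends theoretical into experimental smoothly", {
  s <- s_grid(5, 0.02)
  a <- diffraction_curve(s, sin(2 * s), role = "modified")
  b <- diffraction_curve(s, cos(3 * s), role = "modified")

  expect_equal(splice_low_s(a, b, 0)$values, a$values)
  expect_equal(splice_low_s(a, b, 10)$values, b$values)
  expect_equal(splice_low_s(a, a, 2)$values, a$values)

  spliced <- splice_low_s(a, b, 2)$values
  expect_equal(spliced[s < 2], b$values[s < 2])
  expect_equal(spliced[s > 2.2], a$values[s > 2.2])
  # no step: increments bounded by curve slopes plus the fade-rate term
  ds <- 0.02
  bound <- max(abs(diff(a$values)), abs(diff(b$values))) +
    max(abs(a$values - b$values)) * ds / 0.2
  expect_lte(max(abs(diff(spliced))), bound * 1.001)
})

test_that("sine transform is linear, vanishes at r = 0, and locates diatomic distances", {
  tab <- scattering_table()
  s <- s_grid()
  set <- inversion_settings()

  zero <- diffraction_curve(s, numeric(length(s)), role = "modified")
  expect_true(all(sine_transform(zero, set)$f == 0))

  sm1 <- modified_scattering(molecular_intensity(diatomic("C", 1.5), s, tab),
                             atomic_intensity(diatomic("C", 1.5), s, tab))
  sm2 <- modified_scattering(molecular_intensity(diatomic("O", 2.5), s, tab),
                             atomic_intensity(diatomic("O", 2.5), s, tab))
  f1 <- sine_transform(sm1, set)$f
  f2 <- sine_transform(sm2, set)$f
  combo <- diffraction_curve(s, 2.5 * sm1$values - 0.7 * sm2$values,
                             role = "modified")
  expect_equal(sine_transform(combo, set)$f, 2.5 * f1 - 0.7 * f2,
               tolerance = 1e-10)

  expect_identical(sine_transform(sm1, set)$f[1], 0)  # r = 0 exactly

  for (r0 in c(1.0, 1.5, 2.5, 4.0)) {
    d <- diatomic("C", r0)
    sm <- modified_scattering(molecular_intensity(d, s, tab),
                              atomic_intensity(d, s, tab))
    fr <- sine_transform(sm, set)
    peak <- find_peaks(fr, c(max(0.3, r0 - 0.8), r0 + 0.8))
    expect_equal(peak$position[1], r0, tolerance = 0.011)
  }

  expect_error(sine_transform(sm1, inversion_settings(s_max = 20)), "s_max")
})

test_that("full diatomic round trip: simulate, extract, invert", {
  tab <- scattering_table()
  s <- s_grid()
  set <- inversion_settings()
  for (r0 in c(1.0, 1.5, 2.5, 4.0)) {
    d <- diatomic("O", r0)
    tot <- total_intensity(d, s, tab)
    at <- atomic_intensity(d, s, tab)
    sm <- extract_sm(tot, at, background_order = 0L)
    fr <- sine_transform(sm, set)
    peak <- find_peaks(fr, c(max(0.3, r0 - 0.8), r0 + 0.8))
    expect_equal(peak$position[1], r0, tolerance = 0.011)
  }
})

test_that("stronger damping broadens and lowers peaks without moving them", {
  tab <- scattering_table()
  s <- s_grid()
  d <- diatomic("C", 1.5)
  sm <- modified_scattering(molecular_intensity(d, s, tab),
                            atomic_intensity(d, s, tab))
  ks <- c(0.01, 0.023, 0.05)
  heights <- numeric(length(ks)); positions <- numeric(length(ks))
  widths <- numeric(length(ks))
  for (i in seq_along(ks)) {
    fr <- sine_transform(sm, inversion_settings(k = ks[i]))
    pk <- find_peaks(fr, c(1.0, 2.0))
    heights[i] <- pk$height[1]; positions[i] <- pk$position[1]
    above <- fr$f > pk$height[1] / 2
    widths[i] <- diff(range(fr$r[above & fr$r > 0.8 & fr$r < 2.2]))
  }
  expect_true(all(diff(heights) < 0))
  expect_true(all(diff(widths) > 0))
  expect_lt(max(abs(positions - positions[1])), 0.011)
})

test_that("find_peaks refines, sorts, and rejects bad windows", {
  x <- seq(0, 10, 0.1)
  y <- exp(-(x - 3.17)^2)
  pk <- find_peaks(list(x = x, y = y), c(1, 5))
  expect_equal(pk$position[1], 3.17, tolerance = 0.1)

  expect_equal(nrow(find_peaks(list(x = x, y = x), c(1, 5))), 0L)
  expect_error(find_peaks(list(x = x, y = y), c(5, 15)), "window")

  two <- exp(-(x - 2)^2) + 3 * exp(-(x - 7)^2 / 2)
  pk2 <- find_peaks(list(x = x, y = two), c(0.5, 9.5))
  expect_equal(pk2$position[1], 7, tolerance = 0.1)   # sorted by height
  expect_equal(pk2$position[2], 2, tolerance = 0.1)
})
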