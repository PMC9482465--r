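test_that("scattering amplitudes are positive and decay for light elements", {
  tab <- scattering_table()
  s <- seq(0, 20, by = 0.1)
  for (el in c("H", "C", "O")) {
    f <- scattering_amplitude(tab, el, s)
    expect_true(all(f > 0))
    expect_true(all(diff(f) <= 0))  # monotone non-increasing
  }
  expect_error(scattering_amplitude(tab, "Xe", 1), "not tabulated")
  expect_equal(scattering_phase(tab, "C", c(0, 5)), c(0, 0))
})

test_that("electron wavelength follows the relativistic de Broglie formula", {
  # independent scalar evaluation: lambda = h / sqrt(2 m e V (1 + eV/2mc^2))
  h <- 6.62607015e-34; me <- 9.1093837015e-31; qe <- 1.602176634e-19
  cl <- 299792458
  V <- 100e3
  lam_ref <- h / sqrt(2 * me * qe * V * (1 + qe * V / (2 * me * cl^2))) * 1e10
  expect_equal(electron_wavelength(100), lam_ref, tolerance = 1e-4)
  expect_equal(round(electron_wavelength(100), 4), 0.0370)
  expect_lt(electron_wavelength(200), electron_wavelength(100))
  expect_error(electron_wavelength(0), "positive")
  expect_error(electron_wavelength(-5), "positive")
})

test_that("atomic intensity is the coordinate-free sum of squared amplitudes", {
  tab <- scattering_table()
  s <- s_grid(5, 0.1)
  h1 <- molecular_geometry("H", matrix(0, 1, 3))
  expect_equal(atomic_intensity(h1, s, tab)$values,
               scattering_amplitude(tab, "H", s)^2)

  h2 <- diatomic("H", 0.9)
  expect_equal(atomic_intensity(h2, s, tab)$values,
               2 * atomic_intensity(h1, s, tab)$values)

  gly <- build_glycerol()
  per_atom <- Reduce(`+`, lapply(gly$elements, function(el)
    scattering_amplitude(tab, el, s)^2))
  expect_equal(atomic_intensity(gly, s, tab)$values, per_atom)
})

test_that("molecular intensity matches closed forms and the double-loop oracle", {
  tab <- scattering_table()
  s <- s_grid(8, 0.25)
  single <- molecular_geometry("O", matrix(0, 1, 3))
  expect_true(all(molecular_intensity(single, s, tab)$values == 0))

  r0 <- 1.2
  d <- diatomic("O", r0)
  f <- scattering_amplitude(tab, "O", s)
  closed <- 2 * f^2 * ifelse(s == 0, 1, sin(s * r0) / (s * r0))
  expect_equal(molecular_intensity(d, s, tab)$values, closed,
               tolerance = 1e-12)
  # s -> 0 limit equals 2|f(0)|^2
  expect_equal(molecular_intensity(d, 0, tab)$values,
               2 * scattering_amplitude(tab, "O", 0)^2)

  set.seed(42)
  for (n in c(3L, 8L, 20L)) {
    g <- random_geometry(n)
    got <- molecular_intensity(g, s, tab)$values
    want <- debye_double_loop(g, s, tab)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("s -> 0 molecular limit equals (sum f)^2 - sum f^2 at zero phases", {
  tab <- scattering_table()
  set.seed(7)
  g <- random_geometry(12)
  f0 <- vapply(g$elements, function(el) scattering_amplitude(tab, el, 0),
               numeric(1))
  expect_equal(molecular_intensity(g, 0, tab)$values,
               sum(f0)^2 - sum(f0^2), tolerance = 1e-10)
})

test_that("molecular intensity is invariant under rigid-body transforms", {
  tab <- scattering_table()
  s <- s_grid(8, 0.2)
  set.seed(11)
  g <- random_geometry(15)
  base <- molecular_intensity(g, s, tab)$values
  for (rep in 1:3) {
    R <- plumediff:::.random_rotation()
    g2 <- g
    g2$coords <- g$coords %*% t(R)
    g2$coords <- sweep(g2$coords, 2, rnorm(3, sd = 5), "+")
    moved <- molecular_intensity(g2, s, tab)$values
    expect_equal(moved, base, tolerance = 1e-10)
  }
})

test_that("histogram Debye path agrees with the direct path", {
  tab <- scattering_table()
  s <- s_grid(10, 0.05)
  set.seed(3)
  g <- random_geometry(60, box = 12)
  direct <- molecular_intensity(g, s, tab, method = "direct")$values
  hist <- molecular_intensity(g, s, tab, method = "histogram")$values
  expect_lt(max(abs(hist - direct)) / max(abs(direct)), 5e-3)
})

test_that("total intensity decomposes exactly and respects grids", {
  tab <- scattering_table()
  s <- s_grid(6, 0.1)
  single <- molecular_geometry("C", matrix(0, 1, 3))
  expect_equal(total_intensity(single, s, tab)$values,
               atomic_intensity(single, s, tab)$values)

  gly <- build_glycerol()
  tot <- total_intensity(gly, s, tab)
  expect_equal(tot$values - atomic_intensity(gly, s, tab)$values,
               molecular_intensity(gly, s, tab)$values)

  bg_wrong <- diffraction_curve(s_grid(6, 0.2), rep(1, length(s_grid(6, 0.2))),
                                role = "background")
  expect_error(total_intensity(gly, s, tab, background = bg_wrong),
               "different s grids")
})

test_that("one-molecule liquid configurations scatter like the gas phase", {
  tab <- scattering_table()
  s <- s_grid(8, 0.1)
  gly <- build_glycerol()
  cfg <- pack_droplet(gly, 1, density = 1.26, contact_distance = 3.2, seed = 5)
  liquid <- total_intensity(cfg, s, tab)
  gas <- total_intensity(gly, s, tab)
  expect_equal(liquid$values, gas$values, tolerance = 1e-9)
})

test_that("modified scattering sM has the right structure", {
  tab <- scattering_table()
  s <- s_grid(10, 0.02)
  gly <- build_glycerol()
  at <- atomic_intensity(gly, s, tab)

  zero_mol <- diffraction_curve(s, numeric(length(s)), role = "molecular")
  expect_true(all(modified_scattering(zero_mol, at)$values == 0))

  # homonuclear diatomic: sM proportional to s sinc(s r); zeros at n pi / r
  r0 <- 1.5
  d <- diatomic("C", r0)
  sm <- modified_scattering(molecular_intensity(d, s, tab),
                            atomic_intensity(d, s, tab))
  expect_identical(sm$values[1], 0)  # s = 0
  sign_flips <- which(diff(sign(sm$values[-1])) != 0)
  first_zero <- s[-1][sign_flips[1]]
  expect_equal(first_zero, pi / r0, tolerance = 0.02)

  # total-curve route: I_mol reconstructed as total - atomic
  tot <- total_intensity(gly, s, tab)
  sm1 <- modified_scattering(tot, at)
  sm2 <- modified_scattering(molecular_intensity(gly, s, tab), at)
  expect_equal(sm1$values, sm2$values, tolerance = 1e-12)
  expect_identical(sm1$values[1], 0)
})

test_that("s2 weighting multiplies elementwise and zeroes the origin", {
  s <- s_grid(4, 0.5)
  const <- diffraction_curve(s, rep(1, length(s)))
  expect_equal(s2_weighted(const)$values, s^2)
  expect_identical(s2_weighted(const)$values[1], 0)
})
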