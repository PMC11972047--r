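test_that("range-energy inversion round-trips over the clinical window", {
  m <- range_energy_model()
  set.seed(21)
  E <- runif(20, 50, 100)
  expect_equal(energy_from_range(range_from_energy(E, m), m), E,
               tolerance = 1e-10)
  expect_equal(range_from_energy(0, m), 0)
  expect_error(range_energy_model(p = 2.5))
})

test_that("power-law ranges agree with the CSDA reference table within 2%", {
  m <- range_energy_model()
  tab <- gadodose:::.CSDA_WATER
  r <- range_from_energy(tab$energy_MeV, m)
  expect_true(all(abs(r - tab$range_cm) / tab$range_cm < 0.02))
})

test_that("a tabulated range-energy override reproduces its nodes", {
  tab <- gadodose:::.CSDA_WATER
  m <- range_energy_model(table = tab)
  expect_equal(range_from_energy(tab$energy_MeV, m), tab$range_cm,
               tolerance = 1e-9)
  expect_equal(energy_from_range(tab$range_cm, m), tab$energy_MeV,
               tolerance = 1e-9)
  # log-log interpolation stays monotone between nodes
  E <- seq(52, 98, by = 1)
  expect_true(all(diff(range_from_energy(E, m)) > 0))
})

test_that("the Bragg peak sits within one voxel of the nominal range", {
  m <- range_energy_model()
  b <- pencil_beam_model()
  E <- 80
  R <- range_from_energy(E, m)
  d <- seq(0, R + 1, by = 0.001)
  dd <- depth_dose(E, d, m, b)
  peak <- d[which.max(dd)]
  expect_lt(abs(peak - R), 0.1) # cm
  expect_true(all(dd >= 0))
  expect_equal(depth_dose(E, R + 6 * b$straggling_fraction * R + 0.5, m, b),
               0)
})

test_that("depth-dose integral conserves energy minus nuclear losses", {
  m <- range_energy_model()
  b <- pencil_beam_model()
  for (E in c(70, 80, 90)) {
    R <- range_from_energy(E, m)
    d <- seq(0, R + 1, by = 0.0025)
    dd <- depth_dose(E, d, m, b)
    integral <- sum((dd[-1] + dd[-length(dd)]) / 2 * diff(d))
    q <- 1 / m$p
    expected <- E * (1 - b$nuclear_loss_per_cm * R / (1 + q))
    expect_lt(abs(integral - expected) / expected, 1e-3)
  }
})

test_that("fluence factor is a survival fraction frozen past the range", {
  b <- pencil_beam_model()
  f <- gadodose:::fluence_factor(b, c(0, 3, 6, 9), 6)
  expect_true(all(f > 0 & f <= 1))
  expect_true(all(diff(f[1:3]) < 0))
  expect_equal(f[3], f[4]) # no loss beyond the range
})

test_that("dense depth-dose lookup matches the quadrature", {
  m <- range_energy_model()
  b <- pencil_beam_model()
  f <- gadodose:::depth_dose_lut(80, m, b)
  d <- seq(0.1, 5.5, by = 0.137)
  direct <- depth_dose(80, d, m, b)
  expect_lt(max(abs(f(d) - direct)) / max(direct), 1e-3)
})

test_that("Gaussian band mass matches numerical integration", {
  g <- gadodose:::gauss_band(-0.3, 0.55, 0.1, 0.4)
  ref <- stats::integrate(stats::dnorm, -0.3, 0.55, mean = 0.1,
                          sd = 0.4)$value
  expect_equal(g, ref, tolerance = 1e-8)
})

test_that("single-spot dose is linear in weight and conserves energy", {
  g <- fx_phantom_water()
  m <- range_energy_model()
  b <- pencil_beam_model()
  w <- 1e8
  dg1 <- spot_dose(g, 80, 0, 0, w, m, b)
  dg2 <- spot_dose(g, 80, 0, 0, 2 * w, m, b)
  expect_equal(dg2$dose, 2 * dg1$dose, tolerance = 1e-12)
  mass_kg <- g$body$density * g$voxel_cm^3 * 1e-3
  imparted_MeV <- sum(dg1$dose) * mass_kg / 1.602176634e-13
  R <- range_from_energy(80, m)
  expected <- w * 80 * (1 - b$nuclear_loss_per_cm * R / (1 + 1 / m$p))
  expect_lt(abs(imparted_MeV - expected) / expected, 0.03)
})

test_that("dose grids round-trip through the binary container", {
  g <- phantom_grid(extent_cm = 2, voxel_mm = 2, target_cm = 1)
  dg <- spot_dose(g, 30, 0, 0, 1e6)
  stem <- tempfile()
  write_dose_grid(dg, stem)
  back <- read_dose_grid(stem)
  expect_identical(back$dose, dg$dose)
  expect_equal(back$voxel_mm, dg$voxel_mm)
  unlink(paste0(stem, c(".bin", ".json")))
})
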