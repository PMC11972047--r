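test_that("K-shell cross section interpolates its table monotonically", {
  ks <- kshell_model()
  tab <- ks$sigma_table
  expect_equal(sigma_k(tab$energy_MeV, ks), tab$sigma_barns,
               tolerance = 1e-10)
  E <- seq(5, 250, by = 1)
  expect_true(all(diff(sigma_k(E, ks)) >= 0))
  expect_equal(sigma_k(0, ks), 0)
  # log-log interpolation between two nodes matches hand arithmetic
  i <- 3
  Em <- sqrt(tab$energy_MeV[i] * tab$energy_MeV[i + 1])
  ref <- exp(mean(log(tab$sigma_barns[i + 0:1])))
  expect_equal(sigma_k(Em, ks), ref, tolerance = 1e-10)
})

test_that("PIXE yield is linear in spot weight", {
  g <- fx_phantom_dotarem()
  spot <- data.frame(spot_id = 1L, layer = 1L, energy_MeV = 85,
                     x_mm = 0, y_mm = 0, weight_protons = 1e7)
  y1 <- pixe_yield(g, spot)
  spot$weight_protons <- 3e7
  expect_equal(pixe_yield(g, spot), 3 * y1, tolerance = 1e-12)
  expect_gt(y1, 0)
})

test_that("PIXE and capture yields are linear in Gd concentration", {
  base <- dotarem_material()
  mk <- function(conc) {
    material("agent", base$density, base$composition,
             gd_concentration_mmol_ml = conc)
  }
  spot <- data.frame(spot_id = 1L, layer = 1L, energy_MeV = 85,
                     x_mm = 0, y_mm = 0, weight_protons = 1e7)
  y <- vapply(c(0.25, 0.5, 1.0), function(conc) {
    g <- phantom_grid(target = mk(conc))
    c(pixe = pixe_yield(g, spot), capture = capture_yield(g, spot))
  }, numeric(2))
  expect_equal(y[, 2], 2 * y[, 1], tolerance = 1e-9)
  expect_equal(y[, 3], 4 * y[, 1], tolerance = 1e-9)
})

test_that("higher beam energy raises PIXE yield while target dose falls", {
  g <- fx_phantom_dotarem()
  models <- engine_models()
  mk_spot <- function(E) data.frame(spot_id = 1L, layer = 1L, energy_MeV = E,
                                    x_mm = 0, y_mm = 0, weight_protons = 1e7)
  geo <- gadodose:::precompute_geometry(g)
  vox <- gadodose:::target_voxel_table(g, geo)
  dose_of <- function(E) {
    lut <- gadodose:::lut_cache(models$model, models$beam)
    dd <- lut(E)(vox$we_mid)
    g_lat <- gadodose:::lateral_mass(g, vox, 0, 0, models$beam)
    sum(dd * g_lat)
  }
  # both energies traverse the whole target; the higher one peaks beyond it
  expect_gt(pixe_yield(g, mk_spot(98)), pixe_yield(g, mk_spot(90)))
  expect_lt(dose_of(98), dose_of(90))
})

test_that("the screened kernel agrees with a first-flight MC oracle", {
  fixtures <- list(
    list(src = c(0, 0, 0), lo = c(-0.5, -0.5, 1.5), hi = c(0.5, 0.5, 2.5),
         L = 2.8, seed = 41),
    list(src = c(0.5, -0.3, 0), lo = c(1.2, 0.8, -0.6), hi = c(2.2, 1.8, 0.4),
         L = 2.0, seed = 42),
    list(src = c(0, 0, 0), lo = c(-0.2, -0.2, 0.9), hi = c(0.2, 0.2, 1.3),
         L = 2.8, seed = 43)
  )
  for (f in fixtures) {
    mc <- mc_first_flight(f$src, f$lo, f$hi, f$L, n = 1e5, seed = f$seed)
    pred <- kernel_box_integral(f$src, f$lo, f$hi, f$L, cells = 24)
    expect_lt(abs(pred - mc$mean), 3 * mc$se)
  }
})

test_that("kernel flux decreases monotonically with distance", {
  r <- seq(0.2, 6, by = 0.1)
  expect_true(all(diff(capture_kernel(r, 2.8)) < 0))
  expect_error(capture_kernel(0, 2.8))
})

test_that("a Gd-free target emits no capture or PIXE photons", {
  g <- fx_phantom_water()
  spot <- data.frame(spot_id = 1L, layer = 1L, energy_MeV = 85,
                     x_mm = 0, y_mm = 0, weight_protons = 1e7)
  expect_equal(capture_yield(g, spot), 0)
  expect_equal(pixe_yield(g, spot), 0)
})

test_that("escape survival through one water HVL is exactly one half", {
  mu <- mu_from_hvl(2.6)
  expect_lt(abs(attenuation_survival(2.6, mu) - 0.5), 1e-6)
  expect_lt(abs(attenuation_survival(5.2, mu) - 0.25), 1e-6)
})

test_that("detection never creates counts and survival lies in (0, 1]", {
  g <- fx_phantom_dotarem()
  geo <- gadodose:::precompute_geometry(g)
  vox <- gadodose:::target_voxel_table(g, geo)
  surv <- survival_map(g, vox, 8.7, 64)
  expect_true(all(surv > 0 & surv <= 1))
  emission <- rep(100, nrow(vox))
  expect_lt(detect(emission, g, vox, 8.7, 64), sum(emission))
  expect_error(survival_map(g, vox, 5), "sphere")
})

test_that("detection directions are unit quasi-uniform vectors", {
  u <- gadodose:::fibonacci_sphere(128)
  expect_equal(dim(u), c(128L, 3L))
  expect_equal(sqrt(rowSums(u^2)), rep(1, 128), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(u))), 0.05)
})

test_that("spectrum synthesis is seeded and the 43 keV line is recovered", {
  s1 <- synthesize_spectrum(2e5, background_per_keV = 40, seed = 7)
  s2 <- synthesize_spectrum(2e5, background_per_keV = 40, seed = 7)
  s3 <- synthesize_spectrum(2e5, background_per_keV = 40, seed = 8)
  expect_identical(s1$counts, s2$counts)
  expect_false(identical(s1$counts, s3$counts))
  line <- extract_line(s1, 43)
  expect_lt(abs(line$net - 2e5), 5 * line$error)
  expect_error(extract_line(s1, 199), "window")
})

test_that("seeded evaluation restores the caller's RNG stream", {
  set.seed(123)
  ref <- runif(3)
  set.seed(123)
  gadodose:::with_seed(999, runif(10))
  expect_identical(runif(3), ref)
  a <- gadodose:::substream_seed(1L, 5L, 2L)
  b <- gadodose:::substream_seed(1L, 5L, 2L)
  expect_identical(a, b)
  expect_false(gadodose:::substream_seed(1L, 6L, 2L) == a)
  expect_true(a >= 1 && a < 2^31)
})
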