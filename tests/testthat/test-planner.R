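test_that("energy layers are distal-anchored at the fixed WE spacing", {
  g <- fx_phantom_water()
  layers <- select_energy_layers(g)
  expect_equal(nrow(layers), 11)
  expect_equal(layers$peak_we_cm, seq(6.0, 4.0, by = -0.2))
  expect_true(all(diff(layers$energy_MeV) < 0))
  # layer energies invert back to their peak depths
  expect_equal(range_from_energy(layers$energy_MeV), layers$peak_we_cm,
               tolerance = 1e-10)
})

test_that("the Dotarem target pushes the distal layer deeper in WE terms", {
  gd <- fx_phantom_dotarem()
  layers <- select_energy_layers(gd)
  rsp <- gd$target$relative_stopping_power
  expect_equal(nrow(layers), 12)
  expect_equal(max(layers$peak_we_cm), 4 + 2 * rsp, tolerance = 1e-9)
  expect_gt(max(layers$energy_MeV),
            max(select_energy_layers(fx_phantom_water())$energy_MeV))
})

test_that("the lateral lattice covers the target cross-section", {
  lat <- place_spots(2, 3)
  expect_equal(nrow(lat), 49)
  expect_equal(sort(unique(lat$x_mm)), seq(-9, 9, by = 3))
  expect_equal(max(abs(lat$x_mm)), 9)
  # a finer lattice on a wider target
  lat2 <- place_spots(3, 2.5)
  expect_equal(sort(unique(lat2$x_mm)), seq(-12.5, 12.5, by = 2.5))
})

test_that("plan skeleton is the layer x lattice product with unique ids", {
  sk <- plan_skeleton(fx_phantom_water())
  expect_equal(nrow(sk), 11 * 49)
  expect_false(any(duplicated(sk$spot_id)))
  expect_equal(as.vector(table(sk$layer)), rep(49L, 11))
})

test_that("projected-gradient NNLS matches the Lawson-Hanson oracle", {
  set.seed(31)
  for (rep in 1:8) {
    A <- matrix(runif(40 * 12), 40, 12)
    b <- runif(40)
    w <- gadodose:::nnls_pg(A, b)
    ref <- pracma::lsqnonneg(A, b)$x
    expect_lt(max(abs(w - ref)), 1e-6)
    expect_true(all(w >= 0))
    # objectives agree to high accuracy
    expect_lt(sum((A %*% w - b)^2), sum((A %*% ref - b)^2) + 1e-9)
  }
})

test_that("NNLS solution satisfies the KKT conditions on the real plan", {
  plan <- fx_plan_dotarem()
  g <- fx_phantom_dotarem()
  geo <- gadodose:::precompute_geometry(g)
  vox <- which(geo$mask, arr.ind = TRUE)
  vox <- data.frame(ix = vox[, 1], iy = vox[, 2], iz = vox[, 3])
  A <- spot_influence(g, plan$spots, vox, geo = geo)
  w <- plan$spots$weight_protons
  grad <- crossprod(A, as.vector(A %*% w) - plan$prescription_Gy)
  scale <- max(abs(crossprod(A, rep(plan$prescription_Gy, nrow(vox)))))
  active <- w > 0
  expect_lt(max(abs(grad[active])) / scale, 1e-4)   # stationarity
  expect_gt(min(grad[!active]) / scale, -1e-4)      # dual feasibility
})

test_that("optimized weights inherit the lattice reflection symmetry", {
  plan <- fx_plan_dotarem()
  sp <- plan$spots
  key <- paste(sp$layer, sp$x_mm, sp$y_mm)
  w <- sp$weight_protons
  for (sgn in list(c(-1, 1), c(1, -1), c(-1, -1))) {
    m <- match(paste(sp$layer, sgn[1] * sp$x_mm, sgn[2] * sp$y_mm), key)
    expect_lt(max(abs(w - w[m])) / max(w), 1e-12)
  }
})

test_that("symmetrization preserves asymmetric lattices untouched", {
  sk <- data.frame(layer = 1L, x_mm = c(0, 3), y_mm = c(0, 0))
  expect_equal(gadodose:::symmetrize_weights(sk, c(1, 2)), c(1, 2))
})

test_that("the optimized plan recovers the uniform prescription", {
  plan <- fx_plan_dotarem()
  expect_lt(abs(plan$mean_target_dose_Gy - plan$prescription_Gy) /
              plan$prescription_Gy, 0.03)
  expect_lte(plan$d90_Gy, plan$mean_target_dose_Gy)
  expect_gt(plan$d90_Gy, 0.9 * plan$prescription_Gy)
})

test_that("spot lists round-trip losslessly through CSV", {
  plan <- fx_plan_dotarem()
  path <- tempfile(fileext = ".csv")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_identical(back$weight_protons, plan$spots$weight_protons)
  expect_identical(back$energy_MeV, plan$spots$energy_MeV)
  expect_identical(gadodose:::plan_hash(back),
                   gadodose:::plan_hash(plan))
  unlink(path)
})

test_that("fluence rescaling preserves relative weights and scales dose", {
  plan <- fx_plan_dotarem()
  small <- downscale_fluence(plan, 1e9)
  expect_equal(sum(small$spots$weight_protons), 1e9)
  f <- 1e9 / plan$total_protons
  expect_equal(small$spots$weight_protons,
               plan$spots$weight_protons * f, tolerance = 1e-12)
  expect_equal(small$mean_target_dose_Gy,
               plan$mean_target_dose_Gy * f, tolerance = 1e-12)
})
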