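test_that("formula parsing and molar mass match hand arithmetic", {
  mm <- molar_mass(c(C = 23, H = 42, O = 13, N = 5, Gd = 1))
  expect_equal(mm, 23 * 12.011 + 42 * 1.008 + 13 * 15.999 + 5 * 14.007 +
                 157.25, tolerance = 1e-12)
  fr <- element_fractions_from_formula(c(H = 2, O = 1))
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["H"]), 2 * 1.008 / (2 * 1.008 + 15.999))
  expect_error(element_fractions_from_formula(c(Xx = 1)), "unknown element")
})

test_that("mass fractions of every shipped material sum to 1 within 1e-9", {
  mats <- list(water_material(), dotarem_material(),
               dotarem_material(0.25), dotarem_material(0))
  for (m in mats) expect_lt(abs(sum(m$composition) - 1), 1e-9)
  expect_error(material("bad", 1, c(H = 0.5, O = 0.4)), "sum to 1")
})

test_that("relative stopping power: water is 1, density scaling is exact", {
  expect_equal(water_material()$relative_stopping_power, 1)
  wf <- c(H = 2 * 1.008, O = 15.999) / (2 * 1.008 + 15.999)
  dense <- material("dense-water", 2.0, wf)
  expect_equal(dense$relative_stopping_power, 2, tolerance = 1e-12)
})

test_that("Dotarem RSP matches the independent Bragg-additivity oracle", {
  d <- dotarem_material()
  expect_equal(d$relative_stopping_power,
               oracle_rsp(d$density, d$composition), tolerance = 1e-10)
  # frozen computed value for the 0.5 mmol/mL, 1.1753 g/cm^3 agent
  expect_equal(d$relative_stopping_power, 1.1270, tolerance = 1e-3)
})

test_that("two-isotope capture cross section reproduces the printed value", {
  iso <- gd_isotopes()
  two <- iso[iso$mass_number %in% c(155, 157), ]
  sigma2 <- total_absorption_cross_section(two)
  # hand arithmetic: 0.148 x 60900 + 0.157 x 254000
  expect_equal(sigma2, 0.148 * 60900 + 0.157 * 254000, tolerance = 1e-12)
  expect_lt(abs(sigma2 - 48800) / 48800, 0.01)
  expect_lt(abs(sum(iso$natural_abundance) - 1), 1e-9)
})

test_that("macroscopic capture cross section and mean free path", {
  d <- dotarem_material()
  # independent hand product: n_Gd = c * 1e-3 * N_A; Sigma = n sigma (barns)
  n_gd <- 0.5e-3 * 6.02214076e23
  expect_equal(d$gd_number_density, n_gd, tolerance = 1e-12)
  sigma <- macroscopic_capture_xs(d)
  expect_lt(abs(sigma - n_gd * total_absorption_cross_section() * 1e-24),
            1e-9)
  expect_lt(abs(sigma - 14.7) / 14.7, 0.01)
  expect_lt(abs(1 / sigma - 0.068), 0.002) # mean free path ~0.68 mm
})

test_that("gd_number_density and cross-section sum are linear", {
  cs <- c(0.1, 0.4, 0.5, 2)
  expect_equal(gd_number_density(2 * cs), 2 * gd_number_density(cs))
  expect_equal(gd_number_density(cs[1] + cs[2]),
               gd_number_density(cs[1]) + gd_number_density(cs[2]))
  iso <- gd_isotopes()
  scaled <- iso
  scaled$thermal_capture_cross_section <-
    3 * iso$thermal_capture_cross_section
  expect_equal(total_absorption_cross_section(scaled),
               3 * total_absorption_cross_section(iso))
  half <- iso
  half$natural_abundance <- iso$natural_abundance / 2
  expect_equal(total_absorption_cross_section(half),
               total_absorption_cross_section(iso) / 2)
})

test_that("HVL to attenuation coefficient conversion", {
  expect_equal(mu_from_hvl(2.6), log(2) / 2.6)
  expect_equal(mu_from_hvl(1.0), log(2))
  expect_equal(mu_from_hvl(Inf), 0)
  expect_error(mu_from_hvl(0))
  expect_error(mu_from_hvl(-1))
})

test_that("water 43 keV attenuation is consistent with the ~2.6 cm HVL", {
  w <- water_material()
  expect_lt(abs(log(2) / w$mu_43keV - 2.6) / 2.6, 0.02)
  tab <- attenuation_table()
  expect_setequal(tab$tissue, c("water", "lung", "air", "bone"))
  expect_true(all(tab$mu_lo_cm <= tab$mu_hi_cm))
})

test_that("materials load from a YAML config with HVL override", {
  cfg <- list(
    list(name = "solventA", density = 1.05,
         formula = list(H = 2, O = 1), hvl_43keV = 3.0),
    list(name = "agentB", density = 1.1753,
         fractions = as.list(dotarem_material()$composition),
         gd_concentration = 0.5)
  )
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  mats <- materials_from_config(path)
  expect_named(mats, c("solventA", "agentB"))
  expect_equal(mats$solventA$mu_43keV, log(2) / 3.0)
  # YAML rounds the fractions slightly, so compare loosely
  expect_equal(mats$agentB$relative_stopping_power,
               dotarem_material()$relative_stopping_power, tolerance = 1e-6)
  unlink(path)
})
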