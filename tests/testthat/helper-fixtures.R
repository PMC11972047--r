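# Heavy shared fixtures, built lazily once per test run and cached in a
# session-local environment. Everything here is deterministic ("expected"
# mode), so a fixture is identical no matter which test builds it first.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

fx_phantom_dotarem <- function() {
  fixture("ph_dotarem", function() phantom_grid())
}

fx_phantom_water <- function() {
  fixture("ph_water", function() phantom_grid(target = water_material()))
}

fx_plan_dotarem <- function() {
  fixture("plan_dotarem", function() plan_treatment(fx_phantom_dotarem()))
}

fx_plan_water <- function() {
  fixture("plan_water", function() plan_treatment(fx_phantom_water()))
}

# Canonical displacement series of the fixed Dotarem plan (expected mode).
fx_series_x <- function() {
  fixture("series_x", function() {
    displacement_series(fx_plan_dotarem(), fx_phantom_dotarem(), "x",
                        mode = "expected", seed = 101L)
  })
}

fx_series_z <- function() {
  fixture("series_z", function() {
    displacement_series(fx_plan_dotarem(), fx_phantom_dotarem(), "z",
                        mode = "expected", seed = 101L)
  })
}

# Baseline (undisplaced) scenario shared by several tests.
fx_baseline <- function() fx_series_x()$results[[1]]
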