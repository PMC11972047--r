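# A reduced plan (heaviest spots only) keeps sampled-mode tests fast while
# exercising the identical code path.
reduced_plan <- function(n = 24) {
  plan <- fx_plan_dotarem()
  keep <- order(plan$spots$weight_protons, decreasing = TRUE)[seq_len(n)]
  plan$spots <- plan$spots[sort(keep), ]
  plan
}

test_that("identical seeds give identical sampled scenarios", {
  plan <- reduced_plan()
  ph <- fx_phantom_dotarem()
  r1 <- run_scenario(plan, ph, "x", 0, mode = "sampled", seed = 7L)
  r2 <- run_scenario(plan, ph, "x", 0, mode = "sampled", seed = 7L)
  r3 <- run_scenario(plan, ph, "x", 0, mode = "sampled", seed = 8L)
  expect_identical(r1$spots, r2$spots)
  expect_identical(r1$totals, r2$totals)
  expect_false(identical(r1$spots$detected_sampled,
                         r3$spots$detected_sampled))
})

test_that("sampled totals converge on the expected-mode totals", {
  plan <- reduced_plan()
  ph <- fx_phantom_dotarem()
  ex <- run_scenario(plan, ph, "x", 0, mode = "expected")
  sa <- run_scenario(plan, ph, "x", 0, mode = "sampled", seed = 5L)
  expect_lt(abs(sa$totals$detected_sampled - ex$totals$detected_total) /
              ex$totals$detected_total, 0.01)
  expect_lt(abs(sa$totals$dose_target_Gy - ex$totals$dose_target_Gy) /
              ex$totals$dose_target_Gy, 0.01)
})

test_that("channel-split tallies are consistent and additive", {
  plan <- reduced_plan()
  ph <- fx_phantom_dotarem()
  both <- run_scenario(plan, ph, "x", 0, channels = "both")
  pixe <- run_scenario(plan, ph, "x", 0, channels = "pixe")
  capt <- run_scenario(plan, ph, "x", 0, channels = "capture")
  expect_equal(both$spots$detected_total,
               both$spots$detected_pixe + both$spots$detected_capture)
  expect_equal(pixe$spots$detected_pixe, both$spots$detected_pixe)
  expect_equal(pixe$spots$detected_capture, rep(0, nrow(pixe$spots)))
  expect_equal(capt$spots$detected_capture, both$spots$detected_capture)
  expect_true(all(both$spots$detected_pixe <= both$spots$emitted_pixe))
})

test_that("displacements are validated against the voxel lattice", {
  plan <- reduced_plan()
  ph <- fx_phantom_dotarem()
  expect_error(run_scenario(plan, ph, "x", 3), "multiple")
  expect_error(run_scenario(plan, ph, "x", 12), "multiple|<=")
})

test_that("the displaced target keeps its volume in every scenario", {
  for (r in c(fx_series_x()$results, fx_series_z()$results)) {
    expect_equal(r$dvh$n, 1000)
    expect_equal(length(r$target_dose_vox), 1000)
  }
})

test_that("per-spot records and voxel doses agree on the totals", {
  r <- fx_baseline()
  expect_equal(r$totals$dose_target_Gy, mean(r$target_dose_vox),
               tolerance = 1e-12)
  expect_equal(r$totals$dose_target_Gy, sum(r$spots$dose_target_Gy),
               tolerance = 1e-12)
  tot <- series_totals(fx_series_x())
  expect_equal(tot$v95[1], v_at(r$dvh, 0.95))
})

test_that("all scenarios of a series share the fixed plan", {
  sx <- fx_series_x()
  hashes <- vapply(sx$results, `[[`, "", "plan_hash")
  expect_true(all(hashes == sx$plan_hash))
  expect_identical(sx$plan_hash, gadodose:::plan_hash(fx_plan_dotarem()))
})

test_that("full-grid accumulation matches the target-voxel tally", {
  plan <- reduced_plan(6)
  ph <- fx_phantom_dotarem()
  r <- run_scenario(plan, ph, "x", 0, full_grid = TRUE)
  geo <- gadodose:::precompute_geometry(ph)
  vox <- gadodose:::target_voxel_table(ph, geo)
  cum_target <- r$cumulative_dose$dose[cbind(vox$ix, vox$iy, vox$iz)]
  expect_equal(cum_target, r$target_dose_vox, tolerance = 1e-9)
})

test_that("batch replicates estimate a positive counting-noise width", {
  plan <- downscale_fluence(reduced_plan(), 1e6)
  ph <- fx_phantom_dotarem()
  u <- batch_uncertainty(plan, ph, "x", 0, n_batches = 4, seed = 3L)
  expect_true(all(is.finite(u$mean)) && all(u$mean > 0))
  expect_true(all(u$sd >= 0) && any(u$sd > 0))
})
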