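# Preset experiment reconstructions.

calibrated <- kinetic_parameters()

test_that("the substrate sweep shows substrate inhibition without GSH", {
  tab <- mmas_sweep(0, c(0, 1, 2, 3, 4, 6, 10, 15, 20), calibrated)
  expect_equal(tab$total_DMAs[1], 0)
  expect_equal(tab$trivalent_DMAs[1], 0)
  opt <- interpolated_argmax(tab$dose, tab$total_DMAs)
  expect_lt(tab$total_DMAs[nrow(tab)], max(tab$total_DMAs))
  expect_gt(opt, 2); expect_lt(opt, 6)
})

test_that("1 mM GSH raises the peak DMAs yield about four-fold", {
  doses <- seq(0, 20, by = 1)
  r0 <- mmas_sweep(0, doses, calibrated)
  r1 <- mmas_sweep(1, doses, calibrated)
  ratio <- max(r1$total_DMAs) / max(r0$total_DMAs)
  expect_gt(ratio, 3); expect_lt(ratio, 5)
})

test_that("the 40-minute time course conserves arsenic and favours 1 mM GSH", {
  t0 <- time_course(0, calibrated, n_times = 9)
  t1 <- time_course(1, calibrated, n_times = 9)
  expect_true(all(abs(t0$derived$total_arsenic - 1) < 1e-6))
  expect_true(all(abs(t1$derived$total_arsenic - 1) < 1e-6))
  n <- length(t1$times)
  expect_gt(t1$derived$total_DMAs[n], t0$derived$total_DMAs[n])
  # pentavalent DMAs is immediately reduced: negligible free DMAsV
  expect_lt(t1$states[n, "DMAsV"] / t1$derived$total_DMAs[n], 0.1)
  expect_gte(length(t1$times), 9)
})

test_that("the GSH dose-response has an interior optimum and respects conservation", {
  dr <- gsh_dose_response(params = calibrated)
  expect_true(all(dr$table$total_methylated <= 1))
  expect_true(all(dr$table$total_MMAs <= 1))
  expect_gt(dr$optimum_mM, min(dr$table$dose_mM))
  expect_lt(dr$optimum_mM, max(dr$table$dose_mM))
  # methylation at the highest dose is below the optimum response
  imax <- which.max(dr$table$total_methylated)
  expect_lt(dr$table$total_methylated[nrow(dr$table)],
            dr$table$total_methylated[imax] + 1e-15)
})

test_that("ablation presets share the dose-response protocol apart from the variant", {
  doses <- c(1, 5, 20)
  a <- ablation("no_conjugation", doses, calibrated)
  b <- gsh_dose_response(doses, calibrated, variant = "no_conjugation")
  expect_identical(a, b)
})

test_that("removing conjugation at zero GSH changes nothing", {
  doses <- c(0, 1)
  full <- gsh_dose_response(doses, calibrated)
  nc <- gsh_dose_response(doses, calibrated, variant = "no_conjugation")
  expect_equal(full$table[1, ], nc$table[1, ], tolerance = 1e-9)
})

test_that("frozen activation is monotone non-increasing, no conjugation non-decreasing", {
  uc <- ablation("u_constant_5000", params = calibrated)$table$total_methylated
  nc <- ablation("no_conjugation", params = calibrated)$table$total_methylated
  expect_true(all(diff(uc) <= 1e-12))
  expect_true(all(diff(nc) >= -1e-12))
})

test_that("the total methylation flux under decaying GSH peaks at an interior time", {
  fx <- flux_time_course(calibrated, n_times = 161)
  ft <- fx$result$derived$flux_total
  expect_gt(fx$peak_time_h, 0)
  expect_lt(fx$peak_time_h, 8)
  expect_lt(ft[1], max(ft))
  expect_lt(ft[length(ft)], max(ft))
})

test_that("the experiment catalog is uniquely labelled and runnable", {
  cat <- experiment_catalog()
  expect_false(any(duplicated(names(cat))))
  for (preset in cat) {
    expect_true(is.function(preset$run))
    expect_true(nzchar(preset$signature))
  }
  # spot-run the cheapest preset through the catalog interface
  out <- cat$gsh_dose_response$run(calibrated)
  expect_true(is.data.frame(out$table))
})
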