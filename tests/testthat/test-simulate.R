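test_that("scenario invariants are enforced", {
  expect_error(ms_scenario(c(erianin = -1)), "contents")
  expect_error(ms_scenario(recovery_factor = 1.2), "recovery_factor")
  expect_error(ms_scenario(sample_mass = 0), "sample_mass")
  expect_error(ms_scenario(elution_volume = -1), "elution_volume")
  expect_error(ms_scenario(response_factor = 0), "response_factor")
  expect_error(ms_scenario(noise_level = -5), "noise_level")
})

test_that("extract concentration follows content * recovery * mass / volume", {
  # 425 mg/kg at full recovery, 0.5 g into 10 mL -> 21.25 ug/mL
  sc <- ms_scenario(c(erianin = 425), response_factor = 1000, seed = 1)
  run <- simulate_run(sc, full_scan = FALSE)
  tr <- run$truth[run$truth$compound == "erianin", ]
  expect_equal(tr$extract_conc, 21.25)
  expect_equal(tr$true_area, 21250)

  sc2 <- ms_scenario(c(erianin = 425), response_factor = 1000,
                     recovery_factor = 0.8, seed = 1)
  run2 <- simulate_run(sc2, full_scan = FALSE)
  expect_equal(run2$truth$extract_conc[run2$truth$compound == "erianin"],
               21.25 * 0.8)
})

test_that("noise-free SIM area equals response_factor * concentration within 1%", {
  # extract conc 10 ug/mL needs content 200 mg/kg at 0.5 g / 10 mL
  sc <- ms_scenario(c(erianin = 200), response_factor = 1000, seed = 1)
  run <- simulate_run(sc, full_scan = FALSE)
  pks <- detect_peaks(extract_sim(run, 341, "positive"))
  expect_equal(nrow(pks), 1)
  expect_lt(abs(pks$area - 10000) / 10000, 0.01)
})

test_that("zero content gives identically zero traces; doubling content doubles area", {
  sc0 <- ms_scenario(setNames(rep(0, 12), phenol_library()$compound),
                     seed = 3)
  run0 <- simulate_run(sc0, full_scan = FALSE)
  expect_true(all(run0$sim_traces$intensity == 0))

  area_of <- function(content) {
    sc <- ms_scenario(c(moscatilin = content), response_factor = 2000,
                      seed = 4)
    run <- simulate_run(sc, full_scan = FALSE)
    pks <- detect_peaks(extract_sim(run, 327, "positive"))
    pks$area[1]
  }
  expect_equal(area_of(300) / area_of(150), 2, tolerance = 1e-9)
})

test_that("unknown compounds are rejected", {
  sc <- ms_scenario(c(quercetin = 10), seed = 1)
  expect_error(simulate_run(sc), class = "phenolscreen_unknown_compound")
})

test_that("run invariants: increasing cycle times, bins in range, non-negative intensities", {
  sc <- reference_scenario(c(gigantol = 50, apigenin = 80),
                           noise_level = 30, seed = 11)
  run <- simulate_run(sc)
  expect_true(!is.unsorted(run$metadata$rt, strictly = TRUE))
  expect_true(all(run$full_scans$mz >= 50 & run$full_scans$mz <= 400))
  expect_true(all(run$full_scans$intensity >= 0))
  expect_true(all(run$sim_traces$intensity >= 0))
})

test_that("simulation is reproducible for a given seed", {
  sc <- reference_scenario(c(erianin = 100), noise_level = 50, seed = 99)
  r1 <- simulate_run(sc, full_scan = FALSE)
  r2 <- simulate_run(sc, full_scan = FALSE)
  expect_identical(r1$sim_traces, r2$sim_traces)
  r3 <- simulate_run(sc, full_scan = FALSE, seed = 100)
  expect_false(identical(r1$sim_traces, r3$sim_traces))
})

test_that("calibration series: layout, degenerate cases and exact refit", {
  sc <- ms_scenario(response_factor = c(erianin = 14667),
                    intercept = c(erianin = 3462), seed = 5)
  series <- simulate_calibration_series("erianin", c(2, 5, 10, 20, 50, 100),
                                        sc, n_replicates = 3)
  expect_equal(nrow(series), 18)

  single <- simulate_calibration_series("erianin", 10, sc, n_replicates = 1)
  expect_equal(nrow(single), 1)

  expect_error(simulate_calibration_series("erianin", numeric(), sc))
  expect_error(simulate_calibration_series("erianin", c(5, 2), sc))

  # round trip: true areas generated from the line refit to it exactly
  m <- fit_calibration(series$level, series$true_area, "erianin")
  expect_equal(m$slope, 14667, tolerance = 1e-12)
  expect_equal(m$intercept, 3462, tolerance = 1e-9)
  expect_equal(m$r_squared, 1)
})

test_that("spiked batches encode endogenous + recovery * spike", {
  batch <- simulate_spiked_batch(
    endogenous = c(gigantol = 12.7), spike_level = 50, n_replicates = 5,
    recovery_true = c(gigantol = 0.958), seed = 8,
    scenario = reference_scenario(), compounds = "gigantol"
  )
  expect_equal(nrow(batch$spiked), 5)
  expect_equal(nrow(batch$blanks), 5)
  expect_equal(batch$truth$true_content, 12.7 + 0.958 * 50)  # 60.6
  expect_equal(batch$truth$true_content, 60.6)

  two <- simulate_spiked_batch(spike_level = c(50, 200), n_replicates = 5,
                               seed = 8, scenario = reference_scenario(),
                               compounds = "gigantol")
  expect_equal(nrow(two$spiked), 10)

  expect_error(simulate_spiked_batch(spike_level = -1, seed = 1),
               class = "phenolscreen_bad_spike")
  expect_error(simulate_spiked_batch(spike_level = 50, n_replicates = 1,
                                     seed = 1))
})

test_that("runs round-trip through the CSV serialization", {
  sc <- reference_scenario(c(moscatilin = 230, apigenin = 10.6),
                           noise_level = 25, seed = 21)
  run <- simulate_run(sc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_run_csv(run, path)
  back <- read_run_csv(path)
  expect_equal(back$sim_traces, run$sim_traces)
  expect_equal(as.data.frame(back$full_scans),
               as.data.frame(run$full_scans))
  expect_equal(back$metadata$rt, run$metadata$rt)
  expect_equal(back$metadata$scan_range, run$metadata$scan_range)
})

test_that("full scans round-trip through mzML", {
  skip_if_not_installed("mzR")
  sc <- reference_scenario(c(gigantol = 40), seed = 31, rt_range = c(5, 6.5))
  run <- simulate_run(sc)
  path <- withr::local_tempfile(fileext = ".mzML")
  suppressWarnings(write_run_mzml(run, path))
  back <- read_run_mzml(path)
  orig <- dplyr::arrange(run$full_scans, rt, polarity, mz)
  got <- dplyr::arrange(back, rt, polarity, mz)
  expect_equal(got$mz, orig$mz)
  expect_equal(got$intensity, orig$intensity, tolerance = 1e-6)
  expect_equal(got$rt, orig$rt, tolerance = 1e-6)
  expect_equal(got$polarity, orig$polarity)
})

test_that("scenario round-trips through the YAML config format", {
  sc <- ms_scenario(c(erianin = 425, gigantol = 15),
                    response_factor = c(erianin = 14667), noise_level = 10,
                    seed = 77)
  path <- withr::local_tempfile(fileext = ".yml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$contents, sc$contents)
  expect_equal(back$response_factor, sc$response_factor)
  expect_equal(back$seed, sc$seed)
})
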