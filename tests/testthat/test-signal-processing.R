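test_that("XIC pulls out a single compound's elution and rejects bad input", {
  sc <- reference_scenario(c(moscatilin = 230), seed = 2)
  run <- simulate_run(sc)
  x <- extract_xic(run, 327, 0.5, "positive")
  pks <- detect_peaks(x)
  expect_equal(nrow(pks), 1)
  expect_lt(abs(pks$apex_rt - 5.62), 0.06)

  # an m/z with no ions gives an all-zero trace of full run length
  x0 <- extract_xic(run, 399, 0.5, "positive")
  expect_equal(nrow(x0), length(run$metadata$rt))
  expect_true(all(x0$intensity == 0))

  expect_error(extract_xic(run, 327, 0.5, "anion"), "polarity")
  expect_error(extract_xic(run, 450, 0.5, "positive"), "scan range")
})

test_that("XICs over all bins sum to the TIC at every cycle", {
  sc <- reference_scenario(c(gigantol = 60, naringenin = 30, moscatin = 45),
                           noise_level = 15, seed = 6)
  run <- simulate_run(sc)
  tic <- extract_tic(run, "positive")
  bins <- sort(unique(run$full_scans$mz[run$full_scans$polarity ==
                                          "positive"]))
  acc <- rep(0, nrow(tic))
  for (b in bins) {
    acc <- acc + extract_xic(run, b, 0, "positive")$intensity
  }
  expect_equal(acc, tic$intensity)
})

test_that("peak detection: flat traces, Gaussian height, resolved doublets", {
  flat <- tibble::tibble(rt = seq(0, 5, 0.05), intensity = 0)
  expect_equal(nrow(detect_peaks(flat)), 0)

  g <- gaussian_chrom(amplitude = 1000, center = 5, sigma = 0.05)
  pks <- detect_peaks(g)
  expect_equal(nrow(pks), 1)
  expect_equal(pks$apex_rt, 5)
  expect_lt(abs(pks$height - 1000) / 1000, 0.02)

  two <- gaussian_chrom(1000, 4, 0.05)
  two$intensity <- two$intensity +
    gaussian_chrom(800, 5, 0.05)$intensity
  pks2 <- detect_peaks(two)
  expect_equal(nrow(pks2), 2)
  expect_equal(pks2$apex_rt, c(4, 5))
  expect_true(pks2$end_rt[1] <= pks2$start_rt[2])  # disjoint
})

test_that("trapezoidal integration matches the Gaussian closed form", {
  g <- gaussian_chrom(amplitude = 1000, center = 5, sigma = 0.05)
  closed <- 1000 * 0.05 * sqrt(2 * pi)  # 125.33
  area <- integrate_peak(g, tibble::tibble(start_rt = 5 - 0.2,
                                           end_rt = 5 + 0.2))
  expect_lt(abs(area - closed) / closed, 0.01)

  z <- tibble::tibble(rt = seq(0, 5, 0.05), intensity = 0)
  expect_equal(integrate_peak(z, tibble::tibble(start_rt = 1,
                                                end_rt = 2)), 0)

  g2 <- g
  g2$intensity <- 2 * g$intensity
  a1 <- integrate_peak(g, tibble::tibble(start_rt = 4.8, end_rt = 5.2))
  a2 <- integrate_peak(g2, tibble::tibble(start_rt = 4.8, end_rt = 5.2))
  expect_equal(a2, 2 * a1)

  expect_error(integrate_peak(g, tibble::tibble(start_rt = -1,
                                                end_rt = 5)),
               "outside")
})

test_that("area error vs the closed form shrinks as the cycle period halves", {
  closed <- 1000 * 0.05 * sqrt(2 * pi)
  err <- sapply(c(0.2, 0.1, 0.05, 0.025) / 4, function(p) {
    # periods from sigma down to sigma/8
    g <- gaussian_chrom(1000, 5, 0.05, period = p)
    a <- integrate_peak(g, tibble::tibble(start_rt = 4.8, end_rt = 5.2))
    abs(a - closed) / closed
  })
  expect_true(all(diff(err) <= 1e-12))  # non-increasing over halvings
  # floor set by the +-4 sigma truncation and baseline anchoring, ~0.1%
  expect_lt(err[length(err)], 2e-3)
})

test_that("baseline noise estimation follows the blank-window SD", {
  const <- tibble::tibble(rt = seq(0, 5, 0.05), intensity = 7)
  expect_equal(estimate_baseline_noise(const, c(0, 5)), 0)

  withr::with_seed(42, {
    noisy <- tibble::tibble(
      rt = seq(0, 30, 0.05),
      intensity = 1000 + rnorm(601, 0, 50)
    )
  })
  est <- estimate_baseline_noise(noisy, c(0, 30), min_snr = 1e9)
  expect_gt(est, 40)
  expect_lt(est, 60)

  # homogeneity: scaling the trace scales the noise
  scaled <- noisy
  scaled$intensity <- noisy$intensity * 3
  expect_equal(estimate_baseline_noise(scaled, c(0, 30), min_snr = 1e9),
               3 * est)

  expect_error(estimate_baseline_noise(const, c(0, 0.5)),
               class = "phenolscreen_blank_too_small")
  g <- gaussian_chrom(1000, 5, 0.05, span = c(0, 10))
  expect_error(estimate_baseline_noise(g, c(4, 6)),
               class = "phenolscreen_blank_has_peak")
})

test_that("peak lists are invariant to a constant intensity offset", {
  withr::with_seed(7, {
    base <- gaussian_chrom(2000, 3, 0.05, span = c(0, 6))
    base$intensity <- base$intensity + abs(rnorm(nrow(base), 0, 10))
  })
  shifted <- base
  shifted$intensity <- base$intensity + 500
  p1 <- detect_peaks(base, min_snr = 10)
  p2 <- detect_peaks(shifted, min_snr = 10)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p1$apex_rt, p2$apex_rt)
  expect_equal(p1$start_rt, p2$start_rt)
  expect_equal(p1$end_rt, p2$end_rt)
  expect_equal(p1$height, p2$height, tolerance = 1e-6)
  expect_equal(p1$area, p2$area, tolerance = 1e-6)
})

test_that("detect-integrate recovers simulated true areas within 5% at high S/N", {
  ok <- sapply(1:100, function(s) {
    true_area <- 50000
    sc <- ms_scenario(c(confusarin = 100), response_factor = 10000,
                      noise_level = 100, seed = s)
    # content 100 -> conc 5 -> area 50000; height ~ 399000; S/N ~ 3990
    run <- simulate_run(sc, full_scan = FALSE)
    pks <- detect_peaks(extract_sim(run, 301, "positive"), min_snr = 20)
    pks <- pks[abs(pks$apex_rt - 5.41) < 0.15, ]
    nrow(pks) == 1 && abs(pks$area - true_area) / true_area < 0.05
  })
  expect_gte(sum(ok), 100)
})

test_that("chromatograms round-trip to CSV", {
  sc <- reference_scenario(c(erianin = 100), noise_level = 5, seed = 13)
  run <- simulate_run(sc, full_scan = FALSE)
  tr <- extract_sim(run, 341, "positive")
  path <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram_csv(tr, path)
  back <- read_chromatogram_csv(path)
  expect_equal(back$rt, tr$rt)
  expect_equal(back$intensity, tr$intensity)
})
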