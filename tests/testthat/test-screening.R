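make_spec <- function(...) {
  v <- c(...)
  tibble::tibble(mz = as.numeric(names(v)), intensity = unname(v))
}

test_that("average_spectrum recovers a compound's adduct pattern", {
  sc <- reference_scenario(c(moscatilin = 230), seed = 2)
  run <- simulate_run(sc)
  sp <- average_spectrum(run, c(5.45, 5.8), "positive")
  expect_true(all(c(305, 327) %in% sp$mz))
  expect_equal(sp$mz[which.max(sp$intensity)], 327)

  # a blank region averages to an all-zero (empty) spectrum
  blank <- average_spectrum(run, c(9, 10), "positive")
  expect_equal(nrow(blank), 0)

  # a single cycle returns that cycle's background-subtracted spectrum
  grid <- run$metadata$rt
  rt0 <- grid[which.min(abs(grid - 5.62))]
  one <- average_spectrum(run, c(rt0, rt0), "positive", flank = 0)
  raw <- run$full_scans[run$full_scans$rt == rt0 &
                          run$full_scans$polarity == "positive", ]
  expect_equal(one$intensity, raw$intensity[order(raw$mz)])

  expect_error(average_spectrum(run, c(20, 21), "positive"),
               class = "phenolscreen_empty_window")
})

test_that("fingerprints keep relative abundances and polarity flags", {
  fp <- build_fingerprint(make_spec("327" = 1000, "305" = 480),
                          make_spec("303" = 120), rt = 5.62)
  expect_equal(fp$base_peak_mz, 327)
  expect_equal(fp$ions$rel_abund[fp$ions$mz == 305], 48)
  expect_equal(fp$ions$rel_abund[fp$ions$mz == 327], 100)
  expect_true(fp$has_positive_signal && fp$has_negative_signal)

  single <- build_fingerprint(make_spec("147" = 500),
                              make_spec()[0, ], rt = 1.79)
  expect_equal(nrow(single$ions), 1)
  expect_equal(single$ions$rel_abund, 100)

  # everything below the abundance cut-off except the base drops out
  thin <- build_fingerprint(make_spec("327" = 1000, "290" = 20),
                            make_spec()[0, ], min_rel_abund = 10)
  expect_equal(nrow(thin$ions), 1)

  expect_error(build_fingerprint(make_spec()[0, ], make_spec()[0, ]),
               class = "phenolscreen_empty_spectra")
})

test_that("family rules classify the canonical patterns", {
  # sodium-adduct pair with confirming protonated ion: bibenzyl
  bib <- classify_family(build_fingerprint(
    make_spec("327" = 1000, "305" = 480), make_spec("303" = 150)))
  expect_equal(bib$family, "bibenzyl")
  expect_equal(bib$inferred_mw, 304)

  # protonated base with strong sodium adduct (the chrysotoxin pattern)
  cht <- classify_family(build_fingerprint(
    make_spec("319" = 1000, "341" = 830), make_spec("317" = 100)))
  expect_equal(cht$family, "bibenzyl")
  expect_equal(cht$inferred_mw, 318)

  # negative-only ion: flavone, MW = base + 1
  fla <- classify_family(build_fingerprint(
    make_spec()[0, ], make_spec("269" = 900)))
  expect_equal(fla$family, "flavone")
  expect_equal(fla$inferred_mw, 270)

  # positive-only pair with a 28-Da neutral loss: phenanthrene
  phe <- classify_family(build_fingerprint(
    make_spec("241" = 1000, "213" = 620), make_spec()[0, ]))
  expect_equal(phe$family, "phenanthrene")
  expect_equal(phe$inferred_mw, 240)

  # positive-only single ion: coumarin-like
  cou <- classify_family(build_fingerprint(
    make_spec("147" = 900), make_spec()[0, ]))
  expect_equal(cou$family, "coumarin")
  expect_equal(cou$inferred_mw, 146)

  # positive-only pair at neither 22 nor a neutral-loss spacing: unknown
  unk <- classify_family(build_fingerprint(
    make_spec("200" = 1000, "150" = 500), make_spec()[0, ]))
  expect_equal(unk$family, "unknown")
  expect_true(is.na(unk$inferred_mw))
})

test_that("classification is invariant to uniform intensity scaling", {
  cases <- list(
    list(pos = c("327" = 1000, "305" = 480), neg = c("303" = 150)),
    list(pos = c("319" = 1000, "341" = 830), neg = c("317" = 100)),
    list(pos = c("241" = 1000, "213" = 620), neg = NULL),
    list(pos = NULL, neg = c("269" = 900)),
    list(pos = c("147" = 900), neg = NULL)
  )
  for (cs in cases) {
    for (scale in c(0.01, 1, 250)) {
      mk <- function(v) if (is.null(v)) make_spec()[0, ] else
        make_spec(v * scale)
      a <- classify_family(build_fingerprint(mk(cs$pos), mk(cs$neg)))
      mkb <- function(v) if (is.null(v)) make_spec()[0, ] else make_spec(v)
      b <- classify_family(build_fingerprint(mkb(cs$pos), mkb(cs$neg)))
      expect_equal(a$family, b$family)
      expect_equal(a$inferred_mw, b$inferred_mw)
    }
  }
})

test_that("identification separates known standards from new compounds", {
  lib <- phenol_library()
  # chrysotoxin-like peak at 6.84: no RT match to erianin (7.12)
  fp <- build_fingerprint(make_spec("319" = 1000, "341" = 830),
                          make_spec("317" = 100), rt = 6.84)
  fc <- classify_family(fp)
  id <- identify_compound(tibble::tibble(apex_rt = 6.84), fp, fc, lib)
  expect_equal(id$status, "newly_elucidated")
  expect_equal(id$surrogate_standard, "erianin")
  expect_equal(id$sim_ion, 341)  # sodium adduct preferred for bibenzyls

  # same fingerprint at erianin's RT: known standard
  fp2 <- build_fingerprint(make_spec("341" = 1000, "319" = 480),
                           make_spec("317" = 100), rt = 7.12)
  id2 <- identify_compound(tibble::tibble(apex_rt = 7.12), fp2,
                           classify_family(fp2), lib)
  expect_equal(id2$status, "known_standard")
  expect_equal(id2$compound, "erianin")

  # unknown family: unidentified, no surrogate
  fp3 <- build_fingerprint(make_spec("200" = 1000, "150" = 500),
                           make_spec()[0, ], rt = 3.3)
  id3 <- identify_compound(tibble::tibble(apex_rt = 3.3), fp3,
                           classify_family(fp3), lib)
  expect_equal(id3$status, "unidentified")
  expect_true(is.na(id3$surrogate_standard))
})

test_that("full screening of noise-free single-compound runs is 12/12 correct", {
  lib <- phenol_library()
  reports <- lapply(lib$compound, function(cp) {
    run <- simulate_run(reference_scenario(setNames(400, cp), seed = 2))
    screen_run(run)
  })
  rep <- dplyr::bind_rows(reports)
  expect_equal(nrow(rep), 12)
  expect_equal(rep$family, lib$family)
  expect_equal(rep$inferred_mw, lib$mw)
  # the nine standards identify as themselves
  expect_equal(rep$compound[lib$is_standard],
               lib$compound[lib$is_standard])
  expect_true(all(rep$status[lib$is_standard] == "known_standard"))
  # the three new compounds get the documented surrogates and SIM ions
  new <- rep[!lib$is_standard, ]
  expect_true(all(new$status == "newly_elucidated"))
  expect_equal(new$surrogate_standard, c("gigantol", "erianin", "erianin"))
  expect_equal(new$sim_ion, c(297, 327, 341))
})

test_that("bibenzyl calls carry the sodium adduct at inferred MW + 23", {
  lib <- phenol_library()
  for (cp in lib$compound[lib$family == "bibenzyl"]) {
    run <- simulate_run(reference_scenario(setNames(300, cp), seed = 5))
    tic <- extract_tic(run, "both")
    pk <- detect_peaks(tic, min_snr = 5)[1, ]
    fp <- build_fingerprint(
      average_spectrum(run, c(pk$start_rt, pk$end_rt), "positive"),
      average_spectrum(run, c(pk$start_rt, pk$end_rt), "negative"),
      rt = pk$apex_rt
    )
    fc <- classify_family(fp)
    expect_equal(fc$family, "bibenzyl")
    expect_true((fc$inferred_mw + 23) %in% fp$ions$mz,
                label = paste(cp, "Na adduct present at MW + 23"))
  }
})

test_that("surrogates always come from the called family", {
  lib <- phenol_library()
  fam_of <- setNames(lib$family, lib$compound)
  specs <- list(
    list(pos = c("327" = 1000, "305" = 480), neg = c("303" = 100),
         rt = 9.9),
    list(pos = c("297" = 1000, "275" = 500), neg = c("273" = 100),
         rt = 9.9),
    list(pos = c("241" = 1000, "213" = 620), neg = NULL, rt = 9.9),
    list(pos = NULL, neg = c("299" = 700), rt = 9.9),
    list(pos = c("161" = 800), neg = NULL, rt = 9.9)
  )
  for (cs in specs) {
    mk <- function(v) if (is.null(v)) make_spec()[0, ] else make_spec(v)
    fp <- build_fingerprint(mk(cs$pos), mk(cs$neg), rt = cs$rt)
    fc <- classify_family(fp)
    id <- identify_compound(tibble::tibble(apex_rt = cs$rt), fp, fc, lib)
    if (id$status == "newly_elucidated") {
      expect_equal(unname(fam_of[id$surrogate_standard]), fc$family)
    }
  }
})
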