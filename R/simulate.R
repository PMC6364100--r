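#' Define a simulation scenario for the instrument model
#'
#' A scenario fixes everything the simulator needs to turn true dry-sample
#' contents into a raw run: the detector response, the chromatographic peak
#' shape, baseline noise, the extraction recovery and the sample-preparation
#' constants (0.5 g of dried powder eluted into 10 mL, so content in mg/kg
#' maps to extract concentration in ug/mL via `mass / volume`, a factor of
#' 1/20 by default).
#'
#' @param contents Named numeric vector of true contents in mg/kg dry
#'   sample, or a tibble with columns `compound` and `content`. Compounds
#'   not listed are absent (content 0).
#' @param response_factor Detector response in area counts.min per (ug/mL)
#'   of extract concentration; a scalar or a vector named by compound.
#' @param intercept Calibration intercept in area counts.min (background
#'   response at zero concentration); scalar or named vector. Applied by
#'   [simulate_calibration_series()]; sample runs use the pure proportional
#'   response.
#' @param recovery_factor Fraction of analyte surviving extraction, in
#'   `[0, 1]`; scalar or named vector.
#' @param peak_sigma Gaussian elution peak width (sigma) in minutes.
#' @param noise_level Baseline noise amplitude: SD in counts of i.i.d.
#'   Gaussian noise added to every trace point and full-scan bin, clipped
#'   at zero.
#' @param sample_mass Dried sample mass in g.
#' @param elution_volume Elution volume in mL.
#' @param cycle_period Scan cycle period in minutes (one positive plus one
#'   negative full scan per cycle).
#' @param rt_range Acquisition time range in minutes.
#' @param scan_range Full-scan m/z range in Da.
#' @param seed Integer seed making all stochastic draws reproducible.
#' @return A list of class `ms_scenario`.
#' @examples
#' sc <- ms_scenario(c(erianin = 425), response_factor = 14667, seed = 1)
#' @export
ms_scenario <- function(contents = numeric(),
                        response_factor = 5e5,
                        intercept = 0,
                        recovery_factor = 1,
                        peak_sigma = 0.05,
                        noise_level = 0,
                        sample_mass = 0.5,
                        elution_volume = 10,
                        cycle_period = 0.05,
                        rt_range = c(0, 12),
                        scan_range = c(50, 400),
                        seed = NULL) {
  if (is_tibble(contents) || is.data.frame(contents)) {
    contents <- setNames(contents$content, contents$compound)
  }
  stopifnot(is.numeric(contents))
  if (length(contents) > 0 && is.null(names(contents))) {
    abort("`contents` must be named by compound")
  }
  if (any(contents < 0)) abort("contents must be >= 0")
  if (any(recovery_factor < 0 | recovery_factor > 1)) {
    abort("`recovery_factor` must lie in [0, 1]")
  }
  if (any(response_factor <= 0)) abort("`response_factor` must be > 0")
  if (noise_level < 0) abort("`noise_level` must be >= 0")
  if (sample_mass <= 0) abort("`sample_mass` must be > 0")
  if (elution_volume <= 0) abort("`elution_volume` must be > 0")
  if (peak_sigma <= 0) abort("`peak_sigma` must be > 0")
  if (cycle_period <= 0) abort("`cycle_period` must be > 0")
  structure(list(
    contents = contents,
    response_factor = response_factor,
    intercept = intercept,
    recovery_factor = recovery_factor,
    peak_sigma = peak_sigma,
    noise_level = noise_level,
    sample_mass = sample_mass,
    elution_volume = elution_volume,
    cycle_period = cycle_period,
    rt_range = rt_range,
    scan_range = scan_range,
    seed = seed
  ), class = "ms_scenario")
}

per_compound <- function(x, compounds, default = NULL) {
  fallback <- if (!is.null(default)) default
              else if (length(x) > 0) x[[1]] else 0
  if (length(x) == 0 || is.null(names(x))) {
    val <- if (length(x) > 0) x[[1]] else fallback
    return(setNames(rep(val, length(compounds)), compounds))
  }
  out <- setNames(rep(fallback, length(compounds)), compounds)
  hit <- intersect(names(x), compounds)
  out[hit] <- x[hit]
  out
}

#' Peak height per unit area of a Gaussian elution peak
#'
#' For a Gaussian peak, height/area = \eqn{1 / (\sigma \sqrt{2\pi})}; this
#' is the conversion [estimate_lod_loq()] needs to translate a calibration
#' slope (area per concentration) into predicted peak height.
#'
#' @param peak_sigma Peak sigma in minutes.
#' @return Height per unit area, 1/min.
#' @export
height_per_area <- function(peak_sigma) {
  stopifnot(peak_sigma > 0)
  1 / (peak_sigma * sqrt(2 * pi))
}

gauss_trace <- function(rt, center, sigma, area) {
  amp <- area / (sigma * sqrt(2 * pi))
  amp * exp(-0.5 * ((rt - center) / sigma)^2)
}

add_noise <- function(x, noise_level) {
  if (noise_level <= 0) return(x)
  pmax(x + rnorm(length(x), 0, noise_level), 0)
}

run_seed <- function(seed) {
  if (is.null(seed)) sample.int(2^31 - 1, 1) else as.integer(seed)
}

#' Simulate one LC-MS injection
#'
#' Emulates a unit-resolution single-quadrupole acquisition: alternating
#' positive/negative full scans over the configured m/z range plus SIM
#' traces on the library channels. Each compound elutes as a Gaussian
#' centred at its library retention time; its ions are spread over the
#' nominal m/z bins according to the library adduct fingerprint, and the
#' SIM trace is scaled so the integrated area equals
#' `response_factor * extract_concentration`, with
#' `extract_concentration = content * recovery * sample_mass / elution_volume`.
#' I.i.d. Gaussian baseline noise (clipped at zero) is added when
#' `noise_level > 0`.
#'
#' Compounds sharing a SIM channel (same ion, polarity and window, e.g.
#' gigantol and its dimethoxybibenzyl isomer at m/z 297) appear in the same
#' trace as separate retention-time peaks, as they would on the instrument.
#'
#' @param scenario An [ms_scenario()].
#' @param library Compound library, see [phenol_library()].
#' @param full_scan Generate full-scan cycles (set `FALSE` for SIM-only
#'   simulations, e.g. large Monte-Carlo batches).
#' @param seed Overrides `scenario$seed`.
#' @return An object of class `ms_run`: a list with `full_scans` (long
#'   tibble `rt, polarity, mz, intensity`), `sim_traces` (long tibble
#'   `channel_mz, polarity, window_start, window_stop, rt, intensity`),
#'   `truth` (tibble of true contents, extract concentrations and areas)
#'   and `metadata`.
#' @export
simulate_run <- function(scenario, library = phenol_library(),
                         full_scan = TRUE, seed = scenario$seed) {
  stopifnot(inherits(scenario, "ms_scenario"))
  unknown <- setdiff(names(scenario$contents), library$compound)
  if (length(unknown) > 0) {
    abort(paste0("compound(s) not in library: ",
                 paste(unknown, collapse = ", ")),
          class = "phenolscreen_unknown_compound")
  }
  seed <- run_seed(seed)
  cmp <- library$compound
  content <- per_compound(scenario$contents, cmp, default = 0)
  rf <- per_compound(scenario$response_factor, cmp)
  rec <- per_compound(scenario$recovery_factor, cmp)
  conc <- content * rec * scenario$sample_mass / scenario$elution_volume
  area <- rf * conc
  sigma <- scenario$peak_sigma
  rt <- seq(scenario$rt_range[1], scenario$rt_range[2],
            by = scenario$cycle_period)

  truth <- tibble(
    compound = cmp, content = unname(content),
    recovery = unname(rec), extract_conc = unname(conc),
    true_area = unname(area), rt = library$rt
  )

  withr::with_seed(seed, {
    # SIM traces: one per distinct acquisition channel; every compound whose
    # channel ion this is contributes its own Gaussian
    channels <- distinct(library, .data$sim_mz, .data$sim_polarity,
                         .data$sim_start, .data$sim_stop)
    sim_traces <- pmap(
      list(channels$sim_mz, channels$sim_polarity,
           channels$sim_start, channels$sim_stop),
      function(mz, pol, lo, hi) {
        t <- rt[rt >= lo & rt <= hi]
        y <- rep(0, length(t))
        contrib <- library$sim_mz == mz & library$sim_polarity == pol &
          library$sim_start == lo & library$sim_stop == hi
        for (i in which(contrib)) {
          if (area[[library$compound[i]]] > 0) {
            y <- y + gauss_trace(t, library$rt[i], sigma,
                                 area[[library$compound[i]]])
          }
        }
        tibble(channel_mz = mz, polarity = pol, window_start = lo,
               window_stop = hi, rt = t,
               intensity = add_noise(y, scenario$noise_level))
      }
    ) %>% list_rbind()

    full_scans <- NULL
    if (full_scan) {
      sig <- pmap(
        list(library$compound, library$rt, library$ions),
        function(cp, crt, io) {
          a <- area[[cp]]
          if (a == 0) return(NULL)
          keep <- abs(rt - crt) <= 6 * sigma
          if (!any(keep)) return(NULL)
          t <- rt[keep]
          base_amp_trace <- gauss_trace(t, crt, sigma, a)
          pmap(list(io$mz, io$polarity, io$rel_abund),
               function(mz, pol, rel) {
                 tibble(rt = t, polarity = pol, mz = mz,
                        intensity = base_amp_trace * rel / 100)
               }) %>% list_rbind()
        }
      ) %>% list_rbind()
      if (!is.null(sig) && nrow(sig) > 0) {
        sig <- sig %>%
          group_by(.data$rt, .data$polarity, .data$mz) %>%
          summarise(intensity = sum(.data$intensity), .groups = "drop")
      }
      if (scenario$noise_level > 0) {
        bins <- seq(scenario$scan_range[1], scenario$scan_range[2])
        dense <- tidyr::expand_grid(rt = rt,
                                    polarity = c("positive", "negative"),
                                    mz = bins)
        if (!is.null(sig) && nrow(sig) > 0) {
          dense <- left_join(dense, sig,
                             by = c("rt", "polarity", "mz")) %>%
            mutate(intensity = ifelse(is.na(.data$intensity), 0,
                                      .data$intensity))
        } else {
          dense$intensity <- 0
        }
        dense$intensity <- add_noise(dense$intensity, scenario$noise_level)
        full_scans <- dense
      } else {
        full_scans <- if (is.null(sig)) {
          tibble(rt = numeric(), polarity = character(), mz = numeric(),
                 intensity = numeric())
        } else {
          sig
        }
      }
      full_scans <- arrange(full_scans, .data$rt, .data$polarity, .data$mz)
    }
  })

  structure(list(
    full_scans = full_scans,
    sim_traces = sim_traces,
    truth = truth,
    metadata = list(
      rt = rt, cycle_period = scenario$cycle_period,
      rt_range = scenario$rt_range, scan_range = scenario$scan_range,
      peak_sigma = sigma, noise_level = scenario$noise_level,
      sample_mass = scenario$sample_mass,
      elution_volume = scenario$elution_volume,
      seed = seed
    )
  ), class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  md <- x$metadata
  cat("<ms_run> ", length(md$rt), " cycles over ",
      md$rt_range[1], "-", md$rt_range[2], " min, scan range ",
      md$scan_range[1], "-", md$scan_range[2], " Da\n", sep = "")
  cat("  SIM channels: ",
      nrow(distinct(x$sim_traces, .data$channel_mz, .data$polarity)),
      "; full scans: ",
      if (is.null(x$full_scans)) "none" else
        paste0(nrow(x$full_scans), " points"),
      "\n", sep = "")
  invisible(x)
}

#' Simulate a calibration series
#'
#' One SIM-only run per concentration level per replicate for a single
#' standard, with true area `slope * level + intercept` where the slope is
#' the scenario's response factor for that compound. The standard series
#' spans 2-100 ug/mL at six levels injected in triplicate by default.
#'
#' @param compound Standard compound name.
#' @param levels Increasing positive concentrations, ug/mL.
#' @param scenario An [ms_scenario()]; its `response_factor` and
#'   `intercept` entries for `compound` define the true line.
#' @param n_replicates Injections per level.
#' @param library Compound library.
#' @param seed Overrides `scenario$seed`.
#' @return A tibble with one row per injection: `level`, `replicate`,
#'   `true_area` and a list-column `run` of `ms_run` objects.
#' @export
simulate_calibration_series <- function(compound,
                                        levels = c(2, 5, 10, 20, 50, 100),
                                        scenario = ms_scenario(),
                                        n_replicates = 3,
                                        library = phenol_library(),
                                        seed = scenario$seed) {
  if (length(levels) == 0) abort("`levels` must be non-empty")
  if (any(levels <= 0)) abort("`levels` must be positive")
  if (is.unsorted(levels, strictly = TRUE)) {
    abort("`levels` must be strictly increasing")
  }
  rec <- library_lookup(library, compound)
  slope <- per_compound(scenario$response_factor, rec$compound)[[1]]
  intercept <- per_compound(scenario$intercept, rec$compound,
                            default = 0)[[1]]
  seed <- run_seed(seed)
  grid <- tidyr::expand_grid(level = levels,
                             replicate = seq_len(n_replicates))
  grid$true_area <- slope * grid$level + intercept
  grid$run <- pmap(list(grid$level, grid$true_area, seq_len(nrow(grid))),
                   function(lvl, ta, k) {
    # back-compute a content giving exactly this area through simulate_run
    eff_conc <- max(ta, 0) / slope
    content <- eff_conc * scenario$elution_volume / scenario$sample_mass
    sc <- scenario
    sc$contents <- setNames(content, rec$compound)
    sc$recovery_factor <- 1
    simulate_run(sc, library, full_scan = FALSE, seed = seed + k)
  })
  grid
}

#' Simulate a fortified-sample (spike-recovery) batch
#'
#' Builds replicate spiked runs whose true content is
#' `endogenous + recovery_true * spike_level`, together with paired blank
#' (unspiked) runs at the endogenous level, the design used to validate
#' accuracy and precision (two fortification levels, five replicates each).
#'
#' @param endogenous Endogenous content, mg/kg: scalar or vector named by
#'   compound; `NA` is treated as 0.
#' @param spike_level Fortification level(s), mg/kg; one set of replicates
#'   is generated per level.
#' @param n_replicates Replicates per level (>= 2).
#' @param recovery_true True extraction recovery applied to the spike,
#'   scalar or named vector in (0, 1].
#' @param noise Baseline noise SD in counts, passed to the run simulator.
#' @param seed Integer seed.
#' @param scenario Base [ms_scenario()] providing response factors and
#'   sample constants.
#' @param compounds Compounds to fortify (default: every library compound).
#' @param library Compound library.
#' @return A list with `spiked` (tibble: `spike_level`, `replicate`,
#'   list-column `run`), `blanks` (tibble with list-column `run`) and
#'   `truth` (tibble of true spiked contents per compound and level).
#' @export
simulate_spiked_batch <- function(endogenous = 0,
                                  spike_level = c(50, 200),
                                  n_replicates = 5,
                                  recovery_true = 1,
                                  noise = 0,
                                  seed = NULL,
                                  scenario = ms_scenario(),
                                  compounds = NULL,
                                  library = phenol_library()) {
  if (any(spike_level <= 0)) {
    abort("`spike_level` must be > 0", class = "phenolscreen_bad_spike")
  }
  if (n_replicates < 2) abort("`n_replicates` must be >= 2")
  if (is.null(compounds)) compounds <- library$compound
  endo <- per_compound(endogenous, compounds, default = 0)
  endo[is.na(endo)] <- 0
  rec <- per_compound(recovery_true, compounds)
  seed <- run_seed(seed)
  sc <- scenario
  sc$noise_level <- noise
  sc$recovery_factor <- 1   # extraction loss is applied to the spike below

  truth <- tidyr::expand_grid(compound = compounds, level = spike_level) %>%
    mutate(endogenous = unname(endo[.data$compound]),
           recovery_true = unname(rec[.data$compound]),
           true_content = .data$endogenous +
             .data$recovery_true * .data$level)

  spiked <- tidyr::expand_grid(spike_level = spike_level,
                               replicate = seq_len(n_replicates))
  spiked$run <- pmap(list(spiked$spike_level, seq_len(nrow(spiked))),
                     function(lvl, k) {
    sck <- sc
    sck$contents <- setNames(endo + rec * lvl, compounds)
    simulate_run(sck, library, full_scan = FALSE, seed = seed + 1000L + k)
  })

  blanks <- tibble(replicate = seq_len(n_replicates))
  blanks$run <- map(seq_len(n_replicates), function(k) {
    scb <- sc
    scb$contents <- setNames(endo, compounds)
    simulate_run(scb, library, full_scan = FALSE, seed = seed + 2000L + k)
  })

  list(spiked = spiked, blanks = blanks, truth = truth)
}
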