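#' Spike recovery in percent
#'
#' `100 * (mean_spiked - endogenous) / added`: the fraction of the known
#' fortification recovered through the whole procedure.
#'
#' @param mean_spiked Mean measured content of the spiked replicates,
#'   mg/kg (>= 0).
#' @param endogenous Endogenous (blank) content, mg/kg; `NA` counts as 0.
#' @param added Fortification level, mg/kg (> 0).
#' @return Recovery, percent.
#' @examples
#' recovery_pct(60.6, 12.7, 50)  # 95.8
#' @export
recovery_pct <- function(mean_spiked, endogenous, added) {
  if (any(added <= 0)) abort("`added` must be > 0")
  endogenous[is.na(endogenous)] <- 0
  100 * (mean_spiked - endogenous) / added
}

#' Relative standard deviation in percent
#'
#' `100 * sd(values) / mean(values)` with the sample (n-1) standard
#' deviation, the repeatability measure of analytical chemistry.
#'
#' @param values At least two numeric values with non-zero mean.
#' @return RSD, percent.
#' @examples
#' rsd_pct(c(90, 100, 110))  # 10
#' @export
rsd_pct <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("need at least 2 values")
  m <- mean(values)
  if (m == 0) abort("mean of `values` is zero")
  100 * sd(values) / m
}

#' Configuration bundle for the measurement pipeline
#'
#' Collects everything needed to turn a raw run into per-compound
#' contents: the calibration models (named by standard compound), the
#' library, the sample-preparation constants and the peak-processing
#' settings.
#'
#' @param calibrations Named list of `phenol_calibration` models, one per
#'   standard compound.
#' @param library Compound library.
#' @param sample_mass,elution_volume Sample-preparation constants.
#' @param min_snr,min_width Peak detection settings for SIM traces.
#' @param rt_assign_tol Maximum apex distance (min) from the library RT
#'   when assigning a SIM peak to a compound.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(calibrations, library = phenol_library(),
                            sample_mass = 0.5, elution_volume = 10,
                            min_snr = 3, min_width = 0.02,
                            rt_assign_tol = 0.15) {
  structure(list(
    calibrations = calibrations, library = library,
    sample_mass = sample_mass, elution_volume = elution_volume,
    min_snr = min_snr, min_width = min_width,
    rt_assign_tol = rt_assign_tol
  ), class = "pipeline_config")
}

#' Measure per-compound contents in one run
#'
#' The quantification leg of the pipeline: for every library compound,
#' take its SIM trace, detect peaks, pick the peak whose apex is nearest
#' the library retention time (within the assignment tolerance), integrate
#' it and invert the compound's own or surrogate calibration. A compound
#' with no assignable peak is reported below LOQ with missing content.
#'
#' @param run An `ms_run`.
#' @param config A [pipeline_config()].
#' @return A tibble with one row per library compound (the columns of
#'   [quantify()]).
#' @export
measure_contents <- function(run, config) {
  stopifnot(inherits(config, "pipeline_config"))
  lib <- config$library
  map(seq_len(nrow(lib)), function(k) {
    cmp <- lib$compound[k]
    std <- lib$surrogate[k]
    model <- config$calibrations[[std]]
    if (is.null(model)) {
      abort(paste0("missing calibration for surrogate standard '", std,
                   "' (required by compound '", cmp, "')"),
            class = "phenolscreen_missing_calibration")
    }
    trace <- extract_sim(run, lib$sim_mz[k], lib$sim_polarity[k])
    peaks <- detect_peaks(trace, min_snr = config$min_snr,
                          min_width = config$min_width)
    if (nrow(peaks) > 0) {
      d <- abs(peaks$apex_rt - lib$rt[k])
      peaks <- peaks[d <= config$rt_assign_tol, ]
      d <- d[d <= config$rt_assign_tol]
    }
    if (nrow(peaks) == 0) {
      out <- quantify(NA_real_, model, compound = cmp,
                      sample_mass = config$sample_mass,
                      elution_volume = config$elution_volume)
    } else {
      pk <- peaks[which.min(d), ]
      out <- quantify(pk$area, model, compound = cmp,
                      sample_mass = config$sample_mass,
                      elution_volume = config$elution_volume)
    }
    out
  }) %>% list_rbind()
}

#' Validate a fortified-sample batch
#'
#' Runs the full detect-integrate-quantify pipeline on every spiked and
#' blank run, subtracts the mean blank (endogenous) content — below-LOQ
#' blanks count as zero — and reports recovery and RSD per compound and
#' fortification level.
#'
#' @param spiked_runs Tibble with columns `spike_level`, `replicate` and a
#'   list-column `run` (as produced by [simulate_spiked_batch()]).
#' @param blank_runs Tibble with a list-column `run` of blank injections.
#' @param config A [pipeline_config()].
#' @return A tibble with one row per (compound, spike level):
#'   `compound`, `spike_level`, `endogenous`, `n`, `mean_spiked`,
#'   `recovery_pct`, `rsd_pct` and the list-column `replicate_contents`.
#' @export
validate_batch <- function(spiked_runs, blank_runs, config) {
  if (is.null(blank_runs) || nrow(blank_runs) == 0) {
    abort("blank runs are required", class = "phenolscreen_missing_blanks")
  }
  counts <- spiked_runs %>% group_by(.data$spike_level) %>%
    summarise(n = n(), .groups = "drop")
  if (any(counts$n < 2)) {
    abort("need at least 2 replicates per spike level")
  }
  blank_contents <- map(blank_runs$run, measure_contents, config) %>%
    list_rbind() %>%
    group_by(.data$compound) %>%
    summarise(endogenous = {
      v <- .data$content
      v[is.na(v)] <- 0
      mean(v)
    }, .groups = "drop")

  spiked_contents <- pmap(
    list(spiked_runs$run, spiked_runs$spike_level, spiked_runs$replicate),
    function(r, lvl, rep) {
      measure_contents(r, config) %>%
        mutate(spike_level = lvl, replicate = rep)
    }
  ) %>% list_rbind()

  spiked_contents %>%
    mutate(content_filled = ifelse(is.na(.data$content), 0,
                                   .data$content)) %>%
    group_by(.data$compound, .data$spike_level) %>%
    summarise(
      n = n(),
      mean_spiked = mean(.data$content_filled),
      rsd_pct = if (mean(.data$content_filled) > 0) {
        rsd_pct(.data$content_filled)
      } else NA_real_,
      replicate_contents = list(.data$content_filled),
      .groups = "drop"
    ) %>%
    # compounds with no signal anywhere in the batch were not fortified
    filter(.data$mean_spiked > 0) %>%
    left_join(blank_contents, by = "compound") %>%
    mutate(recovery_pct = recovery_pct(.data$mean_spiked,
                                       .data$endogenous,
                                       .data$spike_level)) %>%
    select("compound", "spike_level", "endogenous", "n", "mean_spiked",
           "recovery_pct", "rsd_pct", "replicate_contents") %>%
    arrange(.data$compound, .data$spike_level)
}
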