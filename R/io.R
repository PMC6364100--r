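#' Write / read a raw run as plain CSV
#'
#' Long-format serialization of a run: one row per stored intensity, with
#' a `section` column separating full-scan bins from SIM trace points and
#' the acquisition metadata in commented header lines. The round trip
#' restores bins and traces exactly.
#'
#' @param run An `ms_run`.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  md <- run$metadata
  hdr <- c(
    sprintf("# phenolscreen ms_run v1"),
    sprintf("# rt_range: %.10g %.10g", md$rt_range[1], md$rt_range[2]),
    sprintf("# cycle_period: %.10g", md$cycle_period),
    sprintf("# scan_range: %.10g %.10g", md$scan_range[1],
            md$scan_range[2]),
    sprintf("# peak_sigma: %.10g", md$peak_sigma),
    sprintf("# noise_level: %.10g", md$noise_level),
    sprintf("# sample_mass: %.10g", md$sample_mass),
    sprintf("# elution_volume: %.10g", md$elution_volume),
    sprintf("# seed: %d", md$seed)
  )
  fs <- run$full_scans
  rows <- list()
  if (!is.null(fs) && nrow(fs) > 0) {
    rows$fs <- fs %>% mutate(section = "full_scan",
                             window_start = NA_real_,
                             window_stop = NA_real_,
                             channel_mz = NA_real_)
  }
  st <- run$sim_traces
  if (nrow(st) > 0) {
    rows$sim <- st %>% mutate(section = "sim", mz = NA_real_)
  }
  body <- bind_rows(rows) %>%
    select("section", "rt", "polarity", "mz", "intensity",
           "channel_mz", "window_start", "window_stop")
  writeLines(hdr, path)
  readr::write_csv(body, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_kv_header <- function(path) {
  lines <- readLines(path, n = 20)
  lines <- lines[startsWith(lines, "# ")]
  kv <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(sub("^# ", "", ln), ": ", fixed = TRUE)[[1]]
    kv[[parts[1]]] <- as.numeric(strsplit(parts[2], " ")[[1]])
  }
  kv
}

#' @rdname write_run_csv
#' @return For `read_run_csv`, the reconstructed `ms_run` (without ground
#'   truth, which is simulation metadata, not part of the raw data).
#' @export
read_run_csv <- function(path) {
  kv <- read_kv_header(path)
  body <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  fs <- body %>% filter(.data$section == "full_scan") %>%
    select("rt", "polarity", "mz", "intensity")
  st <- body %>% filter(.data$section == "sim") %>%
    select("channel_mz", "polarity", "window_start", "window_stop",
           "rt", "intensity")
  rt <- seq(kv$rt_range[1], kv$rt_range[2], by = kv$cycle_period)
  structure(list(
    full_scans = if (nrow(fs) > 0) fs else NULL,
    sim_traces = st,
    truth = NULL,
    metadata = list(
      rt = rt, cycle_period = kv$cycle_period, rt_range = kv$rt_range,
      scan_range = kv$scan_range, peak_sigma = kv$peak_sigma,
      noise_level = kv$noise_level, sample_mass = kv$sample_mass,
      elution_volume = kv$elution_volume, seed = as.integer(kv$seed)
    )
  ), class = "ms_run")
}

#' Write / read full scans as mzML
#'
#' Exports the run's full-scan cycles as a centroided mzML file with one
#' spectrum per cycle and polarity, via Bioconductor's mzR. SIM traces and
#' metadata are not part of mzML level-1 spectra; use [write_run_csv()]
#' for a complete round trip.
#'
#' @param run An `ms_run` with full scans.
#' @param path Output mzML file.
#' @return `path`, invisibly.
#' @export
write_run_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("mzML export needs the mzR package")
  }
  stopifnot(inherits(run, "ms_run"))
  if (is.null(run$full_scans)) abort("run has no full scans")
  fs <- run$full_scans
  grid <- run$metadata$rt
  scans <- tidyr::expand_grid(rt = grid,
                              polarity = c("positive", "negative"))
  pk <- pmap(list(scans$rt, scans$polarity), function(t, pol) {
    sel <- fs[fs$rt == t & fs$polarity == pol, ]
    if (nrow(sel) == 0) {
      cbind(mz = numeric(), intensity = numeric())
    } else {
      cbind(mz = sel$mz, intensity = sel$intensity)
    }
  })
  n <- nrow(scans)
  sr <- run$metadata$scan_range
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = ifelse(scans$polarity == "positive", 1L, 0L),
    peaksCount = vapply(pk, nrow, integer(1)),
    totIonCurrent = vapply(pk, function(m) sum(m[, 2]), numeric(1)),
    retentionTime = scans$rt * 60,
    basePeakMZ = vapply(pk, function(m)
      if (nrow(m) > 0) m[which.max(m[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(m)
      if (nrow(m) > 0) max(m[, 2]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = sr[1], highMZ = sr[2],
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = sr[1], scanWindowUpperLimit = sr[2],
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' @rdname write_run_mzml
#' @return For `read_run_mzml`, a long tibble
#'   `(rt, polarity, mz, intensity)` of the spectra in the file.
#' @export
read_run_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("mzML import needs the mzR package")
  }
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  h <- mzR::header(f)
  pk <- mzR::peaks(f)
  if (is.matrix(pk)) pk <- list(pk)
  map(seq_len(nrow(h)), function(i) {
    m <- pk[[i]]
    if (nrow(m) == 0) return(NULL)
    tibble(rt = h$retentionTime[i] / 60,
           polarity = ifelse(h$polarity[i] == 1, "positive", "negative"),
           mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]))
  }) %>% list_rbind()
}

#' Write / read a chromatogram as CSV
#'
#' Two columns (`rt`, `intensity`) with the channel descriptor in a
#' commented header line.
#'
#' @param chrom Chromatogram tibble.
#' @param path CSV file.
#' @return `path` invisibly; for the reader, the chromatogram.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  check_chromatogram(chrom)
  ch <- attr(chrom, "channel")
  desc <- if (is.null(ch)) "unknown" else {
    paste(names(ch), vapply(ch, function(v)
      paste(format(v), collapse = " "), character(1)),
      sep = "=", collapse = "; ")
  }
  writeLines(paste0("# channel: ", desc), path)
  readr::write_csv(tibble(rt = chrom$rt, intensity = chrom$intensity),
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_chromatogram_csv
#' @export
read_chromatogram_csv <- function(path) {
  first <- readLines(path, n = 1)
  body <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  out <- new_chromatogram(body$rt, body$intensity,
                          list(descriptor = sub("^# channel: ", "", first)))
  out
}

#' Write / read a scenario as a flat YAML config
#'
#' @param scenario An [ms_scenario()].
#' @param path YAML file.
#' @return `path` invisibly; for the reader, the scenario.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "ms_scenario"))
  out <- unclass(scenario)
  # yaml drops names on named atomic vectors; store them as maps
  for (f in c("contents", "response_factor", "intercept",
              "recovery_factor")) {
    if (!is.null(names(out[[f]]))) out[[f]] <- as.list(out[[f]])
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("contents", "response_factor", "intercept",
              "recovery_factor")) {
    if (!is.null(raw[[f]]) && is.list(raw[[f]])) {
      raw[[f]] <- unlist(raw[[f]])
    }
  }
  do.call(ms_scenario, raw)
}

#' Write ground truth to CSV
#'
#' @param run A simulated `ms_run` (with a `truth` element).
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  if (is.null(run$truth)) abort("run carries no ground truth")
  readr::write_csv(run$truth, path)
  invisible(path)
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "phenolscreen")
  if (path == "") abort(paste0("packaged file not found: ", file))
  path
}

#' Reference method parameters
#'
#' Packaged constants of the published determination: the calibration
#' equations, determination coefficients, LOD/LOQ and linear ranges of the
#' nine standards (`phenol_calibration_reference()`); the fortified-sample
#' recovery/RSD design values at the 50 and 200 mg/kg spike levels
#' (`phenol_recovery_reference()`); and the reported per-sample contents
#' of the four Dendrobium chrysotoxum samples
#' (`dendrobium_sample_contents()`, wide: one row per sample, one column
#' per compound, `NA` where the compound was not found).
#'
#' @return A tibble.
#' @export
phenol_calibration_reference <- function() {
  readr::read_csv(extdata("calibration_reference.csv"),
                  show_col_types = FALSE)
}

#' @rdname phenol_calibration_reference
#' @export
phenol_recovery_reference <- function() {
  readr::read_csv(extdata("recovery_reference.csv"),
                  show_col_types = FALSE)
}

#' @rdname phenol_calibration_reference
#' @export
dendrobium_sample_contents <- function() {
  readr::read_csv(extdata("dendrobium_sample_contents.csv"),
                  show_col_types = FALSE)
}
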