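#' Average full-scan spectrum across a peak
#'
#' Bin-wise mean intensity over the scan cycles falling inside an RT
#' window, background-subtracted using the bin-wise mean of flanking blank
#' cycles (a few cycles immediately before and after the window); negative
#' results are clipped to zero.
#'
#' @param run An `ms_run` with full scans.
#' @param rt_window `c(lo, hi)` in minutes; must contain at least one cycle.
#' @param polarity `"positive"` or `"negative"`.
#' @param flank Number of flanking cycles on each side used for the
#'   background estimate (0 disables subtraction).
#' @return A tibble `(mz, intensity)` of non-zero bins, with the polarity
#'   and window stored in attributes.
#' @export
average_spectrum <- function(run, rt_window, polarity = "positive",
                             flank = 5) {
  stopifnot(inherits(run, "ms_run"))
  if (is.null(run$full_scans)) abort("run has no full scans")
  grid <- run$metadata$rt
  inside <- grid[grid >= rt_window[1] & grid <= rt_window[2]]
  if (length(inside) == 0) {
    abort("rt window contains no scan cycle",
          class = "phenolscreen_empty_window")
  }
  fs <- run$full_scans[run$full_scans$polarity == polarity, ]
  mean_bins <- function(cycles) {
    sel <- fs[fs$rt %in% cycles, ]
    if (nrow(sel) == 0) {
      return(tibble(mz = numeric(), intensity = numeric()))
    }
    sel %>% group_by(.data$mz) %>%
      summarise(intensity = sum(.data$intensity) / length(cycles),
                .groups = "drop")
  }
  avg <- mean_bins(inside)
  if (flank > 0) {
    before <- tail(grid[grid < rt_window[1]], flank)
    after <- head(grid[grid > rt_window[2]], flank)
    fl <- c(before, after)
    if (length(fl) > 0) {
      bg <- mean_bins(fl)
      avg <- dplyr::full_join(avg, bg, by = "mz",
                              suffix = c("", "_bg")) %>%
        mutate(
          intensity = tidyr::replace_na(.data$intensity, 0) -
            tidyr::replace_na(.data$intensity_bg, 0)
        ) %>%
        select("mz", "intensity")
    }
  }
  out <- avg %>% filter(.data$intensity > 0) %>% arrange(.data$mz)
  attr(out, "polarity") <- polarity
  attr(out, "rt_window") <- rt_window
  out
}

#' Build an adduct fingerprint from paired polarity spectra
#'
#' The base peak is the most intense positive bin, or the most intense
#' negative bin when the positive spectrum is empty (the flavone case).
#' Ions of the base-peak polarity with relative abundance of at least
#' `min_rel_abund` percent are retained, expressed as percent of the base
#' peak. Polarity flags record whether each spectrum's maximum exceeds the
#' detection threshold.
#'
#' @param spec_pos,spec_neg Tibbles `(mz, intensity)` from
#'   [average_spectrum()]; either may be empty (but not both).
#' @param min_rel_abund Minimum relative abundance retained, percent.
#' @param detection_threshold Intensity above which a polarity counts as
#'   giving a signal.
#' @param rt Apex retention time carried along for identification.
#' @return An object of class `adduct_fingerprint`.
#' @export
build_fingerprint <- function(spec_pos, spec_neg, min_rel_abund = 10,
                              detection_threshold = 0, rt = NA_real_) {
  pos_max <- if (nrow(spec_pos) > 0) max(spec_pos$intensity) else 0
  neg_max <- if (nrow(spec_neg) > 0) max(spec_neg$intensity) else 0
  if (pos_max <= detection_threshold && neg_max <= detection_threshold) {
    abort("both spectra are empty", class = "phenolscreen_empty_spectra")
  }
  has_pos <- pos_max > detection_threshold
  has_neg <- neg_max > detection_threshold
  base_pol <- if (has_pos) "positive" else "negative"
  base_spec <- if (base_pol == "positive") spec_pos else spec_neg
  base_max <- max(base_spec$intensity)
  base_mz <- base_spec$mz[which.max(base_spec$intensity)]
  ions <- base_spec %>%
    mutate(rel_abund = 100 * .data$intensity / base_max) %>%
    # pin the base ion to exactly 100 (floating division may fall short)
    mutate(rel_abund = ifelse(.data$intensity == base_max, 100,
                              .data$rel_abund)) %>%
    filter(.data$rel_abund >= min_rel_abund) %>%
    select("mz", "rel_abund") %>%
    arrange(.data$mz)
  structure(list(
    base_peak_mz = base_mz,
    base_polarity = base_pol,
    ions = ions,
    has_positive_signal = has_pos,
    has_negative_signal = has_neg,
    pos_max = pos_max,
    neg_max = neg_max,
    pos_base_mz = if (has_pos) spec_pos$mz[which.max(spec_pos$intensity)]
                  else NA_real_,
    neg_base_mz = if (has_neg) spec_neg$mz[which.max(spec_neg$intensity)]
                  else NA_real_,
    rt = rt
  ), class = "adduct_fingerprint")
}

#' @export
print.adduct_fingerprint <- function(x, ...) {
  cat("<adduct_fingerprint> base m/z ", x$base_peak_mz, " (",
      x$base_polarity, "), rt ", round(x$rt, 2), " min\n", sep = "")
  cat("  ions: ",
      paste0(x$ions$mz, " (", round(x$ions$rel_abund), "%)",
             collapse = ", "), "\n", sep = "")
  cat("  signal: positive=", x$has_positive_signal,
      ", negative=", x$has_negative_signal, "\n", sep = "")
  invisible(x)
}

#' Classify a fingerprint into a phenol family and infer molecular weight
#'
#' Decision rules, applied in order, built on how each family ionises on
#' the unit-resolution detector:
#'
#' 1. **Bibenzyl** — a positive-ion pair 22 Da apart (the sodium adduct
#'    \eqn{[M+Na]^+} and protonated \eqn{[M+H]^+} ions). When the sodium
#'    adduct is the base peak, the protonated ion must confirm with a
#'    relative abundance in 20--80%; when the protonated ion is the base
#'    peak (the chrysotoxin pattern), the sodium adduct must be present at
#'    20% or more. MW = (lower-pair ion) - 1. A bibenzyl without hydroxyl
#'    groups (chrysotobibenzyl) shows no negative-mode signal; the rule
#'    does not require one.
#' 2. **Flavone** — negative-mode signal strictly stronger than positive;
#'    MW = (negative base peak) + 1.
#' 3. **Positive-only, no 22-Da pair** — two ions with a 28- or 32-Da
#'    neutral-loss spacing: phenanthrene, MW = base - 1; a single ion:
#'    coumarin-like, MW = base - 1.
#'
#' Anything else is `unknown` (no MW). Classification depends only on
#' relative abundances and polarity comparisons, so it is invariant to
#' uniform intensity scaling.
#'
#' @param fp An `adduct_fingerprint`.
#' @return A one-row tibble `(family, inferred_mw, evidence)`.
#' @export
classify_family <- function(fp) {
  stopifnot(inherits(fp, "adduct_fingerprint"))
  call <- function(family, mw, evidence) {
    tibble(family = family, inferred_mw = mw, evidence = evidence)
  }
  ions <- fp$ions
  # rule 1: sodium-adduct pair
  if (fp$base_polarity == "positive" && nrow(ions) >= 2) {
    for (k in seq_len(nrow(ions))) {
      m <- ions$mz[k]
      up <- which(ions$mz == m + 22)
      if (length(up) == 1) {
        lower_rel <- ions$rel_abund[k]
        upper_rel <- ions$rel_abund[up]
        if (upper_rel >= 100 - 1e-6 && lower_rel >= 20 && lower_rel <= 80) {
          return(call("bibenzyl", m - 1, "na_adduct_base_pair"))
        }
        if (lower_rel >= 100 - 1e-6 && upper_rel >= 20) {
          return(call("bibenzyl", m - 1, "protonated_base_na_adduct"))
        }
      }
    }
  }
  # rule 2: negative mode dominates
  if (fp$has_negative_signal && fp$neg_max > fp$pos_max) {
    return(call("flavone", fp$neg_base_mz + 1, "negative_dominant"))
  }
  # rule 3: positive-only patterns
  if (fp$base_polarity == "positive" && !fp$has_negative_signal) {
    if (nrow(ions) == 2) {
      spacing <- abs(diff(ions$mz))
      if (spacing %in% c(28, 32)) {
        return(call("phenanthrene", fp$base_peak_mz - 1,
                    paste0("neutral_loss_", spacing)))
      }
    }
    if (nrow(ions) == 1) {
      return(call("coumarin", fp$base_peak_mz - 1, "single_protonated_ion"))
    }
  }
  call("unknown", NA_real_, "no_rule_fired")
}

family_surrogate <- function(family, mw) {
  switch(family,
    bibenzyl = if (!is.na(mw) && mw == 274) "gigantol" else "erianin",
    flavone = "naringenin",
    phenanthrene = "moscatin",
    coumarin = "coumarin",
    NA_character_
  )
}

#' Identify a screened peak against the compound library
#'
#' A peak matches a reference standard when its apex RT is within `rt_tol`
#' of the standard's RT *and* its fingerprint base peak is within `mz_tol`
#' of the standard's base ion. Otherwise, a peak with a classified family
#' is a newly elucidated compound: it is assigned the family's surrogate
#' standard (bibenzyls: erianin, or gigantol for MW 274; flavones:
#' naringenin; phenanthrenes: moscatin; coumarins: coumarin) and a SIM
#' ion — for bibenzyls the sodium adduct (MW + 23) even when it is not the
#' base peak, otherwise the most intense fingerprint ion. Unclassifiable
#' peaks are `unidentified`.
#'
#' @param peak One-row peak tibble (needs `apex_rt`).
#' @param fp The peak's `adduct_fingerprint`.
#' @param call Family call from [classify_family()].
#' @param library Compound library.
#' @param rt_tol RT match tolerance, minutes.
#' @param mz_tol m/z match tolerance, Da.
#' @return A one-row tibble `(compound, status, matched_rt, family,
#'   inferred_mw, surrogate_standard, sim_ion, sim_polarity)`.
#' @export
identify_compound <- function(peak, fp, call, library = phenol_library(),
                              rt_tol = 0.1, mz_tol = 0.5) {
  if (nrow(library) == 0) abort("`library` is empty")
  std <- library[library$is_standard, ]
  d_rt <- abs(std$rt - peak$apex_rt[1])
  d_mz <- abs(std$base_mz - fp$base_peak_mz)
  hit <- which(d_rt <= rt_tol & d_mz <= mz_tol)
  if (length(hit) > 0) {
    best <- hit[which.min(d_rt[hit])]
    return(tibble(
      compound = std$compound[best], status = "known_standard",
      matched_rt = std$rt[best], family = std$family[best],
      inferred_mw = call$inferred_mw,
      surrogate_standard = std$compound[best],
      sim_ion = std$sim_mz[best], sim_polarity = std$sim_polarity[best]
    ))
  }
  if (call$family != "unknown") {
    surrogate <- family_surrogate(call$family, call$inferred_mw)
    if (call$family == "bibenzyl" &&
        (call$inferred_mw + 23) %in% fp$ions$mz) {
      sim_ion <- call$inferred_mw + 23
    } else {
      sim_ion <- fp$ions$mz[which.max(fp$ions$rel_abund)]
    }
    return(tibble(
      compound = "unknown", status = "newly_elucidated",
      matched_rt = NA_real_, family = call$family,
      inferred_mw = call$inferred_mw,
      surrogate_standard = surrogate,
      sim_ion = sim_ion, sim_polarity = fp$base_polarity
    ))
  }
  tibble(
    compound = "unknown", status = "unidentified", matched_rt = NA_real_,
    family = "unknown", inferred_mw = NA_real_,
    surrogate_standard = NA_character_, sim_ion = NA_real_,
    sim_polarity = NA_character_
  )
}

#' Screen a full-scan run for phenol peaks
#'
#' Runs the screening workflow: detect peaks on the combined total-ion
#' chromatogram, average the positive and negative spectra across each
#' peak, build the adduct fingerprint, classify the family, infer the
#' molecular weight and identify the compound (known standard, newly
#' elucidated with surrogate assignment, or unidentified).
#'
#' @param run An `ms_run` with full scans.
#' @param library Compound library.
#' @param min_snr,min_width Peak detection settings for the TIC.
#' @param min_rel_abund Fingerprint abundance cut-off, percent.
#' @param rt_tol,mz_tol Identification tolerances.
#' @param detection_threshold Spectrum intensity above which a polarity
#'   counts as giving a signal (raise above the noise floor on noisy runs).
#' @return The screening report: one tibble row per detected peak with the
#'   fingerprint summary, family call and identification.
#' @export
screen_run <- function(run, library = phenol_library(), min_snr = 5,
                       min_width = 0.02, min_rel_abund = 10,
                       rt_tol = 0.1, mz_tol = 0.5,
                       detection_threshold = 0) {
  tic <- extract_tic(run, "both")
  peaks <- detect_peaks(tic, min_snr = min_snr, min_width = min_width)
  if (nrow(peaks) == 0) {
    return(tibble(
      apex_rt = numeric(), base_peak_mz = numeric(), ions = character(),
      has_positive_signal = logical(), has_negative_signal = logical(),
      family = character(), inferred_mw = numeric(), compound = character(),
      status = character(), surrogate_standard = character(),
      sim_ion = numeric(), sim_polarity = character()
    ))
  }
  map(seq_len(nrow(peaks)), function(k) {
    pk <- peaks[k, ]
    win <- c(pk$start_rt, pk$end_rt)
    sp <- average_spectrum(run, win, "positive")
    sn <- average_spectrum(run, win, "negative")
    fp <- build_fingerprint(sp, sn, min_rel_abund = min_rel_abund,
                            detection_threshold = detection_threshold,
                            rt = pk$apex_rt)
    fc <- classify_family(fp)
    id <- identify_compound(pk, fp, fc, library, rt_tol, mz_tol)
    tibble(
      apex_rt = pk$apex_rt,
      base_peak_mz = fp$base_peak_mz,
      ions = paste0(fp$ions$mz, " (", round(fp$ions$rel_abund), "%)",
                    collapse = "; "),
      has_positive_signal = fp$has_positive_signal,
      has_negative_signal = fp$has_negative_signal,
      family = id$family,
      inferred_mw = fc$inferred_mw,
      compound = id$compound,
      status = id$status,
      surrogate_standard = id$surrogate_standard,
      sim_ion = id$sim_ion,
      sim_polarity = id$sim_polarity
    )
  }) %>% list_rbind()
}
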