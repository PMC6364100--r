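#' Built-in library of the twelve Dendrobium phenols
#'
#' Returns the packaged compound library used throughout the pipeline: the
#' nine phenol reference standards (gigantol, erianin, chrysotobibenzyl,
#' tristin, moscatin, confusarin, coumarin, naringenin, apigenin) plus the
#' three compounds elucidated from full-scan screening without a standard
#' (3,4-dihydroxy-4',5-dimethoxybibenzyl, moscatilin, chrysotoxin), which are
#' quantified against a family surrogate standard.
#'
#' Each record carries the compound family, nominal molecular weight, the
#' adduct fingerprint observed on a unit-resolution single quadrupole
#' (`ions`: m/z, polarity and relative abundance as percent of the base
#' peak), the retention time, the SIM acquisition channel (ion, polarity,
#' time window) and the quantification standard. Adduct m/z values are
#' nominal: \eqn{[M+H]^+ = M+1}, \eqn{[M+Na]^+ = M+23}, \eqn{[M-H]^- = M-1}.
#'
#' Bibenzyls ionise preferentially as the sodium adduct with a confirming
#' protonated ion 22 Da below; all except chrysotobibenzyl (which lacks a
#' free hydroxyl) also give a weaker deprotonated signal in negative mode.
#' Phenanthrenes and coumarin are positive-only; flavones are detected in
#' negative mode only. Chrysotoxin is the one bibenzyl whose protonated ion
#' is the base peak (sodium adduct at 83%); its SIM channel still uses the
#' sodium adduct, the family convention.
#'
#' @return A tibble with one row per compound and columns `compound`, `code`,
#'   `full_name`, `family`, `mw`, `rt` (min), `sim_mz`, `sim_polarity`,
#'   `sim_start`, `sim_stop` (min), `is_standard`, `surrogate`, `base_mz`,
#'   `neg_rel` (relative abundance of the negative-mode molecular ion, 0 if
#'   absent) and a list-column `ions` of tibbles `(mz, polarity, rel_abund)`.
#' @examples
#' lib <- phenol_library()
#' lib[lib$compound == "moscatilin", c("mw", "sim_mz", "surrogate")]
#' @export
phenol_library <- function() {
  ion <- function(...) {
    rows <- list(...)
    tibble(
      mz = map_dbl(rows, 1),
      polarity = map_chr(rows, 2),
      rel_abund = map_dbl(rows, 3)
    )
  }
  lib <- tibble(
    compound = c(
      "gigantol", "erianin", "chrysotobibenzyl", "tristin", "moscatin",
      "confusarin", "coumarin", "naringenin", "apigenin", "ddb",
      "moscatilin", "chrysotoxin"
    ),
    code = c(
      "GI", "ER", "CHB", "TR", "MON", "COF", "COM", "NAR", "AP", "DDB",
      "MOL", "CHT"
    ),
    full_name = c(
      "gigantol", "erianin", "chrysotobibenzyl", "tristin", "moscatin",
      "confusarin", "coumarin", "naringenin", "apigenin",
      "3,4-dihydroxy-4',5-dimethoxybibenzyl", "moscatilin", "chrysotoxin"
    ),
    family = c(
      "bibenzyl", "bibenzyl", "bibenzyl", "bibenzyl", "phenanthrene",
      "phenanthrene", "coumarin", "flavone", "flavone", "bibenzyl",
      "bibenzyl", "bibenzyl"
    ),
    mw = c(274, 318, 332, 260, 240, 300, 146, 272, 270, 274, 304, 318),
    rt = c(5.59, 7.12, 1.85, 2.90, 4.12, 5.41, 1.79, 4.39, 5.89,
           6.97, 5.62, 6.84),
    sim_mz = c(297, 341, 355, 283, 241, 301, 147, 271, 269, 297, 327, 341),
    sim_polarity = c(
      "positive", "positive", "positive", "positive", "positive",
      "positive", "positive", "negative", "negative", "positive",
      "positive", "positive"
    ),
    sim_start = c(3, 6, 0.5, 2, 3, 4, 0.5, 3, 4.5, 3, 4, 6),
    sim_stop = c(8, 9.5, 3, 4, 7, 7, 3, 6, 9, 8, 8, 9.5),
    is_standard = c(rep(TRUE, 9), FALSE, FALSE, FALSE),
    surrogate = c(
      "gigantol", "erianin", "chrysotobibenzyl", "tristin", "moscatin",
      "confusarin", "coumarin", "naringenin", "apigenin", "gigantol",
      "erianin", "erianin"
    ),
    ions = list(
      ion(list(297, "positive", 100), list(275, "positive", 52)),
      ion(list(341, "positive", 100), list(319, "positive", 48)),
      ion(list(355, "positive", 100), list(333, "positive", 35)),
      ion(list(283, "positive", 100), list(261, "positive", 46)),
      ion(list(241, "positive", 100), list(213, "positive", 62)),
      ion(list(301, "positive", 100), list(269, "positive", 48)),
      ion(list(147, "positive", 100)),
      ion(list(271, "negative", 100)),
      ion(list(269, "negative", 100)),
      ion(list(297, "positive", 100), list(275, "positive", 50)),
      ion(list(327, "positive", 100), list(305, "positive", 49)),
      # protonated ion is the base peak for chrysotoxin; Na adduct at 83%
      ion(list(319, "positive", 100), list(341, "positive", 83))
    ),
    # relative abundance (% of positive base) of [M-H]- for compounds with
    # a negative-mode signal; hydroxyl-free chrysotobibenzyl gives none
    neg_rel = c(30, 30, 0, 30, 0, 0, 0, 100, 100, 30, 30, 30)
  )
  lib$ions <- pmap(list(lib$ions, lib$mw, lib$neg_rel), function(io, mw, nr) {
    if (nr > 0 && !any(io$polarity == "negative")) {
      io <- bind_rows(io, tibble(
        mz = mw - 1, polarity = "negative", rel_abund = nr
      ))
    }
    arrange(io, .data$polarity, .data$mz)
  })
  lib$base_mz <- map_dbl(lib$ions, function(io) {
    pos <- io[io$polarity == "positive", ]
    if (nrow(pos) > 0) pos$mz[which.max(pos$rel_abund)]
    else io$mz[which.max(io$rel_abund)]
  })
  lib
}

#' Look up one compound record
#'
#' @param library A compound library tibble from [phenol_library()].
#' @param compound Compound name or code.
#' @return The matching one-row tibble.
#' @export
library_lookup <- function(library, compound) {
  hit <- library[library$compound == compound | library$code == compound, ]
  if (nrow(hit) == 0) {
    abort(paste0("compound '", compound, "' is not in the library"),
          class = "phenolscreen_unknown_compound")
  }
  hit
}
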