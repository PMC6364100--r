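#' Fit a calibration line
#'
#' Ordinary least squares of peak area on concentration, the plain
#' unweighted line used for matrix-matched standards. The fitted range is
#' retained as the linear range. A non-positive slope is flagged as
#' degenerate (with a warning) rather than silently returned.
#'
#' @param levels Concentrations, ug/mL; at least 3 distinct values.
#' @param areas Peak areas, counts.min; same length as `levels`.
#' @param compound Optional compound name carried on the model.
#' @return An object of class `phenol_calibration` with elements
#'   `compound`, `slope`, `intercept`, `r_squared`, `linear_range`,
#'   `lod`, `loq` (`NA` until [add_lod_loq()]), `degenerate` and `data`.
#' @examples
#' m <- fit_calibration(c(2, 5, 10, 20, 50, 100),
#'                      14667 * c(2, 5, 10, 20, 50, 100) + 3462, "erianin")
#' glance(m)
#' @export
fit_calibration <- function(levels, areas, compound = NA_character_) {
  if (length(levels) != length(areas)) {
    abort("`levels` and `areas` must have the same length")
  }
  if (length(unique(levels)) < 3) {
    abort("need at least 3 distinct concentration levels",
          class = "phenolscreen_too_few_levels")
  }
  if (sd(levels) == 0) abort("zero variance in `levels`")
  fit <- lm(areas ~ levels)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  ss_res <- sum(residuals_of(fit)^2)
  ss_tot <- sum((areas - mean(areas))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  degenerate <- slope <= 0
  if (degenerate) {
    warn(paste0("calibration slope is not positive (",
                signif(slope, 4), "); model flagged degenerate"))
  }
  structure(list(
    compound = compound,
    slope = slope,
    intercept = intercept,
    r_squared = r2,
    linear_range = range(levels),
    lod = NA_real_,
    loq = NA_real_,
    degenerate = degenerate,
    data = tibble(level = levels, area = areas),
    fit = fit
  ), class = "phenol_calibration")
}

residuals_of <- function(fit) stats::residuals(fit)

#' @export
print.phenol_calibration <- function(x, ...) {
  cat("<phenol_calibration>", if (!is.na(x$compound)) x$compound else "",
      "\n  y =", signif(x$slope, 6), "x",
      if (x$intercept >= 0) "+" else "-", signif(abs(x$intercept), 6),
      "  R^2 =", signif(x$r_squared, 4), "\n")
  cat("  linear range:", x$linear_range[1], "-", x$linear_range[2],
      "ug/mL; LOD =", signif(x$lod, 3), "LOQ =", signif(x$loq, 3),
      "ug/mL\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.phenol_calibration <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @exportS3Method generics::glance
glance.phenol_calibration <- function(x, ...) {
  tibble(
    compound = x$compound, slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, range_lo = x$linear_range[1],
    range_hi = x$linear_range[2], lod = x$lod, loq = x$loq,
    degenerate = x$degenerate, n = nrow(x$data)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.phenol_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$level, y = .data$area)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "concentration (ug/mL)", y = "peak area (counts min)",
      title = object$compound,
      subtitle = sprintf("y = %.5g x %s %.5g,  R² = %.4f",
                         object$slope,
                         ifelse(object$intercept >= 0, "+", "-"),
                         abs(object$intercept), object$r_squared)
    )
}

#' Detection and quantification limits from baseline noise
#'
#' LOD is the concentration whose predicted peak height equals 3x the
#' baseline noise SD; LOQ uses 10x, so LOQ/LOD = 10/3 exactly. The signal
#' is the analyte response above baseline, so the calibration intercept is
#' excluded: predicted height = `slope * x * height_per_area`. Zero noise
#' degenerates to LOD = LOQ = 0 with a warning.
#'
#' @param model A `phenol_calibration`.
#' @param noise Baseline noise SD in counts (>= 0), e.g. from
#'   [estimate_baseline_noise()].
#' @param height_per_area Peak height per unit area, 1/min; see
#'   [height_per_area()].
#' @return A one-row tibble `(lod, loq)` in ug/mL.
#' @examples
#' m <- fit_calibration(c(2, 5, 10), 1000 * c(2, 5, 10))
#' estimate_lod_loq(m, noise = 1000, height_per_area = 10)
#' @export
estimate_lod_loq <- function(model, noise, height_per_area) {
  stopifnot(inherits(model, "phenol_calibration"))
  if (noise < 0) abort("`noise` must be >= 0")
  if (height_per_area <= 0) abort("`height_per_area` must be > 0")
  if (model$degenerate) abort("cannot derive limits from a degenerate fit")
  if (noise == 0) {
    warn("zero baseline noise: LOD and LOQ degenerate to 0")
    return(tibble(lod = 0, loq = 0))
  }
  lod <- 3 * noise / (model$slope * height_per_area)
  tibble(lod = lod, loq = 10 / 3 * lod)
}

#' Attach LOD/LOQ to a calibration model
#'
#' @inheritParams estimate_lod_loq
#' @return The model with `lod` and `loq` filled in.
#' @export
add_lod_loq <- function(model, noise, height_per_area) {
  ll <- estimate_lod_loq(model, noise, height_per_area)
  model$lod <- ll$lod
  model$loq <- ll$loq
  model
}

#' Convert extract concentration to dry-sample content
#'
#' `content (mg/kg) = concentration (ug/mL) * elution_volume (mL) /
#' sample_mass (g)`; with the default 0.5 g in 10 mL this is a factor of
#' 20 (ug/g and mg/kg are the same unit).
#'
#' @param concentration Extract concentration, ug/mL.
#' @param sample_mass Dried sample mass, g (> 0).
#' @param elution_volume Elution volume, mL (> 0).
#' @return Content in mg/kg dry sample.
#' @export
content_conversion <- function(concentration, sample_mass = 0.5,
                               elution_volume = 10) {
  if (sample_mass <= 0) abort("`sample_mass` must be > 0")
  if (elution_volume <= 0) abort("`elution_volume` must be > 0")
  concentration * elution_volume / sample_mass
}

#' Quantify a peak area against a calibration model
#'
#' Inverts the (own or surrogate) calibration line:
#' `x = (area - intercept) / slope`, clipped at zero. Concentrations below
#' the model's LOQ are flagged and their content reported as missing;
#' above it, content is converted to mg/kg dry sample with the
#' sample-preparation constants. A newly elucidated compound quantified
#' here is assumed to share its surrogate standard's response — the
#' built-in accuracy caveat of surrogate quantification.
#'
#' @param area Peak area(s), counts.min (>= 0).
#' @param model `phenol_calibration` of the compound's own or surrogate
#'   standard.
#' @param compound Compound being quantified (defaults to the model's).
#' @param sample_mass,elution_volume Sample-preparation constants.
#' @return A tibble with one row per area: `compound`, `area`,
#'   `concentration` (ug/mL), `content` (mg/kg, `NA` below LOQ),
#'   `below_loq`, `surrogate_used`.
#' @export
quantify <- function(area, model, compound = model$compound,
                     sample_mass = 0.5, elution_volume = 10) {
  stopifnot(inherits(model, "phenol_calibration"))
  if (any(area < 0, na.rm = TRUE)) abort("`area` must be >= 0")
  conc <- pmax((area - model$intercept) / model$slope, 0)
  loq <- if (is.na(model$loq)) 0 else model$loq
  below <- is.na(area) | conc < loq
  content <- content_conversion(conc, sample_mass, elution_volume)
  content[below] <- NA_real_
  conc[is.na(area)] <- NA_real_
  tibble(
    compound = compound,
    area = area,
    concentration = conc,
    content = content,
    below_loq = below,
    surrogate_used = model$compound
  )
}
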