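#' Average with missing values
#'
#' Arithmetic mean of the non-missing entries; missing if everything is
#' missing. This is the convention of the per-compound `Average` row of a
#' content table: samples where a compound was not found do not drag the
#' average down.
#'
#' @param values Numeric vector, `NA` for missing.
#' @return A single number or `NA`.
#' @examples
#' average_content(c(12.7, 8.9, NA, 23.4))  # 15
#' @export
average_content <- function(values) {
  if (length(values) == 0) abort("`values` must be non-empty")
  if (all(is.na(values))) return(NA_real_)
  mean(values, na.rm = TRUE)
}

#' Display rounding of contents
#'
#' Truncates (toward zero) to three significant digits, dropping a
#' trailing ".0" on integers — the display convention of reported content
#' tables. Internal values keep full precision; this is display-only. A
#' tiny relative guard (1e-12) is applied first so decimal values whose
#' binary representation falls infinitesimally below a truncation boundary
#' still print as their decimal truncation.
#'
#' @param value Non-negative content(s), mg/kg; `NA` gives `NA`.
#' @return Character vector of display strings.
#' @examples
#' display_round(c(425.5, 20.875, 9.7475))  # "425" "20.8" "9.74"
#' @export
display_round <- function(value) {
  map_chr(value, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0) abort("`value` must be >= 0")
    if (x == 0) return("0")
    x <- x * (1 + 1e-12)
    p <- floor(log10(x))
    scale <- 10^(p - 2)
    y <- floor(x / scale) * scale
    dec <- max(0, 2 - p)
    out <- formatC(y, format = "f", digits = dec)
    if (dec > 0) {
      out <- sub("0+$", "", out)
      out <- sub("\\.$", "", out)
    }
    out
  })
}

#' Assemble a content table
#'
#' Pivots per-sample, per-compound contents into the reporting layout
#' (samples as rows, compounds as columns) and appends the `Average` row
#' computed with [average_content()] — so a compound missing in some
#' samples is averaged over the samples where it was found, and a
#' compound found nowhere has a missing average.
#'
#' @param contents Tibble with columns `sample`, `compound`, `content`
#'   (`NA` = missing / below LOQ).
#' @param compound_order Optional column order.
#' @return A `content_table`: a tibble whose first column is `sample`
#'   (character, ending with `"Average"`), one numeric column per
#'   compound.
#' @export
content_table <- function(contents, compound_order = NULL) {
  stopifnot(all(c("sample", "compound", "content") %in% names(contents)))
  wide <- contents %>%
    mutate(sample = as.character(.data$sample)) %>%
    tidyr::pivot_wider(id_cols = "sample", names_from = "compound",
                       values_from = "content")
  if (!is.null(compound_order)) {
    wide <- wide %>% select("sample", dplyr::all_of(compound_order))
  }
  avg <- wide %>%
    summarise(dplyr::across(-"sample", average_content)) %>%
    mutate(sample = "Average", .before = 1)
  out <- bind_rows(wide, avg)
  class(out) <- c("content_table", class(out))
  out
}

#' Render a content table for display
#'
#' Applies [display_round()] to every cell and replaces missing values
#' with an em dash.
#'
#' @param ct A [content_table()].
#' @param missing Marker for missing cells.
#' @return A tibble of display strings.
#' @export
format_content_table <- function(ct, missing = "—") {
  out <- ct %>%
    mutate(dplyr::across(-"sample", function(v) {
      s <- display_round(v)
      ifelse(is.na(s), missing, s)
    }))
  class(out) <- setdiff(class(out), "content_table")
  out
}

#' @export
print.content_table <- function(x, ...) {
  print(format_content_table(x), n = nrow(x))
  invisible(x)
}

#' Write a content table to CSV
#'
#' Cells are display-rounded; missing cells are written empty.
#'
#' @param ct A [content_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_content_table <- function(ct, path) {
  readr::write_csv(format_content_table(ct, missing = ""), path)
  invisible(path)
}
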