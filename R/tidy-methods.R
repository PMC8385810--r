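#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sample call into one row per screened chromosome
#'
#' @param x A `nipt_call`.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `chrom`, `z`, `decision`.
#' @export
tidy.nipt_call <- function(x, ...) {
  dplyr::mutate(x$decisions, sample_id = x$sample_id, .before = 1)
}

#' One-row summary of a sample call
#'
#' @param x A `nipt_call`.
#' @param ... Unused.
#' @return A tibble with the fetal fraction, sex karyotype, maximum target
#'   z, overall screen result and CNV segment count.
#' @export
glance.nipt_call <- function(x, ...) {
  dec <- x$decisions$decision
  result <- if (any(dec %in% c("positive", "gray_positive"))) {
    "positive"
  } else if (all(dec == "no_call_low_ff")) {
    "no_call"
  } else {
    "negative"
  }
  tibble::tibble(
    sample_id = x$sample_id, ff = x$ff, ff_source = x$ff_source,
    sex_karyotype = x$sex_karyotype, max_target_z = max(x$decisions$z),
    result = result, n_cnv = nrow(x$cnv)
  )
}

#' Tidy a reference panel
#'
#' @param x A `nipt_panel`.
#' @param unit `"chromosome"` or `"window"`.
#' @param ... Unused.
#' @return Tibble of means and SDs per unit.
#' @export
tidy.nipt_panel <- function(x, unit = c("chromosome", "window"), ...) {
  unit <- match.arg(unit)
  if (unit == "chromosome") x$chromosomes else x$windows
}

#' One-row summary of a reference panel
#'
#' @param x A `nipt_panel`.
#' @param ... Unused.
#' @return A tibble with panel size, unit counts and chrY baselines.
#' @export
glance.nipt_panel <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples, n_chromosomes = nrow(x$chromosomes),
    n_windows = nrow(x$windows), r_y0 = x$r_y0, r_y = x$r_y
  )
}

#' Tidy a stratified screening report
#'
#' @param x A `nipt_report`.
#' @param table `"class"`, `"indication"` or `"headline"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.nipt_report <- function(x, table = c("class", "indication", "headline"),
                             ...) {
  switch(match.arg(table),
         class = x$by_class,
         indication = x$by_indication,
         headline = x$headline)
}

#' @export
glance.nipt_report <- function(x, ...) x$headline
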