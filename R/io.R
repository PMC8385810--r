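#' Read a per-sample bin-count table
#'
#' Reads a BED-like tab-separated file with a header row and columns
#' `chrom`, `start`, `end`, `gc`, `count` (0-based half-open coordinates;
#' "chr"-prefixed labels are accepted and stripped). Malformed rows are
#' rejected with the offending data line number.
#'
#' @param path Path to a TSV file.
#' @param sample_id,run_id Identifiers attached to the returned table;
#'   default to the file name and `"run1"`.
#' @return A tibble with columns `sample_id`, `run_id`, `chrom`, `start`,
#'   `end`, `gc`, `count`.
#' @export
read_bin_counts <- function(path, sample_id = NULL, run_id = "run1") {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(tsv|txt|bed)$", "", basename(path))
  }
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), gc = readr::col_character(),
      count = readr::col_double()
    ),
    progress = FALSE
  )
  # base R strtod is correctly rounded, so gc round-trips bit-exactly
  df$gc <- as.numeric(df$gc)
  required <- c("chrom", "start", "end", "gc", "count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) stop("no bins in ", path)
  df$chrom <- sub("^chr", "", df$chrom)

  bad_row <- function(cond, what) {
    if (any(cond)) {
      stop(sprintf("%s at data line %d of %s", what, which(cond)[1], path))
    }
  }
  bad_row(is.na(df$start) | is.na(df$end) | is.na(df$count), "malformed row")
  bad_row(df$count < 0 | df$count != floor(df$count), "negative or non-integer count")
  bad_row(df$end <= df$start, "empty or inverted bin")
  bad_row(!is.na(df$gc) & (df$gc < 0 | df$gc > 1), "gc outside [0, 1]")
  ov <- df |>
    dplyr::mutate(.line = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.overlap = .data$start < dplyr::lag(.data$end, default = -Inf)) |>
    dplyr::ungroup()
  if (any(ov$.overlap)) {
    stop(sprintf("overlapping bins at data line %d of %s",
                 ov$.line[which(ov$.overlap)[1]], path))
  }
  tibble::tibble(sample_id = sample_id, run_id = run_id,
                 chrom = df$chrom, start = df$start, end = df$end,
                 gc = df$gc, count = as.double(df$count))
}

#' Write a per-sample bin-count table
#'
#' Inverse of [read_bin_counts()]; `read_bin_counts(write_bin_counts(x, p))`
#' returns the genomic columns of `x` bit-exactly.
#'
#' @param counts A bin-count tibble (columns `chrom`, `start`, `end`, `gc`,
#'   `count`; identifier columns are dropped on write).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(counts, path) {
  stopifnot(all(c("chrom", "start", "end", "gc", "count") %in% names(counts)))
  out <- dplyr::select(counts, "chrom", "start", "end", "gc", "count")
  # 17 significant digits guarantee an exact double round trip for gc
  out$gc <- ifelse(is.na(out$gc), NA_character_, sprintf("%.17g", out$gc))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a reference panel to JSON
#'
#' @param panel A `nipt_panel` object from [build_reference_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_panel <- function(panel, path) {
  stopifnot(inherits(panel, "nipt_panel"))
  payload <- list(
    n_samples = panel$n_samples,
    r_y0 = panel$r_y0, r_y = panel$r_y,
    chromosomes = panel$chromosomes,
    windows = panel$windows
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a reference panel from JSON
#'
#' @param path Path written by [write_reference_panel()].
#' @return A `nipt_panel` object.
#' @export
read_reference_panel <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_nipt_panel(
    chromosomes = tibble::as_tibble(raw$chromosomes),
    windows = tibble::as_tibble(raw$windows),
    n_samples = raw$n_samples,
    r_y0 = raw$r_y0, r_y = raw$r_y
  )
}
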