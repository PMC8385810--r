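#' Analysis configuration
#'
#' Bundles the tunable thresholds of the screening pipeline. Defaults encode
#' the kit-style decision rules: a chromosome is flagged when its z-score
#' exceeds 3 with fetal fraction at least 4%, calls with 3 < z < 5 carry a
#' gray-zone flag, and 1-Mb-window copy-number segments require a combined
#' Stouffer |Z| above 5.
#'
#' @param bin_size Genomic window width in bases (default 1 Mb).
#' @param loess_span Span of the LOESS GC fit, in (0, 1].
#' @param z_positive_cutoff Chromosome z-score above which a sample is
#'   reported screen-positive (default 3).
#' @param z_gray_upper Upper bound of the gray zone: positives with
#'   z below this value are flagged `gray_positive` (default 5).
#' @param ff_min Minimum fetal fraction for a reportable call (default 0.04).
#' @param cnv_z_cutoff Combined Stouffer |Z| required to emit a
#'   microduplication/microdeletion segment (default 5).
#' @param cnv_seed_z Single-window |z| threshold that seeds a candidate
#'   segment run (default 2).
#' @param min_panel_size Minimum number of euploid samples in a reference
#'   panel (default 30).
#' @param gc_band Length-2 numeric; bins with GC outside this band are
#'   excluded from the analysis (default `c(0.3, 0.6)`).
#' @param seed Optional integer seed recorded for provenance.
#'
#' @return A list of class `nipt_config`.
#' @examples
#' cfg <- nipt_config()
#' cfg$z_positive_cutoff
#' @export
nipt_config <- function(bin_size = 1e6,
                        loess_span = 0.3,
                        z_positive_cutoff = 3,
                        z_gray_upper = 5,
                        ff_min = 0.04,
                        cnv_z_cutoff = 5,
                        cnv_seed_z = 2,
                        min_panel_size = 30,
                        gc_band = c(0.3, 0.6),
                        seed = NULL) {
  cfg <- list(
    bin_size = bin_size, loess_span = loess_span,
    z_positive_cutoff = z_positive_cutoff, z_gray_upper = z_gray_upper,
    ff_min = ff_min, cnv_z_cutoff = cnv_z_cutoff, cnv_seed_z = cnv_seed_z,
    min_panel_size = min_panel_size, gc_band = gc_band, seed = seed
  )
  validate_nipt_config(cfg)
  structure(cfg, class = "nipt_config")
}

validate_nipt_config <- function(cfg) {
  stopifnot(
    "bin_size must be >= 100000" = cfg$bin_size >= 1e5,
    "loess_span must be in (0, 1]" = cfg$loess_span > 0 && cfg$loess_span <= 1,
    "cutoffs must be positive" = all(c(
      cfg$z_positive_cutoff, cfg$z_gray_upper, cfg$cnv_z_cutoff,
      cfg$cnv_seed_z
    ) > 0),
    "z_gray_upper must exceed z_positive_cutoff" =
      cfg$z_gray_upper > cfg$z_positive_cutoff,
    "ff_min must be in (0, 1)" = cfg$ff_min > 0 && cfg$ff_min < 1,
    "min_panel_size must be >= 2" = cfg$min_panel_size >= 2,
    "gc_band must be an increasing pair in [0, 1]" =
      length(cfg$gc_band) == 2 && cfg$gc_band[1] < cfg$gc_band[2] &&
        cfg$gc_band[1] >= 0 && cfg$gc_band[2] <= 1
  )
  invisible(cfg)
}

#' @export
print.nipt_config <- function(x, ...) {
  cat("<nipt_config>\n")
  cat(sprintf("  bin size         : %s bp\n", format(x$bin_size, big.mark = ",")))
  cat(sprintf("  LOESS span       : %.2f\n", x$loess_span))
  cat(sprintf("  z cutoff (gray)  : > %g (gray below %g)\n",
              x$z_positive_cutoff, x$z_gray_upper))
  cat(sprintf("  fetal fraction   : >= %.0f%%\n", 100 * x$ff_min))
  cat(sprintf("  CNV |Z| cutoff   : %g (seed |z| > %g)\n",
              x$cnv_z_cutoff, x$cnv_seed_z))
  cat(sprintf("  GC band          : [%.2f, %.2f]\n", x$gc_band[1], x$gc_band[2]))
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' Parses lines of the form `key = value` (or `key: value`); blank lines and
#' `#` comments are ignored. Recognised keys override [nipt_config()]
#' defaults; unknown keys raise an error.
#'
#' @param path Path to a plain-text configuration file.
#' @return A `nipt_config` object.
#' @export
read_nipt_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  }
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  known <- names(formals(nipt_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "gc_band") {
      as.numeric(strsplit(vals[i], "\\s*,\\s*")[[1]])
    } else {
      as.numeric(vals[i])
    }
  })
  names(args) <- keys
  do.call(nipt_config, args)
}
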