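#' hg19-scale chromosome lengths
#'
#' A bundled table of the 24 human chromosomes with hg19 assembly lengths,
#' so that genome-wide bin grids can be built without any reference download.
#' Labels carry no "chr" prefix.
#'
#' @return A tibble with columns `chrom` (character) and `length` (double).
#' @examples
#' hg19_chromosomes()
#' @export
hg19_chromosomes <- function() {
  tibble::tibble(
    chrom = c(as.character(1:22), "X", "Y"),
    length = c(
      249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
      159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
      115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
      59128983, 63025520, 48129895, 51304566, 155270560, 59373566
    )
  )
}

.valid_chroms <- c(as.character(1:22), "X", "Y")

#' Tile chromosomes into fixed-width genomic bins
#'
#' Partitions each chromosome into consecutive, non-overlapping windows of
#' `bin_size` bases (0-based, half-open); the last bin of a chromosome may be
#' shorter. GC content is left `NA` — attach it from data or with
#' [simulate_gc_content()].
#'
#' @param chrom_lengths Data frame with columns `chrom` and `length`.
#' @param bin_size Window width in bases.
#' @return A tibble with columns `chrom`, `start`, `end`, `gc`, `usable`.
#' @examples
#' make_genome_bins(tibble::tibble(chrom = "21", length = 2.5e6), 1e6)
#' @export
make_genome_bins <- function(chrom_lengths, bin_size = 1e6) {
  stopifnot(is.data.frame(chrom_lengths),
            all(c("chrom", "length") %in% names(chrom_lengths)),
            bin_size > 0)
  chrom_lengths <- dplyr::mutate(
    chrom_lengths, chrom = sub("^chr", "", as.character(.data$chrom))
  )
  unknown <- setdiff(chrom_lengths$chrom, .valid_chroms)
  if (length(unknown) > 0) {
    stop("unknown chromosome label(s): ", paste(unknown, collapse = ", "))
  }
  if (any(chrom_lengths$length <= 0)) stop("chromosome lengths must be positive")
  bins <- purrr::pmap_dfr(chrom_lengths, function(chrom, length) {
    starts <- seq(0, length - 1, by = bin_size)
    tibble::tibble(
      chrom = chrom, start = starts,
      end = pmin(starts + bin_size, length)
    )
  })
  dplyr::mutate(bins, gc = NA_real_, usable = TRUE)
}

#' Attach a smooth synthetic GC profile to genome bins
#'
#' Draws per-bin GC fractions from a first-order autoregressive process along
#' each chromosome (so neighbouring bins have correlated GC, as in real
#' genomes), centred at `mean` with marginal standard deviation `sd`, clipped
#' to \[0.25, 0.75\]. Bins with GC outside `gc_band` are marked unusable —
#' the count-level analogue of upstream read filtering.
#'
#' @param bins Genome-bin tibble from [make_genome_bins()].
#' @param mean,sd Marginal mean and SD of the GC fraction.
#' @param rho Lag-1 autocorrelation between adjacent bins.
#' @param gc_band Usability band for GC; see [nipt_config()].
#' @param seed Integer seed for reproducibility.
#' @return `bins` with `gc` filled and `usable` updated.
#' @export
simulate_gc_content <- function(bins, mean = 0.41, sd = 0.05, rho = 0.7,
                                gc_band = c(0.3, 0.6), seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  out <- bins |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
      g <- numeric(n)
      g[1] <- stats::rnorm(1, 0, sd)
      for (i in seq_len(n)[-1]) g[i] <- rho * g[i - 1] + e[i]
      df$gc <- pmin(pmax(mean + g, 0.25), 0.75)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("chrom")
  dplyr::mutate(out,
                usable = .data$gc >= gc_band[1] & .data$gc <= gc_band[2])
}

#' Default genome-wide 1-Mb bin grid
#'
#' Convenience wrapper: hg19-scale chromosomes tiled at `bin_size` with a
#' reproducible synthetic GC profile attached.
#'
#' @inheritParams make_genome_bins
#' @param seed Seed for the GC profile.
#' @param gc_band Usability band for GC content.
#' @return A genome-bin tibble.
#' @examples
#' bins <- nipt_bins()
#' dplyr::count(bins, chrom)
#' @export
nipt_bins <- function(bin_size = 1e6, seed = 1L, gc_band = c(0.3, 0.6)) {
  make_genome_bins(hg19_chromosomes(), bin_size) |>
    simulate_gc_content(gc_band = gc_band, seed = seed)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

validate_genome_bins <- function(bins) {
  stopifnot(all(c("chrom", "start", "end", "gc", "usable") %in% names(bins)))
  by_chrom <- split(bins, bins$chrom)
  for (df in by_chrom) {
    if (is.unsorted(df$start)) stop("bins not sorted within chromosome ", df$chrom[1])
    if (any(df$end <= df$start)) stop("empty bin on chromosome ", df$chrom[1])
    if (nrow(df) > 1 && any(df$start[-1] != df$end[-nrow(df)])) {
      stop("gap or overlap in bins on chromosome ", df$chrom[1])
    }
  }
  gc <- bins$gc[!is.na(bins$gc)]
  if (any(gc < 0 | gc > 1)) stop("gc out of [0, 1]")
  invisible(bins)
}
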