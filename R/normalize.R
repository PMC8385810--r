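#' LOESS GC-bias correction of bin counts
#'
#' Fits count versus GC by locally weighted regression (degree 1, robust
#' "symmetric" family) over usable bins, with weights proportional to bin
#' length so short terminal and zero-count bins still inform the fit, then
#' rescales each bin by `global median fitted / fitted(gc)`. A degenerate
#' input in which all usable bins share one GC value is returned unchanged
#' with a message.
#'
#' @param counts Bin-count tibble (from [read_bin_counts()] or
#'   [simulate_sample()]).
#' @param bins Genome-bin tibble aligned with `counts` (same chrom/start
#'   order); supplies the `usable` flag.
#' @param span LOESS span in (0, 1].
#' @return A corrected-profile tibble: columns `sample_id`, `run_id`,
#'   `chrom`, `start`, `end`, `gc`, `usable`, `value`.
#' @export
loess_gc_correct <- function(counts, bins, span = 0.3) {
  stopifnot(span > 0, span <= 1, nrow(counts) == nrow(bins))
  usable <- bins$usable
  if (sum(usable) < 100) stop("need at least 100 usable bins")
  prof <- tibble::tibble(
    sample_id = counts$sample_id[1], run_id = counts$run_id[1],
    chrom = counts$chrom, start = counts$start, end = counts$end,
    gc = counts$gc, usable = usable, value = as.double(counts$count)
  )
  auto <- usable & !prof$chrom %in% c("X", "Y")
  gc <- prof$gc[auto]
  if (length(unique(prof$gc[usable])) == 1) {
    message("all GC values identical; LOESS correction is the identity")
    return(prof)
  }
  len <- (prof$end - prof$start)[auto]
  # fit the GC response on autosomes (diploid in every sample); apply the
  # correction to every usable bin so sex-chromosome dosage is preserved
  fit <- stats::loess(
    prof$value[auto] ~ gc, weights = len, span = span, degree = 1,
    family = "symmetric",
    control = stats::loess.control(surface = "interpolate", statistics = "none")
  )
  gc_all <- pmin(pmax(prof$gc[usable], min(gc)), max(gc))
  fitted <- stats::predict(fit, gc_all)
  floor_v <- max(stats::median(fitted, na.rm = TRUE) * 1e-3, 1e-9)
  fitted <- pmax(fitted, floor_v)
  v <- prof$value[usable] * stats::median(fitted) / fitted
  # anchor the global median so the correction changes shape, not scale
  m0 <- stats::median(prof$value[usable])
  m1 <- stats::median(v)
  if (m0 > 0 && m1 > 0) v <- v * m0 / m1
  prof$value[usable] <- v
  prof
}

#' Intra-run median normalization
#'
#' Removes run-shared per-bin artifacts: each usable autosomal bin is
#' divided by the across-sample median of that (depth-normalized) bin
#' within the run, then each sample is rescaled to unit mean over usable
#' autosomal bins. Sex-chromosome bins are depth- and length-normalized
#' only — their across-run median would depend on the fetal-sex mix of the
#' run and dividing by it would erase the X/Y dosage that fetal-fraction
#' estimation and sex classification read. A single-sample run is returned
#' unchanged. Autosomal bins whose across-run median is zero are flagged
#' unusable for every member of the run.
#'
#' @param profiles List of corrected-profile tibbles sharing a run.
#' @return List of normalized profiles (same order).
#' @export
intra_run_normalize <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  if (length(profiles) == 1) return(profiles)
  p1 <- profiles[[1]]
  auto <- p1$usable & !p1$chrom %in% c("X", "Y")
  vals <- vapply(profiles, function(p) p$value, p1$value)
  # depth-normalize on autosomes so samples are comparable
  scale <- colMeans(vals[auto, , drop = FALSE])
  vals_n <- sweep(vals, 2, scale, "/")
  med <- row_medians(vals_n)
  len <- p1$end - p1$start
  # reference level per bin: run median for autosomes, expected
  # length share for X/Y (dosage-preserving)
  ref <- ifelse(auto, med, len / mean(len[auto]))
  dead <- auto & med <= 0
  purrr::map(seq_along(profiles), function(j) {
    p <- profiles[[j]]
    p$usable <- p$usable & !dead
    v <- ifelse(ref > 0, vals_n[, j] / ref, 0)
    u <- p$usable & !p$chrom %in% c("X", "Y")
    m <- mean(v[u])
    p$value <- ifelse(p$usable, v / m, 0)
    p
  })
}

# Row medians via one global sort (much faster than apply for wide
# bin-by-sample matrices).
row_medians <- function(m) {
  k <- ncol(m)
  s <- matrix(m[order(row(m), m)], nrow = nrow(m), byrow = TRUE)
  if (k %% 2 == 1) s[, (k + 1) / 2] else (s[, k / 2] + s[, k / 2 + 1]) / 2
}

#' Residual quadratic-GC regression
#'
#' Final trend-removal step: fits `value ~ gc + gc^2` by least squares on
#' usable autosomal bins and replaces the value by
#' `residual + mean(fitted)`, removing any GC trend that survives the first
#' two steps while keeping the overall scale (sex-chromosome bins, whose
#' level encodes fetal dosage, are left untouched). Values are floored at
#' zero. A rank-deficient design (constant GC) skips the step with a
#' message.
#'
#' @param profile A corrected-profile tibble.
#' @return The profile with `value` residualized.
#' @export
residualize_linear <- function(profile) {
  u <- profile$usable & !profile$chrom %in% c("X", "Y")
  gc <- profile$gc[u]
  if (length(unique(gc)) < 3) {
    message("GC design rank-deficient; skipping residual regression")
    return(profile)
  }
  fit <- stats::lm.fit(cbind(1, gc, gc^2), profile$value[u])
  profile$value[u] <- pmax(fit$residuals + mean(profile$value[u] - fit$residuals), 0)
  profile
}

#' Full three-step GC-bias correction for a run of samples
#'
#' Applies [loess_gc_correct()] per sample, [intra_run_normalize()] across
#' the run, and [residualize_linear()] per sample, in that order.
#'
#' @param counts_list List of bin-count tibbles from one sequencing run.
#' @param bins Genome-bin tibble.
#' @param config A [nipt_config()].
#' @return List of corrected-profile tibbles.
#' @export
normalize_run <- function(counts_list, bins, config = nipt_config()) {
  profiles <- purrr::map(counts_list, loess_gc_correct, bins = bins,
                         span = config$loess_span)
  profiles <- intra_run_normalize(profiles)
  purrr::map(profiles, residualize_linear)
}

#' Normalize one sample against fixed run companions
#'
#' Convenience path for calling a single new sample: the sample is
#' GC-corrected with [loess_gc_correct()], the intra-run median step is
#' taken against a fixed set of companion profiles (euploid samples of the
#' same run, already LOESS-corrected), and the result is residualized.
#' Equivalent to [normalize_run()] for the last sample of the run, without
#' re-residualizing the companions.
#'
#' @param counts Bin-count tibble of the sample to normalize.
#' @param companions List of LOESS-corrected companion profiles.
#' @param bins Genome-bin tibble.
#' @param config A [nipt_config()].
#' @return The sample's corrected-profile tibble.
#' @export
normalize_sample_in_run <- function(counts, companions, bins,
                                    config = nipt_config()) {
  prof <- loess_gc_correct(counts, bins, span = config$loess_span)
  profs <- intra_run_normalize(c(companions, list(prof)))
  residualize_linear(profs[[length(profs)]])
}

#' Chromosome proportions of a corrected profile
#'
#' `p_c` = share of the sample's corrected signal on chromosome *c* over
#' usable bins (autosomes, X and Y); the vector sums to 1.
#'
#' @param profile A corrected-profile tibble.
#' @return A tibble with columns `chrom` and `p`.
#' @export
chromosome_proportions <- function(profile) {
  u <- dplyr::filter(profile, .data$usable)
  total <- sum(u$value)
  if (total <= 0) stop("all-zero profile: cannot form chromosome proportions")
  u |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(p = sum(.data$value) / total, .groups = "drop") |>
    dplyr::arrange(match(.data$chrom, .valid_chroms))
}

#' Chromosome shares on the autosomal-denominator scale
#'
#' Like [chromosome_proportions()] but divided by the autosomal total, the
#' scale on which z-scores and the chrY fetal-fraction estimate are
#' computed: a sex-chromosome dosage change (male fetus, 45,X, maternal
#' 47,XXX) then cannot shift every autosomal share at once. Autosomal
#' shares sum to 1; X and Y ride on top.
#'
#' @param profile A corrected-profile tibble.
#' @return A tibble with columns `chrom` and `p`.
#' @export
chromosome_shares <- function(profile) {
  u <- dplyr::filter(profile, .data$usable)
  total <- sum(u$value[!u$chrom %in% c("X", "Y")])
  if (total <= 0) stop("all-zero profile: cannot form chromosome shares")
  u |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(p = sum(.data$value) / total, .groups = "drop") |>
    dplyr::arrange(match(.data$chrom, .valid_chroms))
}

#' Window proportions of a corrected profile
#'
#' Per-bin share of the sample's corrected signal, the unit on which
#' subchromosomal Stouffer statistics are computed. The denominator is the
#' autosomal total, so that sex-chromosome dosage (fetal sex, maternal or
#' fetal X abnormalities) cannot shift every autosomal window at once.
#'
#' @param profile A corrected-profile tibble.
#' @return A tibble with `chrom`, `start`, `end`, `q` (usable bins only).
#' @export
window_proportions <- function(profile) {
  u <- dplyr::filter(profile, .data$usable)
  total <- sum(u$value[!u$chrom %in% c("X", "Y")])
  if (total <= 0) stop("all-zero profile: cannot form window proportions")
  dplyr::transmute(u, chrom = .data$chrom, start = .data$start,
                   end = .data$end, q = .data$value / total)
}
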