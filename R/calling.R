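new_nipt_panel <- function(chromosomes, windows, n_samples, r_y0, r_y,
                           loo_qc = NULL) {
  structure(
    list(chromosomes = chromosomes, windows = windows,
         n_samples = n_samples, r_y0 = r_y0, r_y = r_y, loo_qc = loo_qc),
    class = "nipt_panel"
  )
}

#' Build a euploid reference panel
#'
#' Computes, from corrected euploid female-fetus profiles, the mean and
#' unbiased SD of chromosome shares and of per-window proportions (both on
#' the autosomal-denominator scale, see [chromosome_shares()]) — the
#' reference data set against which sample z-scores are measured. The
#' chromosome-Y baseline `r_y0` (mapping-noise floor) comes from the same
#' female profiles; the male chrY dose-response used for fetal-fraction
#' estimation is calibrated from euploid male-fetus profiles with known
#' fetal fractions and stored as `r_y` with
#' `slope = r_y / 2 - r_y0` (so `r_y` is the extrapolated chrY share of a
#' pure male sample, counting Y at one copy per diploid genome).
#' A leave-one-out z per panel member (leave-one-out mean, full-panel SD)
#' is retained for QC.
#'
#' @param profiles List of corrected euploid female-fetus profiles
#'   ([normalize_run()]).
#' @param male_profiles Optional list of corrected euploid male-fetus
#'   profiles for chrY calibration.
#' @param male_ff Known fetal fractions of `male_profiles` (same order).
#' @param config A [nipt_config()].
#' @return A `nipt_panel` object.
#' @export
build_reference_panel <- function(profiles, male_profiles = NULL,
                                  male_ff = NULL, config = nipt_config()) {
  n <- length(profiles)
  if (n < config$min_panel_size) {
    stop("reference panel needs >= ", config$min_panel_size,
         " profiles, got ", n)
  }
  props <- purrr::map(profiles, chromosome_shares)
  chroms <- props[[1]]$chrom
  pmat <- vapply(props, function(p) p$p[match(chroms, p$chrom)],
                 numeric(length(chroms)))
  mu <- rowMeans(pmat)
  sd <- apply(pmat, 1, stats::sd)
  if (any(sd == 0)) {
    stop("zero panel SD for chromosome ", chroms[which(sd == 0)[1]])
  }
  chrom_tbl <- tibble::tibble(chrom = chroms, mu = mu, sd = sd)

  wins <- purrr::map(profiles, window_proportions)
  common <- purrr::reduce(
    purrr::map(wins, ~ dplyr::select(.x, "chrom", "start", "end")),
    dplyr::inner_join, by = c("chrom", "start", "end")
  )
  qmat <- vapply(wins, function(w) {
    dplyr::left_join(common, w, by = c("chrom", "start", "end"))$q
  }, numeric(nrow(common)))
  wmu <- rowMeans(qmat)
  wsd <- apply(qmat, 1, stats::sd)
  if (any(wsd == 0)) {
    i <- which(wsd == 0)[1]
    stop(sprintf("zero panel SD for window %s:%d-%d",
                 common$chrom[i], common$start[i], common$end[i]))
  }
  win_tbl <- dplyr::mutate(common, mu = wmu, sd = wsd)

  # leave-one-out QC: mean_{-i} with full-panel SD, so the mean over
  # members is exactly zero per chromosome
  loo <- purrr::map_dfr(seq_len(n), function(i) {
    m_i <- (mu * n - pmat[, i]) / (n - 1)
    tibble::tibble(member = i, chrom = chroms,
                   z = (pmat[, i] - m_i) / sd)
  })

  r_y0 <- mu[chroms == "Y"]
  r_y <- NA_real_
  if (!is.null(male_profiles)) {
    if (is.null(male_ff) || length(male_ff) != length(male_profiles)) {
      stop("male_ff must accompany male_profiles, one value per profile")
    }
    p_y <- vapply(male_profiles, function(p) {
      pr <- chromosome_shares(p)
      pr$p[pr$chrom == "Y"]
    }, 0)
    slope <- stats::median((p_y - r_y0) / male_ff)
    if (slope <= 0) stop("chrY calibration failed: non-positive slope")
    r_y <- 2 * (slope + r_y0)
  }
  new_nipt_panel(chrom_tbl, win_tbl, n_samples = n,
                 r_y0 = unname(r_y0), r_y = unname(r_y), loo_qc = loo)
}

#' @export
print.nipt_panel <- function(x, ...) {
  cat("<nipt_panel>\n")
  cat(sprintf("  samples      : %d\n", x$n_samples))
  cat(sprintf("  chromosomes  : %d\n", nrow(x$chromosomes)))
  cat(sprintf("  1-Mb windows : %d\n", nrow(x$windows)))
  cat(sprintf("  chrY baseline: %.3g (female), %.3g (male, extrapolated)\n",
              x$r_y0, x$r_y))
  invisible(x)
}

#' Chromosome z-scores against a reference panel
#'
#' `z_c = (p_c - mu_c) / sd_c`: the number of reference-panel standard
#' deviations separating the sample's chromosome share from the euploid
#' mean. Chromosomes absent from the panel are omitted with a message.
#'
#' @param profile A corrected-profile tibble.
#' @param panel A `nipt_panel`.
#' @return A tibble with columns `chrom`, `p`, `z`.
#' @export
zscore_chromosomes <- function(profile, panel) {
  stopifnot(inherits(panel, "nipt_panel"))
  p <- chromosome_shares(profile)
  missing <- setdiff(p$chrom, panel$chromosomes$chrom)
  if (length(missing) > 0) {
    message("chromosome(s) absent from panel, omitted: ",
            paste(missing, collapse = ", "))
  }
  dplyr::inner_join(p, panel$chromosomes, by = "chrom") |>
    dplyr::transmute(chrom = .data$chrom, p = .data$p,
                     z = (.data$p - .data$mu) / .data$sd)
}

#' Chromosome-Y fetal-fraction estimate
#'
#' For a male fetus at fraction *f*, the fetal genome contributes chrY at
#' half weight (one Y per diploid genome), so the chrY share rises linearly
#' from the female mapping-noise baseline `r_y0`:
#' `ff = (p_Y - r_y0) / (r_y / 2 - r_y0)`, clipped to \[0, 1\]. For a female
#' fetus chrY carries no fetal signal; an externally supplied `override`
#' (e.g. from a kit) is returned, otherwise `NA` (downstream treats unknown
#' fetal fraction as a no-call).
#'
#' @param profile A corrected-profile tibble.
#' @param panel A `nipt_panel` with chrY calibration.
#' @param fetal_sex `"male"` or `"female"`.
#' @param override Known fetal fraction to pass through (required route for
#'   female fetuses).
#' @return A single fetal fraction, or `NA` when unavailable.
#' @export
estimate_fetal_fraction <- function(profile, panel, fetal_sex,
                                    override = NULL) {
  fetal_sex <- match.arg(fetal_sex, c("male", "female"))
  if (fetal_sex == "female") {
    return(if (is.null(override)) NA_real_ else override)
  }
  if (is.na(panel$r_y)) stop("panel lacks chrY male calibration (r_y)")
  p <- chromosome_shares(profile)
  p_y <- p$p[p$chrom == "Y"]
  slope <- panel$r_y / 2 - panel$r_y0
  ff <- (p_y - panel$r_y0) / slope
  if (ff < 0) warning("chrY share below female baseline; clipping ff to 0")
  min(max(ff, 0), 1)
}

#' Aneuploidy decision per target chromosome
#'
#' Applies the kit-style decision rule per chromosome: fetal fraction below
#' `ff_min` (or unknown) gives `no_call_low_ff` regardless of z; otherwise
#' `z <= 3` is `negative`, `3 < z < 5` is `gray_positive` (reported
#' positive, but flagged as the gray zone in which false positives
#' concentrate) and `z >= 5` is `positive`.
#'
#' @param z Chromosome z-score tibble from [zscore_chromosomes()] (or any
#'   tibble with `chrom` and `z`).
#' @param ff Fetal fraction (may be `NA`).
#' @param config A [nipt_config()].
#' @param targets Chromosomes to screen (default 21, 18, 13).
#' @return A tibble with `chrom`, `z`, `decision`.
#' @export
call_aneuploidy <- function(z, ff, config = nipt_config(),
                            targets = c("21", "18", "13")) {
  z <- dplyr::filter(z, .data$chrom %in% targets)
  decide <- function(zv) {
    if (is.na(ff) || ff < config$ff_min) return("no_call_low_ff")
    if (zv >= config$z_gray_upper) return("positive")
    if (zv > config$z_positive_cutoff) return("gray_positive")
    "negative"
  }
  z |>
    dplyr::mutate(decision = vapply(.data$z, decide, "")) |>
    dplyr::select("chrom", "z", "decision")
}

#' Classify the sex-chromosome karyotype
#'
#' Y presence is decided by comparing the sample's chrY share with the
#' midpoint between the female baseline and the expectation for a male
#' fetus at the sample's fetal fraction. Without Y, the ±3 convention on
#' the chrX z-score gives XO (z < -3), XXX (z > +3) or XX. With Y, the
#' chrX share is tested against the *male* expectation at the chrY-implied
#' fetal fraction: an excess (> +3 SD) means an extra X dose, read as XXY
#' when the X share matches the maternal (female) mean and as XYY when the
#' X share is significantly below it (a double-Y sample doubles the
#' chrY-implied fraction, so the male expectation overshoots). Conflicting
#' signals give `undetermined`.
#'
#' @param z_x Chromosome-X z-score against the (female) panel.
#' @param p_y chrY proportion of the sample.
#' @param ff Fetal fraction (chrY-based for Y-bearing samples).
#' @param panel A `nipt_panel` with chrY calibration.
#' @param config A [nipt_config()].
#' @return One of `"XX"`, `"XY"`, `"XO"`, `"XXY"`, `"XXX"`, `"XYY"`,
#'   `"undetermined"`.
#' @export
classify_sex_karyotype <- function(z_x, p_y, ff, panel,
                                   config = nipt_config()) {
  if (is.na(ff) || ff < config$ff_min) return("undetermined")
  slope <- panel$r_y / 2 - panel$r_y0
  exp_male <- panel$r_y0 + ff * slope
  has_y <- p_y > (panel$r_y0 + exp_male) / 2
  cut <- config$z_positive_cutoff
  mu_x <- panel$chromosomes$mu[panel$chromosomes$chrom == "X"]
  sd_x <- panel$chromosomes$sd[panel$chromosomes$chrom == "X"]
  if (!has_y) {
    if (z_x < -cut) return("XO")
    if (z_x > cut) return("XXX")
    return("XX")
  }
  ff_y <- min(max((p_y - panel$r_y0) / slope, 0), 1)
  # z of chrX relative to the male expectation at the chrY-implied ff
  z_x_male <- z_x + (ff_y / 2) * mu_x / sd_x
  if (z_x_male > cut) {
    if (z_x > -cut) return("XXY")
    return("XYY")
  }
  if (z_x_male < -cut) return("undetermined")
  "XY"
}

#' Stouffer combined Z
#'
#' Combines k standard-normal window statistics as `sum(z) / sqrt(k)`.
#'
#' @param z Numeric vector of finite window z-scores (length >= 1).
#' @return The combined Z.
#' @examples
#' stouffer_z(c(3, 3, 3, 3)) # 6
#' @export
stouffer_z <- function(z) {
  if (length(z) == 0) stop("empty window set")
  if (!all(is.finite(z))) stop("non-finite window z")
  sum(z) / sqrt(length(z))
}

#' Window z-scores against the panel
#'
#' @param profile A corrected-profile tibble.
#' @param panel A `nipt_panel`.
#' @return A tibble `chrom`, `start`, `end`, `z` over windows shared with
#'   the panel.
#' @export
zscore_windows <- function(profile, panel) {
  dplyr::inner_join(window_proportions(profile), panel$windows,
                    by = c("chrom", "start", "end")) |>
    dplyr::transmute(chrom = .data$chrom, start = .data$start,
                     end = .data$end, z = (.data$q - .data$mu) / .data$sd)
}

#' Call subchromosomal CNV segments by Stouffer combination
#'
#' Scans each chromosome for maximal runs of consecutive windows whose
#' single-window |z| exceeds the seed threshold (same sign), combines each
#' run with [stouffer_z()], and emits a segment when |Z| exceeds
#' `cnv_z_cutoff`: Z > 5 is a microduplication, Z < -5 a microdeletion.
#' Adjacent emitted segments of the same sign separated by one
#' sub-threshold window are merged when the merged combined Z still passes.
#'
#' @param window_z Window z tibble from [zscore_windows()].
#' @param config A [nipt_config()].
#' @return A tibble `chrom`, `start`, `end`, `Z`, `k`, `type` (0 rows when
#'   nothing passes).
#' @export
call_cnv_segments <- function(window_z, config = nipt_config()) {
  empty <- tibble::tibble(chrom = character(), start = double(),
                          end = double(), Z = double(), k = integer(),
                          type = character())
  if (nrow(window_z) == 0) return(empty)
  seed <- config$cnv_seed_z
  cutoff <- config$cnv_z_cutoff

  one_chrom <- function(chrom, start, end, z) {
    o <- order(start)
    start <- start[o]; end <- end[o]; z <- z[o]
    sgn <- ifelse(z > seed, 1L, ifelse(z < -seed, -1L, 0L))
    r <- rle(sgn)
    to <- cumsum(r$lengths)
    from <- to - r$lengths + 1
    nz <- r$values != 0L
    if (!any(nz)) return(NULL)
    from <- from[nz]; to <- to[nz]; sign <- r$values[nz]
    cz <- c(0, cumsum(z))
    k <- to - from + 1
    Z <- (cz[to + 1] - cz[from]) / sqrt(k)
    pass <- abs(Z) > cutoff
    if (!any(pass)) return(NULL)
    from <- from[pass]; to <- to[pass]; sign <- sign[pass]
    Z <- Z[pass]; k <- k[pass]
    # one-gap merge, left to right
    i <- 1
    while (i < length(from)) {
      gap <- from[i + 1] - to[i] - 1
      if (sign[i + 1] == sign[i] && gap == 1) {
        km <- to[i + 1] - from[i] + 1
        zm <- (cz[to[i + 1] + 1] - cz[from[i]]) / sqrt(km)
        if (abs(zm) > cutoff) {
          to[i] <- to[i + 1]; Z[i] <- zm; k[i] <- km
          from <- from[-(i + 1)]; to <- to[-(i + 1)]; sign <- sign[-(i + 1)]
          Z <- Z[-(i + 1)]; k <- k[-(i + 1)]
          next
        }
      }
      i <- i + 1
    }
    data.frame(chrom = chrom, start = start[from], end = end[to],
               Z = Z, k = as.integer(k),
               type = ifelse(Z > 0, "microduplication", "microdeletion"))
  }
  idx <- split(seq_len(nrow(window_z)), window_z$chrom)
  segs <- lapply(names(idx), function(ch) {
    ii <- idx[[ch]]
    one_chrom(ch, window_z$start[ii], window_z$end[ii], window_z$z[ii])
  })
  segs <- segs[!vapply(segs, is.null, TRUE)]
  if (length(segs) == 0) return(empty)
  tibble::as_tibble(do.call(rbind, segs))
}

#' Run the full caller on one corrected profile
#'
#' Estimates the fetal fraction (chrY route, or an override for female
#' fetuses), computes chromosome and window z-scores, applies the
#' trisomy-21/18/13 decision rule, classifies the sex karyotype and calls
#' CNV segments.
#'
#' @param profile A corrected-profile tibble.
#' @param panel A `nipt_panel`.
#' @param config A [nipt_config()].
#' @param ff_override Known fetal fraction (used for female fetuses, or to
#'   bypass the chrY estimate).
#' @param targets Autosomes screened for trisomy.
#' @return A `nipt_call` object: fields `sample_id`, `ff`, `ff_source`,
#'   `z` (chromosome tibble), `decisions`, `sex_karyotype`, `cnv`,
#'   `window_z`.
#' @export
call_sample <- function(profile, panel, config = nipt_config(),
                        ff_override = NULL, targets = c("21", "18", "13")) {
  z <- zscore_chromosomes(profile, panel)
  p <- chromosome_shares(profile)
  p_y <- p$p[p$chrom == "Y"]
  slope <- panel$r_y / 2 - panel$r_y0
  # Y considered present above half the minimal reportable male signal
  has_y <- !is.na(slope) && p_y > panel$r_y0 + 0.5 * config$ff_min * slope
  if (has_y) {
    ff <- estimate_fetal_fraction(profile, panel, "male")
    ff_source <- "chrY"
  } else {
    ff <- if (is.null(ff_override)) NA_real_ else ff_override
    ff_source <- if (is.null(ff_override)) "unknown" else "override"
  }
  decisions <- call_aneuploidy(z, ff, config, targets)
  sex <- classify_sex_karyotype(
    z_x = z$z[z$chrom == "X"], p_y = p_y, ff = ff, panel = panel,
    config = config
  )
  # CNV scan is autosomal: sex-chromosome windows reflect fetal sex dosage,
  # not subchromosomal events, against a female reference. Chromosomes
  # already flagged as whole-chromosome aneuploidies are excluded so a
  # trisomy is not re-reported as a chromosome-length duplication.
  aneuploid <- z$chrom[abs(z$z) > config$z_positive_cutoff]
  wz <- dplyr::filter(zscore_windows(profile, panel),
                      !.data$chrom %in% c("X", "Y", aneuploid))
  cnv <- call_cnv_segments(wz, config)
  structure(
    list(sample_id = profile$sample_id[1], ff = ff, ff_source = ff_source,
         z = z, decisions = decisions, sex_karyotype = sex, cnv = cnv,
         window_z = wz),
    class = "nipt_call"
  )
}

#' @export
print.nipt_call <- function(x, ...) {
  cat("<nipt_call>", x$sample_id, "\n")
  cat(sprintf("  fetal fraction: %s (%s)\n",
              ifelse(is.na(x$ff), "unknown", sprintf("%.1f%%", 100 * x$ff)),
              x$ff_source))
  cat(sprintf("  sex karyotype : %s\n", x$sex_karyotype))
  for (i in seq_len(nrow(x$decisions))) {
    cat(sprintf("  chr%-2s z = %6.2f  %s\n", x$decisions$chrom[i],
                x$decisions$z[i], x$decisions$decision[i]))
  }
  cat(sprintf("  CNV segments  : %d\n", nrow(x$cnv)))
  invisible(x)
}
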