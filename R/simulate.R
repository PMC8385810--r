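#' Fetal-truth description of one simulated pregnancy
#'
#' Collects everything the forward model needs about a sample: the fetal
#' karyotype, fetal sex, fetal fraction, degree of mosaicism, gestational
#' age, any maternal abnormality, optional subchromosomal CNV events and the
#' clinical indication.
#'
#' @param karyotype One of `"euploid"`, `"T21"`, `"T18"`, `"T13"`, `"XO"`,
#'   `"XXY"`, `"XXX"`, `"XYY"`, or `"cnv"` (with `cnv_events` supplied).
#' @param fetal_sex `"male"` or `"female"`. Required whenever `ff > 0`.
#'   Sex-chromosome karyotypes imply their own sex and may leave this `NULL`.
#' @param ff Fetal fraction in \[0, 1\].
#' @param mosaic_fraction Fraction of fetal (placental) DNA carrying the
#'   abnormality, in \[0, 1\]; 1 = non-mosaic.
#' @param ga_weeks Gestational age in weeks (9-36).
#' @param maternal_abnormality Optional maternal sex-chromosome karyotype,
#'   `"XXX"` or `"XO"` (e.g. a maternal 47,XXX, a designed source of
#'   sex-chromosome false positives), or a CNV-event tibble with columns
#'   `chrom`, `start`, `end`, `delta` applied to the maternal genome.
#' @param cnv_events Optional tibble of fetal CNV events with columns
#'   `chrom`, `start`, `end`, `delta` (`delta` = copy change, +1 gain / -1
#'   loss, per 0-based half-open region).
#' @param indication Clinical indication label.
#' @param sample_id Identifier.
#' @return A list of class `sample_truth`.
#' @export
sample_truth <- function(karyotype = "euploid", fetal_sex = NULL,
                         ff = 0.10, mosaic_fraction = 1,
                         ga_weeks = 17, maternal_abnormality = NULL,
                         cnv_events = NULL, indication = "voluntary",
                         sample_id = "sample1") {
  allowed <- c("euploid", "T21", "T18", "T13", "XO", "XXY", "XXX", "XYY", "cnv")
  karyotype <- match.arg(karyotype, allowed)
  sex_implied <- c(XO = "female", XXY = "male", XXX = "female", XYY = "male")
  if (karyotype %in% names(sex_implied)) fetal_sex <- unname(sex_implied[karyotype])
  if (ff > 0 && is.null(fetal_sex)) {
    stop("fetal_sex must be specified when ff > 0")
  }
  stopifnot(ff >= 0, ff <= 1, mosaic_fraction >= 0, mosaic_fraction <= 1,
            ga_weeks >= 9, ga_weeks <= 36)
  if (karyotype == "cnv" && is.null(cnv_events)) {
    stop("karyotype 'cnv' requires cnv_events")
  }
  structure(
    list(karyotype = karyotype, fetal_sex = fetal_sex, ff = ff,
         mosaic_fraction = mosaic_fraction, ga_weeks = ga_weeks,
         maternal_abnormality = maternal_abnormality,
         cnv_events = cnv_events, indication = indication,
         sample_id = sample_id),
    class = "sample_truth"
  )
}

#' Multiplicative GC-bias curve
#'
#' Returns a smooth unimodal function of GC content used to distort expected
#' bin rates: `exp(-amplitude * (gc - optimum)^2 / (2 * width^2))`.
#' `amplitude = 0` gives a flat (unbiased) curve.
#'
#' @param amplitude Strength of the bias (0 = none).
#' @param optimum GC value at which efficiency peaks.
#' @param width Width of the efficiency peak on the GC scale.
#' @return A vectorised function of GC.
#' @examples
#' curve_fn <- gc_bias_curve(amplitude = 1)
#' curve_fn(c(0.35, 0.45, 0.55))
#' @export
gc_bias_curve <- function(amplitude = 0.6, optimum = 0.45, width = 0.12) {
  force(amplitude); force(optimum); force(width)
  function(gc) exp(-amplitude * (gc - optimum)^2 / (2 * width^2))
}

# Per-bin maternal and fetal copy numbers implied by a truth object.
# Copies are per diploid genome: autosomes 2, each X/Y per karyotype.
copy_numbers <- function(truth, bins) {
  n <- nrow(bins)
  mat <- ifelse(bins$chrom == "Y", 0, 2)
  if (!is.null(truth$maternal_abnormality)) {
    ab <- truth$maternal_abnormality
    if (is.data.frame(ab)) {
      for (i in seq_len(nrow(ab))) {
        hit <- bins$chrom == sub("^chr", "", ab$chrom[i]) &
          bins$start < ab$end[i] & bins$end > ab$start[i]
        mat[hit] <- mat[hit] + ab$delta[i]
      }
    } else if (identical(ab, "XXX")) {
      mat[bins$chrom == "X"] <- 3
    } else if (identical(ab, "XO")) {
      mat[bins$chrom == "X"] <- 1
    } else {
      stop("unsupported maternal_abnormality: ", ab)
    }
  }

  sex <- truth$fetal_sex %||% "female"
  fet_eu <- ifelse(bins$chrom == "Y", if (sex == "male") 1 else 0,
                   ifelse(bins$chrom == "X", if (sex == "male") 1 else 2, 2))
  fet <- fet_eu
  kar <- truth$karyotype
  if (kar %in% c("T21", "T18", "T13")) {
    fet[bins$chrom == sub("T", "", kar)] <- 3
  } else if (kar == "XO") {
    fet[bins$chrom == "X"] <- 1; fet[bins$chrom == "Y"] <- 0
  } else if (kar == "XXY") {
    fet[bins$chrom == "X"] <- 2; fet[bins$chrom == "Y"] <- 1
  } else if (kar == "XXX") {
    fet[bins$chrom == "X"] <- 3
  } else if (kar == "XYY") {
    fet[bins$chrom == "X"] <- 1; fet[bins$chrom == "Y"] <- 2
  }
  if (!is.null(truth$cnv_events)) {
    ev <- truth$cnv_events
    for (i in seq_len(nrow(ev))) {
      hit <- bins$chrom == sub("^chr", "", ev$chrom[i]) &
        bins$start < ev$end[i] & bins$end > ev$start[i]
      fet[hit] <- fet[hit] + ev$delta[i]
    }
  }
  # mosaicism dilutes the abnormality toward the sex-matched euploid state
  fet <- fet_eu + truth$mosaic_fraction * (fet - fet_eu)
  list(maternal = mat, fetal = fet)
}

#' Simulate one sample's binned read counts
#'
#' Forward model for shallow-WGS cfDNA: the expected rate of bin *b* is
#' proportional to `bin_length * gc_bias(gc) * copy_factor`, where the copy
#' factor mixes the maternal and fetal per-bin copy numbers at fetal
#' fraction `ff` — on an autosomal trisomy region it equals
#' `1 + ff * mosaic_fraction / 2`. Counts are drawn as a gamma-weighted
#' multinomial (negative-binomial-like overdispersion, controlled by
#' `nb_size`) conditioned to sum exactly to `depth`. Chromosome-Y bins of
#' female-fetus samples receive only a small mapping-noise floor.
#'
#' @param truth A [sample_truth()] object.
#' @param bins Genome-bin tibble with GC attached.
#' @param depth Total fragment count (>= 10,000).
#' @param gc_bias A function of GC, e.g. [gc_bias_curve()].
#' @param nb_size Negative-binomial size parameter (larger = closer to
#'   Poisson); `Inf` gives multinomial sampling.
#' @param y_noise chrY mapping-noise floor as a fraction of the average
#'   per-base rate.
#' @param seed Optional integer seed (same seed + truth = identical counts).
#' @return A bin-count tibble (see [read_bin_counts()]) with `count` filled
#'   for usable bins and 0 elsewhere.
#' @export
simulate_sample <- function(truth, bins, depth = 9e6,
                            gc_bias = gc_bias_curve(), nb_size = 2e4,
                            y_noise = 0.01, seed = NULL) {
  stopifnot(inherits(truth, "sample_truth"), depth >= 1e4)
  validate_genome_bins(bins)
  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    set.seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  cn <- copy_numbers(truth, bins)
  f <- truth$ff
  copy_factor <- (1 - f) * cn$maternal / 2 + f * cn$fetal / 2
  len <- bins$end - bins$start
  lambda <- len * gc_bias(bins$gc) * copy_factor
  # mapping-noise floor so chrY is never an exact zero rate
  lambda[bins$chrom == "Y"] <- lambda[bins$chrom == "Y"] +
    y_noise * len[bins$chrom == "Y"] * gc_bias(bins$gc[bins$chrom == "Y"])
  lambda[!bins$usable] <- 0
  if (all(lambda == 0)) stop("no usable bins with positive rate")
  w <- if (is.finite(nb_size)) {
    lambda * stats::rgamma(length(lambda), shape = nb_size, rate = nb_size)
  } else {
    lambda
  }
  counts <- as.double(stats::rmultinom(1, size = depth, prob = w)[, 1])
  tibble::tibble(
    sample_id = truth$sample_id, run_id = "run1",
    chrom = bins$chrom, start = bins$start, end = bins$end,
    gc = bins$gc, count = counts
  )
}

#' Simulate fetal fraction from gestational age
#'
#' Linear-plus-noise model `ff = intercept + slope * ga_weeks + e`,
#' `e ~ N(0, noise_sd)`, clipped to \[0.01, 0.40\]. The defaults place mean
#' fetal fraction near 10% at the cohort's median gestational age (17 weeks)
#' and are calibrated so that the fetal-fraction / gestational-age Pearson
#' correlation over a cohort-like age distribution is about 0.70.
#'
#' @param ga_weeks Numeric vector of gestational ages in \[9, 36\].
#' @param intercept,slope,noise_sd Model parameters (fractions; slope per
#'   week).
#' @param seed Optional seed.
#' @return Numeric vector of fetal fractions, same length as `ga_weeks`.
#' @examples
#' simulate_ff(c(12, 20, 30), noise_sd = 0, seed = 1)
#' @export
simulate_ff <- function(ga_weeks, intercept = 0.015, slope = 0.005,
                        noise_sd = 0.0145, seed = NULL) {
  stopifnot(all(ga_weeks >= 9), all(ga_weeks <= 36))
  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    set.seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  ff <- intercept + slope * ga_weeks +
    stats::rnorm(length(ga_weeks), 0, noise_sd)
  pmin(pmax(ff, 0.01), 0.40)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
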