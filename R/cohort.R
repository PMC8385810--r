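#' Cohort simulation settings
#'
#' Defines the composition of a simulated screening cohort: the clinical
#' indication mix, per-class abnormality prevalences, the screening-test
#' error model used when generating record-level results, confirmatory-test
#' uptake among screen positives, and the demographic, fetal-fraction and
#' depth models. The defaults emulate a large single-referral-centre NIPT
#' cohort: an indication mix dominated by abnormal serum screening (53.1%)
#' and advanced maternal age (23.0%), confirmed-abnormality prevalences of
#' roughly 0.32% (T21), 0.08% (T18) and 0.04% (T13), and uptake of invasive
#' confirmation near 98% for T21 positives but only ~70-75% for sex-chromosome
#' and T13/T18 positives.
#'
#' @param n_samples Number of pregnancies to simulate.
#' @param indication_mix Named proportions over indication categories
#'   (must sum to 1).
#' @param prevalence Named per-class probabilities that a pregnancy truly
#'   carries each abnormality (`maternal_XXX` denotes a maternal 47,XXX with
#'   a euploid fetus). The remainder is euploid.
#' @param screen_sens Named per-class sensitivity of the screen used for
#'   record-level simulation.
#' @param screen_fp Named per-class probability that a non-carrier screens
#'   positive for the class.
#' @param confirm_uptake Named per-class probability that a screen positive
#'   undergoes confirmatory diagnosis.
#' @param neg_followup Probability that a screen-negative pregnancy has
#'   outcome follow-up (others are `lost`).
#' @param ga_mean,ga_sd Gestational-age model (weeks), clipped to 9-36.
#' @param bmi_mean,bmi_sd Maternal BMI model.
#' @param ff_intercept,ff_slope,ff_noise_sd Fetal-fraction model passed to
#'   [simulate_ff()].
#' @param depth_meanlog,depth_sdlog Log-normal total-fragment model.
#' @param gc_amplitude,gc_optimum,gc_width GC-bias curve parameters
#'   ([gc_bias_curve()]).
#' @param gc_amplitude_sd Between-sample SD of the bias amplitude: real
#'   libraries differ in how strongly GC distorts them, which is what the
#'   correction chain exists to remove.
#' @param nb_size Count overdispersion (see [simulate_sample()]).
#' @param run_size Samples per sequencing run when counts are generated.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 1000,
                        indication_mix = default_indication_mix(),
                        prevalence = default_prevalence(),
                        screen_sens = default_screen_sens(),
                        screen_fp = default_screen_fp(),
                        confirm_uptake = default_confirm_uptake(),
                        neg_followup = 0.95,
                        ga_mean = 16.99, ga_sd = 2.82,
                        bmi_mean = 22.52, bmi_sd = 3.16,
                        ff_intercept = 0.015, ff_slope = 0.005,
                        ff_noise_sd = 0.0145,
                        depth_meanlog = log(9e6), depth_sdlog = 0.15,
                        gc_amplitude = 0.6, gc_optimum = 0.45,
                        gc_width = 0.12, gc_amplitude_sd = 0.2,
                        nb_size = 2e4, run_size = 24, seed = 1L) {
  stopifnot(n_samples >= 0,
            abs(sum(indication_mix) - 1) < 1e-9,
            all(prevalence >= 0 & prevalence <= 1),
            sum(prevalence) < 1,
            all(screen_sens >= 0 & screen_sens <= 1),
            all(screen_fp >= 0 & screen_fp <= 1),
            all(confirm_uptake >= 0 & confirm_uptake <= 1))
  structure(
    list(n_samples = n_samples, indication_mix = indication_mix,
         prevalence = prevalence, screen_sens = screen_sens,
         screen_fp = screen_fp, confirm_uptake = confirm_uptake,
         neg_followup = neg_followup,
         ga_mean = ga_mean, ga_sd = ga_sd,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         ff_intercept = ff_intercept, ff_slope = ff_slope,
         ff_noise_sd = ff_noise_sd,
         depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
         gc_amplitude = gc_amplitude, gc_optimum = gc_optimum,
         gc_width = gc_width, gc_amplitude_sd = gc_amplitude_sd,
         nb_size = nb_size, run_size = run_size,
         seed = seed),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_indication_mix <- function() {
  counts <- c(
    AMA = 3295, aMSS = 7608, thickened_NT = 120, aUS = 112,
    twin_IVF = 429, missed_screening = 5, voluntary = 2524,
    surgery_contraindication = 14, other_risk = 209
  )
  counts / sum(counts)
}

#' @rdname cohort_spec
#' @export
default_prevalence <- function() {
  c(T21 = 46, T18 = 11, T13 = 6, XO = 22, XXY = 8, XXX = 3, XYY = 5,
    maternal_XXX = 2, cnv = 2, other_aneuploidy = 2) / 14316
}

#' @rdname cohort_spec
#' @export
default_screen_sens <- function() {
  c(T21 = 45 / 46, T18 = 1, T13 = 1, XO = 1, XXY = 1, XXX = 1, XYY = 1,
    cnv = 1, other_aneuploidy = 1)
}

#' @rdname cohort_spec
#' @export
default_screen_fp <- function() {
  c(T21 = 4, T18 = 5, T13 = 10, XO = 7, XXY = 8, XXX = 6, XYY = 4,
    cnv = 12, other_aneuploidy = 29) / 14316
}

#' @rdname cohort_spec
#' @export
default_confirm_uptake <- function() {
  sca <- 44 / 63
  c(T21 = 48 / 49, T18 = 13 / 16, T13 = 12 / 16,
    XO = sca, XXY = sca, XXX = sca, XYY = sca,
    cnv = 19 / 45, other_aneuploidy = 19 / 45)
}

# Per-indication maternal-age models (mean, sd); AMA is truncated at 35.
.indication_age <- tibble::tribble(
  ~indication, ~age_mean, ~age_sd,
  "AMA", 37.39, 2.37,
  "aMSS", 28.06, 3.52,
  "thickened_NT", 27.58, 3.54,
  "aUS", 27.69, 3.22,
  "twin_IVF", 28.81, 3.27,
  "missed_screening", 25.80, 2.99,
  "voluntary", 27.59, 3.68,
  "surgery_contraindication", 27.64, 2.12,
  "other_risk", 28.44, 3.41
)

#' Simulate a screening cohort with known truth
#'
#' Draws, per pregnancy: an indication, maternal age (AMA implies age >= 35),
#' gestational age, BMI, fetal fraction (via [simulate_ff()]), a true
#' abnormality class from the prevalence model, a record-level screen result
#' from the sensitivity/false-positive model, and a confirmation status from
#' the uptake model. With `generate_counts = TRUE` a bin-count table is also
#' simulated for each sample (batched into sequencing runs of
#' `spec$run_size`) together with the full truth objects.
#'
#' @param spec A [cohort_spec()].
#' @param bins Genome-bin tibble; required when `generate_counts = TRUE`.
#' @param generate_counts Also run the count-level forward model per sample?
#' @return A list with `records` (tibble, one row per pregnancy), `truths`
#'   (list of [sample_truth()]; only abnormal-relevant fields populated when
#'   counts are skipped) and `counts` (list of bin-count tibbles, or `NULL`).
#' @export
simulate_cohort <- function(spec, bins = NULL, generate_counts = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_samples == 0) {
    return(list(records = empty_cohort_records(), truths = list(),
                counts = if (generate_counts) list() else NULL))
  }
  if (generate_counts && is.null(bins)) {
    stop("bins are required when generate_counts = TRUE")
  }
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)

  n <- spec$n_samples
  ids <- sprintf("S%05d", seq_len(n))
  indication <- sample(names(spec$indication_mix), n, replace = TRUE,
                       prob = spec$indication_mix)
  age_par <- .indication_age[match(indication, .indication_age$indication), ]
  age <- stats::rnorm(n, age_par$age_mean, age_par$age_sd)
  age <- pmin(pmax(age, 16), 51)
  age[indication == "AMA"] <- pmax(age[indication == "AMA"], 35)
  ga <- pmin(pmax(stats::rnorm(n, spec$ga_mean, spec$ga_sd), 9), 36)
  bmi <- pmin(pmax(stats::rnorm(n, spec$bmi_mean, spec$bmi_sd), 13.67), 42.36)
  ff <- simulate_ff(ga, spec$ff_intercept, spec$ff_slope, spec$ff_noise_sd)

  classes <- names(spec$prevalence)
  truth_class <- sample(
    c(classes, "euploid"), n, replace = TRUE,
    prob = c(spec$prevalence, 1 - sum(spec$prevalence))
  )
  fetal_sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  implied <- c(XO = "female", XXX = "female", XXY = "male", XYY = "male")
  hit <- truth_class %in% names(implied)
  fetal_sex[hit] <- implied[truth_class[hit]]

  # record-level screen: carriers miss with 1 - sens; non-carriers can
  # false-positive for any class (at most one reported class per sample)
  nipt_result <- rep("negative", n)
  screen_class <- function(tc) {
    if (tc %in% names(spec$screen_sens)) {
      if (stats::runif(1) < spec$screen_sens[[tc]]) return(tc)
      return("negative")
    }
    if (tc == "maternal_XXX") return("XXX") # maternal 47,XXX reads as fetal XXX
    fp <- spec$screen_fp
    u <- stats::runif(1)
    cum <- cumsum(fp)
    k <- which(u < cum)
    if (length(k) > 0) names(fp)[k[1]] else "negative"
  }
  nipt_result <- vapply(truth_class, screen_class, "")

  is_tp <- nipt_result != "negative" & nipt_result == truth_class
  confirmation <- rep(NA_character_, n)
  pos <- nipt_result != "negative"
  for (i in which(pos)) {
    up <- spec$confirm_uptake[[nipt_result[i]]]
    confirmation[i] <- if (stats::runif(1) < up) {
      if (is_tp[i]) "confirmed_positive" else "confirmed_negative"
    } else {
      "declined"
    }
  }
  neg <- !pos
  followed <- stats::runif(n) < spec$neg_followup
  confirmation[neg & followed] <-
    ifelse(truth_class[neg & followed] %in% names(spec$screen_sens),
           "confirmed_positive", "confirmed_negative")
  confirmation[neg & !followed] <- "lost"

  run_id <- sprintf("run%03d", (seq_len(n) - 1) %/% spec$run_size + 1)
  records <- tibble::tibble(
    sample_id = ids, run_id = run_id, indication = indication,
    maternal_age = age, ga_weeks = ga, bmi = bmi, ff = ff,
    fetal_sex = fetal_sex, truth_class = truth_class,
    nipt_result = nipt_result, confirmation = confirmation
  )

  truths <- purrr::pmap(
    list(ids, truth_class, fetal_sex, ff, ga, indication),
    function(id, tc, sex, f, g, ind) {
      kar <- if (tc %in% c("euploid", "maternal_XXX", "cnv",
                           "other_aneuploidy")) "euploid" else tc
      cnv <- NULL
      if (tc == "cnv") {
        kar <- "cnv"
        cnv <- tibble::tibble(chrom = "4", start = 1e6, end = 4e6, delta = -1)
      }
      sample_truth(
        karyotype = kar, fetal_sex = sex, ff = f, ga_weeks = g,
        maternal_abnormality = if (tc == "maternal_XXX") "XXX" else NULL,
        cnv_events = cnv, indication = ind, sample_id = id
      )
    }
  )

  counts <- NULL
  if (generate_counts) {
    amp <- pmax(0, stats::rnorm(n, spec$gc_amplitude, spec$gc_amplitude_sd))
    depth <- round(stats::rlnorm(n, spec$depth_meanlog, spec$depth_sdlog))
    counts <- purrr::map(seq_len(n), function(i) {
      gc_bias <- gc_bias_curve(amp[i], spec$gc_optimum, spec$gc_width)
      x <- simulate_sample(truths[[i]], bins, depth = depth[i],
                           gc_bias = gc_bias, nb_size = spec$nb_size)
      x$run_id <- run_id[i]
      x
    })
  }
  list(records = records, truths = truths, counts = counts)
}

empty_cohort_records <- function() {
  tibble::tibble(
    sample_id = character(), run_id = character(), indication = character(),
    maternal_age = double(), ga_weeks = double(), bmi = double(),
    ff = double(), fetal_sex = character(), truth_class = character(),
    nipt_result = character(), confirmation = character()
  )
}
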