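#' Simulate and build a euploid reference panel
#'
#' Generates euploid pregnancies (mostly female fetuses, plus male fetuses
#' with known fetal fraction for the chrY calibration) across several
#' sequencing runs, normalizes each run with the three-step chain and
#' builds the reference panel. The LOESS-corrected profiles of each run are
#' returned as companion sets: a new test sample should be normalized
#' *inside* one of these runs ([normalize_sample_in_run()]), so that the
#' run-median reference of the test sample is the same one the panel saw —
#' rotating test samples across the companion sets cancels run-median batch
#' effects between panel and test exactly.
#'
#' @param bins Genome-bin tibble.
#' @param n_runs Number of simulated sequencing runs.
#' @param females_per_run,males_per_run Euploid samples per run.
#' @param depth Total fragments per sample.
#' @param gc_amplitude,gc_amplitude_sd Mean and between-sample SD of the
#'   GC-bias amplitude ([gc_bias_curve()]).
#' @param nb_size Count overdispersion ([simulate_sample()]).
#' @param config A [nipt_config()].
#' @param seed Integer seed.
#' @return A list of class `nipt_reference`: `panel` (a `nipt_panel`),
#'   `companions` (list of `n_runs` lists of LOESS-corrected profiles) and
#'   `male_ff` (the known male fetal fractions).
#' @export
simulate_reference_panel <- function(bins, n_runs = 4, females_per_run = 25,
                                     males_per_run = 5, depth = 9e6,
                                     gc_amplitude = 0.6,
                                     gc_amplitude_sd = 0.2, nb_size = 2e4,
                                     config = nipt_config(), seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  female_profiles <- list()
  male_profiles <- list()
  male_ff <- numeric(0)
  companions <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run <- sprintf("run%02d", r)
    ffm <- simulate_ff(stats::runif(males_per_run, 12, 25))
    truths <- c(
      purrr::map(seq_len(females_per_run), function(i) {
        sample_truth("euploid", "female", ff = 0.1,
                     sample_id = sprintf("%sF%02d", run, i))
      }),
      purrr::map(seq_len(males_per_run), function(i) {
        sample_truth("euploid", "male", ff = ffm[i],
                     sample_id = sprintf("%sM%02d", run, i))
      })
    )
    counts <- purrr::map(truths, function(tr) {
      amp <- max(0, stats::rnorm(1, gc_amplitude, gc_amplitude_sd))
      x <- simulate_sample(tr, bins, depth = depth,
                           gc_bias = gc_bias_curve(amp), nb_size = nb_size)
      x$run_id <- run
      x
    })
    loess_profs <- purrr::map(counts, loess_gc_correct, bins = bins,
                              span = config$loess_span)
    full <- purrr::map(intra_run_normalize(loess_profs), residualize_linear)
    companions[[r]] <- loess_profs
    female_profiles <- c(female_profiles, full[seq_len(females_per_run)])
    male_profiles <- c(male_profiles,
                       full[females_per_run + seq_len(males_per_run)])
    male_ff <- c(male_ff, ffm)
  }
  panel <- build_reference_panel(female_profiles, male_profiles, male_ff,
                                 config)
  structure(list(panel = panel, companions = companions, male_ff = male_ff),
            class = "nipt_reference")
}

#' Normalize and call a new sample against a simulated reference
#'
#' Convenience wrapper: normalizes `counts` inside one of the reference's
#' companion runs and runs [call_sample()].
#'
#' @param counts Bin-count tibble of the sample.
#' @param reference A `nipt_reference` from [simulate_reference_panel()].
#' @param bins Genome-bin tibble.
#' @param run_index Which companion run to join (recycled modulo the number
#'   of runs; rotate across samples to average out run effects).
#' @param config A [nipt_config()].
#' @param ... Passed to [call_sample()] (e.g. `ff_override`).
#' @return A `nipt_call`.
#' @export
call_with_reference <- function(counts, reference, bins, run_index = 1L,
                                config = nipt_config(), ...) {
  stopifnot(inherits(reference, "nipt_reference"))
  r <- ((run_index - 1L) %% length(reference$companions)) + 1L
  prof <- normalize_sample_in_run(counts, reference$companions[[r]], bins,
                                  config)
  call_sample(prof, reference$panel, config, ...)
}
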