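# Shared fixtures, built lazily and cached for the whole test session.
# All randomness is seeded so the suite is deterministic.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, builder(), envir = .fx)
  }
  get(name, envir = .fx, inherits = FALSE)
}

# full hg19-scale 1-Mb grid
fx_bins <- function() fixture("bins", function() nipt_bins(seed = 1L))

# small five-chromosome genome for cheap unit tests
fx_mini_bins <- function() {
  fixture("mini_bins", function() {
    make_genome_bins(
      tibble::tibble(chrom = c("1", "2", "21", "X", "Y"),
                     length = c(60e6, 50e6, 30e6, 40e6, 12e6))
    ) |>
      simulate_gc_content(seed = 11L)
  })
}

# mini-genome reference (fast; for unit tests of the caller)
fx_mini_ref <- function() {
  fixture("mini_ref", function() {
    simulate_reference_panel(fx_mini_bins(), n_runs = 2,
                             females_per_run = 18, males_per_run = 5,
                             depth = 2e5, seed = 21L)
  })
}

# genome-wide references at the default depth and at 3M fragments
fx_ref9 <- function() {
  fixture("ref9", function() {
    simulate_reference_panel(fx_bins(), n_runs = 4, females_per_run = 25,
                             males_per_run = 5, depth = 9e6, seed = 31L)
  })
}

fx_ref3 <- function() {
  fixture("ref3", function() {
    simulate_reference_panel(fx_bins(), n_runs = 4, females_per_run = 40,
                             males_per_run = 5, depth = 3e6, seed = 41L)
  })
}

# simulate one case and call it against a reference, rotating companion runs
sim_and_call <- function(truth, ref, bins, depth, i = 1L, ff_override = NULL,
                         gc_amplitude = 0.6, config = nipt_config()) {
  cts <- simulate_sample(truth, bins, depth = depth,
                         gc_bias = gc_bias_curve(gc_amplitude))
  call_with_reference(cts, ref, bins, run_index = i, config = config,
                      ff_override = ff_override)
}
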