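# synthetic one-bin-per-chromosome profile whose chromosome shares are set
# directly (autosomal values sum to 1 on the analysis scale)
profile_with_shares <- function(panel, tweak = c()) {
  tbl <- panel$chromosomes
  v <- tbl$mu
  names(v) <- tbl$chrom
  v[names(tweak)] <- tweak
  tibble::tibble(
    sample_id = "syn", run_id = "r", chrom = tbl$chrom,
    start = 0, end = 1e6, gc = 0.45, usable = TRUE, value = unname(v)
  )
}

test_that("degenerate panels are rejected", {
  p <- tibble::tibble(
    sample_id = "a", run_id = "r",
    chrom = rep(c("1", "2", "21", "X", "Y"), each = 30),
    start = rep((0:29) * 1e6, 5), end = rep((1:30) * 1e6, 5),
    gc = 0.45, usable = TRUE, value = 1
  )
  identical_profiles <- lapply(1:30, function(i) {
    q <- p
    q$sample_id <- paste0("s", i)
    q
  })
  expect_error(build_reference_panel(identical_profiles), "zero panel SD")
  expect_error(build_reference_panel(identical_profiles[1:5]),
               "needs >= 30")
})

test_that("leave-one-out panel z-scores are centred at zero", {
  ref <- fx_mini_ref()
  loo <- ref$panel$loo_qc
  centred <- tapply(loo$z, loo$chrom, mean)
  expect_true(all(abs(centred) < 1e-6))
})

test_that("z-scores are exact at the panel mean and at +3 SD", {
  panel <- fx_mini_ref()$panel
  at_mean <- profile_with_shares(panel)
  z0 <- zscore_chromosomes(at_mean, panel)
  expect_true(all(abs(z0$z) < 1e-9))
  # chrX is outside the autosomal denominator, so the shift is exact
  mu_x <- panel$chromosomes$mu[panel$chromosomes$chrom == "X"]
  sd_x <- panel$chromosomes$sd[panel$chromosomes$chrom == "X"]
  at_3sd <- profile_with_shares(panel, c(X = mu_x + 3 * sd_x))
  z3 <- zscore_chromosomes(at_3sd, panel)
  expect_equal(z3$z[z3$chrom == "X"], 3, tolerance = 1e-9)
})

test_that("trisomy z-scores match the analytic copy-factor oracle", {
  # needs the genome-wide reference: on a small genome chr21 is so large a
  # share that the GC fits absorb part of the trisomy signal
  ref <- fx_ref3()
  bins <- fx_bins()
  panel <- ref$panel
  ff <- 0.10
  # oracle: share shift = mu_21 * (1 + ff/2) / (1 + mu_21 * ff/2) - mu_21,
  # in panel SD units
  mu <- panel$chromosomes$mu[panel$chromosomes$chrom == "21"]
  sdv <- panel$chromosomes$sd[panel$chromosomes$chrom == "21"]
  oracle_z <- (mu * (1 + ff / 2) / (1 + mu * ff / 2) - mu) / sdv
  set.seed(301)
  z21 <- vapply(1:100, function(i) {
    truth <- sample_truth("T21", ifelse(i %% 2 == 1, "male", "female"),
                          ff = ff, sample_id = "t")
    cl <- sim_and_call(truth, ref, bins, depth = 3e6, i = i,
                       ff_override = ff)
    cl$decisions$z[cl$decisions$chrom == "21"]
  }, 0)
  expect_lt(abs(mean(z21) - oracle_z) / oracle_z, 0.05)
})

test_that("chrY fetal fraction is zero at the female baseline and clips", {
  panel <- fx_mini_ref()$panel
  at_baseline <- profile_with_shares(panel, c(Y = panel$r_y0))
  expect_equal(estimate_fetal_fraction(at_baseline, panel, "male"), 0)
  below <- profile_with_shares(panel, c(Y = panel$r_y0 / 2))
  expect_warning(ff <- estimate_fetal_fraction(below, panel, "male"),
                 "clipping")
  expect_equal(ff, 0)
  # female fetus: override passes through, otherwise unknown
  expect_equal(estimate_fetal_fraction(at_baseline, panel, "female",
                                       override = 0.07), 0.07)
  expect_true(is.na(estimate_fetal_fraction(at_baseline, panel, "female")))
})

test_that("chrY fetal fraction recovers the simulated truth", {
  ref <- fx_mini_ref()
  bins <- fx_mini_bins()
  set.seed(302)
  est <- vapply(1:40, function(i) {
    truth <- sample_truth("euploid", "male", ff = 0.10, sample_id = "m")
    cts <- simulate_sample(truth, bins, depth = 2e5)
    prof <- normalize_sample_in_run(cts, ref$companions[[1 + i %% 2]], bins)
    estimate_fetal_fraction(prof, ref$panel, "male")
  }, 0)
  expect_lt(abs(mean(est) - 0.10), 0.02)
})

test_that("the decision rule encodes the gray zone and the ff gate", {
  cfg <- nipt_config()
  z_of <- function(z21) tibble::tibble(chrom = "21", p = 0.02, z = z21)
  dec <- function(z21, ff) {
    call_aneuploidy(z_of(z21), ff, cfg)$decision
  }
  expect_equal(dec(2.99, 0.08), "negative")
  expect_equal(dec(3.00, 0.08), "negative")
  expect_equal(dec(4.20, 0.05), "gray_positive")
  expect_equal(dec(5.00, 0.08), "positive")
  expect_equal(dec(7.00, 0.03), "no_call_low_ff")
  expect_equal(dec(7.00, NA), "no_call_low_ff")
  expect_equal(dec(1.00, 0.039), "no_call_low_ff")
})

test_that("sex karyotypes are recovered from simulation", {
  ref <- fx_mini_ref()
  bins <- fx_mini_bins()
  set.seed(303)
  call_sex <- function(karyotype, n, ff = 0.10, maternal = NULL) {
    vapply(seq_len(n), function(i) {
      truth <- sample_truth(karyotype, if (karyotype == "euploid") "female",
                            ff = ff, maternal_abnormality = maternal,
                            sample_id = "s")
      cl <- sim_and_call(truth, ref, bins, depth = 2e5, i = i,
                         ff_override = ff)
      cl$sex_karyotype
    }, "")
  }
  xo <- call_sex("XO", 100)
  expect_gte(mean(xo == "XO"), 0.95)
  expect_true(all(call_sex("XXY", 25) == "XXY"))
  expect_true(all(call_sex("XYY", 25) == "XYY"))
  expect_true(all(call_sex("XXX", 25) == "XXX"))
  # maternal 47,XXX with a euploid female fetus is a designed false positive
  expect_true(all(call_sex("euploid", 10, maternal = "XXX") == "XXX"))
  # euploid male fetuses are XY with a chrY-based fetal fraction
  set.seed(304)
  truth <- sample_truth("euploid", "male", ff = 0.10, sample_id = "xy")
  cl <- sim_and_call(truth, ref, bins, depth = 2e5)
  expect_equal(cl$sex_karyotype, "XY")
  expect_equal(cl$ff_source, "chrY")
})

test_that("Stouffer combination equals its closed form", {
  expect_equal(stouffer_z(2.4), 2.4)
  expect_equal(stouffer_z(rep(3, 4)), 6)
  expect_error(stouffer_z(numeric(0)), "empty")
  expect_error(stouffer_z(c(1, NA)), "non-finite")
  set.seed(305)
  for (i in 1:50) {
    z <- rnorm(sample(1:40, 1))
    expect_equal(stouffer_z(z), sum(z) / sqrt(length(z)), tolerance = 1e-12)
  }
  # null distribution: combining N(0,1) windows stays N(0,1)
  zmat <- matrix(rnorm(25 * 1e4), nrow = 25)
  combined <- colSums(zmat) / sqrt(25)
  expect_lt(abs(mean(combined)), 0.05)
  expect_lt(abs(sd(combined) - 1), 0.05)
})

window_track <- function(z, chrom = "4") {
  n <- length(z)
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * 1e6,
                 end = seq_len(n) * 1e6, z = z)
}

test_that("CNV segmentation follows the Stouffer rule exactly", {
  cfg <- nipt_config()
  expect_equal(nrow(call_cnv_segments(window_track(rep(0, 50)), cfg)), 0)
  # a three-window run of (4, 5, 4): Z = 13 / sqrt(3) > 5
  tr <- window_track(c(rep(0, 10), 4, 5, 4, rep(0, 10)))
  seg <- call_cnv_segments(tr, cfg)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$Z, 13 / sqrt(3), tolerance = 1e-12)
  expect_equal(seg$k, 3L)
  expect_equal(seg$type, "microduplication")
  expect_equal(c(seg$start, seg$end), c(10e6, 13e6))
  # sign symmetry
  seg_del <- call_cnv_segments(window_track(-c(rep(0, 5), 4, 5, 4)), cfg)
  expect_equal(seg_del$type, "microdeletion")
  # a weak run below the combined cutoff is not emitted
  expect_equal(nrow(call_cnv_segments(window_track(c(2.5, 2.5)), cfg)), 0)
  # one-gap merge keeps a single segment when the merged Z still passes
  tr2 <- window_track(c(rep(0, 4), 3, 3, 3, 0, 3, 3, 3, rep(0, 4)))
  seg2 <- call_cnv_segments(tr2, cfg)
  expect_equal(nrow(seg2), 1)
  expect_equal(seg2$k, 7L)
  expect_equal(seg2$Z, 18 / sqrt(7), tolerance = 1e-12)
  # window order does not matter
  shuffled <- tr2[sample(nrow(tr2)), ]
  expect_equal(call_cnv_segments(shuffled, cfg), seg2)
})

test_that("detection power rises with fetal fraction", {
  ref <- fx_mini_ref()
  bins <- fx_mini_bins()
  set.seed(306)
  power_at <- function(ff, n = 30) {
    hits <- vapply(seq_len(n), function(i) {
      truth <- sample_truth("T21", "female", ff = ff, sample_id = "p")
      cl <- sim_and_call(truth, ref, bins, depth = 2e5, i = i,
                         ff_override = ff)
      cl$decisions$decision[cl$decisions$chrom == "21"] %in%
        c("positive", "gray_positive")
    }, TRUE)
    mean(hits)
  }
  p <- vapply(c(0.04, 0.08, 0.12), power_at, 0)
  expect_true(all(diff(p) >= 0))
  expect_gte(p[3], 0.95)
})

test_that("calls do not depend on chromosome processing order", {
  ref <- fx_mini_ref()
  bins <- fx_mini_bins()
  set.seed(307)
  truth <- sample_truth("T21", "male", ff = 0.12, sample_id = "o")
  cts <- simulate_sample(truth, bins, depth = 2e5)
  prof <- normalize_sample_in_run(cts, ref$companions[[1]], bins)
  cl1 <- call_sample(prof, ref$panel)
  cl2 <- call_sample(prof[sample(nrow(prof)), ], ref$panel)
  expect_equal(cl1$decisions, cl2$decisions)
  expect_equal(cl1$cnv, cl2$cnv)
  expect_equal(cl1$ff, cl2$ff)
})
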