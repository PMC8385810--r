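# Independent expectation oracle: per-bin rates rebuilt from first
# principles (length x GC efficiency x mixture copy number, chrY noise
# floor), without touching the simulator's internals.
oracle_bin_rates <- function(bins, karyotype, fetal_sex, ff, mosaic = 1,
                             gc_bias = gc_bias_curve(), y_noise = 0.01) {
  len <- bins$end - bins$start
  mat <- ifelse(bins$chrom == "Y", 0, 2)
  fet <- ifelse(bins$chrom == "Y", if (fetal_sex == "male") 1 else 0,
                ifelse(bins$chrom == "X", if (fetal_sex == "male") 1 else 2, 2))
  fet_eu <- fet
  if (karyotype == "T21") fet[bins$chrom == "21"] <- 3
  fet <- fet_eu + mosaic * (fet - fet_eu)
  lam <- len * gc_bias(bins$gc) * ((1 - ff) * mat / 2 + ff * fet / 2)
  lam[bins$chrom == "Y"] <- lam[bins$chrom == "Y"] +
    y_noise * (len * gc_bias(bins$gc))[bins$chrom == "Y"]
  lam[!bins$usable] <- 0
  lam
}

oracle_share <- function(bins, chrom, ...) {
  lam <- oracle_bin_rates(bins, ...)
  sum(lam[bins$chrom == chrom]) / sum(lam)
}

test_that("zero fetal fraction makes any fetal abnormality invisible", {
  bins <- fx_mini_bins()
  base <- oracle_share(bins, "21", karyotype = "euploid",
                       fetal_sex = "female", ff = 0)
  t21 <- oracle_share(bins, "21", karyotype = "T21",
                      fetal_sex = "female", ff = 0)
  expect_identical(base, t21)
  set.seed(101)
  truth <- sample_truth("T21", "female", ff = 0, sample_id = "z")
  shares <- replicate(400, {
    x <- simulate_sample(truth, bins, depth = 2e5)
    sum(x$count[x$chrom == "21"]) / sum(x$count)
  })
  se <- sd(shares) / sqrt(length(shares))
  expect_lt(abs(mean(shares) - base), 4 * se)
})

test_that("a trisomy shifts the chromosome share by 1 + ff/2 (oracle)", {
  bins <- fx_mini_bins()
  expected <- oracle_share(bins, "21", karyotype = "T21",
                           fetal_sex = "female", ff = 0.10)
  base <- oracle_share(bins, "21", karyotype = "euploid",
                       fetal_sex = "female", ff = 0.10)
  # the oracle itself obeys the closed form (up to renormalization)
  expect_equal(expected / base * (1 + 0.05 * base) / 1, 1.05,
               tolerance = 1e-9)
  set.seed(102)
  truth <- sample_truth("T21", "female", ff = 0.10, sample_id = "t")
  shares <- replicate(1000, {
    x <- simulate_sample(truth, bins, depth = 2e5)
    sum(x$count[x$chrom == "21"]) / sum(x$count)
  })
  se <- sd(shares) / sqrt(length(shares))
  expect_lt(abs(mean(shares) - expected), 3.5 * se)
})

test_that("single-region copy events scale by 1 + ff * mosaic / 2", {
  bins <- fx_mini_bins()
  cases <- list(c(ff = 0.10, m = 1), c(ff = 0.15, m = 1), c(ff = 0.10, m = 0.5))
  set.seed(103)
  for (cs in cases) {
    ev <- tibble::tibble(chrom = "2", start = 10e6, end = 20e6, delta = 1)
    truth <- sample_truth("cnv", "female", ff = cs[["ff"]],
                          mosaic_fraction = cs[["m"]], cnv_events = ev,
                          sample_id = "c")
    in_ev <- bins$chrom == "2" & bins$start >= 10e6 & bins$end <= 20e6
    lam0 <- oracle_bin_rates(bins, "euploid", "female", cs[["ff"]])
    reps <- replicate(400, {
      x <- simulate_sample(truth, bins, depth = 2e5)
      sum(x$count[in_ev]) / sum(x$count)
    })
    factor <- cs[["ff"]] * cs[["m"]] / 2
    ev_share0 <- sum(lam0[in_ev]) / sum(lam0)
    expected <- ev_share0 * (1 + factor) / (1 + ev_share0 * factor)
    se <- sd(reps) / sqrt(length(reps))
    expect_lt(abs(mean(reps) - expected), 3.5 * se)
  }
})

test_that("the same seed and truth give bit-identical counts", {
  bins <- fx_mini_bins()
  truth <- sample_truth("T18", "male", ff = 0.12, sample_id = "r")
  a <- simulate_sample(truth, bins, depth = 1e5, seed = 77L)
  b <- simulate_sample(truth, bins, depth = 1e5, seed = 77L)
  expect_identical(a$count, b$count)
})

test_that("counts are conserved: every sample sums to its depth", {
  bins <- fx_mini_bins()
  set.seed(104)
  for (i in 1:8) {
    kar <- sample(c("euploid", "T21", "XO", "XXY"), 1)
    sex <- if (kar %in% c("XO", "XXY")) NULL else "female"
    depth <- sample(c(1e4, 5e4, 2e5), 1)
    x <- simulate_sample(sample_truth(kar, sex, ff = runif(1, 0.04, 0.2),
                                      sample_id = "s"),
                         bins, depth = depth)
    expect_identical(sum(x$count), as.double(depth))
    expect_true(all(x$count >= 0))
    expect_true(all(x$count[!bins$usable] == 0))
  }
})

test_that("a fetal signal requires a fetal sex", {
  expect_error(sample_truth("T21", ff = 0.1), "fetal_sex")
  expect_error(sample_truth("cnv", "female", ff = 0.1), "cnv_events")
  expect_silent(sample_truth("euploid", NULL, ff = 0))
})

test_that("fetal fraction follows gestational age as specified", {
  ga <- seq(10, 30, length.out = 50)
  ff0 <- simulate_ff(ga, noise_sd = 0, seed = 1L)
  expect_equal(cor(ga, ff0), 1)
  set.seed(105)
  ga2 <- pmin(pmax(rnorm(1e4, 16.99, 2.82), 9), 36)
  ff_null <- simulate_ff(ga2, slope = 0)
  expect_lt(abs(cor(ga2, ff_null)), 0.05)
  # clipping bounds
  lo <- simulate_ff(rep(9, 100), intercept = -1)
  expect_true(all(lo == 0.01))
  hi <- simulate_ff(rep(36, 100), intercept = 1)
  expect_true(all(hi == 0.40))
  expect_error(simulate_ff(8), "ga_weeks")
})

test_that("a degenerate indication mix is honoured exactly", {
  spec <- cohort_spec(n_samples = 300,
                      indication_mix = c(AMA = 1), seed = 5L)
  out <- simulate_cohort(spec)
  expect_true(all(out$records$indication == "AMA"))
  expect_true(all(out$records$maternal_age >= 35))
})

test_that("class prevalences follow the binomial oracle", {
  prev <- default_prevalence()
  prev["T21"] <- 0.0034
  spec <- cohort_spec(n_samples = 1e4, prevalence = prev, seed = 6L)
  out <- simulate_cohort(spec)
  n_t21 <- sum(out$records$truth_class == "T21")
  expect_gte(n_t21, qbinom(0.025, 1e4, 0.0034))
  expect_lte(n_t21, qbinom(0.975, 1e4, 0.0034))
})

test_that("the default indication mix is dominated by serum screening", {
  spec <- cohort_spec(n_samples = 1e4, seed = 7L)
  out <- simulate_cohort(spec)
  amss_pct <- 100 * mean(out$records$indication == "aMSS")
  expect_lt(abs(amss_pct - 53.14), 2)
})

test_that("an empty cohort is empty, not an error", {
  out <- simulate_cohort(cohort_spec(n_samples = 0))
  expect_equal(nrow(out$records), 0)
  expect_length(out$truths, 0)
})

test_that("records and truths are in bijection by sample id", {
  bins <- fx_mini_bins()
  spec <- cohort_spec(n_samples = 25, run_size = 10, seed = 8L,
                      depth_meanlog = log(5e4))
  out <- simulate_cohort(spec, bins, generate_counts = TRUE)
  truth_ids <- vapply(out$truths, function(t) t$sample_id, "")
  expect_identical(out$records$sample_id, truth_ids)
  expect_false(anyDuplicated(truth_ids) > 0)
  count_ids <- vapply(out$counts, function(x) x$sample_id[1], "")
  expect_identical(count_ids, truth_ids)
  # runs are batched as configured
  expect_equal(as.integer(table(out$records$run_id)), c(10L, 10L, 5L))
  # same spec, same seed: identical cohort
  again <- simulate_cohort(spec, bins, generate_counts = TRUE)
  expect_identical(out$records, again$records)
  expect_identical(out$counts[[3]]$count, again$counts[[3]]$count)
})
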