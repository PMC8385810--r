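#' Screening confusion statistics
#'
#' Computes the screening-performance quantities from the counts a
#' follow-up study yields: `P` screen positives, `TP` confirmed true
#' positives, `FN` screen negatives later diagnosed positive, and `tn_pool`
#' confirmed-negative screen negatives (the followed-up pool; pregnancies
#' without a genetic diagnosis or with incomplete outcome are excluded by
#' the caller before counting). Then `PPV = TP / P`,
#' `sensitivity = TP / (TP + FN)`, `FP = P - TP`,
#' `specificity = TN / (TN + FP)` and `NPV = TN / (TN + FN)`.
#' Undefined ratios (zero denominators) are returned as `NA`, matching the
#' "NA" cells of sparse strata.
#'
#' @param P,TP,FN Non-negative integer counts with `TP <= P`.
#' @param tn_pool Confirmed-negative screen negatives (TN).
#' @return A one-row tibble with `P`, `TP`, `FP`, `FN`, `TN`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` (proportions in \[0, 1\]).
#' @examples
#' confusion_stats(P = 49, TP = 45, FN = 1, tn_pool = 14000)
#' @export
confusion_stats <- function(P, TP, FN, tn_pool = NA_real_) {
  stopifnot(P >= 0, TP >= 0, FN >= 0, TP <= P)
  FP <- P - TP
  TN <- tn_pool
  ratio <- function(num, den) {
    if (is.na(den) || den == 0) NA_real_ else num / den
  }
  tibble::tibble(
    P = P, TP = TP, FP = FP, FN = FN, TN = TN,
    sensitivity = ratio(TP, TP + FN),
    specificity = ratio(TN, TN + FP),
    ppv = ratio(TP, P),
    npv = ratio(TN, TN + FN)
  )
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` over the table
#' `rbind(c(a, b), c(c, d))`, with 1 degree of freedom; no Yates continuity
#' correction is applied.
#'
#' @param a,b,c,d Non-negative cell counts; rows are the groups, columns
#'   the outcome.
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_2x2(63, 3232, 24, 7584)
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(o < 0)) stop("counts must be non-negative")
  if (any(rowSums(o) == 0) || any(colSums(o) == 0)) {
    stop("zero margin: chi-squared statistic undefined")
  }
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  stat <- sum((o - e)^2 / e)
  tibble::tibble(statistic = stat, df = 1,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: requires at least three
#' observations and non-constant inputs.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(x, y)
}

#' Half-up percentage rounding for display
#'
#' Renders a proportion as a percentage rounded half-up to `digits`
#' decimals (R's own `round` is half-even); internal statistics stay at
#' full precision.
#'
#' @param p Proportion in \[0, 1\] (or `NA`).
#' @param digits Decimal places.
#' @return Numeric percentage.
#' @examples
#' format_pct(45 / 49) # 91.84
#' @export
format_pct <- function(p, digits = 2) {
  scaled <- p * 100 * 10^digits
  floor(scaled + 0.5 + sqrt(.Machine$double.eps)) / 10^digits
}

#' Indication- and class-stratified screening report
#'
#' Reproduces the reporting layout of a screening study from a cohort
#' record table ([simulate_cohort()] or real follow-up data): a per-class
#' performance table (P, TP, FN, sensitivity, specificity, PPV, NPV against
#' the followed-up negative pool), a per-indication table (n, share, mean ±
#' SD maternal and gestational age, P(TP) and PPV per class), and headline
#' rates (overall positive rate, confirmed fraction among positives).
#' `declined` and `lost` outcomes are excluded from the confirmed pools.
#'
#' @param records Cohort record tibble with columns `sample_id`,
#'   `indication`, `maternal_age`, `ga_weeks`, `nipt_result` (`"negative"`
#'   or a class label) and `confirmation` (`confirmed_positive`,
#'   `confirmed_negative`, `declined`, `lost`).
#' @return A list of class `nipt_report`: `by_class`, `by_indication`,
#'   `headline`.
#' @export
stratified_report <- function(records) {
  if (nrow(records) == 0) {
    return(structure(list(
      by_class = tibble::tibble(), by_indication = tibble::tibble(),
      headline = tibble::tibble(n = 0L, positives = 0L,
                                positive_rate_pct = NA_real_,
                                confirmed_fraction_pct = NA_real_)
    ), class = "nipt_report"))
  }
  n <- nrow(records)
  pos <- dplyr::filter(records, .data$nipt_result != "negative")
  neg <- dplyr::filter(records, .data$nipt_result == "negative")
  tn_pool_all <- sum(neg$confirmation == "confirmed_negative", na.rm = TRUE)

  classes <- sort(unique(pos$nipt_result))
  by_class <- purrr::map_dfr(classes, function(k) {
    pk <- dplyr::filter(pos, .data$nipt_result == k)
    tp <- sum(pk$confirmation == "confirmed_positive", na.rm = TRUE)
    fn <- if ("truth_class" %in% names(records)) {
      sum(neg$truth_class == k &
            neg$confirmation == "confirmed_positive", na.rm = TRUE)
    } else {
      0L
    }
    dplyr::bind_cols(
      tibble::tibble(class = k),
      confusion_stats(P = nrow(pk), TP = tp, FN = fn, tn_pool = tn_pool_all)
    )
  })

  by_indication <- records |>
    dplyr::group_by(.data$indication) |>
    dplyr::summarise(
      n = dplyr::n(),
      share_pct = format_pct(dplyr::n() / !!n),
      maternal_age_mean = mean(.data$maternal_age),
      maternal_age_sd = stats::sd(.data$maternal_age),
      ga_mean = mean(.data$ga_weeks),
      ga_sd = stats::sd(.data$ga_weeks),
      P = sum(.data$nipt_result != "negative"),
      TP = sum(.data$nipt_result != "negative" &
                 .data$confirmation == "confirmed_positive", na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(ppv = ifelse(.data$P > 0, .data$TP / .data$P, NA_real_)) |>
    dplyr::arrange(dplyr::desc(.data$n))

  headline <- tibble::tibble(
    n = n,
    positives = nrow(pos),
    positive_rate_pct = format_pct(nrow(pos) / n),
    confirmed_fraction_pct = if (nrow(pos) > 0) {
      format_pct(sum(pos$confirmation == "confirmed_positive",
                     na.rm = TRUE) / nrow(pos))
    } else {
      NA_real_
    }
  )
  structure(list(by_class = by_class, by_indication = by_indication,
                 headline = headline),
            class = "nipt_report")
}

#' @export
print.nipt_report <- function(x, ...) {
  cat("<nipt_report>\n")
  cat(sprintf("  n = %d, positives = %d (%.2f%%), confirmed %.2f%%\n",
              x$headline$n, x$headline$positives,
              x$headline$positive_rate_pct,
              x$headline$confirmed_fraction_pct))
  cat("  per-class performance:\n")
  print(x$by_class, n = Inf)
  invisible(x)
}
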