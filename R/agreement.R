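#' Percentage error between gold-standard and algorithm class time
#'
#' `PE = 100 * (gold - predicted) / gold`. Positive values mean the
#' algorithm underestimates the gold-standard (video) total; PE cancels
#' over- and underestimation at group level.
#'
#' @param gold_seconds gold-standard total time in a class (> 0).
#' @param predicted_seconds algorithm total time in the same class.
#' @return percentage error (vectorized).
#' @export
percentage_error <- function(gold_seconds, predicted_seconds) {
  if (any(!is.finite(gold_seconds)) || any(gold_seconds <= 0)) {
    stop("gold_seconds must be positive (undefined denominator otherwise)",
         call. = FALSE)
  }
  100 * (gold_seconds - predicted_seconds) / gold_seconds
}

#' Absolute percentage error
#'
#' `APE = |PE|`; unlike PE it does not cancel over- and underestimation,
#' so it reflects individual-level error.
#'
#' @inheritParams percentage_error
#' @return absolute percentage error (>= 0, vectorized).
#' @export
absolute_percentage_error <- function(gold_seconds, predicted_seconds) {
  abs(percentage_error(gold_seconds, predicted_seconds))
}

#' Acceptability of a percentage error
#'
#' Agreement between 90% and 110% of the gold standard, i.e.
#' `|PE| <= 10`, is considered acceptable (closed band).
#'
#' @param pe percentage error(s).
#' @return logical vector.
#' @export
is_within_acceptable_limits <- function(pe) {
  if (any(!is.finite(pe))) stop("pe must be finite", call. = FALSE)
  abs(pe) <= 10
}

#' Median with distribution-free 95% confidence interval
#'
#' Summarizes per-participant errors as the sample median with a
#' conservative distribution-free CI from binomial order statistics:
#' the lower/upper bounds are the order statistics at the largest rank
#' `l` with `pbinom(l - 1, n, 0.5) <= 0.025` and at `n + 1 - l`, giving
#' coverage of at least 95%. For n < 6 no such ranks exist and the
#' range (min, max) is returned with a warning.
#'
#' @param values numeric vector, length >= 3.
#' @return list with `median`, `ci_lower`, `ci_upper`, `n`, `method`.
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  n <- length(values)
  s <- sort(values)
  l <- stats::qbinom(0.025, n, 0.5)
  if (l < 1L) {
    warning("n too small for the exact binomial CI; reporting the range",
            call. = FALSE)
    ci <- c(s[1L], s[n])
    method <- "range"
  } else {
    ci <- c(s[l], s[n + 1L - l])
    method <- "binomial-order-statistic"
  }
  list(median = stats::median(values), ci_lower = ci[1L], ci_upper = ci[2L],
       n = n, method = method)
}

#' Bland-Altman limits of agreement
#'
#' For paired measurements of the same quantity by two methods, reports
#' the mean difference (a - b) and the 95% limits of agreement
#' `mean +/- 1.96 * SD` with the sample (n - 1) standard deviation.
#'
#' @param a,b numeric vectors of paired measurements (seconds), length
#'   >= 2.
#' @return list with `mean_difference`, `loa_lower`, `loa_upper`,
#'   `sd_difference`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_difference = m, loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       sd_difference = s, n = length(d))
}

#' ICC(2,1): two-way random effects, absolute agreement, single measures
#'
#' Inter-rater reliability from the two-way ANOVA mean squares of a
#' complete subjects x raters matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, where MSR, MSC
#' and MSE are the subject, rater and residual mean squares.
#'
#' @param ratings numeric matrix, n subjects (rows) x k raters
#'   (columns), no missing cells.
#' @return ICC value (1 when all cells are identical).
#' @export
icc_two_way_random_absolute <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters",
                             call. = FALSE)
  if (any(!is.finite(ratings))) {
    stop("ratings must be complete (no missing cells)", call. = FALSE)
  }
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(as.vector(row(ratings))),
                   rater = factor(as.vector(col(ratings))))
  # only the mean squares are used; silence anova()'s F-test caveat on
  # perfect-fit (zero-residual) data such as identical rater columns
  tab <- suppressWarnings(stats::anova(stats::aov(y ~ subject + rater,
                                                  data = df)))
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) return(1)  # zero variance everywhere: perfect agreement
  (msr - mse) / denom
}

#' Per-participant agreement between annotations and classifications
#'
#' For every participant in a cohort, classifies the recording and
#' computes PE and APE per activity class against the gold-standard
#' annotation totals. Classes with zero gold time for a participant are
#' excluded with a warning (undefined denominator).
#'
#' @param cohort list of participants; each element is a list with
#'   components `recording` ([acc_recording()]) and `annotation`
#'   ([activity_annotation()]).
#' @param params an [algorithm_parameters()] object.
#' @return data frame with columns `subject_id, class, gold_s,
#'   predicted_s, pe, ape`.
#' @export
compute_agreement <- function(cohort, params = algorithm_parameters()) {
  stopifnot(length(cohort) > 0L)
  rows <- lapply(cohort, function(part) {
    series <- classify_recording(part$recording, params)
    .agreement_rows(part$recording$subject_id,
                    annotation_totals(part$annotation), class_totals(series))
  })
  do.call(rbind, rows)
}

# shared by compute_agreement and the grid evaluator
.agreement_rows <- function(subject_id, gold, predicted) {
  classes <- activity_levels()
  keep <- gold[classes] > 0
  if (any(!keep)) {
    warning(sprintf("subject %s: zero gold time in class(es) %s; excluded",
                    subject_id, paste(classes[!keep], collapse = ", ")),
            call. = FALSE)
  }
  cls <- classes[keep]
  data.frame(
    subject_id = subject_id, class = cls,
    gold_s = as.numeric(gold[cls]), predicted_s = as.numeric(predicted[cls]),
    pe = percentage_error(gold[cls], predicted[cls]),
    ape = absolute_percentage_error(gold[cls], predicted[cls]),
    row.names = NULL
  )
}

#' Group-level agreement report
#'
#' Summarizes per-participant PE and APE per class as median and 95% CI,
#' and flags each class as acceptable when the median APE lies within
#' the +/-10% band.
#'
#' @param per_participant data frame from [compute_agreement()].
#' @return data frame with one row per class: medians, CIs and the
#'   acceptability flag.
#' @export
agreement_report <- function(per_participant) {
  stopifnot(all(c("class", "pe", "ape") %in% names(per_participant)))
  classes <- intersect(activity_levels(), unique(per_participant$class))
  rows <- lapply(classes, function(cl) {
    sub <- per_participant[per_participant$class == cl, ]
    pe <- group_summary(sub$pe)
    ape <- group_summary(sub$ape)
    data.frame(class = cl, n = pe$n,
               median_pe = pe$median, pe_ci_low = pe$ci_lower,
               pe_ci_high = pe$ci_upper,
               median_ape = ape$median, ape_ci_low = ape$ci_lower,
               ape_ci_high = ape$ci_upper,
               acceptable = is_within_acceptable_limits(ape$median),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
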