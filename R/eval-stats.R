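#' Round half away from zero
#'
#' Published diagnostic tables conventionally round 0.5 up; R's
#' `round()` rounds half to even. Used everywhere printed values are
#' reproduced.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Confusion counts from recording-level predictions
#'
#' @param pred Logical vector of predicted labels.
#' @param truth Logical vector of reference labels (same length).
#' @return Object of class `confusion_counts` with fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth differ in length (", length(pred), " vs ",
         length(truth), ")")
  if (length(pred) == 0) stop("empty input: no recordings to score")
  pred <- as.logical(pred); truth <- as.logical(truth)
  confusion_counts(TP = sum(pred & truth), FP = sum(pred & !truth),
                   FN = sum(!pred & truth), TN = sum(!pred & !truth))
}

#' @rdname confusion
#' @param TP,FP,FN,TN Non-negative integer counts.
#' @export
confusion_counts <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0, TP + FP + FN + TN > 0)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c("wheeze", "no wheeze"),
                              predicted = c("wheeze", "no wheeze")))
  print(m)
  invisible(x)
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' Diagnostic metrics from a confusion table
#'
#' Computes PPV, sensitivity, specificity, accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, and the F1 score
#' `2*PPV*sensitivity/(PPV+sensitivity)`, each with a 95% Wilson score
#' confidence interval (F1's interval uses the effective proportion
#' `2TP/(2TP+FP+FN)` with its Wilson bounds). A metric whose denominator
#' is zero is defined as 0 and flagged in the `undefined` field.
#'
#' @param c A `confusion_counts` object.
#' @param conf Confidence level for the intervals.
#' @return Object of class `metric_report`: a data.frame with one row
#'   per metric (`estimate`, `lo`, `hi`) plus an `undefined` attribute.
#' @export
metrics <- function(c, conf = 0.95) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$TP + c$TN + c$FP + c$FN
  safe <- function(num, den) if (den > 0) num / den else 0
  ppv  <- safe(c$TP, c$TP + c$FP)
  sens <- safe(c$TP, c$TP + c$FN)
  spec <- safe(c$TN, c$TN + c$FP)
  acc  <- (c$TP + c$TN) / total
  f1   <- if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  und <- c(ppv = c$TP + c$FP == 0, sensitivity = c$TP + c$FN == 0,
           specificity = c$TN + c$FP == 0, accuracy = FALSE,
           f1 = ppv + sens == 0)
  ci <- rbind(ppv = wilson_ci(c$TP, c$TP + c$FP, conf),
              sensitivity = wilson_ci(c$TP, c$TP + c$FN, conf),
              specificity = wilson_ci(c$TN, c$TN + c$FP, conf),
              accuracy = wilson_ci(c$TP + c$TN, total, conf),
              f1 = wilson_ci(2 * c$TP, 2 * c$TP + c$FP + c$FN, conf))
  out <- data.frame(metric = c("ppv", "sensitivity", "specificity",
                               "accuracy", "f1"),
                    estimate = c(ppv, sens, spec, acc, f1),
                    lo = ci[, 1], hi = ci[, 2], row.names = NULL)
  attr(out, "undefined") <- und
  attr(out, "counts") <- c
  class(out) <- c("metric_report", "data.frame")
  out
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  d <- as.data.frame(x)
  d$estimate <- round(d$estimate, digits)
  d$lo <- round(d$lo, digits); d$hi <- round(d$hi, digits)
  print(d, row.names = FALSE)
  und <- attr(x, "undefined")
  if (any(und)) cat("undefined (set to 0):",
                    paste(names(und)[und], collapse = ", "), "\n")
  invisible(x)
}

# agreement bands of Landis & Koch, as used for kappa interpretation
kappa_interpretation <- function(k) {
  if (is.na(k)) return(NA_character_)
  if (k < 0) "poor"
  else if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost_perfect"
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e)/(1 - p_e)` from a square
#' cross-tabulation of two raters' labels, with the standard
#' interpretation bands attached (0.41-0.60 moderate, 0.61-0.80
#' substantial, 0.81-1.00 almost perfect, etc.).
#'
#' @param table Square contingency matrix (rater 1 in rows, rater 2 in
#'   columns), or a 2-column matrix/data.frame of per-item labels.
#' @return Object of class `kappa_result`: `kappa`, `n_raters`,
#'   `interpretation`, `undefined` flag.
#' @export
cohens_kappa <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (!is.matrix(table) || nrow(table) != ncol(table) ||
      !all(table == round(table))) {
    # treat as per-item labels
    if (ncol(table) != 2) stop("expected a square count matrix or 2 label columns")
    lv <- sort(unique(c(table[, 1], table[, 2])))
    table <- table(factor(table[, 1], lv), factor(table[, 2], lv))
    table <- matrix(as.numeric(table), length(lv), length(lv))
  }
  n <- sum(table)
  if (n == 0) stop("empty table")
  po <- sum(diag(table)) / n
  pe <- sum(rowSums(table) * colSums(table)) / n^2
  if (abs(1 - pe) < 1e-12) {
    k <- NA_real_
    undef <- TRUE
  } else {
    k <- (po - pe) / (1 - pe)
    undef <- FALSE
  }
  structure(list(kappa = k, n_raters = 2L,
                 interpretation = kappa_interpretation(k),
                 undefined = undef),
            class = "kappa_result")
}

#' Fleiss' kappa for three or more raters
#'
#' @param counts Matrix of n_items rows x n_categories columns, each cell
#'   the number of raters assigning that category to that item; all rows
#'   must sum to the same number of raters (>= 3).
#' @return `kappa_result`.
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  m <- unique(rowSums(counts))
  if (length(m) != 1) stop("all items must be rated by the same number of raters")
  if (m < 3) stop("Fleiss' kappa here requires >= 3 raters (use cohens_kappa)")
  n <- nrow(counts)
  p_j <- colSums(counts) / (n * m)
  P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (abs(1 - Pe) < 1e-12) {
    k <- NA_real_; undef <- TRUE
  } else {
    k <- (Pbar - Pe) / (1 - Pe); undef <- FALSE
  }
  structure(list(kappa = k, n_raters = as.integer(m),
                 interpretation = kappa_interpretation(k),
                 undefined = undef),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("kappa = %s (%d raters): %s agreement\n",
              if (is.na(x$kappa)) "undefined" else sprintf("%.3f", x$kappa),
              x$n_raters, x$interpretation %||% "NA"))
  invisible(x)
}

#' Chi-square / Fisher test with the expected-count selection rule
#'
#' Computes the expected counts of the contingency table; when more than
#' 20% of cells have expected count below 5 a Fisher exact test is used
#' (network algorithm for small tables, seeded Monte-Carlo with 1e5
#' draws when exhaustive computation is infeasible), otherwise Pearson's
#' chi-squared test (without continuity correction, matching the plain
#' Pearson statistic).
#'
#' @param t Contingency matrix of non-negative integer counts.
#' @param mc_draws Monte-Carlo draws for large Fisher tables.
#' @param seed Seed for the Monte-Carlo path.
#' @return List of class `assoc_test`: `test` (`"chisq"` or
#'   `"fisher"`), `p_value`, `statistic` (chi-square only), `expected`,
#'   `frac_expected_lt5`.
#' @export
select_and_run_test <- function(t, mc_draws = 1e5, seed = 1L) {
  t <- as.matrix(t)
  if (any(t < 0) || any(t != round(t))) stop("counts must be non-negative integers")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("degenerate margins: empty row or column")
  n <- sum(t)
  expected <- outer(rowSums(t), colSums(t)) / n
  frac <- mean(expected < 5)
  if (frac > 0.20) {
    big <- n > 200 && prod(dim(t)) > 4
    res <- if (big)
      with_seed(seed, stats::fisher.test(t, simulate.p.value = TRUE,
                                         B = mc_draws))
    else stats::fisher.test(t)
    out <- list(test = "fisher", p_value = res$p.value, statistic = NA_real_,
                expected = expected, frac_expected_lt5 = frac,
                monte_carlo = big)
  } else {
    res <- suppressWarnings(stats::chisq.test(t, correct = FALSE))
    out <- list(test = "chisq", p_value = res$p.value,
                statistic = unname(res$statistic),
                expected = expected, frac_expected_lt5 = frac,
                monte_carlo = FALSE)
  }
  class(out) <- "assoc_test"
  out
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s test: p = %.4g (%.0f%% of expected counts < 5)\n",
              if (x$test == "chisq") "Pearson chi-squared" else "Fisher exact",
              x$p_value, 100 * x$frac_expected_lt5))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, the correction applied to post hoc
#' comparisons.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param m Number of comparisons (defaults to `length(pvals)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1), m >= 1)
  pmin(1, m * pvals)
}

#' Reconstruct confusion tables from published aggregates
#'
#' Given the total number of scored recordings, the number of
#' reference-positive and predicted-positive recordings, and a printed
#' (rounded) sensitivity percentage, enumerates every integer TP whose
#' rounded sensitivity matches, completing each candidate table as
#' FP = n_pred_pos - TP, FN = n_true_pos - TP, TN = remainder.
#'
#' @param n_total Total scored recordings.
#' @param n_true_pos Reference-positive count.
#' @param n_pred_pos Predicted-positive count.
#' @param printed_sensitivity_pct Printed sensitivity, percent (integer
#'   precision).
#' @return List of `confusion_counts`, one per consistent TP; empty with
#'   attribute `inconsistent = TRUE` when no TP matches.
#' @export
reconstruct_from_aggregates <- function(n_total, n_true_pos, n_pred_pos,
                                        printed_sensitivity_pct) {
  stopifnot(n_true_pos <= n_total, n_pred_pos <= n_total)
  out <- list()
  for (tp in 0:min(n_true_pos, n_pred_pos)) {
    if (round_half_up(100 * tp / n_true_pos) == printed_sensitivity_pct) {
      tn <- n_total - n_true_pos - n_pred_pos + tp
      if (tn < 0) next
      out[[length(out) + 1]] <- confusion_counts(
        TP = tp, FP = n_pred_pos - tp, FN = n_true_pos - tp, TN = tn)
    }
  }
  if (length(out) == 0) attr(out, "inconsistent") <- TRUE
  out
}
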