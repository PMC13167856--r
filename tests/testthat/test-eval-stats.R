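test_that("confusion counts partition the recordings", {
  pred  <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  truth <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  cc <- confusion(pred, truth)
  expect_equal(c(cc$TP, cc$FP, cc$FN, cc$TN), c(2, 1, 1, 2))

  all_right <- confusion(truth, truth)
  expect_equal(all_right$FP + all_right$FN, 0)

  expect_error(confusion(logical(0), logical(0)), "empty")
  expect_error(confusion(c(TRUE, FALSE), TRUE), "length")
})

test_that("metrics reproduce their formulas with Wilson intervals", {
  cc <- confusion_counts(TP = 149, FP = 68, FN = 122, TN = 1161)
  m <- metrics(cc)
  est <- setNames(m$estimate, m$metric)
  expect_equal(round_half_up(100 * est[["accuracy"]]), 87)
  expect_equal(round_half_up(100 * est[["ppv"]]), 69)
  expect_equal(round_half_up(100 * est[["f1"]]), 61)
  expect_equal(est[["accuracy"]], (149 + 1161) / 1500)
  expect_equal(est[["f1"]],
               2 * est[["ppv"]] * est[["sensitivity"]] /
                 (est[["ppv"]] + est[["sensitivity"]]))
  expect_true(all(m$lo <= m$estimate & m$estimate <= m$hi))

  # degenerate denominators: defined 0 and flagged
  none <- metrics(confusion_counts(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_equal(none$estimate[none$metric == "ppv"], 0)
  expect_true(attr(none, "undefined")[["ppv"]])

  perfect <- metrics(confusion_counts(TP = 10, FP = 0, FN = 0, TN = 10))
  expect_true(all(perfect$estimate == 1))
})

test_that("F1 lies between PPV and sensitivity for random tables", {
  set.seed(61)
  for (i in 1:200) {
    cc <- confusion_counts(TP = rpois(1, 20) + 1, FP = rpois(1, 10),
                           FN = rpois(1, 10), TN = rpois(1, 50))
    est <- setNames(metrics(cc)$estimate, metrics(cc)$metric)
    expect_gte(est[["f1"]], min(est[["ppv"]], est[["sensitivity"]]) - 1e-12)
    expect_lte(est[["f1"]], max(est[["ppv"]], est[["sensitivity"]]) + 1e-12)
  }
})

test_that("Wilson intervals achieve nominal coverage", {
  set.seed(62)
  n <- 80
  p <- 0.3
  reps <- 10000
  ks <- rbinom(reps, n, p)
  covered <- vapply(ks, function(k) {
    ci <- wheezr:::wilson_ci(k, n)
    p >= ci[1] && p <= ci[2]
  }, logical(1))
  expect_gte(mean(covered) * 100, 93)
  expect_lte(mean(covered) * 100, 97)
})

test_that("Cohen's kappa matches hand computation and the 2x2 closed form", {
  # perfect agreement across >= 2 categories
  perf <- cohens_kappa(diag(c(10, 15)))
  expect_equal(perf$kappa, 1)
  expect_equal(perf$interpretation, "almost_perfect")

  # worked table: p_o = 35/50 = 0.7, p_e = 0.5 -> kappa = 0.40
  k <- cohens_kappa(matrix(c(20, 10, 5, 15), 2))
  expect_equal(k$kappa, 0.4)
  expect_equal(k$interpretation, "fair")

  # a table in the moderate band
  km <- cohens_kappa(matrix(c(30, 10, 5, 25), 2))
  expect_gt(km$kappa, 0.41); expect_lt(km$kappa, 0.60)
  expect_equal(km$interpretation, "moderate")

  # closed form 2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d)) on random tables
  set.seed(63)
  for (i in 1:500) {
    a <- rpois(1, 20); b <- rpois(1, 8); c_ <- rpois(1, 8); d <- rpois(1, 20)
    if (a + b + c_ + d == 0) next
    tab <- matrix(c(a, c_, b, d), 2)  # rows rater 1, cols rater 2
    closed <- 2 * (a * d - b * c_) /
      ((a + b) * (b + d) + (a + c_) * (c_ + d))
    if (!is.finite(closed)) next
    expect_equal(cohens_kappa(tab)$kappa, closed, tolerance = 1e-12)
  }

  # single category everywhere: chance agreement is 1, kappa undefined
  und <- cohens_kappa(matrix(c(30, 0, 0, 0), 2))
  expect_true(und$undefined)
})

test_that("Fleiss' kappa matches direct arithmetic and a random-rater null", {
  # unanimous raters
  un <- fleiss_kappa(matrix(c(3, 0, 0, 3, 3, 0, 0, 3, 0, 3), 5, 2,
                            byrow = TRUE))
  expect_equal(un$kappa, 1)

  # hand-computed 3-rater, 5-item, 2-category table
  counts <- matrix(c(3, 0,
                     2, 1,
                     1, 2,
                     0, 3,
                     2, 1), 5, 2, byrow = TRUE)
  m <- 3; n <- 5
  p_j <- colSums(counts) / (n * m)
  P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  expected <- (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
  expect_equal(fleiss_kappa(counts)$kappa, expected, tolerance = 1e-12)

  # three independent raters drawing from the same marginal: kappa ~ 0
  set.seed(64)
  items <- 2000
  ratings <- matrix(rbinom(items * 3, 1, 0.35), items, 3)
  counts0 <- cbind(rowSums(ratings == 0), rowSums(ratings == 1))
  expect_lt(abs(fleiss_kappa(counts0)$kappa), 0.05)

  expect_error(fleiss_kappa(matrix(c(2, 1, 0, 1), 2)), ">= 3 raters")
  expect_error(fleiss_kappa(matrix(c(3, 0, 1, 2), 2)), "same number")
})

test_that("the expected-count rule selects chi-square vs Fisher", {
  hom <- select_and_run_test(matrix(50, 2, 2))
  expect_equal(hom$test, "chisq")
  expect_equal(hom$p_value, 1)

  # expected counts 1.5/1.5/8.5/8.5: half the cells < 5 -> Fisher
  small <- select_and_run_test(matrix(c(1, 2, 9, 8), 2))
  expect_equal(small$test, "fisher")
  expect_equal(small$frac_expected_lt5, 0.5)
  expect_equal(sort(unique(as.vector(small$expected))), c(1.5, 8.5))
  expect_equal(small$p_value,
               stats::fisher.test(matrix(c(1, 2, 9, 8), 2))$p.value)

  expect_error(select_and_run_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
  expect_error(select_and_run_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("chi-square p agrees with a permutation oracle on healthy tables", {
  set.seed(65)
  for (i in 1:3) {
    tab <- matrix(rpois(6, 40) + 20, 2, 3)
    res <- select_and_run_test(tab)
    expect_equal(res$test, "chisq")
    # permutation null with fixed margins
    B <- 4000
    stat <- function(t) {
      e <- outer(rowSums(t), colSums(t)) / sum(t)
      sum((t - e)^2 / e)
    }
    sims <- r2dtable(B, rowSums(tab), colSums(tab))
    p_mc <- mean(vapply(sims, stat, 1) >= stat(tab) - 1e-9)
    se <- sqrt(max(p_mc * (1 - p_mc), 1 / B) / B)
    expect_lt(abs(res$p_value - p_mc), 3 * se + 0.005)
  }
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.018, 3), 0.054)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0, 7), 0)
  expect_equal(bonferroni(c(0.01, 0.2, 0.6)), c(0.03, 0.6, 1))
  # matches the stats library on uncapped values
  expect_equal(bonferroni(c(0.01, 0.02, 0.03)),
               stats::p.adjust(c(0.01, 0.02, 0.03), "bonferroni"))
})

test_that("aggregate reconstruction enumerates consistent confusion tables", {
  cands <- reconstruct_from_aggregates(1500, 271, 217, 55)
  expect_equal(vapply(cands, `[[`, 1, "TP"), c(148, 149, 150))
  for (cc in cands) {
    expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 1500)
    expect_equal(cc$TP + cc$FN, 271)
    expect_equal(cc$TP + cc$FP, 217)
    expect_equal(round_half_up(100 * cc$TP / 271), 55)
  }

  # infeasible printed sensitivity flags inconsistency
  empty <- reconstruct_from_aggregates(100, 50, 20, 100)
  expect_length(empty, 0)
  expect_true(attr(empty, "inconsistent"))
})

test_that("per-stratum evaluation recomputes metrics within each stratum", {
  set.seed(66)
  strata <- rep(c("a", "b"), each = 30)
  truth <- rbinom(60, 1, 0.4) == 1
  pred <- truth
  pred[sample(60, 10)] <- !pred[sample(60, 10)]
  tab <- evaluate_by_stratum(pred, truth, strata)
  expect_setequal(unique(tab$stratum), c("a", "b"))
  ix <- strata == "a"
  ma <- metrics(confusion(pred[ix], truth[ix]))
  expect_equal(tab$estimate[tab$stratum == "a"], ma$estimate)
})
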