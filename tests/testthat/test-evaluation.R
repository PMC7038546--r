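test_that("exact intervals reproduce known operating points and the tail-sum oracle", {
  expect_equal(r1(exact_ci(41, 43)), c(lower = 84.2, upper = 99.4))
  expect_equal(r1(exact_ci(16, 16)), c(lower = 79.4, upper = 100.0))
  expect_equal(exact_ci(0, 10)[["lower"]], 0)
  expect_equal(exact_ci(10, 10)[["upper"]], 1)
  expect_error(exact_ci(1, 0), "at least 1")
  # oracle equivalence by bisection on the binomial tail sums
  expect_equal(unname(exact_ci(7, 9)), oracle_ci_bisect(7, 9), tolerance = 1e-8)
  for (n in c(1, 5, 12, 30)) {
    for (x in 0:n) {
      expect_equal(unname(exact_ci(x, n)), oracle_ci_bisect(x, n),
                   tolerance = 1e-8, label = sprintf("x=%d n=%d", x, n))
    }
  }
})

test_that("kappa matches published rows and is symmetric in the positive class", {
  expect_equal(r2(cohen_kappa(confusion_matrix(42, 19, 18, 10117))), 0.69)
  expect_equal(r2(cohen_kappa(confusion_matrix(28, 9, 15, 5049))), 0.70)
  expect_equal(cohen_kappa(confusion_matrix(5, 0, 0, 5)), 1)
  expect_equal(cohen_kappa(confusion_matrix(10, 0, 0, 0)), 1)  # degenerate, perfect
  expect_equal(cohen_kappa(confusion_matrix(0, 10, 0, 0)), 0)  # degenerate, disjoint
  set.seed(3)
  for (i in 1:50) {
    cm <- confusion_matrix(sample(0:30, 1), sample(0:30, 1),
                           sample(0:30, 1), sample(1:30, 1))
    swapped <- confusion_matrix(cm$tn, cm$fn, cm$fp, cm$tp)
    expect_equal(cohen_kappa(cm), cohen_kappa(swapped))
  }
})

test_that("test characteristics reproduce headline validation rows", {
  ch <- characteristics(confusion_matrix(41, 280, 2, 4778))
  expect_equal(r1(ch$sensitivity), c(est = 95.3, lower = 84.2, upper = 99.4))
  expect_equal(r1(ch$specificity[["est"]]), 94.5)
  expect_equal(r1(ch$ppv), c(est = 12.8, lower = 9.3, upper = 16.9))
  expect_equal(r1(ch$npv[["est"]]), 100.0)

  ch2 <- characteristics(confusion_matrix(16, 0, 27, 5058))
  expect_equal(r1(ch2$ppv), c(est = 100.0, lower = 79.4, upper = 100.0))
  expect_equal(r1(ch2$sensitivity), c(est = 37.2, lower = 23.0, upper = 53.3))
  expect_equal(r1(ch2$calculated_t1_proportion), 0.3)
  expect_equal(r1(ch2$true_t1_proportion), 0.8)
})

test_that("the PPV-undefined convention is switchable", {
  cm <- confusion_matrix(0, 1, 11, 9347)
  default <- characteristics(cm)
  expect_false(default$ppv_defined)
  expect_true(is.na(default$ppv[["est"]]))
  standard <- characteristics(cm, ppv_convention = "standard")
  expect_true(standard$ppv_defined)
  expect_equal(standard$ppv[["est"]], 0)
  # with no positive calls at all, both conventions are undefined
  none <- confusion_matrix(0, 0, 5, 5)
  expect_true(is.na(characteristics(none, ppv_convention = "standard")$ppv[["est"]]))
})

test_that("confusion cross-tabulation is exact and validates its inputs", {
  calls <- data.frame(person_id = c("a", "b", "c", "d"),
                      call = c("T1D", "T1D", "T2D", "T2D"))
  labels <- data.frame(person_id = c("a", "b", "c", "d"),
                       true_type = c("T1D", "T2D", "T1D", "T2D"))
  cm <- confusion(calls, labels)
  expect_identical(unlist(cm), c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  perfect <- confusion(calls, data.frame(person_id = calls$person_id,
                                         true_type = calls$call))
  expect_identical(perfect$fp + perfect$fn, 0L)
  expect_error(confusion(calls[0, ], labels), "no calls")
  expect_error(confusion(calls, labels[1:2, ]), "no label")
})

test_that("stratified evaluation partitions the all-ages matrix and complements T2D", {
  set.seed(21)
  n <- 400
  cohort <- data.frame(
    person_id = sprintf("p%03d", 1:n),
    age_at_diagnosis = runif(n, 2, 90),
    true_type = sample(c("T1D", "T2D"), n, TRUE, prob = c(0.2, 0.8)))
  calls <- data.frame(person_id = cohort$person_id,
                      call = sample(c("T1D", "T2D"), n, TRUE, prob = c(0.25, 0.75)))
  res <- evaluate_stratified(cohort, list(alg = calls), strata = c(20, 40))
  expect_identical(nrow(res), 4L)
  all_row <- res[res$stratum == "all", ]
  strat <- res[res$stratum != "all", ]
  for (cell in c("tp", "fp", "fn", "tn")) {
    expect_identical(sum(strat[[cell]]), all_row[[cell]])
  }
  # T2D sensitivity equals T1D specificity (binary complement identity)
  cm1 <- confusion(calls, cohort)
  cm2 <- confusion(calls, cohort, positive = "T2D")
  expect_equal(cm2$tp / (cm2$tp + cm2$fn), cm1$tn / (cm1$tn + cm1$fp))
  # empty stratum yields undefined metrics, not an error
  young <- cohort[cohort$age_at_diagnosis > 45, ]
  res2 <- evaluate_stratified(young, list(alg = calls[calls$person_id %in%
                                                        young$person_id, ]),
                              strata = c(20, 40))
  expect_true(is.na(res2$sensitivity[res2$stratum == "<20"]))
})

test_that("the moving-average proportion curve behaves on constant and ramp inputs", {
  n <- 300
  cohort <- data.frame(person_id = sprintf("p%03d", 1:n),
                       age_at_diagnosis = runif(n, 5, 60),
                       true_type = "T1D")
  curve <- proportion_curve(cohort)
  expect_true(all(curve$proportion == 1))

  # all-T1D below 20, all-T2D above: a ramp spanning 12.5 to 27.5
  cohort$true_type <- ifelse(cohort$age_at_diagnosis < 20, "T1D", "T2D")
  ramp <- proportion_curve(cohort, window_years = 15)
  expect_true(all(ramp$proportion[ramp$age <= 12] == 1))
  expect_true(all(ramp$proportion[ramp$age >= 28] == 0))
  mid <- ramp$proportion[ramp$age >= 13 & ramp$age <= 27]
  expect_true(all(diff(mid) <= 0))
  # direct window-average oracle at one grid point
  a <- 20
  sel <- abs(cohort$age_at_diagnosis - a) <= 7.5
  expect_equal(ramp$proportion[ramp$age == a], mean(cohort$true_type[sel] == "T1D"))
})
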