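diag <- as.Date("2010-01-01")

enc_rows <- function(codes, sources, days = 30) {
  data.frame(person_id = "p1", date = diag + days, icd9 = codes,
             source = sources, setting = "outpatient", stringsAsFactors = FALSE)
}
rx_rows <- function(classes, days, dur = 90L) {
  data.frame(person_id = "p1", drug_class = classes, start_date = diag + days,
             duration_days = dur, stringsAsFactors = FALSE)
}

test_that("count_codes counts typed codes after diagnosis, split by source", {
  z <- count_codes(NULL, diag)
  expect_identical(unlist(z), c(n_type1 = 0L, n_type2 = 0L, n_type1_principal = 0L,
                                n_type1_mixed = 0L, n_type2_principal = 0L,
                                n_type2_mixed = 0L))
  enc <- enc_rows(c("250.01", "250.03", "250.11", "428.0"),
                  c("principal", "principal", "mixed", "mixed"))
  got <- count_codes(enc, diag)
  expect_identical(got$n_type1, 3L)
  expect_identical(got$n_type1_principal, 2L)
  expect_identical(got$n_type1_mixed, 1L)
  expect_identical(got$n_type2, 0L)
  # codes before diagnosis or beyond the horizon are not counted
  early <- enc_rows("250.01", "principal", days = -5)
  late <- enc_rows("250.01", "principal", days = 400)
  both <- rbind(enc, early, late)
  expect_identical(count_codes(both, diag, diag + 365)$n_type1, 3L)
  expect_identical(count_codes(both, diag)$n_type1, 4L)
})

test_that("ratio positivity treats a zero denominator as infinite", {
  cc <- function(n1, n2) {
    structure(list(n_type1 = n1, n_type2 = n2, n_type1_principal = n1,
                   n_type1_mixed = 0L, n_type2_principal = n2, n_type2_mixed = 0L),
              class = "code_counts")
  }
  expect_true(code_ratio_positive(cc(3, 0), 4))
  expect_true(code_ratio_positive(cc(1, 0), 0.5))
  expect_false(code_ratio_positive(cc(0, 0), 0.5))
  expect_false(code_ratio_positive(cc(0, 5), 0.5))
  # the threshold is inclusive
  expect_true(code_ratio_positive(cc(2, 1), 2))
  expect_false(code_ratio_positive(cc(2, 1), 3))
  # raising the threshold never turns a negative positive
  set.seed(5)
  for (i in 1:50) {
    n1 <- sample(0:6, 1); n2 <- sample(0:6, 1)
    r <- sort(runif(2, 0.1, 6))
    if (code_ratio_positive(cc(n1, n2), r[2])) {
      expect_true(code_ratio_positive(cc(n1, n2), r[1]))
    }
  }
})

test_that("prescription variants implement the windowed insulin semantics", {
  ins <- rx_rows("insulin_long", 10)
  expect_true(rx_positive(ins, diag, "any_insulin", 90))
  # sub-28-day insulin never qualifies
  expect_false(rx_positive(rx_rows("insulin_long", 10, 14L), diag, "any_insulin", 90))
  # window boundary: start exactly at diagnosis + w is inside
  expect_true(rx_positive(rx_rows("insulin_long", 90), diag, "any_insulin", 90))
  expect_false(rx_positive(rx_rows("insulin_long", 91), diag, "any_insulin", 90))
  # prescriptions before diagnosis are ignored
  expect_false(rx_positive(rx_rows("insulin_long", -10), diag, "any_insulin", 90))

  with_su <- rbind(ins, rx_rows("sulfonylurea", 30))
  expect_true(rx_positive(with_su, diag, "any_insulin", 90))
  expect_false(rx_positive(with_su, diag, "insulin_no_other_glm", 90))
  with_met <- rbind(ins, rx_rows("metformin", 30))
  expect_false(rx_positive(with_met, diag, "insulin_no_other_glm", 90))
  expect_true(rx_positive(with_met, diag, "insulin_no_other_glm_except_metformin", 90))
  # a co-prescription outside the window does not disqualify
  late_su <- rbind(ins, rx_rows("sulfonylurea", 200))
  expect_true(rx_positive(late_su, diag, "insulin_no_other_glm", 90))

  mdi <- rx_rows(c("insulin_long", "insulin_short"), c(5, 5))
  expect_true(rx_positive(mdi, diag, "mdi", 90))
  expect_true(rx_positive(mdi, diag, "mdi_no_other_glm", 90))
  # co-initiation must be within mdi_coinit_days
  spread <- rx_rows(c("insulin_long", "insulin_short"), c(5, 50))
  expect_false(rx_positive(spread, diag, "mdi", 90, mdi_coinit_days = 31))
  expect_true(rx_positive(spread, diag, "mdi", 90, mdi_coinit_days = 60))
  # long alone is not MDI
  expect_false(rx_positive(ins, diag, "mdi", 90))

  expect_true(rx_positive(rx_rows("metformin", 400), diag, "any_metformin", Inf))
  expect_false(rx_positive(rx_rows("metformin", 400), diag, "other_glm_only", Inf))
  expect_true(rx_positive(rx_rows("dpp4", 10), diag, "other_glm_only", Inf))
  expect_false(rx_positive(NULL, diag, "any_insulin", 90))
})

test_that("widening the window never shrinks the at-least-one positives", {
  set.seed(9)
  monotone_variants <- c("any_insulin", "mdi", "any_metformin", "other_glm_only")
  for (i in 1:40) {
    p <- random_person_events()
    if (is.null(p$rx)) next
    for (v in monotone_variants) {
      narrow <- rx_positive(p$rx, p$diag, v, 90)
      wide <- rx_positive(p$rx, p$diag, v, 365)
      if (narrow) expect_true(wide)
    }
  }
})

test_that("classification matches the brute-force rule evaluator", {
  set.seed(13)
  for (i in 1:80) {
    p <- random_person_events()
    spec <- random_spec()
    mine <- spec_positive_via_classify(spec, p)
    oracle <- oracle_positive(spec, p$enc, p$rx, p$diag,
                              horizon = as.Date("2016-12-31"))
    expect_identical(mine, oracle,
                     label = sprintf("spec %s rep %d", spec$name, i))
  }
})

test_that("combination algebra nests as expected and or/and behave on examples", {
  B <- alg_code_ratio(4, name = "B")
  C <- alg_rx("any_insulin", 90, name = "C")
  # insulin at day 10, no typed codes: B-or-C positive, B-and-C negative
  p_rx <- list(diag = diag, enc = NULL, rx = rx_rows("insulin_long", 10))
  expect_true(spec_positive_via_classify(alg_combo(B, C, "or"), p_rx))
  expect_false(spec_positive_via_classify(alg_combo(B, C, "and"), p_rx))
  # one type-1 and one type-2 code: ratio 1 passes A (>= 0.5)
  A <- alg_code_ratio(0.5, name = "A")
  p_code <- list(diag = diag,
                 enc = enc_rows(c("250.01", "250.00"), c("mixed", "mixed")),
                 rx = NULL)
  expect_true(spec_positive_via_classify(A, p_code))

  set.seed(17)
  for (i in 1:40) {
    p <- random_person_events()
    x <- random_spec(); y <- random_spec()
    if (x$kind == "combo" || y$kind == "combo") next
    px <- spec_positive_via_classify(x, p)
    pand <- spec_positive_via_classify(alg_combo(x, y, "and"), p)
    por <- spec_positive_via_classify(alg_combo(x, y, "or"), p)
    if (pand) expect_true(px)   # positives(and) is a subset of positives(x)
    if (px) expect_true(por)    # positives(x) is a subset of positives(or)
  }
})

test_that("the registry holds the twelve algorithms and the headline aliases", {
  reg <- algorithm_registry()
  twelve <- c("A", "B", "C", "D",
              "A_and_C", "A_or_C", "A_and_D", "A_or_D",
              "B_and_C", "B_or_C", "B_and_D", "B_or_D")
  expect_true(all(twelve %in% names(reg)))
  expect_identical(anyDuplicated(twelve), 0L)
  expect_equal(reg$optimized, reg$B_and_C)
  expect_equal(reg$high_ppv_t1, reg$B_and_D)
  expect_equal(reg$high_sensitivity_t1, reg$B_or_C)
  expect_identical(reg$A$threshold, 0.5)
  expect_identical(reg$B$threshold, 4)
  expect_identical(reg$C$variant, "any_insulin")
  expect_identical(reg$C$window_days, 90)
  expect_identical(reg$D$variant, "mdi_no_other_glm")
  # combos are single-depth only
  expect_error(alg_combo(reg$B_and_C, reg$C, "or"), "non-combo")
})
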