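cfg <- onset_config()

test_that("calendar-month arithmetic clamps at month end", {
  expect_equal(add_months(as.Date("2010-01-31"), 1), as.Date("2010-02-28"))
  expect_equal(add_months(as.Date("2012-01-31"), 1), as.Date("2012-02-29"))
  expect_equal(add_months(as.Date("2010-06-01"), -9), as.Date("2009-09-01"))
  expect_equal(add_months(as.Date("2010-06-01"), 6), as.Date("2010-12-01"))
  expect_equal(add_months(as.Date("2010-03-31"), -1), as.Date("2010-02-28"))
})

test_that("gestational windows follow deliveries and pregnancy encounters", {
  expect_identical(nrow(gestational_windows(NULL, NULL, cfg)), 0L)

  del <- data.frame(person_id = "p", date = as.Date("2010-06-01"), kind = "delivery")
  w <- gestational_windows(del, NULL, cfg)
  expect_equal(w$start, as.Date("2009-09-01"))
  expect_equal(w$end, as.Date("2010-12-01"))

  # a pregnancy encounter inside the delivery window adds nothing
  enc_in <- data.frame(person_id = "p", date = as.Date("2010-07-01"),
                       icd9 = "650", source = "mixed", setting = "outpatient")
  expect_equal(gestational_windows(del, enc_in, cfg), w)

  # one outside spawns its own +/- 9 month window
  enc_out <- data.frame(person_id = "p", date = as.Date("2013-03-15"),
                        icd9 = "650", source = "mixed", setting = "outpatient")
  w2 <- gestational_windows(del, enc_out, cfg)
  expect_identical(nrow(w2), 2L)
  expect_equal(w2$start[2], as.Date("2012-06-15"))
  expect_equal(w2$end[2], as.Date("2013-12-15"))

  # non-pregnancy encounters are ignored
  enc_other <- data.frame(person_id = "p", date = as.Date("2013-03-15"),
                          icd9 = "428.0", source = "mixed", setting = "outpatient")
  expect_equal(gestational_windows(del, enc_other, cfg), w)
})

test_that("window membership agrees with a day-by-day oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n_del <- sample(0:2, 1); n_enc <- sample(0:2, 1)
    del <- if (n_del) data.frame(
      person_id = "p", date = as.Date("2008-01-01") + sample(0:2000, n_del),
      kind = "delivery") else NULL
    enc <- if (n_enc) data.frame(
      person_id = "p", date = as.Date("2008-01-01") + sample(0:2000, n_enc),
      icd9 = "650", source = "mixed", setting = "outpatient") else NULL
    w <- gestational_windows(del, enc, cfg)
    # raw (unmerged) windows for the oracle
    raw_s <- raw_e <- as.Date(character(0))
    if (n_del) {
      raw_s <- c(raw_s, add_months(del$date, -9)); raw_e <- c(raw_e, add_months(del$date, 6))
    }
    if (n_enc) {
      keep <- !vapply(enc$date, function(d)
        n_del > 0 && any(d >= add_months(del$date, -9) & d <= add_months(del$date, 6)),
        logical(1))
      raw_s <- c(raw_s, add_months(enc$date[keep], -9))
      raw_e <- c(raw_e, add_months(enc$date[keep], 9))
    }
    probes <- as.Date("2007-06-01") + sample(0:2500, 40)
    for (d in probes) {
      d <- as.Date(d, origin = "1970-01-01")
      expect_identical(nrow(w) > 0 && any(d >= w$start & d <= w$end),
                       oracle_in_windows(d, raw_s, raw_e))
    }
  }
})

lab_row <- function(date, test = "hba1c", value = 7, setting = "outpatient") {
  data.frame(person_id = "p", date = as.Date(date), test = test, value = value,
             setting = setting)
}
rx_row <- function(date, class = "metformin", dur = 90L) {
  data.frame(person_id = "p", drug_class = class, start_date = as.Date(date),
             duration_days = dur)
}

test_that("onset detection honours settings, thresholds and durations", {
  # inpatient glucose is never an onset trigger
  expect_null(detect_onset(list(labs = lab_row("2005-01-01", "fpg", 9, "inpatient"))))
  # sub-threshold values do not trigger
  expect_null(detect_onset(list(labs = lab_row("2005-01-01", value = 6.4))))
  # short insulin courses do not trigger
  expect_null(detect_onset(list(prescriptions = rx_row("2005-01-01", "insulin_long", 14L))))
  # long-term insulin does
  got <- detect_onset(list(prescriptions = rx_row("2005-01-01", "insulin_long", 28L)))
  expect_equal(got, list(date = as.Date("2005-01-01"), criterion = "long_term_insulin"))
  # the earliest candidate wins
  got <- detect_onset(list(labs = lab_row("2005-03-01", value = 6.5),
                           prescriptions = rx_row("2005-04-01")))
  expect_equal(got, list(date = as.Date("2005-03-01"), criterion = "hba1c"))
  # same-day ties break by fixed criterion priority
  got <- detect_onset(list(labs = rbind(lab_row("2005-03-01", "fpg", 8),
                                        lab_row("2005-03-01", "hba1c", 7)),
                           prescriptions = rx_row("2005-03-01")))
  expect_identical(got$criterion, "hba1c")
  # the inpatient-HbA1c exemption switch
  ev <- list(labs = lab_row("2005-01-01", setting = "inpatient"))
  expect_null(detect_onset(ev))
  relaxed <- onset_config(exclude_inpatient_hba1c = FALSE)
  expect_identical(detect_onset(ev, cfg = relaxed)$criterion, "hba1c")
})

test_that("candidates inside gestational windows are discarded", {
  win <- data.frame(start = as.Date("2009-09-01"), end = as.Date("2010-12-01"))
  ev <- list(labs = lab_row("2010-01-15"))
  expect_null(detect_onset(ev, win))
  ev2 <- list(labs = rbind(lab_row("2010-01-15"), lab_row("2011-02-01")))
  expect_equal(detect_onset(ev2, win)$date, as.Date("2011-02-01"))
})

test_that("onset detection is monotone under added events", {
  set.seed(11)
  for (rep in 1:30) {
    p <- random_person_events()
    labs1 <- lab_row(p$diag + sample(0:500, 1))
    ev1 <- list(labs = labs1, prescriptions = p$rx)
    base <- detect_onset(ev1)
    extra <- lab_row(p$diag + sample(0:500, 1))
    more <- detect_onset(list(labs = rbind(labs1, extra), prescriptions = p$rx))
    if (!is.null(base)) {
      expect_true(!is.null(more) && more$date <= base$date)
    }
  }
})

cohort_fixture <- function() {
  persons <- data.frame(
    person_id = c("ok", "baby", "mono", "miss", "old_dx"),
    sex = "female",
    birth_date = as.Date(c("1990-01-01", "2004-01-01", "1980-01-01",
                           "1970-01-01", "1950-01-01")))
  labs <- data.frame(
    person_id = c("ok", "baby", "mono", "miss", "old_dx"),
    date = as.Date(c("2005-03-01", "2005-04-01", "2010-01-01", "2010-01-01",
                     "2000-06-01")),
    test = "hba1c", value = 7.5, setting = "outpatient")
  labels <- data.frame(
    person_id = c("ok", "baby", "mono", "miss", "old_dx"),
    true_type = c("T1D", "T1D", "monogenic_secondary", "missing", "T2D"))
  event_tables(persons = persons, labs = labs, labels = labels)
}

test_that("cohort building applies eligibility rules in order and keeps the ledger consistent", {
  tabs <- cohort_fixture()
  cohort <- build_cohort(tabs)
  expect_identical(cohort$person_id, "ok")
  # exact day-difference age
  expect_equal(cohort$age_at_diagnosis,
               as.numeric(as.Date("2005-03-01") - as.Date("1990-01-01")) / 365.25)
  excl <- attr(cohort, "exclusions")
  expect_identical(excl[["age"]], 1L)            # diagnosed at ~1.25 years
  expect_identical(excl[["monogenic_secondary"]], 1L)
  expect_identical(excl[["missing_label"]], 1L)
  expect_identical(excl[["out_of_window"]], 1L)  # diagnosed in 2000
  # ledger counts sum to input persons minus cohort size
  expect_identical(sum(excl), nrow(tabs$persons) - nrow(cohort))
})

test_that("a detected onset without any label row is an error naming the person", {
  tabs <- cohort_fixture()
  tabs$labels <- tabs$labels[tabs$labels$person_id != "ok", ]
  expect_error(build_cohort(tabs), "ok")
})

test_that("the 2:1 split is seeded, order-stable and binomially sized", {
  cohort <- data.frame(person_id = sprintf("P%05d", 1:15297))
  a <- randomize_split(cohort, seed = 20150101)
  # permuting rows does not change any person's assignment
  perm <- cohort[sample(nrow(cohort)), , drop = FALSE]
  b <- randomize_split(perm, seed = 20150101)
  expect_identical(b$split[match(a$person_id, b$person_id)], a$split)
  # different seeds give different splits
  expect_false(identical(randomize_split(cohort, 1)$split, a$split))
  # realised size within the central 99% binomial interval around 2/3
  n_deriv <- sum(a$split == "derivation")
  expect_gte(n_deriv, qbinom(0.005, 15297, 2 / 3))
  expect_lte(n_deriv, qbinom(0.995, 15297, 2 / 3))
  # fraction 1 puts everyone in derivation
  expect_true(all(randomize_split(cohort, 1, fraction_derivation = 1)$split ==
                    "derivation"))
})
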