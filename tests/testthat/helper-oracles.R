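# Independent oracles used across the suite.  These deliberately avoid the
# implementation paths they check.

# Clopper-Pearson by bisection on the exact binomial tail sums: the lower
# bound solves P(X >= x | p) = alpha/2, the upper solves P(X <= x | p) =
# alpha/2, each located to `iter` halvings.
oracle_ci_bisect <- function(x, n, level = 0.95, iter = 60) {
  alpha <- 1 - level
  upper_tail <- function(p) 1 - pbinom(x - 1, n, p)   # P(X >= x)
  lower_tail <- function(p) pbinom(x, n, p)           # P(X <= x)
  bisect <- function(f, target, increasing) {
    lo <- 0; hi <- 1
    for (i in seq_len(iter)) {
      mid <- (lo + hi) / 2
      hit <- f(mid) < target
      if (hit == increasing) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else bisect(upper_tail, alpha / 2, increasing = TRUE)
  upper <- if (x == n) 1 else bisect(lower_tail, alpha / 2, increasing = FALSE)
  c(lower, upper)
}

# day-by-day membership oracle for gestational shielding: enumerates every
# day of every raw (unmerged) window
oracle_in_windows <- function(date, raw_starts, raw_ends) {
  if (!length(raw_starts)) return(FALSE)
  days <- unlist(lapply(seq_along(raw_starts), function(i) {
    seq(raw_starts[i], raw_ends[i], by = "day")
  }))
  as.numeric(date) %in% as.numeric(days)
}

# brute-force rule evaluator: recomputes positivity from the raw rows with
# explicit loops, independent of count_codes()/rx_positive()
oracle_positive <- function(spec, enc, rx, diag, horizon = NULL,
                            coinit = 31, min_ins = 28) {
  typed <- function(code) {
    if (!grepl("^250\\.", code) || nchar(code) != 6) return("other")
    fifth <- substr(code, 6, 6)
    if (fifth %in% c("1", "3")) "type1" else if (fifth %in% c("0", "2")) "type2" else "other"
  }
  enc_rows <- if (is.null(enc)) list() else split(enc, seq_len(nrow(enc)))
  rx_rows <- if (is.null(rx)) list() else split(rx, seq_len(nrow(rx)))
  in_horizon <- function(d) d >= diag && (is.null(horizon) || d <= horizon)
  count <- function(cls, src) {
    k <- 0
    for (row in enc_rows) {
      if (!in_horizon(as.Date(row$date))) next
      if (typed(row$icd9) != cls) next
      if (src != "any" && row$source != src) next
      k <- k + 1
    }
    k
  }
  rx_in <- function(w) {
    keep <- list()
    for (row in rx_rows) {
      d <- as.Date(row$start_date)
      if (d < diag) next
      lim <- if (is.finite(w)) diag + w else horizon
      if (!is.null(lim) && d > lim) next
      keep[[length(keep) + 1]] <- row
    }
    keep
  }
  switch(spec$kind,
    code_count = count(spec$code_class, spec$source) >= spec$min_count,
    code_ratio = {
      n1 <- count("type1", "any"); n2 <- count("type2", "any")
      if (n2 > 0) n1 / n2 >= spec$threshold else n1 >= 1
    },
    rx = {
      rows <- rx_in(spec$window_days)
      ins <- Filter(function(r) startsWith(r$drug_class, "insulin_") &&
                      r$duration_days >= min_ins, rows)
      glm <- Filter(function(r) !startsWith(r$drug_class, "insulin_"), rows)
      glm_xmet <- Filter(function(r) r$drug_class != "metformin", glm)
      mdi <- local({
        longs <- Filter(function(r) r$drug_class == "insulin_long", ins)
        shorts <- Filter(function(r) r$drug_class == "insulin_short", ins)
        hit <- FALSE
        for (a in longs) for (b in shorts) {
          if (abs(as.numeric(as.Date(a$start_date) - as.Date(b$start_date))) <= coinit)
            hit <- TRUE
        }
        hit
      })
      switch(spec$variant,
        any_insulin = length(ins) > 0,
        insulin_no_other_glm = length(ins) > 0 && length(glm) == 0,
        insulin_no_other_glm_except_metformin = length(ins) > 0 && length(glm_xmet) == 0,
        mdi = mdi,
        mdi_no_other_glm = mdi && length(glm) == 0,
        mdi_no_other_glm_except_metformin = mdi && length(glm_xmet) == 0,
        any_metformin = any(vapply(rows, function(r) r$drug_class == "metformin",
                                   logical(1))),
        other_glm_only = length(glm_xmet) > 0)
    },
    combo = {
      l <- oracle_positive(spec$left, enc, rx, diag, horizon, coinit, min_ins)
      r <- oracle_positive(spec$right, enc, rx, diag, horizon, coinit, min_ins)
      if (spec$op == "and") l && r else l || r
    })
}

# small random event fixture for one person (encounters + prescriptions)
random_person_events <- function() {
  diag <- as.Date("2010-01-01")
  n_enc <- sample(0:6, 1)
  enc <- if (n_enc) data.frame(
    person_id = "p1",
    date = diag + sample(-30:400, n_enc, replace = TRUE),
    icd9 = sample(c("250.01", "250.03", "250.00", "250.02", "428.0", "250.1"),
                  n_enc, replace = TRUE),
    source = sample(c("principal", "mixed"), n_enc, replace = TRUE),
    setting = sample(c("inpatient", "outpatient"), n_enc, replace = TRUE),
    stringsAsFactors = FALSE) else NULL
  n_rx <- sample(0:5, 1)
  rx <- if (n_rx) data.frame(
    person_id = "p1",
    drug_class = sample(c("insulin_long", "insulin_short", "insulin_premixed",
                          "metformin", "sulfonylurea", "dpp4"),
                        n_rx, replace = TRUE),
    start_date = diag + sample(-10:400, n_rx, replace = TRUE),
    duration_days = sample(c(7L, 14L, 28L, 90L, 180L), n_rx, replace = TRUE),
    stringsAsFactors = FALSE) else NULL
  list(diag = diag, enc = enc, rx = rx)
}

# route a single person's events through the public classify() interface
spec_positive_via_classify <- function(spec, p) {
  persons <- data.frame(person_id = "p1", sex = "female",
                        birth_date = as.Date("1980-01-01"))
  tabs <- event_tables(persons = persons, encounters = p$enc,
                       prescriptions = p$rx)
  cohort <- data.frame(person_id = "p1", diagnosis_date = p$diag)
  classify(tabs, cohort, spec)$call[1] == "T1D"
}

random_spec <- function() {
  prim <- function() {
    switch(sample(3, 1),
      alg_code_count(sample(c("type1", "type2"), 1),
                     sample(c("any", "principal", "mixed"), 1),
                     sample(1:3, 1)),
      alg_code_ratio(sample(c(0.5, 1, 2, 4), 1)),
      alg_rx(sample(c("any_insulin", "insulin_no_other_glm", "mdi",
                      "mdi_no_other_glm", "any_metformin", "other_glm_only"), 1),
             sample(c(90, 180, 365, Inf), 1)))
  }
  if (runif(1) < 0.5) prim() else alg_combo(prim(), prim(), sample(c("and", "or"), 1))
}
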