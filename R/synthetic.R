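#' Configuration of the synthetic EHR generator
#'
#' Parameters of the seeded generator in [generate_ehr()].  Defaults are
#' calibrated to the registry population the classification rules were
#' developed on: a rare-T1D adult-dominated diabetes register.
#'
#' * `t1d_fraction`: overall probability a person has true T1D (default
#'   0.008, the validation-cohort true proportion).
#' * Age at diagnosis: truncated normals on 1.5--100 years, T1D mean 22.7
#'   (SD 12.6), T2D mean 55.9 (SD 11.4).
#' * `coding_model`: negative-binomial marginals for post-diagnosis type 1
#'   and type 2 code counts per true type, with a binomial
#'   principal/mixed source split.  Defaults reproduce the observed
#'   medians/IQRs (T1D: median 3 type 1 codes, 0 type 2; T2D: 0 and 1).
#' * `rx_model`: per-type prescription event probabilities --
#'   `p_any_insulin`, `p_insulin_90d` (insulin initiated within 90 days,
#'   nested inside any-insulin), `p_mdi` (long- plus short-acting insulin
#'   co-initiated, nested inside any-insulin), `p_metformin`,
#'   `p_other_glm`.  Defaults: T1D 0.983/0.967/0.783/0.367/0.167,
#'   T2D 0.336/0.061/0.027/0.886/0.757.
#' * `rx_correlation`: a single latent per-person severity draw couples
#'   code counts and prescription events through a Gaussian copula of this
#'   strength (marginals are preserved exactly); 0 gives independence.
#' * `pregnancy_rate`: fraction of women given a post-diagnosis delivery
#'   (plus a pregnancy-related encounter), exercising the gestational
#'   shielding code.
#' * `onset_lab_mix`: probabilities that a person's onset presentation is
#'   an HbA1c lab, a fasting-glucose lab, or a glucose-lowering
#'   prescription (prescription onsets fall back to HbA1c when the person
#'   has no modelled non-insulin prescription).
#' * `missing_label_rate`, `monogenic_rate`: fractions whose reference
#'   label is `missing` / `monogenic_secondary` (excluded downstream).
#'
#' Nested probabilities are validated: `p_insulin_90d` and `p_mdi` may not
#' exceed `p_any_insulin`.
#'
#' @param n_persons number of persons to simulate.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param t1d_fraction,t1d_age_mean,t1d_age_sd,t2d_age_mean,t2d_age_sd
#'   disease mix and age-at-diagnosis model.
#' @param coding_model,rx_model,rx_correlation,pregnancy_rate,onset_lab_mix,
#'   female_fraction,missing_label_rate,monogenic_rate see above.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_persons = 5000, seed = 1,
                             t1d_fraction = 0.008,
                             t1d_age_mean = 22.7, t1d_age_sd = 12.6,
                             t2d_age_mean = 55.9, t2d_age_sd = 11.4,
                             coding_model = NULL, rx_model = NULL,
                             rx_correlation = 0.4,
                             pregnancy_rate = 0.05,
                             onset_lab_mix = c(hba1c = 0.6, fpg = 0.25, rx = 0.15),
                             female_fraction = c(T1D = 0.533, T2D = 0.439),
                             missing_label_rate = 0.023,
                             monogenic_rate = 0.001) {
  if (is.null(coding_model)) {
    coding_model <- list(
      T1D = list(type1 = c(mu = 3.5, size = 1.5), type2 = c(mu = 0.8, size = 0.2),
                 p_principal_type1 = 0.65, p_principal_type2 = 0.4),
      T2D = list(type1 = c(mu = 0.05, size = 0.2), type2 = c(mu = 2.9, size = 0.3),
                 p_principal_type1 = 0.3, p_principal_type2 = 0.5))
  }
  if (is.null(rx_model)) {
    rx_model <- list(
      T1D = c(p_any_insulin = 0.983, p_insulin_90d = 0.967, p_mdi = 0.783,
              p_metformin = 0.367, p_other_glm = 0.167),
      T2D = c(p_any_insulin = 0.336, p_insulin_90d = 0.061, p_mdi = 0.027,
              p_metformin = 0.886, p_other_glm = 0.757))
  }
  for (type in c("T1D", "T2D")) {
    p <- rx_model[[type]]
    if (any(p < 0 | p > 1)) stop("rx_model probabilities must be in [0, 1]",
                                 call. = FALSE)
    if (p[["p_insulin_90d"]] > p[["p_any_insulin"]] ||
        p[["p_mdi"]] > p[["p_any_insulin"]]) {
      stop("infeasible nested probabilities for ", type,
           ": p_insulin_90d and p_mdi may not exceed p_any_insulin",
           call. = FALSE)
    }
  }
  stopifnot(n_persons >= 0, t1d_fraction >= 0, t1d_fraction <= 1,
            rx_correlation >= 0, rx_correlation < 1,
            pregnancy_rate >= 0, pregnancy_rate <= 1,
            abs(sum(onset_lab_mix) - 1) < 1e-8)
  structure(list(
    n_persons = as.integer(n_persons), seed = as.integer(seed),
    t1d_fraction = t1d_fraction,
    t1d_age_mean = t1d_age_mean, t1d_age_sd = t1d_age_sd,
    t2d_age_mean = t2d_age_mean, t2d_age_sd = t2d_age_sd,
    coding_model = coding_model, rx_model = rx_model,
    rx_correlation = rx_correlation, pregnancy_rate = pregnancy_rate,
    onset_lab_mix = onset_lab_mix, female_fraction = female_fraction,
    missing_label_rate = missing_label_rate, monogenic_rate = monogenic_rate
  ), class = "synthetic_config")
}

rtrunc_norm <- function(n, mean, sd, lo = 1.5, hi = 100) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

# correlated uniform: Gaussian copula against the shared severity draw z,
# preserving the U(0,1) marginal exactly
copula_u <- function(z, rho) {
  stats::pnorm(sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(length(z)))
}

#' Generate a seeded synthetic EHR
#'
#' Emits a full set of event tables -- persons, diabetes-typed and noise
#' encounter codes, prescriptions (insulin with long-term durations,
#' metformin, other glucose-lowering drugs), onset-qualifying outpatient
#' labs plus sub-threshold and inpatient noise labs, deliveries for a
#' fraction of women -- together with reference labels and the ground-truth
#' person-level record.  Every person carries an onset-qualifying event on
#' their intended diagnosis date, so [build_cohort()] recovers the intended
#' cohort; insulin-within-90-days is nested inside any-insulin by
#' construction.  The output is a pure function of the configuration
#' (including its seed); the caller's RNG state is left untouched.
#'
#' @param config a [synthetic_config()].
#' @param cfg an [onset_config()] fixing the enrolment and follow-up dates.
#' @return list with elements `tables` (an [event_tables] including the
#'   `labels` table), `labels`, and `truth` (per-person ground truth:
#'   type, age, intended diagnosis date and the drawn prescription events).
#' @export
generate_ehr <- function(config = synthetic_config(), cfg = onset_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_persons
  if (n == 0) {
    return(list(tables = event_tables(), labels = empty_table("labels"),
                truth = data.frame()))
  }
  ids <- sprintf("S%06d", seq_len(n))
  t1d <- stats::runif(n) < config$t1d_fraction
  type <- ifelse(t1d, "T1D", "T2D")
  age <- numeric(n)
  age[t1d] <- rtrunc_norm(sum(t1d), config$t1d_age_mean, config$t1d_age_sd)
  age[!t1d] <- rtrunc_norm(sum(!t1d), config$t2d_age_mean, config$t2d_age_sd)
  sex <- ifelse(stats::runif(n) < config$female_fraction[type], "female", "male")

  span <- as.integer(cfg$enrol_end - cfg$enrol_start)
  diag_date <- cfg$enrol_start + floor(stats::runif(n) * (span + 1))
  birth_date <- diag_date - round(age * 365.25)
  fu_days <- as.integer(cfg$followup_end - diag_date)

  # latent severity shared by coding and prescribing
  z <- stats::rnorm(n)
  rho <- config$rx_correlation
  rx <- do.call(rbind, config$rx_model[type])
  any_ins <- copula_u(z, rho) < rx[, "p_any_insulin"]
  ins90 <- any_ins & stats::runif(n) < rx[, "p_insulin_90d"] / rx[, "p_any_insulin"]
  mdi <- any_ins & stats::runif(n) < rx[, "p_mdi"] / rx[, "p_any_insulin"]
  metf <- copula_u(z, rho) < rx[, "p_metformin"]
  oglm <- copula_u(z, rho) < rx[, "p_other_glm"]

  cm <- config$coding_model
  nb <- function(which, par) {
    m <- vapply(cm[type], function(x) x[[which]][[par]], numeric(1))
    m
  }
  n1 <- stats::qnbinom(copula_u(z, rho), mu = nb("type1", "mu"), size = nb("type1", "size"))
  n2 <- stats::qnbinom(copula_u(z, rho), mu = nb("type2", "mu"), size = nb("type2", "size"))
  pp1 <- vapply(cm[type], function(x) x$p_principal_type1, numeric(1))
  pp2 <- vapply(cm[type], function(x) x$p_principal_type2, numeric(1))

  # onset presentation; prescription onsets need a non-insulin drug to hang on
  crit <- sample(names(config$onset_lab_mix), n, replace = TRUE,
                 prob = config$onset_lab_mix)
  crit[crit == "rx" & !(metf | oglm)] <- "hba1c"

  # labels: mostly the true type, with a little missingness and a few
  # monogenic/secondary cases as in real registers
  u <- stats::runif(n)
  lab <- type
  lab[u < config$missing_label_rate] <- "missing"
  lab[u >= config$missing_label_rate &
      u < config$missing_label_rate + config$monogenic_rate] <- "monogenic_secondary"

  persons <- data.frame(person_id = ids, sex = sex, birth_date = birth_date,
                        stringsAsFactors = FALSE)
  labels <- data.frame(person_id = ids, true_type = lab, stringsAsFactors = FALSE)

  ## labs: the onset lab (outpatient, at/above threshold) on day 0, plus
  ## pre-diagnosis sub-threshold screens and inpatient stress glucose noise
  lab_rows <- list()
  onset_lab <- crit %in% c("hba1c", "fpg")
  lab_rows$onset <- data.frame(
    person_id = ids[onset_lab], date = diag_date[onset_lab],
    test = crit[onset_lab],
    value = ifelse(crit[onset_lab] == "hba1c",
                   cfg$hba1c_threshold + stats::runif(sum(onset_lab)) * 3,
                   cfg$fpg_threshold + stats::runif(sum(onset_lab)) * 5),
    setting = "outpatient", stringsAsFactors = FALSE)
  screen <- stats::runif(n) < 0.3
  lab_rows$screen <- data.frame(
    person_id = ids[screen],
    date = diag_date[screen] - 30 - floor(stats::runif(sum(screen)) * 370),
    test = "hba1c", value = 4.5 + stats::runif(sum(screen)) * 1.8,
    setting = "outpatient", stringsAsFactors = FALSE)
  stress <- stats::runif(n) < 0.1
  lab_rows$stress <- data.frame(
    person_id = ids[stress],
    date = diag_date[stress] + floor(stats::runif(sum(stress)) * pmax(fu_days[stress], 1)),
    test = "fpg", value = 8 + stats::runif(sum(stress)) * 6,
    setting = "inpatient", stringsAsFactors = FALSE)
  labs <- do.call(rbind, lab_rows)

  ## prescriptions
  rx_rows <- list()
  ins_start <- integer(n)
  ins_start[ins90] <- floor(stats::runif(sum(ins90)) * 91)
  late <- any_ins & !ins90
  ins_start[late] <- 91 + floor(stats::runif(sum(late)) * pmax(fu_days[late] - 91, 1))
  ins_start <- pmin(ins_start, pmax(fu_days, 0))
  dur <- function(k) 30L + floor(stats::runif(k) * 150)
  plain <- any_ins & !mdi
  rx_rows$ins <- data.frame(
    person_id = ids[plain],
    drug_class = sample(c("insulin_long", "insulin_intermediate", "insulin_premixed"),
                        sum(plain), replace = TRUE),
    start_date = diag_date[plain] + ins_start[plain],
    duration_days = dur(sum(plain)), stringsAsFactors = FALSE)
  gap <- floor(stats::runif(sum(mdi)) * 15)
  rx_rows$mdi_long <- data.frame(
    person_id = ids[mdi], drug_class = "insulin_long",
    start_date = diag_date[mdi] + ins_start[mdi],
    duration_days = dur(sum(mdi)), stringsAsFactors = FALSE)
  rx_rows$mdi_short <- data.frame(
    person_id = ids[mdi], drug_class = "insulin_short",
    start_date = pmin(diag_date[mdi] + ins_start[mdi] + gap, cfg$followup_end),
    duration_days = dur(sum(mdi)), stringsAsFactors = FALSE)
  met_start <- floor(stats::runif(n) * 366)
  met_start[crit == "rx" & metf] <- 0L
  rx_rows$met <- data.frame(
    person_id = ids[metf], drug_class = "metformin",
    start_date = diag_date[metf] + met_start[metf],
    duration_days = dur(sum(metf)), stringsAsFactors = FALSE)
  oglm_start <- floor(stats::runif(n) * 366)
  oglm_start[crit == "rx" & oglm & !metf] <- 0L
  rx_rows$oglm <- data.frame(
    person_id = ids[oglm],
    drug_class = sample(c("sulfonylurea", "dpp4", "thiazolidinedione", "agi"),
                        sum(oglm), replace = TRUE),
    start_date = diag_date[oglm] + oglm_start[oglm],
    duration_days = dur(sum(oglm)), stringsAsFactors = FALSE)
  prescriptions <- do.call(rbind, rx_rows)

  ## encounters: typed diabetes codes after diagnosis, plus noise codes
  typed_enc <- function(count, fifth_digits) {
    who <- rep(seq_len(n), count)
    k <- length(who)
    if (!k) return(NULL)
    code <- paste0("250.", sample(0:9, k, TRUE), sample(fifth_digits, k, TRUE))
    principal <- stats::runif(k) <
      (if (identical(fifth_digits, c(1, 3))) pp1 else pp2)[who]
    data.frame(
      person_id = ids[who],
      date = diag_date[who] + floor(stats::runif(k) * pmax(fu_days[who], 1)),
      icd9 = code,
      source = ifelse(principal, "principal", "mixed"),
      setting = ifelse(principal, "inpatient",
                       sample(c("inpatient", "outpatient"), k, TRUE)),
      stringsAsFactors = FALSE)
  }
  n_noise <- stats::rpois(n, 1.2)
  who <- rep(seq_len(n), n_noise)
  noise_enc <- if (length(who)) data.frame(
    person_id = ids[who],
    date = diag_date[who] + floor(stats::runif(length(who)) *
                                    (pmax(fu_days[who], 1) + 365)) - 365,
    icd9 = sample(c("401.9", "414.01", "428.0", "780.79", "599.0"),
                  length(who), TRUE),
    source = sample(c("principal", "mixed"), length(who), TRUE, prob = c(.3, .7)),
    setting = sample(c("inpatient", "outpatient"), length(who), TRUE),
    stringsAsFactors = FALSE) else NULL
  encounters <- rbind(typed_enc(n1, c(1, 3)), typed_enc(n2, c(0, 2)), noise_enc)

  ## deliveries well after diagnosis, with an accompanying pregnancy encounter
  preg <- sex == "female" & stats::runif(n) < config$pregnancy_rate & fu_days > 320
  del_date <- pmin(diag_date[preg] + 300 +
                     floor(stats::runif(sum(preg)) * 1200), cfg$followup_end)
  deliveries <- data.frame(person_id = ids[preg], date = del_date,
                           kind = "delivery", stringsAsFactors = FALSE)
  preg_enc <- data.frame(
    person_id = ids[preg], date = del_date - 60,
    icd9 = "650", source = "mixed", setting = "outpatient",
    stringsAsFactors = FALSE)
  if (nrow(preg_enc)) encounters <- rbind(encounters, preg_enc)

  tables <- event_tables(persons = persons, encounters = encounters,
                         prescriptions = prescriptions, labs = labs,
                         deliveries = deliveries, labels = labels)
  truth <- data.frame(
    person_id = ids, true_type = type, age_at_diagnosis = age,
    diagnosis_date = diag_date, onset_presentation = crit,
    any_insulin = any_ins, insulin_90d = ins90, mdi = mdi,
    metformin = metf, other_glm = oglm, stringsAsFactors = FALSE)
  list(tables = tables, labels = labels, truth = truth)
}

# archetype event tables making `spec` positive / negative for one person;
# every person gets an onset-qualifying outpatient HbA1c on the diagnosis
# date, so the constructed cohort survives build_cohort unchanged
archetype_events <- function(spec, id, diag_date, positive, followup_end) {
  enc <- NULL
  rx <- NULL
  if (positive) {
    add_enc <- function(code, k, source = "mixed") {
      data.frame(person_id = id, date = diag_date + 30, icd9 = rep(code, k),
                 source = source, setting = "outpatient", stringsAsFactors = FALSE)
    }
    add_rx <- function(class, day, dur = 90L) {
      data.frame(person_id = id, drug_class = class,
                 start_date = diag_date + day, duration_days = dur,
                 stringsAsFactors = FALSE)
    }
    build <- function(s) {
      switch(s$kind,
        code_ratio = list(enc = add_enc("250.01", max(1L, ceiling(s$threshold))), rx = NULL),
        code_count = list(
          enc = add_enc(if (s$code_class == "type1") "250.01" else "250.00",
                        s$min_count,
                        source = if (s$source == "any") "mixed" else s$source),
          rx = NULL),
        rx = {
          day <- if (is.finite(s$window_days)) min(10L, as.integer(s$window_days)) else 10L
          parts <- switch(s$variant,
            any_insulin = ,
            insulin_no_other_glm = ,
            insulin_no_other_glm_except_metformin = add_rx("insulin_long", day),
            mdi = ,
            mdi_no_other_glm = ,
            mdi_no_other_glm_except_metformin =
              rbind(add_rx("insulin_long", day), add_rx("insulin_short", day)),
            any_metformin = add_rx("metformin", day),
            other_glm_only = add_rx("sulfonylurea", day))
          list(enc = NULL, rx = parts)
        },
        combo = {
          l <- build(s$left); r <- if (s$op == "and") build(s$right) else NULL
          list(enc = rbind(l$enc, r$enc), rx = rbind(l$rx, r$rx))
        })
    }
    parts <- build(spec)
    enc <- parts$enc
    rx <- parts$rx
  }
  labs <- data.frame(person_id = id, date = diag_date, test = "hba1c",
                     value = 7.5, setting = "outpatient", stringsAsFactors = FALSE)
  list(encounters = enc, prescriptions = rx, labs = labs)
}

#' Construct a minimal cohort realising a given confusion matrix
#'
#' Builds event tables for exactly `tp + fp + fn + tn` persons whose events
#' make `spec` produce the requested confusion matrix against the labels:
#' true/false positives receive an archetype event pattern satisfying the
#' rule (for a combination rule, the union of its operands' patterns);
#' negatives receive only the onset lab.  Pushing the result through
#' [build_cohort()], [classify()] and [confusion()] reproduces the matrix,
#' which makes printed validation rows replayable end to end.
#'
#' @param cm a `confusion_matrix`.
#' @param spec an [algorithm_spec] (any registry algorithm).
#' @param seed seed for the small amount of jitter in ages.
#' @param age_range ages at diagnosis, drawn uniformly.
#' @param cfg an [onset_config()].
#' @return list `tables` (an [event_tables] with labels) and `labels`.
#' @export
generate_from_matrix <- function(cm, spec, seed = 1, age_range = c(25, 45),
                                 cfg = onset_config()) {
  stopifnot(inherits(cm, "confusion_matrix"), inherits(spec, "algorithm_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  cells <- c(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
  total <- sum(cells)
  ids <- sprintf("M%06d", seq_len(max(total, 1)))[seq_len(total)]
  cell <- rep(names(cells), cells)
  positive <- cell %in% c("tp", "fp")
  truth <- ifelse(cell %in% c("tp", "fn"), "T1D", "T2D")
  diag_date <- as.Date("2010-06-01")
  age <- stats::runif(total, age_range[1], age_range[2])

  persons <- data.frame(person_id = ids, sex = "female",
                        birth_date = diag_date - round(age * 365.25),
                        stringsAsFactors = FALSE)
  labels <- data.frame(person_id = ids, true_type = truth, stringsAsFactors = FALSE)
  labs <- data.frame(person_id = ids, date = diag_date, test = "hba1c",
                     value = 7.5, setting = "outpatient", stringsAsFactors = FALSE)
  enc <- list(); rx <- list()
  for (i in which(positive)) {
    ev <- archetype_events(spec, ids[i], diag_date, TRUE, cfg$followup_end)
    enc[[length(enc) + 1]] <- ev$encounters
    rx[[length(rx) + 1]] <- ev$prescriptions
  }
  tables <- event_tables(
    persons = persons,
    encounters = if (length(enc)) do.call(rbind, enc) else NULL,
    prescriptions = if (length(rx)) do.call(rbind, rx) else NULL,
    labs = labs,
    labels = labels)
  list(tables = tables, labels = labels)
}
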