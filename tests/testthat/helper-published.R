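# Published operating points used as golden values.

reference_rows <- function() {
  read.csv(test_path("fixtures", "reference-operating-points.csv"),
           stringsAsFactors = FALSE, check.names = FALSE)
}

# derivation-cohort candidate screen (60 T1D / 10,136 T2D): number of
# positives among true T1D (tp) and true T2D (fp) for every candidate rule
published_candidate_screen <- function() {
  txt <- "name,kind,family,window_days,tp,fp
ge1_type1,code_count,ge1_type1_any,NA,50,142
ge1_type1_principal,code_count,ge1_type1_principal,NA,42,65
ge1_type1_mixed,code_count,ge1_type1_mixed,NA,38,108
ge1_type2,code_count,ge1_type2_any,NA,43,92
ge1_type2_principal,code_count,ge1_type2_principal,NA,29,25
ge1_type2_mixed,code_count,ge1_type2_mixed,NA,21,66
ratio_ge_0.5,code_ratio,code_ratio,NA,50,97
ratio_ge_0.75,code_ratio,code_ratio,NA,49,81
ratio_ge_1,code_ratio,code_ratio,NA,49,78
ratio_ge_2,code_ratio,code_ratio,NA,47,47
ratio_ge_3,code_ratio,code_ratio,NA,46,38
ratio_ge_4,code_ratio,code_ratio,NA,43,32
any_insulin,rx,any_insulin,Inf,59,3408
any_insulin_90d,rx,any_insulin,90,58,615
any_insulin_180d,rx,any_insulin,180,58,715
any_insulin_365d,rx,any_insulin,365,58,844
insulin_no_other_glm,rx,insulin_no_other_glm,Inf,36,80
insulin_no_other_glm_90d,rx,insulin_no_other_glm,90,43,362
insulin_no_other_glm_180d,rx,insulin_no_other_glm,180,44,483
insulin_no_other_glm_365d,rx,insulin_no_other_glm,365,45,653
insulin_no_other_glm_except_metformin,rx,insulin_no_other_glm_except_metformin,Inf,50,275
insulin_no_other_glm_except_metformin_90d,rx,insulin_no_other_glm_except_metformin,90,53,451
insulin_no_other_glm_except_metformin_180d,rx,insulin_no_other_glm_except_metformin,180,54,566
insulin_no_other_glm_except_metformin_365d,rx,insulin_no_other_glm_except_metformin,365,54,727
mdi,rx,mdi,Inf,47,273
mdi_90d,rx,mdi,90,7,5
mdi_180d,rx,mdi,180,8,9
mdi_365d,rx,mdi,365,12,13
mdi_no_other_glm,rx,mdi_no_other_glm,Inf,32,9
mdi_no_other_glm_90d,rx,mdi_no_other_glm,90,7,2
mdi_no_other_glm_180d,rx,mdi_no_other_glm,180,8,6
mdi_no_other_glm_365d,rx,mdi_no_other_glm,365,12,11
any_metformin,rx,any_metformin,Inf,22,8979
other_glm_only,rx,other_glm_only,Inf,10,7673"
  df <- read.csv(text = txt, stringsAsFactors = FALSE)
  n_pos <- 60L; n_neg <- 10136L
  df$window_days <- as.numeric(df$window_days)
  df$fn <- n_pos - df$tp
  df$tn <- n_neg - df$fp
  df$sensitivity <- df$tp / n_pos
  df$ppv <- ifelse(df$tp + df$fp > 0, df$tp / (df$tp + df$fp), NA_real_)
  df
}

# derivation-cohort all-ages metrics of the twelve evaluated algorithms
published_twelve <- function() {
  rows <- reference_rows()
  rows <- rows[rows$cohort == "derivation" & rows$stratum == "all", ]
  data.frame(
    name = rows$algorithm,
    sensitivity = rows$tp / (rows$tp + rows$fn),
    ppv = ifelse(rows$tp + rows$fp > 0, rows$tp / (rows$tp + rows$fp), NA_real_),
    kappa = vapply(seq_len(nrow(rows)), function(i) {
      cohen_kappa(confusion_matrix(rows$tp[i], rows$fp[i], rows$fn[i], rows$tn[i]))
    }, numeric(1)),
    stringsAsFactors = FALSE)
}

# half-up rounding as the published tables use
r1 <- function(x) floor(x * 1000 + 0.5) / 10   # percent with 1 decimal
r2 <- function(x) floor(x * 100 + 0.5) / 100
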