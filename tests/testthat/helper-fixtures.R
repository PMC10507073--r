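# Fixtures are built in code at test time; nothing is read from disk.

.ts <- function(x) as.POSIXct(x, tz = "UTC")

# An EHRTables bundle with empty tables of the right shape.
emptyEHR <- function() {
  dt <- data.table::data.table
  new("EHRTables",
      patients = dt(subject_id = integer(), gender = character(),
                    dob = .ts(character()), dod = .ts(character())),
      admissions = dt(subject_id = integer(), hadm_id = integer(),
                      admittime = .ts(character()),
                      dischtime = .ts(character()),
                      deathtime = .ts(character()),
                      insurance = character(), ethnicity = character()),
      icustays = dt(subject_id = integer(), hadm_id = integer(),
                    icustay_id = integer(), intime = .ts(character()),
                    outtime = .ts(character())),
      chartevents = dt(subject_id = integer(), hadm_id = integer(),
                       icustay_id = integer(), itemid = integer(),
                       charttime = .ts(character()), valuenum = numeric()),
      labevents = dt(subject_id = integer(), hadm_id = integer(),
                     icustay_id = integer(), itemid = integer(),
                     charttime = .ts(character()), valuenum = numeric()),
      diagnoses_icd = dt(subject_id = integer(), hadm_id = integer(),
                         seq_num = integer(), icd9_code = character()),
      d_icd_diagnoses = dt(icd9_code = character(),
                           long_title = character()),
      noteevents = dt(subject_id = integer(), hadm_id = integer(),
                      category = character(), charttime = .ts(character()),
                      text = character()),
      truth = data.table::data.table())
}

# Hand-built stay skeleton: one patient / admission / ICU stay per row of
# `spec` (subject, intime, outtime, dischtime as POSIXct, optional age,
# gender, deathtime). Used for cohort edge-case tests.
stayEHR <- function(spec) {
  tabs <- emptyEHR()
  n <- nrow(spec)
  age <- if ("age" %in% names(spec)) spec$age else rep(50, n)
  gender <- if ("gender" %in% names(spec)) spec$gender else rep("M", n)
  death <- if ("deathtime" %in% names(spec)) spec$deathtime else
    .ts(rep(NA_character_, n))
  hadm <- if ("hadm_id" %in% names(spec)) spec$hadm_id else 1000L + seq_len(n)
  tabs@patients <- data.table::data.table(
    subject_id = unique(spec$subject),
    gender = gender[!duplicated(spec$subject)],
    dob = spec$intime[!duplicated(spec$subject)] -
      age[!duplicated(spec$subject)] * 365.25 * 86400,
    dod = .ts(rep(NA_character_, length(unique(spec$subject)))))
  tabs@admissions <- data.table::data.table(
    subject_id = spec$subject, hadm_id = hadm,
    admittime = spec$intime - 3600, dischtime = spec$dischtime,
    deathtime = death,
    insurance = rep("Private", n), ethnicity = rep("WHITE", n))
  tabs@icustays <- data.table::data.table(
    subject_id = spec$subject, hadm_id = hadm,
    icustay_id = 2000L + seq_len(n),
    intime = spec$intime, outtime = spec$outtime)
  tabs
}

# Full per-concept event coverage for given stays: n_chart observations
# of every chart concept and n_lab of every lab concept, evenly spaced.
addFullCoverage <- function(tabs, kb, n_chart = 6L, n_lab = 2L) {
  cc <- kbConcepts(kb)
  ch <- list(); lb <- list()
  for (r in seq_len(nrow(tabs@icustays))) {
    st <- tabs@icustays[r, ]
    span <- as.numeric(st$outtime) - as.numeric(st$intime)
    for (j in seq_len(nrow(cc))) {
      nobs <- if (cc$source[j] == "chart") n_chart else n_lab
      tt <- as.numeric(st$intime) + seq_len(nobs) * span / (nobs + 1)
      rng <- kbNormalRange(kb, cc$concept[j])
      ev <- data.table::data.table(
        subject_id = st$subject_id, hadm_id = st$hadm_id,
        icustay_id = st$icustay_id, itemid = cc$itemid[j],
        charttime = as.POSIXct(tt, tz = "UTC", origin = "1970-01-01"),
        valuenum = mean(rng) + seq_len(nobs) * 0.01)
      if (cc$source[j] == "chart") ch[[length(ch) + 1L]] <- ev
      else lb[[length(lb) + 1L]] <- ev
    }
  }
  tabs@chartevents <- data.table::rbindlist(ch)
  tabs@labevents <- data.table::rbindlist(lb)
  tabs
}

# Reference AUROC: brute-force concordant-pair fraction with ties = 1/2.
bruteAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Quick logistic-scorer AUROC on oracle features, split in half.
oracleAuroc <- function(tabs, kb, seed = 1) {
  feats <- oracleFeatures(tabs, kb)
  truth <- truthLabels(tabs)
  m <- merge(feats, truth[, c("icustay_id", "label")], by = "icustay_id")
  x <- as.matrix(m[, setdiff(names(m), c("subject_id", "icustay_id",
                                         "label")), with = FALSE])
  y <- m$label
  set.seed(seed)
  idx <- sample(nrow(x), floor(nrow(x) / 2))
  df_tr <- data.frame(y = y[idx], x[idx, ])
  df_te <- data.frame(x[-idx, ])
  fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                     family = stats::binomial()))
  p <- suppressWarnings(predict(fit, df_te, type = "response"))
  computeMetrics(p, y[-idx], 0.5)$auroc
}
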