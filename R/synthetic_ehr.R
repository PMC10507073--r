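#' Create a synthetic-EHR generator configuration
#'
#' Defaults encode the study conditions the pipeline is evaluated under:
#' an 11.3% marginal readmission rate, hourly chart sampling and daily
#' laboratory sampling with irregular (exponential) gaps, 15% per-concept
#' missingness, and unit effect sizes for each modality. The charts
#' effect is injected as a constant shift toward each concept's abnormal
#' direction by default (`chart_signal_target = "state"`); a
#' `"gradient"` target instead injects measurement plateaus (repeated
#' identical readings), which leave the per-observation value marginal —
#' and hence the state abstraction — essentially unchanged while
#' surfacing as Stable gradient symbols.
#'
#' @param n_patients number of patients.
#' @param readmission_rate marginal probability of the latent label.
#' @param signal_strength named numeric with entries `charts`, `icd9`,
#'   `notes` (non-negative effect sizes; 0 = no signal).
#' @param chart_signal_target `"state"`, `"gradient"` or `"both"`.
#' @param missingness per-concept observation drop probability.
#' @param chart_interval_minutes mean gap between chart observations.
#' @param lab_interval_hours mean gap between lab observations.
#' @param los_days_range uniform ICU length-of-stay range in days.
#' @param seed integer seed.
#' @return a validated [SynthConfig-class].
#' @export
synthConfig <- function(n_patients = 1000L,
                        readmission_rate = 0.113,
                        signal_strength = c(charts = 1, icd9 = 1, notes = 1),
                        chart_signal_target = "state",
                        missingness = 0.15,
                        chart_interval_minutes = 60,
                        lab_interval_hours = 24,
                        los_days_range = c(1.2, 8),
                        seed = 1L) {
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 1)
    stop("n_patients must be a positive integer")
  if (los_days_range[1] > los_days_range[2])
    stop("los_days_range is inverted")
  cfg <- new("SynthConfig",
             n_patients = as.integer(n_patients),
             readmission_rate = as.numeric(readmission_rate),
             signal_strength = signal_strength,
             chart_signal_target = chart_signal_target,
             missingness = as.numeric(missingness),
             chart_interval_minutes = as.numeric(chart_interval_minutes),
             lab_interval_hours = as.numeric(lab_interval_hours),
             los_days_range = as.numeric(los_days_range),
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

# Abnormal direction of each concept's label-dependent shift (+1 = values
# move above the normal range for readmitted patients, -1 = below).
conceptDirections <- function() {
  c(chloride = -1, creatinine = 1, glucose = 1, hemoglobin = -1,
    pco2 = 1, ph = -1, phosphate = 1, platelets = -1, po2 = -1,
    urea = 1, sodium = -1, wbc = 1,
    body_temperature = 1, glasgow_coma_scale = -1, mean_pressure = -1,
    heart_rate = 1, respiratory_rate = 1)
}

#' Bundled synthetic ICD-9 vocabulary
#'
#' A deterministic, self-contained 200-code ICD-9-style vocabulary with
#' invented-but-plausible long titles. Twenty codes are designated
#' readmission-risk codes; the generator over-samples them for patients
#' with a positive latent label, scaled by the `icd9` signal strength.
#'
#' @return `data.table` of `icd9_code`, `long_title`, `risk` (logical).
#' @export
icd9Vocabulary <- function() {
  risk <- data.table::data.table(
    icd9_code = c("4280", "42731", "5849", "5859", "49121", "5070",
                  "99592", "0389", "5770", "5712", "41071", "4439",
                  "34690", "29181", "2875", "5845", "51881", "4589",
                  "7802", "78959"),
    long_title = c(
      "Congestive heart failure, unspecified",
      "Atrial fibrillation",
      "Acute kidney failure, unspecified",
      "Chronic kidney disease, unspecified",
      "Obstructive chronic bronchitis with acute exacerbation",
      "Pneumonitis due to inhalation of food or vomitus",
      "Severe sepsis",
      "Septicemia, unspecified",
      "Acute pancreatitis",
      "Alcoholic cirrhosis of liver",
      "Subendocardial infarction, initial episode of care",
      "Peripheral vascular disease, unspecified",
      "Migraine, unspecified, with intractable status",
      "Alcohol withdrawal",
      "Thrombocytopenia, unspecified",
      "Acute kidney failure with lesion of tubular necrosis",
      "Acute respiratory failure",
      "Hypotension, unspecified",
      "Syncope and collapse",
      "Ascites, other"))
  adjectives <- c("Benign", "Chronic", "Acquired", "Localized", "Recurrent",
                  "Unspecified", "Secondary", "Postoperative", "Mild")
  sites <- c("disorder of skin", "disorder of joint", "disorder of eye",
             "disorder of ear", "disorder of stomach", "anomaly of hand",
             "lesion of nerve", "condition of spine", "disorder of muscle",
             "anomaly of foot")
  combos <- expand.grid(a = adjectives, s = sites, stringsAsFactors = FALSE)
  n_generic <- 200L - nrow(risk)
  candidates <- sprintf("%04d", (seq_len(260L) * 53L + 1000L) %% 10000L)
  candidates <- setdiff(candidates, risk$icd9_code)[seq_len(n_generic)]
  generic <- data.table::data.table(
    icd9_code = candidates,
    long_title = paste(combos$a[seq_len(n_generic)],
                       combos$s[seq_len(n_generic)]))
  out <- data.table::rbindlist(list(
    cbind(risk, risk = TRUE), cbind(generic, risk = FALSE)))
  stopifnot(!anyDuplicated(out$icd9_code))
  out
}

# Risk phrases injected into positive patients' discharge notes.
riskPhrases <- function() {
  c("poor functional status", "persistent tachycardia",
    "ongoing oxygen requirement", "recurrent aspiration events",
    "medication noncompliance", "failure to thrive",
    "unstable vital signs at discharge", "advanced heart failure",
    "worsening renal function", "high risk of decompensation")
}

presentingComplaints <- function() {
  c("shortness of breath", "chest pain", "altered mental status",
    "abdominal pain", "fever and chills", "gastrointestinal bleeding",
    "weakness and falls", "hypotension")
}

.originTime <- function() as.POSIXct("2130-01-01 00:00:00", tz = "UTC")

.secs <- function(x) as.numeric(x)  # seconds helper for clarity

# One concept's observation times within [t0, t1]: first observation soon
# after admission, then a jittered grid with spacing interval*(1 - miss),
# thinned at rate miss so the realised mean inter-event gap matches the
# configured interval (jittered-grid gaps are nearly unbiased under the
# in-stay truncation, unlike exponential gaps in short stays).
.sampleTimes <- function(t0, t1, interval_sec, miss) {
  gap_eff <- interval_sec * (1 - miss)
  span <- .secs(t1) - .secs(t0)
  n_max <- max(2L, ceiling(span / gap_eff) + 3L)
  sched <- (seq_len(n_max) - 1L) * gap_eff +
    runif(n_max, -0.25, 0.25) * gap_eff
  sched[1] <- 0
  tt <- .secs(t0) + runif(1, 300, 2700) + sort(sched)
  tt <- tt[tt <= .secs(t1)]
  if (length(tt) > 1L) {
    keep <- c(TRUE, runif(length(tt) - 1L) >= miss)
    tt <- tt[keep]
  }
  floor(tt)
}

# Latent concept trajectory: centre + patient offset (+ state shift for
# positives) + AR(1) noise + white measurement noise. The gradient-only
# signal is injected as measurement plateaus: with probability grad_q an
# observation repeats the previous reading exactly. Plateaus leave the
# per-observation value marginal (hence the state abstraction)
# essentially unchanged but surface as Stable gradient symbols.
.sampleValues <- function(n, centre, half, shift, grad_q) {
  base <- rnorm(1, 0, 0.3 * half)
  v <- numeric(n)
  v[1] <- rnorm(1, 0, 0.4 * half)
  if (n > 1) {
    delta <- rnorm(n - 1L, 0, 0.25 * half)
    for (t in 2:n) v[t] <- 0.9 * v[t - 1L] + delta[t - 1L]
  }
  x <- centre + base + shift + v + rnorm(n, 0, 0.1 * half)
  if (grad_q > 0 && n > 1) {
    rep_mask <- runif(n - 1L) < grad_q
    for (t in which(rep_mask) + 1L) x[t] <- x[t - 1L]
  }
  x
}

#' Generate a synthetic MIMIC-III-schema EHR
#'
#' Simulates `n_patients` index ICU stays with demographics, irregularly
#' sampled chart and laboratory events for the 17 knowledge-base
#' concepts, ICD-9 diagnosis sequences with textual descriptions, a
#' templated discharge note, and hospital/ICU admission-discharge
#' timestamps. Each patient carries a latent 30-day readmission label
#' with marginal probability `readmission_rate`; positives receive a
#' follow-up ICU admission within 30 days of hospital discharge,
#' negatives either none or one at 45+ days. Label-dependent structure
#' (abnormal-shifted trajectories, over-sampled risk ICD-9 codes,
#' injected risk phrases) is scaled by the per-modality
#' `signal_strength`; at strength 0 a modality is label-independent.
#'
#' @param config a [SynthConfig-class], see [synthConfig()].
#' @param kb a [KnowledgeBase-class]; defaults to the bundled one.
#' @return an [EHRTables-class]; the `truth` slot records the latent
#'   label per patient (`truthLabels()`).
#' @examples
#' tabs <- generateEHR(synthConfig(n_patients = 20, seed = 7))
#' tabs
#' @export
generateEHR <- function(config, kb = loadKnowledgeBase()) {
  validObject(config)
  set.seed(config@seed)
  n <- config@n_patients
  miss <- config@missingness
  sig <- config@signal_strength
  dirs <- conceptDirections()
  origin <- .originTime()
  vocab <- icd9Vocabulary()
  risk_codes <- vocab$icd9_code[vocab$risk]
  phrases <- riskPhrases()
  complaints <- presentingComplaints()

  cc <- kb@concepts
  ranges <- t(vapply(cc$concept, function(nm) kbNormalRange(kb, nm),
                     numeric(2)))
  centres <- rowMeans(ranges)
  halves <- (ranges[, 2] - ranges[, 1]) / 2

  label <- rbinom(n, 1L, config@readmission_rate)
  gender <- sample(c("M", "F"), n, replace = TRUE)
  age <- sample(18:89, n, replace = TRUE)
  insurance <- sample(c("Medicare", "Medicaid", "Private", "Government",
                        "Self Pay"), n, replace = TRUE,
                      prob = c(0.45, 0.1, 0.33, 0.07, 0.05))
  ethnicity <- sample(c("WHITE", "BLACK/AFRICAN AMERICAN", "HISPANIC/LATINO",
                        "ASIAN", "OTHER"), n, replace = TRUE,
                      prob = c(0.68, 0.12, 0.08, 0.05, 0.07))

  admit <- .secs(origin) + floor(runif(n, 0, 3650 * 86400))
  intime <- admit + floor(runif(n, 2, 24) * 3600)
  los <- runif(n, config@los_days_range[1], config@los_days_range[2])
  outtime <- intime + floor(los * 86400)
  disch <- outtime + floor(runif(n, 0.5, 3) * 86400)
  dob <- admit - floor((age + runif(n)) * 365.25 * 86400)

  state_shift_on <- config@chart_signal_target %in% c("state", "both")
  grad_on <- config@chart_signal_target %in% c("gradient", "both")
  grad_q_pos <- if (grad_on) min(0.25 * sig[["charts"]], 0.6) else 0

  ev_time <- vector("list", n); ev_val <- vector("list", n)
  ev_item <- vector("list", n); ev_src <- vector("list", n)
  diag_list <- vector("list", n); note_text <- character(n)

  for (i in seq_len(n)) {
    times_i <- list(); vals_i <- list(); items_i <- list(); src_i <- list()
    for (j in seq_len(nrow(cc))) {
      interval_sec <- if (cc$source[j] == "chart")
        config@chart_interval_minutes * 60 else config@lab_interval_hours * 3600
      tt <- .sampleTimes(intime[i], outtime[i], interval_sec, miss)
      if (!length(tt)) next
      shift <- if (label[i] == 1L && state_shift_on)
        dirs[[cc$concept[j]]] * sig[["charts"]] * 0.6 * halves[j] else 0
      gq <- if (label[i] == 1L) grad_q_pos else 0
      vv <- .sampleValues(length(tt), centres[j], halves[j], shift, gq)
      times_i[[j]] <- tt
      vals_i[[j]] <- round(vv, 3)
      items_i[[j]] <- rep(cc$itemid[j], length(tt))
      src_i[[j]] <- rep(cc$source[j], length(tt))
    }
    ev_time[[i]] <- unlist(times_i); ev_val[[i]] <- unlist(vals_i)
    ev_item[[i]] <- unlist(items_i); ev_src[[i]] <- unlist(src_i)

    n_codes <- 4L + rpois(1, 5)
    w <- rep(1, nrow(vocab))
    if (label[i] == 1L)
      w[vocab$risk] <- 1 + 3 * sig[["icd9"]]
    codes_i <- sample(vocab$icd9_code, min(n_codes, nrow(vocab)),
                      prob = w / sum(w))
    diag_list[[i]] <- codes_i

    lambda <- 0.4 + if (label[i] == 1L) 2 * sig[["notes"]] else 0
    n_phr <- rpois(1, lambda)
    phr <- if (n_phr > 0)
      paste0("Notable for ", paste(sample(phrases, n_phr, replace = TRUE),
                                   collapse = ", and "), ".") else ""
    titles_i <- vocab$long_title[match(codes_i[seq_len(min(3, length(codes_i)))],
                                       vocab$icd9_code)]
    note_text[i] <- paste0(
      "Admission Date: [**", format(as.POSIXct(admit[i], tz = "UTC",
        origin = "1970-01-01"), "%Y-%m-%d"), "**]  Discharge Date: [**",
      format(as.POSIXct(disch[i], tz = "UTC", origin = "1970-01-01"),
             "%Y-%m-%d"), "**]\n",
      "Service: MEDICINE\n",
      "History of Present Illness: ", age[i], " year old ",
      ifelse(gender[i] == "M", "male", "female"), " admitted with ",
      sample(complaints, 1), ".\n",
      "Hospital Course: The patient was monitored in the intensive care ",
      "unit and treated with supportive care. ", phr, "\n",
      "Discharge Diagnosis: ", paste(titles_i, collapse = "; "), "\n",
      "Discharge Condition: ", sample(c("Stable", "Guarded"), 1), ".")
  }

  subj <- seq_len(n)
  hadm <- 100000L + subj
  icu <- 200000L + subj

  # Follow-up ICU admissions implementing the label mechanism.
  fu_gap <- rep(NA_real_, n)
  fu_gap[label == 1L] <- runif(sum(label == 1L), 0.5, 29.5)
  neg <- which(label == 0L)
  has_fu <- neg[runif(length(neg)) < 0.35]
  fu_gap[has_fu] <- runif(length(has_fu), 45, 330)
  fu <- which(!is.na(fu_gap))
  fu_in <- disch[fu] + floor(fu_gap[fu] * 86400)
  fu_admit <- fu_in - floor(runif(length(fu), 1, 6) * 3600)
  fu_out <- fu_in + floor(runif(length(fu), 1, 4) * 86400)
  fu_disch <- fu_out + floor(runif(length(fu), 0.5, 2) * 86400)
  fu_hadm <- 150000L + seq_along(fu)
  fu_icu <- 250000L + seq_along(fu)

  ts <- function(x) as.POSIXct(x, tz = "UTC", origin = "1970-01-01")

  patients <- data.table::data.table(
    subject_id = subj, gender = gender, dob = ts(dob),
    dod = ts(rep(NA_real_, n)))
  admissions <- data.table::data.table(
    subject_id = c(subj, fu),
    hadm_id = c(hadm, fu_hadm),
    admittime = ts(c(admit, fu_admit)),
    dischtime = ts(c(disch, fu_disch)),
    deathtime = ts(rep(NA_real_, n + length(fu))),
    insurance = c(insurance, insurance[fu]),
    ethnicity = c(ethnicity, ethnicity[fu]))
  icustays <- data.table::data.table(
    subject_id = c(subj, fu),
    hadm_id = c(hadm, fu_hadm),
    icustay_id = c(icu, fu_icu),
    intime = ts(c(intime, fu_in)),
    outtime = ts(c(outtime, fu_out)))
  data.table::setkey(icustays, subject_id, intime)

  n_ev <- lengths(ev_time)
  events <- data.table::data.table(
    subject_id = rep(subj, n_ev),
    hadm_id = rep(hadm, n_ev),
    icustay_id = rep(icu, n_ev),
    itemid = unlist(ev_item),
    charttime = ts(unlist(ev_time)),
    valuenum = unlist(ev_val),
    src = unlist(ev_src))
  chartevents <- events[events$src == "chart",
                        !"src"][order(subject_id, itemid, charttime)]
  labevents <- events[events$src == "lab",
                      !"src"][order(subject_id, itemid, charttime)]

  n_dx <- lengths(diag_list)
  diagnoses <- data.table::data.table(
    subject_id = rep(subj, n_dx),
    hadm_id = rep(hadm, n_dx),
    seq_num = unlist(lapply(n_dx, seq_len)),
    icd9_code = unlist(diag_list))

  noteevents <- data.table::data.table(
    subject_id = subj, hadm_id = hadm,
    category = "Discharge summary",
    charttime = ts(disch), text = note_text)

  truth <- data.table::data.table(
    subject_id = subj, icustay_id = icu, label = as.numeric(label),
    followup_gap_days = fu_gap)

  new("EHRTables",
      patients = patients, admissions = admissions, icustays = icustays,
      chartevents = chartevents, labevents = labevents,
      diagnoses_icd = diagnoses,
      d_icd_diagnoses = vocab[, c("icd9_code", "long_title")],
      noteevents = noteevents, truth = truth)
}

#' Latent labels of a synthetic EHR
#' @param tables an [EHRTables-class] produced by [generateEHR()].
#' @return `data.table` of `subject_id`, `icustay_id`, `label`.
#' @export
truthLabels <- function(tables) {
  if (!nrow(tables@truth)) stop("tables carry no generator truth")
  data.table::copy(tables@truth)
}

.tableNames <- function() {
  c("patients", "admissions", "icustays", "chartevents", "labevents",
    "diagnoses_icd", "d_icd_diagnoses", "noteevents")
}

.fileNames <- function() toupper(.tableNames())

#' Write EHR tables to a directory of CSV files
#'
#' One CSV per table (`PATIENTS.csv`, `ADMISSIONS.csv`, ...), timestamps
#' in ISO-8601. Round-trips losslessly through [loadEHR()]. Empty tables
#' produce valid headers-only files.
#'
#' @param tables an [EHRTables-class].
#' @param directory output directory (created if absent).
#' @return invisibly, the vector of written file paths.
#' @export
writeEHR <- function(tables, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  nms <- .tableNames()
  paths <- file.path(directory, paste0(.fileNames(), ".csv"))
  for (k in seq_along(nms)) {
    dt <- data.table::copy(slot(tables, nms[k]))
    for (col in names(dt))
      if (inherits(dt[[col]], "POSIXct"))
        data.table::set(dt, j = col,
                        value = format(dt[[col]], "%Y-%m-%dT%H:%M:%S",
                                       tz = "UTC"))
    data.table::fwrite(dt, paths[k])
  }
  invisible(paths)
}

#' Oracle features of a synthetic EHR
#'
#' Per-stay summary features that read out exactly the structures the
#' generator injects, one composite per injection channel: `chart_dev`,
#' the direction-aligned standardized mean deviation averaged over the
#' chart concepts; `chart_up`, the mean fraction of increasing
#' consecutive differences; `risk_codes`, the count of risk ICD-9
#' codes; and `risk_phrases`, the count of risk-phrase occurrences in
#' the discharge note. A logistic model on these features is the
#' reference scorer used to audit generator signal (its discrimination
#' is chance when all signal strengths are zero and non-decreasing in
#' the signal strength).
#'
#' @param tables an [EHRTables-class].
#' @param kb a [KnowledgeBase-class].
#' @return `data.table` keyed by `subject_id`, `icustay_id`.
#' @export
oracleFeatures <- function(tables, kb) {
  cc <- kb@concepts[kb@concepts$source == "chart", ]
  dirs <- conceptDirections()
  ce <- tables@chartevents
  feats <- tables@icustays[tables@icustays$icustay_id %in%
                             unique(ce$icustay_id),
                           c("subject_id", "icustay_id")]
  per_concept <- list()
  for (j in seq_len(nrow(cc))) {
    rng <- kbNormalRange(kb, cc$concept[j])
    centre <- mean(rng); half <- diff(rng) / 2
    d <- dirs[[cc$concept[j]]]
    sub <- ce[ce$itemid == cc$itemid[j]][order(icustay_id, charttime)]
    per_concept[[j]] <- sub[, list(
      dev = mean((valuenum - centre) / half) * d,
      upfrac = if (.N > 1) mean(diff(valuenum) > 0) else 0.5),
      by = "icustay_id"]
  }
  comp <- data.table::rbindlist(per_concept)[, list(
    chart_dev = mean(dev), chart_up = mean(upfrac)), by = "icustay_id"]
  feats <- merge(feats, comp, by = "icustay_id", all.x = TRUE)
  vocab <- icd9Vocabulary()
  risk <- vocab$icd9_code[vocab$risk]
  dx <- merge(tables@diagnoses_icd,
              tables@icustays[, c("hadm_id", "icustay_id")], by = "hadm_id")
  rc <- dx[, list(risk_codes = sum(icd9_code %in% risk)), by = "icustay_id"]
  feats <- merge(feats, rc, by = "icustay_id", all.x = TRUE)
  notes <- merge(tables@noteevents,
                 tables@icustays[, c("hadm_id", "icustay_id")], by = "hadm_id")
  phr <- riskPhrases()
  countHits <- function(tx, p) {
    m <- gregexpr(p, tx, fixed = TRUE)[[1]]
    sum(m > 0)
  }
  notes$risk_phrases <- vapply(notes$text, function(tx)
    sum(vapply(phr, countHits, 1L, tx = tx)), 1L)
  feats <- merge(feats, notes[, c("icustay_id", "risk_phrases")],
                 by = "icustay_id", all.x = TRUE)
  for (col in setdiff(names(feats), c("subject_id", "icustay_id")))
    data.table::set(feats, which(is.na(feats[[col]])), col, 0)
  feats
}
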