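.schemaColumns <- function() {
  list(
    patients = c("subject_id", "gender", "dob", "dod"),
    admissions = c("subject_id", "hadm_id", "admittime", "dischtime",
                   "deathtime", "insurance", "ethnicity"),
    icustays = c("subject_id", "hadm_id", "icustay_id", "intime", "outtime"),
    chartevents = c("subject_id", "hadm_id", "icustay_id", "itemid",
                    "charttime", "valuenum"),
    labevents = c("subject_id", "hadm_id", "icustay_id", "itemid",
                  "charttime", "valuenum"),
    diagnoses_icd = c("subject_id", "hadm_id", "seq_num", "icd9_code"),
    d_icd_diagnoses = c("icd9_code", "long_title"),
    noteevents = c("subject_id", "hadm_id", "category", "charttime", "text")
  )
}

.timestampColumns <- function() {
  c("dob", "dod", "admittime", "dischtime", "deathtime", "intime",
    "outtime", "charttime")
}

.parseTimes <- function(dt, table_name) {
  for (col in intersect(names(dt), .timestampColumns())) {
    if (inherits(dt[[col]], "POSIXct")) {
      attr(dt[[col]], "tzone") <- "UTC"
      next
    }
    raw <- as.character(dt[[col]])
    fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")
    parsed <- as.POSIXct(rep(NA_real_, length(raw)), tz = "UTC",
                         origin = "1970-01-01")
    for (fmt in fmts) {
      todo <- is.na(parsed)
      if (!any(todo)) break
      parsed[todo] <- as.POSIXct(strptime(raw[todo], fmt, tz = "UTC"))
    }
    bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
    if (length(bad))
      stop(sprintf("%s: unparseable timestamp in column %s at row %d (%s)",
                   table_name, col, bad[1], raw[bad[1]]))
    data.table::set(dt, j = col, value = parsed)
  }
  dt
}

#' Load MIMIC-III-schema CSV tables
#'
#' Reads the eight tables written by [writeEHR()] (or extracted from
#' MIMIC-III with matching headers), keeping only the schema's column
#' subset — unknown extra columns are ignored — and parsing timestamps.
#'
#' @param directory directory holding `PATIENTS.csv`, `ADMISSIONS.csv`,
#'   `ICUSTAYS.csv`, `CHARTEVENTS.csv`, `LABEVENTS.csv`,
#'   `DIAGNOSES_ICD.csv`, `D_ICD_DIAGNOSES.csv`, `NOTEEVENTS.csv`.
#' @return an [EHRTables-class] (with an empty `truth` slot).
#' @export
loadEHR <- function(directory) {
  schema <- .schemaColumns()
  nms <- .tableNames()
  out <- list()
  for (k in seq_along(nms)) {
    path <- file.path(directory, paste0(.fileNames()[k], ".csv"))
    if (!file.exists(path)) stop("missing file: ", path)
    dt <- data.table::fread(path, colClasses = list(
      character = intersect(c("icd9_code", "text", "category", "gender",
                              "insurance", "ethnicity"), schema[[k]])))
    absent <- setdiff(schema[[k]], names(dt))
    if (length(absent))
      stop(path, ": missing column(s) ", paste(absent, collapse = ", "))
    dt <- dt[, schema[[k]], with = FALSE]
    out[[nms[k]]] <- .parseTimes(dt, nms[k])
  }
  new("EHRTables",
      patients = out$patients, admissions = out$admissions,
      icustays = out$icustays, chartevents = out$chartevents,
      labevents = out$labevents, diagnoses_icd = out$diagnoses_icd,
      d_icd_diagnoses = out$d_icd_diagnoses, noteevents = out$noteevents,
      truth = data.table::data.table())
}

.stayFrame <- function(tables) {
  stays <- merge(tables@icustays,
                 tables@admissions[, c("hadm_id", "admittime", "dischtime",
                                       "deathtime", "insurance", "ethnicity")],
                 by = "hadm_id")
  stays <- merge(stays, tables@patients[, c("subject_id", "gender", "dob",
                                            "dod")], by = "subject_id")
  # MIMIC de-identification shifts ages > 89; cap computed ages at 90.
  age <- floor(as.numeric(difftime(stays$intime, stays$dob,
                                   units = "days")) / 365.25)
  stays$age_years <- ifelse(age > 89, 90, age)
  stays$los_days <- as.numeric(difftime(stays$outtime, stays$intime,
                                        units = "days"))
  stays
}

#' Apply the cohort inclusion filters
#'
#' Retains ICU stays of adults (age 18+ at ICU admission) with a length
#' of stay between 1 and 30 days, at least one measurement of every lab
#' concept and at least five of every chart concept during the stay, and
#' no death during the stay or within the 30 days following hospital
#' discharge. Filters are conjunctive; the report records each rule in
#' order with the number removed at that step.
#'
#' @param tables an [EHRTables-class].
#' @param kb a [KnowledgeBase-class] listing the 12 lab and 5 chart
#'   concepts whose coverage is required.
#' @return list with `stays` (the surviving stay table) and `report`
#'   (a `data.table` of `rule`, `n_removed`, `n_remaining`).
#' @export
applyInclusionFilters <- function(tables, kb) {
  if (!nrow(tables@icustays)) stop("no ICU stays in input")
  cc <- kb@concepts
  if (!all(c("chart", "lab") %in% cc$source))
    stop("knowledge base must contain both chart and lab concepts")
  stays <- .stayFrame(tables)

  countPerConcept <- function(events, ids) {
    ev <- merge(events[, c("icustay_id", "itemid", "charttime")],
                stays[, c("icustay_id", "intime", "outtime")],
                by = "icustay_id")
    ev <- ev[ev$charttime >= ev$intime & ev$charttime <= ev$outtime, ]
    ev <- ev[ev$itemid %in% ids, ]
    counts <- ev[, list(n = .N), by = c("icustay_id", "itemid")]
    ok <- counts[, list(n_items = .N, min_n = min(n)), by = "icustay_id"]
    ok
  }
  lab_ids <- cc$itemid[cc$source == "lab"]
  chart_ids <- cc$itemid[cc$source == "chart"]
  lab_cov <- countPerConcept(tables@labevents, lab_ids)
  chart_cov <- countPerConcept(tables@chartevents, chart_ids)

  death <- pmin(stays$deathtime, stays$dod, na.rm = TRUE)
  limit <- stays$dischtime + 30 * 86400

  rules <- list(
    adult_age = stays$age_years >= 18,
    los_1_to_30_days = stays$los_days >= 1 & stays$los_days <= 30,
    lab_coverage = stays$icustay_id %in%
      lab_cov$icustay_id[lab_cov$n_items == length(lab_ids) &
                           lab_cov$min_n >= 1],
    chart_coverage = stays$icustay_id %in%
      chart_cov$icustay_id[chart_cov$n_items == length(chart_ids) &
                             chart_cov$min_n >= 5],
    no_death_within_30d = is.na(death) | death > limit
  )
  keep <- rep(TRUE, nrow(stays))
  report <- data.table::data.table(rule = character(), n_removed = integer(),
                                   n_remaining = integer())
  for (nm in names(rules)) {
    removed <- sum(keep & !rules[[nm]])
    keep <- keep & rules[[nm]]
    report <- rbind(report, data.table::data.table(
      rule = nm, n_removed = removed, n_remaining = sum(keep)))
  }
  list(stays = stays[keep, ], report = report)
}

#' Assign 30-day readmission labels
#'
#' A stay is labeled positive iff another ICU stay of the same patient
#' begins within the 30 days (boundary inclusive, measured as elapsed
#' 30 x 24 h) following the index stay's hospital discharge time. The
#' lookup runs against the full ICU-stay table, so stays excluded from
#' index candidacy still count as readmission targets.
#'
#' @param stays a stay table from [applyInclusionFilters()].
#' @param tables the [EHRTables-class] the stays came from.
#' @return `stays` with a `label` column (0/1).
#' @export
assignLabels <- function(stays, tables) {
  if (any(is.na(stays$dischtime)))
    stop("stay without a hospital discharge time: icustay_id ",
         stays$icustay_id[which(is.na(stays$dischtime))[1]])
  all_in <- tables@icustays[, c("subject_id", "intime")]
  stays$label <- vapply(seq_len(nrow(stays)), function(r) {
    t0 <- stays$dischtime[r]
    cand <- all_in$intime[all_in$subject_id == stays$subject_id[r]]
    gap <- as.numeric(difftime(cand, t0, units = "secs"))
    as.numeric(any(gap > 0 & gap <= 30 * 86400))
  }, numeric(1))
  stays
}

#' Select index stays: first ICU stay per rolling year
#'
#' Scans each patient's labeled stays in chronological order and keeps a
#' stay only if no already-kept stay of that patient began within the
#' preceding 365 days, implementing the exclusion of patients
#' hospitalized within the past year as a rolling window rather than a
#' calendar year.
#'
#' @param stays labeled stay table from [assignLabels()].
#' @return cohort `data.table`, one row per index stay: identifiers,
#'   `label`, `age_years`, `gender`, `insurance`, `ethnicity`,
#'   `los_days`, `intime`, `outtime`, `hospital_dischtime`.
#' @export
selectIndexStays <- function(stays) {
  stays <- stays[order(stays$subject_id, stays$intime), ]
  keep <- logical(nrow(stays))
  last_kept <- NULL; last_subj <- NULL
  for (r in seq_len(nrow(stays))) {
    s <- stays$subject_id[r]
    if (is.null(last_subj) || s != last_subj) {
      keep[r] <- TRUE
      last_subj <- s; last_kept <- stays$intime[r]
    } else {
      gap <- as.numeric(difftime(stays$intime[r], last_kept, units = "days"))
      if (gap > 365) {
        keep[r] <- TRUE
        last_kept <- stays$intime[r]
      }
    }
  }
  out <- stays[keep, c("subject_id", "icustay_id", "hadm_id", "label",
                       "age_years", "gender", "insurance", "ethnicity",
                       "los_days", "intime", "outtime", "dischtime")]
  data.table::setnames(out, "dischtime", "hospital_dischtime")
  out
}

#' Build the unplanned-readmission cohort
#'
#' Convenience wrapper running [applyInclusionFilters()],
#' [assignLabels()] and [selectIndexStays()].
#'
#' @param tables an [EHRTables-class].
#' @param kb a [KnowledgeBase-class].
#' @return list with `cohort` and `report`.
#' @export
buildCohort <- function(tables, kb = loadKnowledgeBase()) {
  flt <- applyInclusionFilters(tables, kb)
  labeled <- assignLabels(flt$stays, tables)
  list(cohort = selectIndexStays(labeled), report = flt$report)
}

#' Patient-level stratified k-fold split
#'
#' Divides patients (never stays) into `k` folds, stratified on whether
#' any of a patient's stays is positive, so every test set holds about
#' 1/k of the patients with a label prevalence close to the global one.
#' Within each fold a stratified `val_fraction` of the training patients
#' is held out as the training loop's validation set. Deterministic
#' given `seed`.
#'
#' @param cohort cohort table from [buildCohort()].
#' @param k number of folds (default 5).
#' @param val_fraction fraction of training patients held out for
#'   validation (default 0.125).
#' @param seed integer seed.
#' @return a [FoldSplit-class].
#' @export
makeFolds <- function(cohort, k = 5L, val_fraction = 0.125, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  pat <- data.table::as.data.table(cohort)[, list(
    stratum = as.integer(any(label == 1))), by = "subject_id"]
  if (length(unique(pat$stratum)) < 2L)
    stop("cohort must contain both labels")
  for (s in unique(pat$stratum))
    if (sum(pat$stratum == s) < k)
      stop("a label class has fewer patients than k")
  set.seed(seed)
  pat$fold <- NA_integer_
  for (s in unique(pat$stratum)) {
    idx <- which(pat$stratum == s)
    idx <- idx[sample.int(length(idx))]
    pat$fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds <- lapply(seq_len(k), function(f) {
    test <- pat$subject_id[pat$fold == f]
    pool <- pat[pat$fold != f, ]
    val <- unlist(lapply(unique(pool$stratum), function(s) {
      ids <- pool$subject_id[pool$stratum == s]
      ids <- ids[sample.int(length(ids))]
      utils::head(ids, max(1L, round(val_fraction * length(ids))))
    }))
    list(train = sort(setdiff(pool$subject_id, val)),
         val = sort(val), test = sort(test))
  })
  new("FoldSplit", assignment = pat, folds = folds, k = as.integer(k))
}

#' Demographic strata of a labeled cohort
#'
#' Cross-tabulates positives and negatives over gender and the 18-65 /
#' over-65 age split, the demographic breakdown used to describe the
#' cohort. The sum of positives over strata equals the total number of
#' positive stays.
#'
#' @param cohort cohort table from [buildCohort()].
#' @return `data.table` of `gender`, `age_group`, `positives`,
#'   `negatives`.
#' @export
cohortStrata <- function(cohort) {
  dt <- data.table::as.data.table(cohort)
  dt$age_group <- ifelse(dt$age_years <= 65, "18-65", ">65")
  out <- dt[, list(positives = sum(label == 1), negatives = sum(label == 0)),
            by = c("gender", "age_group")]
  data.table::setorder(out, gender, age_group)
  out
}

#' Reference cohort strata of the MIMIC-III unplanned-readmission subset
#'
#' The published demographic breakdown of the unplanned-readmission
#' cohort (positives / negatives by gender and age group), bundled as a
#' reference input so its internal consistency — strata summing to the
#' stated totals of 1752 readmissions, 13672 non-readmissions and 15424
#' stays — can be recomputed.
#'
#' @return `data.table` of `gender`, `age_group`, `positives`,
#'   `negatives`.
#' @export
referenceCohortStrata <- function() {
  data.table::data.table(
    gender = c("M", "M", "F", "F"),
    age_group = c("18-65", ">65", "18-65", ">65"),
    positives = c(485L, 531L, 303L, 433L),
    negatives = c(4268L, 3569L, 2659L, 3176L))
}

#' Totals implied by a strata table
#' @param strata a table like [referenceCohortStrata()].
#' @return named numeric: `positives`, `negatives`, `stays`.
#' @export
strataTotals <- function(strata) {
  p <- sum(strata$positives); n <- sum(strata$negatives)
  c(positives = p, negatives = n, stays = p + n)
}
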