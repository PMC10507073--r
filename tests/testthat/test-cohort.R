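kb <- loadKnowledgeBase()

test_that("loadEHR reports missing files and drops unknown columns", {
  tabs <- generateEHR(synthConfig(n_patients = 5, seed = 1), kb)
  d <- withr::local_tempdir()
  writeEHR(tabs, d)
  file.remove(file.path(d, "ICUSTAYS.csv"))
  expect_error(loadEHR(d), "ICUSTAYS.csv")

  writeEHR(tabs, d)
  pt <- data.table::fread(file.path(d, "PATIENTS.csv"))
  pt$row_id <- seq_len(nrow(pt))
  pt$expire_flag <- 0L
  data.table::fwrite(pt, file.path(d, "PATIENTS.csv"))
  back <- loadEHR(d)
  expect_named(back@patients, c("subject_id", "gender", "dob", "dod"))
})

test_that("loadEHR reports unparseable timestamps with their row", {
  tabs <- generateEHR(synthConfig(n_patients = 3, seed = 1), kb)
  d <- withr::local_tempdir()
  writeEHR(tabs, d)
  st <- data.table::fread(file.path(d, "ICUSTAYS.csv"),
                          colClasses = "character")
  st$intime[2] <- "not-a-time"
  data.table::fwrite(st, file.path(d, "ICUSTAYS.csv"))
  expect_error(loadEHR(d), "row 2")
})

test_that("each inclusion rule removes exactly its planted violation", {
  t0 <- .ts("2130-06-01 12:00:00")
  day <- 86400
  spec <- data.frame(
    subject = 1:5,
    intime = t0 + (0:4) * 40 * day,
    age = c(50, 50, 50, 50, 17))
  spec$outtime <- spec$intime + 3 * day
  spec$outtime[2] <- spec$intime[2] + 0.5 * day       # LOS violation
  spec$dischtime <- spec$outtime + day
  spec$deathtime <- .ts(rep(NA_character_, 5))
  spec$deathtime[4] <- spec$dischtime[4] + 10 * day   # death at day 10
  tabs <- stayEHR(spec)
  tabs <- addFullCoverage(tabs, kb)
  hr <- kbConcepts(kb)[concept == "heart_rate", itemid]
  ce <- tabs@chartevents
  drop <- which(ce$subject_id == 3 & ce$itemid == hr)
  tabs@chartevents <- ce[-drop[seq_len(length(drop) - 4L)], ]  # 4 HR left

  res <- applyInclusionFilters(tabs, kb)
  expect_equal(sort(res$stays$subject_id), c(1L))
  rep <- res$report
  expect_equal(rep$n_removed[rep$rule == "adult_age"], 1L)
  expect_equal(rep$n_removed[rep$rule == "los_1_to_30_days"], 1L)
  expect_equal(rep$n_removed[rep$rule == "chart_coverage"], 1L)
  expect_equal(rep$n_removed[rep$rule == "no_death_within_30d"], 1L)
  expect_true(all(diff(rep$n_remaining) <= 0))
})

test_that("filters are conjunctive: survivors equal the rule intersection", {
  tabs <- generateEHR(synthConfig(n_patients = 40, seed = 9), kb)
  res <- applyInclusionFilters(tabs, kb)
  # recompute every rule independently of the pipeline
  stays <- ReadmitTA:::.stayFrame(tabs)
  death <- pmin(stays$deathtime, stays$dod, na.rm = TRUE)
  cc <- kbConcepts(kb)
  coveredIds <- function(events, src, min_n) {
    ids <- cc$itemid[cc$source == src]
    ok <- character(0)
    keep <- vapply(stays$icustay_id, function(sid) {
      row <- stays[stays$icustay_id == sid, ]
      ev <- events[events$icustay_id == sid &
                     events$charttime >= row$intime &
                     events$charttime <= row$outtime, ]
      counts <- table(factor(ev$itemid, levels = ids))
      all(counts >= min_n)
    }, logical(1))
    stays$icustay_id[keep]
  }
  ok <- stays$age_years >= 18 &
    stays$los_days >= 1 & stays$los_days <= 30 &
    (is.na(death) | death > stays$dischtime + 30 * 86400) &
    stays$icustay_id %in% coveredIds(tabs@labevents, "lab", 1) &
    stays$icustay_id %in% coveredIds(tabs@chartevents, "chart", 5)
  expect_setequal(res$stays$icustay_id, stays$icustay_id[ok])
})

test_that("30-day label window is anchored on hospital discharge, inclusive", {
  t0 <- .ts("2131-01-01 00:00:00")
  day <- 86400
  spec <- data.frame(
    subject = c(1L, 1L, 2L, 2L, 3L, 3L, 4L),
    intime = c(t0, t0 + 33 * day,            # gap 29d after disch
               t0, t0 + 35 * day,            # gap 31d
               t0, t0 + 34 * day,            # gap exactly 30.0d
               t0))
  spec$outtime <- spec$intime + 3 * day
  spec$dischtime <- spec$outtime + day       # hospital disch at day 4
  tabs <- stayEHR(spec)
  stays <- ReadmitTA:::.stayFrame(tabs)
  idx <- stays[stays$intime == t0, ]
  labeled <- assignLabels(idx, tabs)
  lab <- labeled$label[order(labeled$subject_id)]
  expect_equal(lab, c(1, 0, 1, 0))
})

test_that("index-stay selection keeps the first stay per rolling year", {
  t0 <- .ts("2132-01-01 00:00:00")
  day <- 86400
  spec <- data.frame(
    subject = c(1L, 1L, 2L, 2L, 3L),
    intime = c(t0, t0 + 180 * day,   # 180 d apart: second dropped
               t0, t0 + 400 * day,   # 400 d apart: both kept
               t0))
  spec$outtime <- spec$intime + 2 * day
  spec$dischtime <- spec$outtime + day
  tabs <- stayEHR(spec)
  stays <- assignLabels(ReadmitTA:::.stayFrame(tabs), tabs)
  cohort <- selectIndexStays(stays)
  expect_equal(sum(cohort$subject_id == 1), 1L)
  expect_equal(sum(cohort$subject_id == 2), 2L)
  expect_equal(sum(cohort$subject_id == 3), 1L)
  expect_equal(cohort$intime[cohort$subject_id == 1], t0)
})

test_that("labels recovered from synthetic data match the generator truth", {
  tabs <- generateEHR(synthConfig(n_patients = 120, seed = 31), kb)
  bc <- buildCohort(tabs, kb)
  m <- merge(bc$cohort, truthLabels(tabs),
             by = c("subject_id", "icustay_id"))
  expect_gt(nrow(m), 100)
  expect_equal(m$label.x, m$label.y)
})

test_that("fold splits are patient-disjoint, sized and stratified", {
  tabs <- generateEHR(synthConfig(n_patients = 300, seed = 5), kb)
  cohort <- buildCohort(tabs, kb)$cohort
  folds <- makeFolds(cohort, k = 5, seed = 11)
  all_test <- unlist(lapply(folds@folds, `[[`, "test"))
  expect_setequal(all_test, unique(cohort$subject_id))
  expect_equal(anyDuplicated(all_test), 0L)
  prev <- mean(cohort$label)
  for (f in folds@folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_equal(length(f$test) / length(unique(cohort$subject_id)), 0.2,
                 tolerance = 0.02)
    test_prev <- mean(cohort$label[cohort$subject_id %in% f$test])
    expect_lt(abs(test_prev - prev), 0.02)
  }
  folds2 <- makeFolds(cohort, k = 5, seed = 11)
  expect_equal(folds@assignment, folds2@assignment)
})

test_that("stratified assignment spreads a small positive class evenly", {
  cohort <- data.frame(subject_id = 1:100,
                       label = c(rep(1, 11), rep(0, 89)))
  folds <- makeFolds(cohort, k = 5, seed = 1)
  pos_per_fold <- vapply(folds@folds, function(f)
    sum(f$test %in% 1:11), numeric(1))
  expect_true(all(pos_per_fold >= 2 & pos_per_fold <= 3))
  tiny <- data.frame(subject_id = 1:10, label = rep(c(0, 1), 5))
  f10 <- makeFolds(tiny, k = 5, seed = 2)
  expect_true(all(vapply(f10@folds, function(f)
    length(f$test), numeric(1)) == 2))
  expect_error(makeFolds(data.frame(subject_id = 1:6,
                                    label = c(1, rep(0, 5))), k = 5),
               "fewer patients than k")
})

test_that("strata positives sum to the cohort's total positives", {
  tabs <- generateEHR(synthConfig(n_patients = 150, seed = 13), kb)
  cohort <- buildCohort(tabs, kb)$cohort
  st <- cohortStrata(cohort)
  expect_equal(sum(st$positives), sum(cohort$label == 1))
  expect_equal(sum(st$positives) + sum(st$negatives), nrow(cohort))
})
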