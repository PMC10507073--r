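#' @import methods
#' @importFrom stats rbinom runif rnorm rexp rpois predict quantile sd setNames
#' @importFrom utils head tail
NULL

setOldClass("data.table")

#' Configuration for the synthetic EHR generator
#'
#' Holds every tunable of [generateEHR()]. Identical configurations
#' (including `seed`) produce byte-identical tables.
#'
#' @slot n_patients number of patients to simulate.
#' @slot readmission_rate marginal probability of the latent 30-day
#'   readmission label. Default 0.113, the prevalence reported for the
#'   unplanned-readmission subset of MIMIC-III.
#' @slot signal_strength named numeric, effect sizes for `charts`, `icd9`
#'   and `notes`; 0 removes all label-dependent structure from a modality.
#' @slot chart_signal_target where the charts effect lands: `"state"`
#'   (a constant shift toward abnormal, visible to state abstraction),
#'   `"gradient"` (measurement plateaus, visible to gradient
#'   abstraction only) or `"both"`.
#' @slot missingness per-concept probability that a scheduled observation
#'   is dropped; scheduling is rate-compensated so the mean inter-event
#'   gap still matches the configured interval.
#' @slot chart_interval_minutes,lab_interval_hours mean sampling gaps of
#'   the high-frequency chart concepts and low-frequency lab concepts.
#' @slot los_days_range ICU length-of-stay range (days), sampled uniformly.
#' @slot seed integer seed; the single source of randomness.
#' @export
setClass("SynthConfig", representation(
  n_patients = "integer",
  readmission_rate = "numeric",
  signal_strength = "numeric",
  chart_signal_target = "character",
  missingness = "numeric",
  chart_interval_minutes = "numeric",
  lab_interval_hours = "numeric",
  los_days_range = "numeric",
  seed = "integer"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (length(object@n_patients) != 1L || is.na(object@n_patients) ||
      object@n_patients < 1L)
    msg <- c(msg, "n_patients must be a positive integer")
  if (object@readmission_rate <= 0 || object@readmission_rate >= 1)
    msg <- c(msg, "readmission_rate must lie in (0, 1)")
  if (!all(c("charts", "icd9", "notes") %in% names(object@signal_strength)))
    msg <- c(msg, "signal_strength needs entries charts, icd9, notes")
  if (any(object@signal_strength < 0))
    msg <- c(msg, "signal strengths must be non-negative")
  if (object@missingness < 0 || object@missingness >= 1)
    msg <- c(msg, "missingness must lie in [0, 1)")
  if (object@chart_interval_minutes <= 0 || object@lab_interval_hours <= 0)
    msg <- c(msg, "sampling intervals must be positive")
  if (length(object@los_days_range) != 2L ||
      any(object@los_days_range <= 0) ||
      object@los_days_range[1] > object@los_days_range[2])
    msg <- c(msg, "los_days_range must be an increasing pair of positive reals")
  if (!object@chart_signal_target %in% c("state", "gradient", "both"))
    msg <- c(msg, "chart_signal_target must be state, gradient or both")
  if (length(msg)) msg else TRUE
})

#' Bundle of MIMIC-III-schema tables
#'
#' The raw input of the pipeline: eight tables mirroring the MIMIC-III
#' column subset used here (PATIENTS, ADMISSIONS, ICUSTAYS, CHARTEVENTS,
#' LABEVENTS, DIAGNOSES_ICD, D_ICD_DIAGNOSES, NOTEEVENTS), each a
#' `data.table`. The `truth` slot carries the generator's latent
#' per-patient labels when the object is synthetic (empty when loaded
#' from disk).
#'
#' @export
setClass("EHRTables", representation(
  patients = "data.table",
  admissions = "data.table",
  icustays = "data.table",
  chartevents = "data.table",
  labevents = "data.table",
  diagnoses_icd = "data.table",
  d_icd_diagnoses = "data.table",
  noteevents = "data.table",
  truth = "data.table"
))

setMethod("show", "EHRTables", function(object) {
  cat("EHRTables:",
      nrow(object@patients), "patients,",
      nrow(object@icustays), "ICU stays,",
      nrow(object@chartevents), "chart events,",
      nrow(object@labevents), "lab events,",
      nrow(object@noteevents), "notes\n")
})

#' Knowledge base of clinical-concept abstraction guidelines
#'
#' One entry per clinical concept: the source table (chart or lab), the
#' ordered state cutoffs with state names (housing the normal range), the
#' gradient significance threshold (delta) and the stable-trend window in
#' hours. The default knowledge base covers 17 readmission-related
#' concepts: 12 low-frequency laboratory concepts and 5 high-frequency
#' chart concepts.
#'
#' @slot concepts `data.table` with one row per concept: `concept`,
#'   `source`, `unit`, `itemid`, `gradient_delta`, `stable_hours`.
#' @slot states named list, per concept a `data.table` of
#'   `state`, `min`, `max` (half-open intervals, lower bound inclusive).
#' @export
setClass("KnowledgeBase", representation(
  concepts = "data.table",
  states = "list"
))

setValidity("KnowledgeBase", function(object) {
  msg <- character()
  cc <- object@concepts
  if (!all(cc$concept %in% names(object@states)))
    msg <- c(msg, "every concept needs a state table")
  if (any(cc$gradient_delta <= 0)) msg <- c(msg, "gradient_delta must be > 0")
  if (any(cc$stable_hours <= 0)) msg <- c(msg, "stable_hours must be > 0")
  for (nm in names(object@states)) {
    st <- object@states[[nm]]
    k <- nrow(st)
    if (k < 3L || k > 6L)
      msg <- c(msg, sprintf("%s: number of states must be in [3, 6]", nm))
    cuts <- st$min[-1]
    if (any(diff(cuts) <= 0) || any(!is.finite(cuts)))
      msg <- c(msg, sprintf("%s: state cutoffs must be strictly increasing", nm))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "KnowledgeBase", function(object) {
  cat("KnowledgeBase:", nrow(object@concepts), "concepts (",
      sum(object@concepts$source == "lab"), "lab,",
      sum(object@concepts$source == "chart"), "chart )\n")
})

#' Patient-level stratified fold assignment
#'
#' `k`-fold split over patients (never stays): test sets partition the
#' patients; within each fold a stratified validation fraction is carved
#' out of the training patients for the training loop.
#'
#' @slot assignment `data.table` of `subject_id`, `stratum`, `fold`.
#' @slot folds list of length `k`; each element has `train`, `val`,
#'   `test` patient-id vectors.
#' @slot k number of folds.
#' @export
setClass("FoldSplit", representation(
  assignment = "data.table",
  folds = "list",
  k = "integer"
))

setMethod("show", "FoldSplit", function(object) {
  cat("FoldSplit: k =", object@k, "over",
      nrow(object@assignment), "patients\n")
})

#' Model-ready encoded samples
#'
#' Token-index sequences padded/truncated to a common length `L` over a
#' vocabulary of size `D` (index 1 is the dedicated pad symbol), with a
#' validity mask. Optionally carries a dense per-timestep matrix layout
#' (`dense`) for the interpolated multivariate representation, and an
#' `extra` matrix of per-sample side features (e.g. demographics one-hot).
#'
#' @slot indices integer matrix, samples x L.
#' @slot mask numeric matrix, samples x L, 1 at valid positions.
#' @slot vocab character vector of length `D`; `vocab[1]` is the pad.
#' @slot L maximal sequence length.
#' @slot extra numeric matrix (samples x extra_dims), possibly 0 columns.
#' @slot dense list of per-sample dense input matrices, or empty list.
#' @slot ids sample identifiers (icustay ids).
#' @slot labels numeric 0/1 labels.
#' @export
setClass("EncodedSampleSet", representation(
  indices = "matrix",
  mask = "matrix",
  vocab = "character",
  L = "integer",
  extra = "matrix",
  dense = "list",
  ids = "integer",
  labels = "numeric"
))

setValidity("EncodedSampleSet", function(object) {
  msg <- character()
  if (ncol(object@indices) != object@L)
    msg <- c(msg, "indices must have L columns")
  if (any(object@indices < 1L) || any(object@indices > length(object@vocab)))
    msg <- c(msg, "all indices must fall inside the vocabulary")
  if (!all(dim(object@mask) == dim(object@indices)))
    msg <- c(msg, "mask must match indices in shape")
  if (any(object@indices[object@mask == 0] != 1L))
    msg <- c(msg, "padding positions must use the pad symbol")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EncodedSampleSet", function(object) {
  cat("EncodedSampleSet:", nrow(object@indices), "samples, L =", object@L,
      ", D =", length(object@vocab), "\n")
})

#' Number of samples in an EncodedSampleSet
#' @param x an `EncodedSampleSet`
#' @export
setMethod("length", "EncodedSampleSet", function(x) nrow(x@indices))

#' Bidirectional GRU classifier
#'
#' Embedding layer (dimension `floor(D^(1/4))`), two GRUs (the second
#' consuming the time-reversed input), an attention layer pooling the
#' concatenated per-timestep outputs into a fixed-size vector, and a
#' fully connected layer producing a single score. An optional extra
#' modality vector is concatenated before the final affine map.
#'
#' @slot config list of architecture sizes (`L`, `D`, `embedding_dim`,
#'   `hidden_size`, `extra_dims`, `input_dim`, `dense_input`).
#' @slot params named list of parameter matrices.
#' @export
setClass("BirnnModel", representation(
  config = "list",
  params = "list"
))

setMethod("show", "BirnnModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf(
    "BirnnModel: L=%d D=%d embed=%d hidden=%d extra=%d (%d parameters)\n",
    cfg$L, cfg$D, cfg$embedding_dim, cfg$hidden_size, cfg$extra_dims, np))
})
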