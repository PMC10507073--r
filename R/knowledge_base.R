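#' Load a clinical-concept knowledge base
#'
#' Reads a YAML knowledge base (one entry per concept: `source`, `unit`,
#' `itemid`, `gradient_delta`, `stable_hours` and an ordered list of
#' `states` with `name`/`min`/`max`) and validates it. The bundled
#' default encodes the 17 readmission-related concepts — 12 low-frequency
#' laboratory concepts and 5 high-frequency chart concepts — with their
#' normal ranges, gradient significance thresholds and stable-trend
#' windows, plus named below/above-normal states.
#'
#' State intervals are half-open with an inclusive lower bound: a value
#' `x` belongs to the state whose `[min, max)` interval contains it.
#'
#' @param path path to a YAML file; defaults to the bundled knowledge base.
#' @return a [KnowledgeBase-class] object.
#' @examples
#' kb <- loadKnowledgeBase()
#' kb
#' @export
loadKnowledgeBase <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "readmission_kb.yaml", package = "ReadmitTA")
  if (!file.exists(path)) stop("knowledge base file not found: ", path)
  raw <- yaml::read_yaml(path)

  required <- defaultConceptNames()
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("knowledge base is missing concepts: ", paste(missing, collapse = ", "))

  concepts <- data.table::rbindlist(lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    for (f in c("source", "itemid", "gradient_delta", "stable_hours", "states"))
      if (is.null(e[[f]])) stop("concept ", nm, ": missing field ", f)
    data.table::data.table(
      concept = nm, source = e$source,
      unit = if (is.null(e$unit)) NA_character_ else e$unit,
      itemid = as.integer(e$itemid),
      gradient_delta = as.numeric(e$gradient_delta),
      stable_hours = as.numeric(e$stable_hours))
  }))

  states <- lapply(raw, function(e) {
    st <- data.table::rbindlist(lapply(e$states, function(s) {
      data.table::data.table(
        state = s$name,
        min = if (is.null(s$min)) -Inf else as.numeric(s$min),
        max = if (is.null(s$max)) Inf else as.numeric(s$max))
    }))
    if (any(st$min[-1] != st$max[-nrow(st)]))
      stop("state intervals must be contiguous and increasing")
    st
  })
  names(states) <- names(raw)

  kb <- new("KnowledgeBase", concepts = concepts, states = states)
  validObject(kb)
  kb
}

defaultConceptNames <- function() {
  c("chloride", "creatinine", "glucose", "hemoglobin", "pco2", "ph",
    "phosphate", "platelets", "po2", "urea", "sodium", "wbc",
    "body_temperature", "glasgow_coma_scale", "mean_pressure",
    "heart_rate", "respiratory_rate")
}

#' Concept table of a knowledge base
#' @param kb a [KnowledgeBase-class]
#' @return `data.table` with one row per concept.
#' @export
kbConcepts <- function(kb) data.table::copy(kb@concepts)

#' State definitions for one concept
#' @param kb a [KnowledgeBase-class]
#' @param concept concept name
#' @return `data.table` of `state`, `min`, `max`.
#' @export
kbStates <- function(kb, concept) {
  if (!concept %in% names(kb@states)) stop("unknown concept: ", concept)
  data.table::copy(kb@states[[concept]])
}

#' Symbol vocabulary implied by a knowledge base
#'
#' Enumerates every concept-qualified abstraction symbol the knowledge
#' base can emit — `concept:State` for each state, and, when `gradients`
#' is `TRUE`, `concept:Increasing/Decreasing/Stable` — preceded by the
#' dedicated pad symbol at index 1. Built from the knowledge base alone,
#' so it is identical across folds and runs (no data leakage and a
#' stable vocabulary size D).
#'
#' @param kb a [KnowledgeBase-class]
#' @param gradients include gradient symbols?
#' @param source restrict to `"chart"`, `"lab"` concepts or `"both"`.
#' @return character vector; element 1 is `"<pad>"`.
#' @export
kbVocabulary <- function(kb, gradients = TRUE, source = "both") {
  cc <- kb@concepts
  if (source != "both") {
    hit <- which(cc$source == source)
    cc <- cc[hit, ]
  }
  syms <- unlist(lapply(cc$concept, function(nm) {
    st <- paste0(nm, ":", kb@states[[nm]]$state)
    if (gradients)
      st <- c(st, paste0(nm, ":", c("Increasing", "Decreasing", "Stable")))
    st
  }), use.names = FALSE)
  c("<pad>", syms)
}

#' Normal range of a concept
#'
#' Convenience accessor for the knowledge base's "Normal" interval, used
#' by the synthetic generator to centre its trajectories. For the Glasgow
#' Coma Scale the middle (Moderate) state plays this role.
#'
#' @param kb a [KnowledgeBase-class]
#' @param concept concept name
#' @return numeric `c(min, max)`.
#' @export
kbNormalRange <- function(kb, concept) {
  st <- kbStates(kb, concept)
  row <- st[st$state %in% c("Normal", "Moderate"), ]
  if (nrow(row) != 1L) row <- st[ceiling(nrow(st) / 2), ]
  c(row$min, row$max)
}
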