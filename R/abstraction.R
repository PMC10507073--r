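#' Discretize a raw series into knowledge-based states
#'
#' Maps each value to the state whose half-open interval
#' `[min, max)` contains it (lower bound inclusive), e.g. a body
#' temperature below 36.2 is Hypothermia, between 36.2 and 37.2 Normal,
#' and 37.2 or above Fever. Timestamps are preserved.
#'
#' @param series `data.frame` with columns `time` and `value`,
#'   timestamps strictly increasing.
#' @param kb a [KnowledgeBase-class].
#' @param concept concept name matching the series.
#' @return `data.table` of `time`, `state`.
#' @export
discretize <- function(series, kb, concept) {
  st <- kbStates(kb, concept)
  if (any(!is.finite(series$value))) stop("non-finite value in series")
  cuts <- st$min[-1]
  idx <- findInterval(series$value, cuts) + 1L
  data.table::data.table(time = series$time, state = st$state[idx])
}

#' Align irregular multivariate series by temporal-linear interpolation
#'
#' The union of all observation timestamps forms a common grid; each
#' concept missing at a grid time is filled by linear interpolation
#' between its two neighbouring observations (the near neighbour
#' receiving the large weight), and by carrying the nearest observed
#' value before the first / after the last observation. The result is a
#' complete grid-by-concept value matrix: one multivariate vector per
#' grid time instead of scattered univariate points.
#'
#' @param series_list named list of `data.frame`s with `time`, `value`;
#'   one entry per concept, each with at least one observation.
#' @return list with `time` (the grid) and `values`
#'   (matrix, grid times x concepts).
#' @export
interpolateToGrid <- function(series_list) {
  if (!length(series_list)) stop("empty series set")
  if (any(vapply(series_list, nrow, 1L) == 0L)) stop("empty series")
  grid <- sort(unique(unlist(lapply(series_list, function(s)
    as.numeric(s$time)))))
  vals <- vapply(series_list, function(s) {
    tt <- as.numeric(s$time)
    if (length(tt) == 1L) return(rep(s$value[1], length(grid)))
    stats::approx(tt, s$value, xout = grid, method = "linear",
                  rule = 2)$y
  }, numeric(length(grid)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(grid))
  colnames(vals) <- names(series_list)
  list(time = grid, values = vals)
}

#' Gradient (trend) abstraction of a raw series
#'
#' Symbolic direction of change between consecutive measurements. In
#' `simple` mode the label is the sign of the difference (Increasing /
#' Decreasing / Stable on exact ties). In `thresholded` mode a change is
#' labeled Stable whenever its absolute size is at most the concept's
#' gradient significance threshold and the elapsed gap is within the
#' stable-trend window; otherwise the sign decides. Gradients are
#' defined from the second observation onward, so the output has one
#' element fewer than the input; each gradient carries the later
#' observation's timestamp.
#'
#' @param series `data.frame` with `time` (POSIXct or numeric seconds)
#'   and `value`; length at least 2.
#' @param kb a [KnowledgeBase-class].
#' @param concept concept name (supplies the threshold and window).
#' @param mode `"simple"` or `"thresholded"`.
#' @return `data.table` of `time`, `gradient`.
#' @export
computeGradients <- function(series, kb, concept, mode = "simple") {
  if (nrow(series) < 2L) stop("series must have at least 2 observations")
  mode <- match.arg(mode, c("simple", "thresholded"))
  d <- diff(series$value)
  lab <- ifelse(d > 0, "Increasing", ifelse(d < 0, "Decreasing", "Stable"))
  if (mode == "thresholded") {
    hit <- which(kb@concepts$concept == concept)
    if (!length(hit)) stop("unknown concept: ", concept)
    row <- kb@concepts[hit, ]
    gap_h <- diff(as.numeric(series$time)) / 3600
    stable <- abs(d) <= row$gradient_delta & gap_h <= row$stable_hours
    lab[stable] <- "Stable"
  }
  data.table::data.table(time = series$time[-1], gradient = lab)
}

#' Flatten abstracted series into one temporally ordered symbol sequence
#'
#' Merges (timestamp, concept, symbol) events from state and gradient
#' series of all concepts into a single univariate sequence, sorted by
#' timestamp with ties broken by the knowledge-base concept order (and
#' states before gradients at identical time and concept). Symbols are
#' concept-qualified (`heart_rate:Tachycardia`,
#' `heart_rate:Increasing`) so the vocabulary keeps concepts apart.
#'
#' @param state_list named list of state series ([discretize()] output),
#'   names are concepts. May be `NULL`.
#' @param gradient_list named list of gradient series
#'   ([computeGradients()] output). May be `NULL`.
#' @param kb a [KnowledgeBase-class] (supplies the concept tie-break
#'   order).
#' @return `data.table` of `time`, `symbol`.
#' @export
flattenEvents <- function(state_list = NULL, gradient_list = NULL, kb) {
  order_map <- setNames(seq_len(nrow(kb@concepts)), kb@concepts$concept)
  parts <- list()
  for (nm in names(state_list)) {
    s <- state_list[[nm]]
    if (!nrow(s)) next
    parts[[length(parts) + 1L]] <- data.table::data.table(
      time = as.numeric(s$time), concept_rank = order_map[[nm]],
      type_rank = 0L, symbol = paste0(nm, ":", s$state))
  }
  for (nm in names(gradient_list)) {
    g <- gradient_list[[nm]]
    if (!nrow(g)) next
    parts[[length(parts) + 1L]] <- data.table::data.table(
      time = as.numeric(g$time), concept_rank = order_map[[nm]],
      type_rank = 1L, symbol = paste0(nm, ":", g$gradient))
  }
  if (!length(parts))
    return(data.table::data.table(time = numeric(), symbol = character()))
  ev <- data.table::rbindlist(parts)
  data.table::setorder(ev, time, concept_rank, type_rank)
  ev[, c("time", "symbol")]
}

#' Encode a symbol sequence as padded token indices
#'
#' Looks each symbol up in the vocabulary, truncates from the start
#' (keeping the most recent symbols) when the sequence exceeds `L`, and
#' pads at the end with the dedicated pad symbol otherwise. The mask
#' marks valid positions.
#'
#' @param symbols character vector of symbols.
#' @param vocab vocabulary with the pad symbol at index 1.
#' @param L target length.
#' @return list of `indices` (integer, length `L`), `mask` (0/1).
#' @export
encodeOnehotPad <- function(symbols, vocab, L) {
  idx <- match(symbols, vocab)
  if (anyNA(idx))
    stop("unknown symbol(s): ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  if (length(idx) > L) idx <- utils::tail(idx, L)
  n_valid <- length(idx)
  indices <- c(idx, rep(1L, L - n_valid))
  mask <- c(rep(1, n_valid), rep(0, L - n_valid))
  list(indices = as.integer(indices), mask = mask)
}

# Per-stay raw series for every knowledge-base concept, restricted to
# events inside [intime, outtime].
.staySeries <- function(tables, kb, stay_ids = NULL) {
  cc <- kb@concepts
  ev <- rbind(tables@chartevents, tables@labevents)
  ev <- merge(ev, tables@icustays[, c("icustay_id", "intime", "outtime")],
              by = "icustay_id")
  ev <- ev[ev$charttime >= ev$intime & ev$charttime <= ev$outtime, ]
  if (!is.null(stay_ids)) ev <- ev[ev$icustay_id %in% stay_ids, ]
  ev$concept <- cc$concept[match(ev$itemid, cc$itemid)]
  ev <- ev[!is.na(ev$concept), ]
  data.table::setorder(ev, icustay_id, concept, charttime)
  split(ev[, c("icustay_id", "concept", "charttime", "valuenum")],
        by = "icustay_id")
}

#' Encode stays as abstracted charts token sequences
#'
#' Full charts pathway for a set of ICU stays: per-concept state
#' abstraction (and optionally gradient abstraction), flattening into a
#' temporally ordered concept-qualified symbol sequence, and one-hot
#' index encoding padded/truncated to length `L`. The vocabulary is
#' derived from the knowledge base alone ([kbVocabulary()]), so it is
#' identical across folds.
#'
#' @param tables an [EHRTables-class].
#' @param cohort cohort table (supplies stay ids and labels).
#' @param kb a [KnowledgeBase-class].
#' @param L maximal sequence length.
#' @param gradients `"none"`, `"simple"` or `"thresholded"`.
#' @param source restrict concepts to `"chart"`, `"lab"` or `"both"`.
#' @param extra optional numeric matrix of per-stay side features, rows
#'   aligned with `cohort`.
#' @return an [EncodedSampleSet-class].
#' @export
encodeChartsSamples <- function(tables, cohort, kb, L = 128L,
                                gradients = c("simple", "none",
                                              "thresholded"),
                                source = "both", extra = NULL) {
  gradients <- match.arg(gradients)
  vocab <- kbVocabulary(kb, gradients = gradients != "none", source = source)
  keep_concepts <- if (source == "both") kb@concepts$concept else
    kb@concepts$concept[kb@concepts$source == source]
  per_stay <- .staySeries(tables, kb, cohort$icustay_id)
  n <- nrow(cohort)
  indices <- matrix(1L, n, L)
  mask <- matrix(0, n, L)
  for (r in seq_len(n)) {
    key <- as.character(cohort$icustay_id[r])
    ev <- per_stay[[key]]
    if (is.null(ev)) next
    ev <- ev[ev$concept %in% keep_concepts, ]
    states <- list(); grads <- list()
    for (nm in unique(ev$concept)) {
      s <- ev[ev$concept == nm, ]
      ser <- data.table::data.table(time = s$charttime, value = s$valuenum)
      states[[nm]] <- discretize(ser, kb, nm)
      if (gradients != "none" && nrow(ser) >= 2L)
        grads[[nm]] <- computeGradients(ser, kb, nm, mode = gradients)
    }
    flat <- flattenEvents(states, if (length(grads)) grads else NULL, kb)
    enc <- encodeOnehotPad(flat$symbol, vocab, L)
    indices[r, ] <- enc$indices
    mask[r, ] <- enc$mask
  }
  if (is.null(extra)) extra <- matrix(numeric(), n, 0)
  new("EncodedSampleSet",
      indices = indices, mask = mask, vocab = vocab, L = as.integer(L),
      extra = extra, dense = list(),
      ids = as.integer(cohort$icustay_id),
      labels = as.numeric(cohort$label))
}
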