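#' Build an ICD-9 code vocabulary from training admissions
#'
#' Index 1 is the pad symbol and index 2 a reserved unknown-code symbol;
#' codes are sorted for stability. Built from training data only, so
#' codes seen only in a test fold map to the unknown index.
#'
#' @param codes character vector of ICD-9 codes observed in training.
#' @return character vector vocabulary.
#' @export
buildIcd9Vocab <- function(codes) {
  c("<pad>", "<unk>", sort(unique(codes)))
}

#' One-hot (index) encoding of an admission's ICD-9 sequence
#'
#' Codes in `seq_num` order become a token-index sequence padded to
#' `L_codes`; both occurrences of a duplicated code are kept in order
#' (the codes form a time-ordered sequence). Codes outside the
#' vocabulary map to the reserved unknown index and are counted in the
#' `n_unknown` attribute.
#'
#' @param icd_seq `data.frame` with `seq_num`, `icd9_code` for one
#'   admission.
#' @param vocab vocabulary from [buildIcd9Vocab()].
#' @param L_codes target length.
#' @return list of `indices`, `mask`, `n_unknown`.
#' @export
encodeIcd9Onehot <- function(icd_seq, vocab, L_codes) {
  ord <- order(icd_seq$seq_num)
  codes <- icd_seq$icd9_code[ord]
  idx <- match(codes, vocab)
  n_unknown <- sum(is.na(idx))
  idx[is.na(idx)] <- 2L
  if (length(idx) > L_codes) idx <- utils::tail(idx, L_codes)
  n_valid <- length(idx)
  list(indices = as.integer(c(idx, rep(1L, L_codes - n_valid))),
       mask = c(rep(1, n_valid), rep(0, L_codes - n_valid)),
       n_unknown = n_unknown)
}

#' Textual rendering of an ICD-9 sequence with demographics
#'
#' A demographics sentence, the fixed prefix
#' `"Procedures patient went through and doctor's diagnoses:"`, and the
#' code long titles joined by `", "` in `seq_num` order.
#'
#' @param icd_seq `data.frame` with `seq_num`, `long_title`.
#' @param demographics list or one-row `data.frame` with `age_years`,
#'   `gender` (`"M"`/`"F"`), `insurance`.
#' @return a single string.
#' @export
buildIcd9Text <- function(icd_seq, demographics) {
  demo <- sprintf("Patient is a %d-year-old %s with %s insurance.",
                  as.integer(demographics$age_years),
                  ifelse(demographics$gender == "M", "male", "female"),
                  demographics$insurance)
  prefix <- "Procedures patient went through and doctor's diagnoses:"
  titles <- icd_seq$long_title[order(icd_seq$seq_num)]
  if (length(titles))
    paste(demo, prefix, paste(titles, collapse = ", "))
  else paste(demo, prefix)
}

#' Default demographics one-hot schema
#'
#' Category levels per demographic field: gender, the 18-65 / over-65
#' age split, insurance and ethnicity.
#'
#' @return named list of character level vectors.
#' @export
demographicsSchema <- function() {
  list(gender = c("M", "F"),
       age_group = c("18-65", ">65"),
       insurance = c("Medicare", "Medicaid", "Private", "Government",
                     "Self Pay"),
       ethnicity = c("WHITE", "BLACK/AFRICAN AMERICAN", "HISPANIC/LATINO",
                     "ASIAN", "OTHER"))
}

#' One-hot encoding of a patient's demographics
#'
#' Concatenated one-hot blocks for gender, age bucket, insurance and
#' ethnicity. A category value absent from the schema yields an all-zero
#' block (with a warning).
#'
#' @param record list or one-row `data.frame` with `gender`,
#'   `age_years`, `insurance`, `ethnicity`.
#' @param schema schema as returned by [demographicsSchema()].
#' @return named binary vector.
#' @export
encodeDemographics <- function(record, schema = demographicsSchema()) {
  values <- list(
    gender = as.character(record$gender),
    age_group = if (record$age_years <= 65) "18-65" else ">65",
    insurance = as.character(record$insurance),
    ethnicity = as.character(record$ethnicity))
  out <- numeric(0)
  for (f in names(schema)) {
    block <- setNames(numeric(length(schema[[f]])),
                      paste0(f, "=", schema[[f]]))
    hit <- match(values[[f]], schema[[f]])
    if (is.na(hit))
      warning("unseen category for ", f, ": ", values[[f]])
    else block[hit] <- 1
    out <- c(out, block)
  }
  out
}

#' Demographics one-hot matrix for a cohort
#' @param cohort cohort table from [buildCohort()].
#' @param schema schema as returned by [demographicsSchema()].
#' @return numeric matrix, one row per stay.
#' @export
demographicsMatrix <- function(cohort, schema = demographicsSchema()) {
  t(vapply(seq_len(nrow(cohort)), function(r)
    suppressWarnings(encodeDemographics(cohort[r, ], schema)),
    numeric(sum(lengths(schema)))))
}

#' Clean a raw clinical note
#'
#' Lower-cases the text, removes bracketed de-identification
#' placeholders (`[** ... **]` spans), collapses whitespace and
#' line-break runs to single spaces and trims; digits are kept.
#'
#' @param text raw note text.
#' @return cleaned string (empty input stays empty).
#' @export
preprocessNote <- function(text) {
  if (is.na(text) || !nzchar(text)) return("")
  x <- tolower(text)
  x <- gsub("\\[\\*\\*.*?\\*\\*\\]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Whitespace tokenizer
#'
#' Minimal injectable tokenizer: splits on whitespace, maps tokens to
#' integer ids over a vocabulary built from a corpus (id 1 reserved for
#' unknown tokens). Any object with the same `encode`/`decode`/`vocab`
#' contract — e.g. a clinical wordpiece tokenizer — can be dropped in.
#'
#' @param corpus character vector of (cleaned) texts to build the
#'   vocabulary from.
#' @return list with `encode(text) -> integer ids`,
#'   `decode(ids) -> tokens`, and `vocab`.
#' @export
whitespaceTokenizer <- function(corpus) {
  toks <- unlist(strsplit(corpus, "\\s+"))
  toks <- toks[nzchar(toks)]
  vocab <- c("<unk>", sort(unique(toks)))
  list(
    encode = function(text) {
      tt <- unlist(strsplit(text, "\\s+"))
      tt <- tt[nzchar(tt)]
      if (!length(tt)) return(integer(0))
      idx <- match(tt, vocab)
      idx[is.na(idx)] <- 1L
      as.integer(idx)
    },
    decode = function(ids) vocab[ids],
    vocab = vocab)
}

#' Split a note into fixed-length token chunks
#'
#' Greedy fixed-length windows over the tokenized note; the last chunk
#' may be short; chunks concatenate back to the full token sequence.
#' `n = ceiling(token_count / chunk_length)`; an empty note yields a
#' single empty chunk.
#'
#' The default chunk length of 318 content tokens leaves room for
#' special tokens inside a 512-token encoder limit.
#'
#' @param text cleaned note text.
#' @param tokenizer tokenizer from [whitespaceTokenizer()] (or
#'   compatible).
#' @param chunk_length tokens per chunk.
#' @return list with `n` and `chunks` (list of integer-id vectors).
#' @export
chunkNote <- function(text, tokenizer, chunk_length = 318L) {
  if (chunk_length <= 0) stop("chunk_length must be positive")
  ids <- tokenizer$encode(text)
  if (!length(ids)) return(list(n = 1L, chunks = list(integer(0))))
  n <- as.integer(ceiling(length(ids) / chunk_length))
  chunks <- lapply(seq_len(n), function(j)
    ids[((j - 1L) * chunk_length + 1L):min(j * chunk_length, length(ids))])
  list(n = n, chunks = chunks)
}

#' Encode a cohort's ICD-9 sequences as an EncodedSampleSet
#'
#' @param tables an [EHRTables-class].
#' @param cohort cohort table.
#' @param vocab vocabulary from [buildIcd9Vocab()].
#' @param L_codes target length (default: longest training sequence).
#' @param extra optional per-stay side-feature matrix.
#' @return an [EncodedSampleSet-class]; total unknown-code count in the
#'   `n_unknown` attribute.
#' @export
encodeIcd9Samples <- function(tables, cohort, vocab, L_codes = NULL,
                              extra = NULL) {
  dx <- tables@diagnoses_icd
  per_adm <- split(dx, by = "hadm_id")
  if (is.null(L_codes))
    L_codes <- max(vapply(per_adm, nrow, 1L), 1L)
  n <- nrow(cohort)
  indices <- matrix(1L, n, L_codes)
  mask <- matrix(0, n, L_codes)
  n_unknown <- 0L
  for (r in seq_len(n)) {
    seqs <- per_adm[[as.character(cohort$hadm_id[r])]]
    if (is.null(seqs)) next
    enc <- encodeIcd9Onehot(seqs, vocab, L_codes)
    indices[r, ] <- enc$indices
    mask[r, ] <- enc$mask
    n_unknown <- n_unknown + enc$n_unknown
  }
  if (is.null(extra)) extra <- matrix(numeric(), n, 0)
  out <- new("EncodedSampleSet",
             indices = indices, mask = mask, vocab = vocab,
             L = as.integer(L_codes), extra = extra, dense = list(),
             ids = as.integer(cohort$icustay_id),
             labels = as.numeric(cohort$label))
  attr(out, "n_unknown") <- n_unknown
  out
}
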