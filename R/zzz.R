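#' @importFrom data.table data.table as.data.table rbindlist setkey set
#'   setnames fwrite fread copy setorder
NULL

.datatable.aware <- TRUE

# silence R CMD check notes for data.table non-standard evaluation columns
utils::globalVariables(c(
  "subject_id", "icustay_id", "hadm_id", "itemid", "charttime", "valuenum",
  "icd9_code", "seq_num", "intime", "outtime", "dischtime", "src", ".N",
  "label", "n", "age_group", "gender", "concept_rank", "type_rank",
  "dev", "upfrac"))
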