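# Sequence-selection filters, per-tool routing rules and the dataset
# accounting arithmetic used when planning a large modeling campaign over a
# reference proteome.

AI_LENGTH_MIN <- 10L
AI_LENGTH_MAX <- 2700L
OPENFOLD_MAX <- 2000L
ESM_API_MAX <- 400L
ESM_BIONEMO_MAX <- 1024L
UNKNOWN_AA <- c("U", "O", "X", "J", "B", "Z")

validate_sequences <- function(sequence) {
  bad <- grepl("[^A-Z]", sequence)
  if (any(bad)) {
    stop(sprintf("sequence %d contains lowercase or non-alphabetic characters",
                 which(bad)[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Filter sequence records for modeling eligibility
#'
#' A record is kept when its existence level is 1 (protein-level evidence)
#' and it is not a fragment. Kept records are additionally scored for
#' AI-predictor eligibility: length within \[10, 2700\] and no ambiguous or
#' non-standard characters (U, O, X, J, B, Z). Every exclusion carries a
#' machine-readable reason.
#'
#' @param records data.frame with columns `accession`, `sequence`
#'   (uppercase), `existence_level`, `is_fragment`.
#' @return list with `kept` (data.frame plus columns `length`,
#'   `ai_eligible`, `ai_reason`) and `excluded` (data.frame plus `reason`).
#' @export
filter_sequences <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  validate_sequences(records$sequence)
  records$length <- nchar(records$sequence)

  reason <- rep(NA_character_, nrow(records))
  reason[records$existence_level != 1L] <- "not_protein_level_existence"
  reason[records$is_fragment] <- "fragment"
  kept <- records[is.na(reason), , drop = FALSE]
  excluded <- records[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]

  ai_reason <- rep(NA_character_, nrow(kept))
  ai_reason[kept$length < AI_LENGTH_MIN] <- "too_short"
  ai_reason[kept$length > AI_LENGTH_MAX] <- "too_long"
  has_unknown <- grepl(paste0("[", paste(UNKNOWN_AA, collapse = ""), "]"),
                       kept$sequence)
  ai_reason[is.na(ai_reason) & has_unknown] <- "unknown_character"
  kept$ai_eligible <- is.na(ai_reason)
  kept$ai_reason <- ai_reason
  list(kept = kept, excluded = excluded)
}

#' Routing plan: which modeling tools can handle a sequence
#'
#' For an AI-eligible record (length within 10-2700): AlphaFold 2 always;
#' OpenFold up to 2000 residues; the ESMFold API for 10-400 residues and the
#' ESMFold BioNeMo service for 401-1024 (mutually exclusive); homology
#' modeling is always attempted (template availability is decided
#' elsewhere).
#'
#' @param record one-row data.frame (or list) with `accession` and
#'   `sequence`; must have passed AI eligibility.
#' @return list with `accession`, `length`, `eligible_tools`,
#'   `exclusion_reasons`.
#' @export
route_models <- function(record) {
  len <- nchar(record$sequence)
  validate_sequences(record$sequence)
  has_unknown <- grepl(paste0("[", paste(UNKNOWN_AA, collapse = ""), "]"),
                       record$sequence)
  if (len < AI_LENGTH_MIN || len > AI_LENGTH_MAX || has_unknown) {
    stop("route_models requires an AI-eligible record", call. = FALSE)
  }
  tools <- c("alphafold2", "homology")
  reasons <- character(0)
  if (len <= OPENFOLD_MAX) tools <- c(tools, "openfold")
  else reasons <- c(reasons, "openfold:too_long")
  if (len <= ESM_API_MAX) tools <- c(tools, "esmfold_api")
  else if (len <= ESM_BIONEMO_MAX) tools <- c(tools, "esmfold_bionemo")
  else reasons <- c(reasons, "esmfold:too_long")
  list(accession = record$accession, length = len,
       eligible_tools = sort(tools), exclusion_reasons = reasons)
}

#' Percentage coverage of a subset within a universe
#'
#' Rounded half-up to two decimals (77.76-style reporting).
#'
#' @param subset,universe non-negative counts, `universe > 0`.
#' @return percentage with two decimals.
#' @export
coverage_pct <- function(subset, universe) {
  stopifnot(universe > 0, subset >= 0)
  floor(100 * subset / universe * 100 + 0.5) / 100
}

#' Dataset accounting arithmetic
#'
#' Derives campaign totals from named component counts:
#' `af2_new = af2_total - af2_from_db` (sequences still to fold after
#' harvesting an existing database), `ai_total = af2_new + openfold +
#' esmfold` (models newly predicted with AI tools), and
#' `novel_total = ai_total + homology`.
#'
#' @param counts named list/vector with non-negative integers `af2_total`,
#'   `af2_from_db`, `openfold`, `esmfold`, `homology`.
#' @return named list of derived totals `af2_new`, `ai_total`,
#'   `novel_total`.
#' @export
dataset_accounting <- function(counts) {
  counts <- as.list(counts)
  need <- c("af2_total", "af2_from_db", "openfold", "esmfold", "homology")
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    stop(sprintf("missing counts: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  vals <- unlist(counts[need])
  if (any(vals < 0) || any(vals != trunc(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  af2_new <- counts$af2_total - counts$af2_from_db
  if (af2_new < 0) {
    stop("inconsistent counts: af2_from_db exceeds af2_total", call. = FALSE)
  }
  ai_total <- af2_new + counts$openfold + counts$esmfold
  list(af2_new = af2_new, ai_total = ai_total,
       novel_total = ai_total + counts$homology)
}

#' Read sequence records from a FASTA file
#'
#' Headers of the form `>accession description` are parsed; existence level
#' and fragment status default to 1 / FALSE unless encoded as
#' `EX=<level> FR=<0|1>` tags in the description.
#'
#' @param path FASTA file path.
#' @return data.frame of sequence records for [filter_sequences()].
#' @export
read_sequence_records <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  acc <- sub("\\s.*$", "", headers)
  ex <- suppressWarnings(as.integer(sub(".*EX=(\\d+).*", "\\1", headers)))
  ex[is.na(ex) | !grepl("EX=", headers)] <- 1L
  fr <- grepl("FR=1", headers)
  data.frame(accession = acc, sequence = toupper(as.character(aa)),
             existence_level = ex, is_fragment = fr,
             stringsAsFactors = FALSE)
}
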