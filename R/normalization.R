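#' Default set of non-informative answer values
#'
#' Answers deemed ambiguous, with no value for research: they earn no
#' phenotype-score credit. Note that a negative answer ("no") *is*
#' informative — declaring a disease absent is as useful to association
#' studies as declaring it present — and is therefore valid.
#'
#' @return lowercase character vector of invalid values.
#' @export
default_invalid_values <- function() {
  c("unsure", "not applicable", "other/don't know/no response",
    "no response", "not sure", "unspecified")
}

#' Is a raw value informative?
#'
#' A value is valid unless, after trimming and lowercasing, it is empty or
#' a member of the invalid set.
#'
#' @param value character vector of raw values.
#' @param invalid_values set of non-informative strings
#'   (case-insensitive); see [default_invalid_values()].
#' @return logical vector.
#' @export
is_valid_value <- function(value, invalid_values = default_invalid_values()) {
  v <- tolower(trimws(as.character(value)))
  nzchar(v) & !(v %in% tolower(invalid_values))
}

#' Default phenotype synonym map
#'
#' The survey-export label variants reconciled to a canonical phenotype
#' name during normalization (e.g. the numbered form `"1.3 --- Weight"`
#' is the same phenotype as `"Weight"`). Fully user-overridable.
#'
#' @return named character vector: `names()` are source labels, values
#'   are canonical names.
#' @export
default_synonym_map <- function() {
  c("1.3 --- Weight" = "Weight",
    "1.2 --- Height" = "Height",
    "1.1 --- Blood Type" = "Blood Type",
    "Race" = "Race/ethnicity",
    "Gender" = "Sex/Gender",
    "Date of Birth (mm/dd/yyyy)" = "Date of Birth")
}

#' Rewrite synonymous phenotype names to their canonical form
#'
#' Every record whose phenotype matches a source label
#' (case-insensitively) is renamed to the canonical label. If a
#' participant ends up with records under both the source and canonical
#' names, the value sets merge and are deduplicated. The map must be
#' acyclic (no canonical name is itself a source), which makes the
#' operation idempotent.
#'
#' @param cohort a cohort.
#' @param synonyms named character vector (source -> canonical); see
#'   [default_synonym_map()].
#' @return the rewritten cohort; the number of renamed records is in
#'   `attr(, "n_renamed")`.
#' @export
apply_synonym_map <- function(cohort, synonyms = default_synonym_map()) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(synonyms) == 0L) return(cohort)
  src <- tolower(names(synonyms))
  if (any(tolower(synonyms) %in% src)) {
    stop("cyclic synonym map: a canonical name is itself a source")
  }
  rec <- cohort$records
  hit <- match(tolower(rec$phenotype), src)
  renamed <- !is.na(hit)
  rec$phenotype[renamed] <- unname(synonyms[hit[renamed]])
  out <- as_cohort(rec, roster = cohort$participants)
  attr(out, "n_renamed") <- sum(renamed)
  out
}

#' Detect which participants took a survey
#'
#' A checklist survey lists only affirmative answers on the public
#' profile, so the presence of *any* entry whose phenotype belongs to the
#' survey — whatever its value, valid or not — is the evidence that the
#' participant took it. The threshold of matching entries is
#' configurable; the default (1) reflects that a single surfaced answer
#' proves participation.
#'
#' @param cohort a cohort.
#' @param survey one survey from [load_survey_catalog()].
#' @param min_entries minimum number of matching entries to count as a
#'   taker (default 1).
#' @return named logical vector over `cohort$participants`.
#' @export
detect_survey_participation <- function(cohort, survey, min_entries = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  phen <- tolower(survey$phenotypes)
  rec <- cohort$records
  hits <- rec$participant_id[tolower(rec$phenotype) %in% phen]
  counts <- table(hits)
  takers <- names(counts)[counts >= min_entries]
  stats::setNames(cohort$participants %in% takers, cohort$participants)
}

#' Fill implicit "no" answers for checklist-survey takers
#'
#' Checklist surveys surface only the phenotypes a participant answered
#' "yes" to; for detected takers, every listed phenotype they are missing
#' is added with the value `"no"` (marked `source = "imputed"`).
#' Participants not detected as takers are untouched, existing entries are
#' never altered, and the operation is idempotent.
#'
#' @param cohort a cohort.
#' @param catalog a `survey_catalog`; only surveys flagged `checklist`
#'   are filled.
#' @param min_entries passed to [detect_survey_participation()].
#' @return the filled cohort; `attr(, "fill_report")` is a tibble with
#'   per-survey taker and imputed-entry counts.
#' @export
fill_survey_negatives <- function(cohort, catalog, min_entries = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  report <- list()
  new_records <- list()
  rec <- cohort$records
  for (s in catalog) {
    if (!isTRUE(s$checklist)) next
    takers <- names(which(detect_survey_participation(cohort, s, min_entries)))
    n_imputed <- 0L
    if (length(takers) > 0L) {
      have <- rec[rec$participant_id %in% takers &
                    tolower(rec$phenotype) %in% tolower(s$phenotypes), ]
      # full taker x phenotype grid minus what is already present
      grid <- tibble(
        participant_id = rep(takers, each = length(s$phenotypes)),
        phenotype = rep(s$phenotypes, times = length(takers))
      )
      missing <- dplyr::anti_join(
        dplyr::mutate(grid, .key = tolower(.data$phenotype)),
        dplyr::mutate(have[, c("participant_id", "phenotype")],
                      .key = tolower(.data$phenotype)),
        by = c("participant_id", ".key")
      )
      if (nrow(missing) > 0L) {
        new_records[[length(new_records) + 1L]] <- tibble(
          participant_id = missing$participant_id,
          phenotype = missing$phenotype,
          value = "no",
          source = "imputed"
        )
        n_imputed <- nrow(missing)
      }
    }
    report[[length(report) + 1L]] <- tibble(
      survey = s$name, n_takers = length(takers), n_imputed = n_imputed
    )
  }
  out <- as_cohort(dplyr::bind_rows(c(list(rec), new_records)),
                   roster = cohort$participants)
  attr(out, "fill_report") <- dplyr::bind_rows(report)
  out
}
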