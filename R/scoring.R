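#' Score every phenotype by its number of valid reporters
#'
#' Each unique phenotype (case-insensitive; first-seen casing is kept as
#' the display name) receives a score equal to the number of distinct
#' participants with at least one valid value for it. A phenotype seen
#' only with invalid values stays listed with score 0. This score is the
#' weight the phenotype later contributes to each reporter's P-index: a
#' phenotype many participants share carries more statistical power for
#' association studies, so it is worth more.
#'
#' @param cohort a cohort.
#' @param invalid_values see [default_invalid_values()].
#' @return tibble with columns `phenotype`, `score`, sorted by descending
#'   score then name.
#' @export
score_phenotypes <- function(cohort, invalid_values = default_invalid_values()) {
  stopifnot(inherits(cohort, "cohort"))
  rec <- cohort$records
  if (nrow(rec) == 0L) {
    return(tibble(phenotype = character(), score = integer()))
  }
  rec %>%
    mutate(.key = tolower(.data$phenotype),
           .valid = is_valid_value(.data$value, invalid_values)) %>%
    group_by(.data$.key) %>%
    summarise(phenotype = first(.data$phenotype),
              score = n_distinct(.data$participant_id[.data$.valid]),
              .groups = "drop") %>%
    arrange(desc(.data$score), tolower(.data$phenotype)) %>%
    select("phenotype", "score")
}

#' Default administrative (non-phenotype) profile entries
#'
#' Entries generated for every enrolled participant regardless of any
#' phenotype reporting (enrollment bookkeeping), excluded from the
#' P-index denominator.
#'
#' @return character vector of names (matched exactly,
#'   case-insensitively).
#' @export
default_administrative_names <- function() {
  c("enrolled", "consent", "account created", "eligibility screening",
    "participant id", "exam")
}

#' Default genotype-data keywords
#'
#' Profile entries describing the participant's *genome data* (sequencing
#' or genotyping uploads) are not phenotypes; any phenotype name
#' containing one of these substrings (case-insensitively) is excluded.
#'
#' @return character vector of substrings.
#' @export
default_genotype_keywords <- function() {
  c("sequencing", "genotyping", "genome data", "23andme", "variant")
}

#' Validity-filter configuration
#'
#' @param administrative_names exact names to drop; see
#'   [default_administrative_names()].
#' @param genotype_keywords substrings marking genotype-data entries; see
#'   [default_genotype_keywords()].
#' @param min_share minimum phenotype score to keep (default 2: a
#'   phenotype reported by a single participant cannot support an
#'   association and is dropped; the cutoff can be raised).
#' @return object of class `exclusion_config`.
#' @export
exclusion_config <- function(administrative_names = default_administrative_names(),
                             genotype_keywords = default_genotype_keywords(),
                             min_share = 2L) {
  min_share <- as.integer(min_share)
  if (is.na(min_share) || min_share < 2L) stop("min_share must be >= 2")
  structure(list(administrative_names = administrative_names,
                 genotype_keywords = genotype_keywords,
                 min_share = min_share),
            class = "exclusion_config")
}

#' Filter the score table down to valid phenotypes
#'
#' Drops administrative entries (exact, case-insensitive match), names
#' containing any genotype keyword, and phenotypes scoring below
#' `min_share`; computes the *theoretical maximum* denominator, the sum
#' of the surviving scores — the raw sum a participant reporting every
#' valid phenotype would attain.
#'
#' @param scores tibble from [score_phenotypes()].
#' @param config an [exclusion_config()].
#' @return object of class `valid_phenotypes`: list with `phenotypes`
#'   (tibble of survivors), `denominator` (sum of surviving scores) and
#'   `audit` (all phenotypes with `valid` flag and `reason`).
#' @export
filter_valid_phenotypes <- function(scores, config = exclusion_config()) {
  stopifnot(is.data.frame(scores))
  key <- tolower(scores$phenotype)
  reason <- rep(NA_character_, nrow(scores))
  admin <- key %in% tolower(config$administrative_names)
  reason[admin] <- "administrative"
  geno <- rep(FALSE, nrow(scores))
  for (kw in tolower(config$genotype_keywords)) {
    geno <- geno | grepl(kw, key, fixed = TRUE)
  }
  reason[geno & is.na(reason)] <- "genotype"
  low <- scores$score < config$min_share
  reason[low & is.na(reason)] <- "low_score"
  audit <- mutate(as_tibble(scores), valid = is.na(reason), reason = reason)
  keep <- audit[audit$valid, c("phenotype", "score")]
  if (nrow(keep) == 0L) {
    stop("no phenotype survives the validity filters (denominator would be 0)")
  }
  structure(list(phenotypes = keep,
                 denominator = sum(as.numeric(keep$score)),
                 audit = audit),
            class = "valid_phenotypes")
}

#' @export
print.valid_phenotypes <- function(x, ...) {
  cat(sprintf("<valid_phenotypes> %d phenotypes, theoretical maximum %s\n",
              nrow(x$phenotypes), format(x$denominator, big.mark = ",")))
  invisible(x)
}

#' Compute the participation index (P-index)
#'
#' For each enrolled participant, sums the scores of the valid phenotypes
#' they validly report and divides by the theoretical maximum (the sum
#' over all valid phenotypes), times 100. 0 means no valid phenotypes
#' reported; 100 means every valid phenotype reported. Participants on
#' the roster without records score 0.
#'
#' @param cohort a cohort.
#' @param valid a [filter_valid_phenotypes()] object.
#' @param invalid_values see [default_invalid_values()].
#' @param weights optional named numeric vector of per-phenotype weight
#'   multipliers (names matched case-insensitively, default 1): the hook
#'   for deliberately biasing the index toward selected phenotypes.
#' @return tibble with columns `participant_id`, `raw_sum`, `p_index`,
#'   one row per enrolled participant; see [rank_participants()] for
#'   ranking.
#' @export
compute_p_index <- function(cohort, valid,
                            invalid_values = default_invalid_values(),
                            weights = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(valid, "valid_phenotypes"))
  vp <- valid$phenotypes
  w <- rep(1, nrow(vp))
  if (!is.null(weights)) {
    hit <- match(tolower(vp$phenotype), tolower(names(weights)))
    w[!is.na(hit)] <- as.numeric(weights[hit[!is.na(hit)]])
  }
  contrib <- as.numeric(vp$score) * w
  denominator <- sum(contrib)
  if (denominator <= 0) stop("theoretical maximum must be positive")
  rec <- cohort$records
  rec <- rec[is_valid_value(rec$value, invalid_values), ]
  hit <- match(tolower(rec$phenotype), tolower(vp$phenotype))
  rec <- rec[!is.na(hit), ]
  hit <- hit[!is.na(hit)]
  pair <- !duplicated(paste(rec$participant_id, hit, sep = "\r"))
  sums <- tapply(contrib[hit[pair]], rec$participant_id[pair], sum)
  raw <- stats::setNames(rep(0, length(cohort$participants)),
                         cohort$participants)
  raw[names(sums)] <- as.numeric(sums)
  tibble(participant_id = cohort$participants,
         raw_sum = unname(raw),
         p_index = 100 * unname(raw) / denominator)
}

#' Rank participants by P-index
#'
#' Orders by descending `p_index`, breaking ties by ascending
#' `participant_id`, and assigns ordinal ranks 1..N (deterministic and
#' unique).
#'
#' @param ptable tibble from [compute_p_index()] (any table with
#'   `participant_id` and `p_index` columns).
#' @return the table sorted, with a `rank` column added.
#' @export
rank_participants <- function(ptable) {
  stopifnot(all(c("participant_id", "p_index") %in% names(ptable)))
  ptable %>%
    arrange(desc(.data$p_index), .data$participant_id) %>%
    mutate(rank = row_number())
}

#' Select quantitative phenotypes
#'
#' Heuristically identifies phenotypes whose valid values are
#' predominantly numeric — a numeric-leading parse (e.g. `"170 cm"`,
#' `"140 lbs"`) succeeds for at least `numeric_fraction` of the valid
#' values — and whose score is at least `min_score` (default 10, so the
#' quantitative index rests on traits with enough reporters to matter).
#'
#' @param cohort a cohort.
#' @param scores tibble from [score_phenotypes()].
#' @param min_score minimum phenotype score (default 10).
#' @param numeric_fraction minimum fraction of valid values that parse
#'   numerically (default 0.8).
#' @param invalid_values see [default_invalid_values()].
#' @return character vector of phenotype display names.
#' @export
select_quantitative_phenotypes <- function(cohort, scores, min_score = 10L,
                                           numeric_fraction = 0.8,
                                           invalid_values = default_invalid_values()) {
  stopifnot(inherits(cohort, "cohort"))
  eligible <- scores$phenotype[scores$score >= min_score]
  if (length(eligible) == 0L) return(character())
  rec <- cohort$records[is_valid_value(cohort$records$value, invalid_values), ]
  hit <- match(tolower(rec$phenotype), tolower(eligible))
  rec <- rec[!is.na(hit), ]
  if (nrow(rec) == 0L) return(character())
  numeric_lead <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)",
                        trimws(rec$value))
  frac <- tapply(numeric_lead, tolower(rec$phenotype), mean)
  keep <- names(frac)[frac >= numeric_fraction]
  eligible[tolower(eligible) %in% keep]
}

#' Compute the quantitative-trait P-index (QtP-index)
#'
#' Identical to the P-index but restricted to a list of quantitative
#' phenotypes: the denominator is the sum of scores over that list only.
#' Encourages contribution of numeric traits (height, weight, blood
#' pressure, ...) suitable for quantitative genetics.
#'
#' @param cohort a cohort.
#' @param quantitative non-empty character vector of phenotype names
#'   (e.g. from [select_quantitative_phenotypes()]).
#' @param scores tibble from [score_phenotypes()].
#' @param invalid_values see [default_invalid_values()].
#' @return tibble like [compute_p_index()]'s.
#' @export
compute_qtp_index <- function(cohort, quantitative, scores,
                              invalid_values = default_invalid_values()) {
  if (length(quantitative) == 0L) {
    stop("quantitative phenotype list is empty")
  }
  sub <- scores[tolower(scores$phenotype) %in% tolower(quantitative), ]
  if (nrow(sub) == 0L || sum(sub$score) == 0) {
    stop("no scored phenotype matches the quantitative list")
  }
  valid <- structure(list(phenotypes = sub[, c("phenotype", "score")],
                          denominator = sum(as.numeric(sub$score)),
                          audit = NULL),
                     class = "valid_phenotypes")
  compute_p_index(cohort, valid, invalid_values)
}

#' Suggest the phenotypes that would raise a participant's P-index most
#'
#' Lists the `k` highest-scoring valid phenotypes the participant has not
#' validly reported, with the P-index gain each would deliver (100 x
#' score / theoretical maximum). Gains are quoted at the *current* score
#' table — the hypothetical new report is not fed back into the scores —
#' matching how the method advertises "points" to participants.
#'
#' @param cohort a cohort.
#' @param participant_id the participant to advise.
#' @param valid a [filter_valid_phenotypes()] object.
#' @param k number of suggestions (default 3).
#' @param invalid_values see [default_invalid_values()].
#' @return tibble with columns `phenotype`, `score`, `p_index_gain`,
#'   descending by score; empty if the participant already reports every
#'   valid phenotype.
#' @export
suggest_phenotypes <- function(cohort, participant_id, valid, k = 3L,
                               invalid_values = default_invalid_values()) {
  stopifnot(inherits(cohort, "cohort"), inherits(valid, "valid_phenotypes"),
            k >= 1L)
  rec <- cohort$records
  rec <- rec[rec$participant_id == participant_id &
               is_valid_value(rec$value, invalid_values), ]
  have <- unique(tolower(rec$phenotype))
  vp <- valid$phenotypes
  miss <- vp[!(tolower(vp$phenotype) %in% have), ]
  miss <- miss[order(-miss$score, tolower(miss$phenotype)), ]
  miss <- utils::head(miss, k)
  tibble(phenotype = miss$phenotype,
         score = miss$score,
         p_index_gain = 100 * as.numeric(miss$score) / valid$denominator)
}

#' Share of valid phenotypes scoring above a threshold
#'
#' Summarizes the upper tail of a phenotype-score distribution: how many
#' phenotypes have a score strictly greater than `threshold`, and what
#' percentage of the listed phenotypes that is.
#'
#' @param scores numeric vector of phenotype scores, or a table with a
#'   `score` column (e.g. from [score_phenotypes()] or the `phenotypes`
#'   element of [filter_valid_phenotypes()]).
#' @param threshold score cutoff (strict inequality).
#' @return list with `n_above`, `n_total` and `pct` (= 100 * n_above /
#'   n_total).
#' @export
score_tail_share <- function(scores, threshold) {
  s <- if (is.data.frame(scores)) scores$score else scores
  s <- as.numeric(s)
  list(n_above = sum(s > threshold),
       n_total = length(s),
       pct = 100 * sum(s > threshold) / length(s))
}

#' Run the full scoring pipeline on a cohort
#'
#' Convenience wrapper chaining normalization and scoring: synonym
#' reconciliation, implicit-"no" filling for checklist surveys (when a
#' catalog is supplied), phenotype scoring, validity filtering, P-index
#' computation and ranking, and — when enough quantitative phenotypes
#' exist — the QtP-index.
#'
#' @param cohort a cohort.
#' @param catalog optional `survey_catalog` for negative filling.
#' @param config an [exclusion_config()].
#' @param synonyms see [default_synonym_map()]; `NULL` to skip.
#' @param invalid_values see [default_invalid_values()].
#' @param quantitative_min_score passed to
#'   [select_quantitative_phenotypes()].
#' @return list with `cohort` (normalized), `scores`, `valid`, `ptable`
#'   (ranked), `quantitative` (names) and `qtp` (ranked QtP table or
#'   `NULL`).
#' @export
pindex_pipeline <- function(cohort, catalog = NULL,
                            config = exclusion_config(),
                            synonyms = default_synonym_map(),
                            invalid_values = default_invalid_values(),
                            quantitative_min_score = 10L) {
  if (!is.null(synonyms)) cohort <- apply_synonym_map(cohort, synonyms)
  if (!is.null(catalog)) cohort <- fill_survey_negatives(cohort, catalog)
  scores <- score_phenotypes(cohort, invalid_values)
  valid <- filter_valid_phenotypes(scores, config)
  ptable <- rank_participants(compute_p_index(cohort, valid, invalid_values))
  quantitative <- select_quantitative_phenotypes(
    cohort, valid$phenotypes, min_score = quantitative_min_score,
    invalid_values = invalid_values
  )
  qtp <- NULL
  if (length(quantitative) > 0L) {
    qtp <- rank_participants(
      compute_qtp_index(cohort, quantitative, valid$phenotypes, invalid_values)
    )
  }
  list(cohort = cohort, scores = scores, valid = valid, ptable = ptable,
       quantitative = quantitative, qtp = qtp)
}
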