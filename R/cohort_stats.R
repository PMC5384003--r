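#' Prevalence table from yes/no phenotype answers
#'
#' For each phenotype, counts participants with an affirmative and a
#' negative answer and computes prevalence = 100 x yes / (yes + no) among
#' respondents. Run this *after* checklist-survey filling
#' ([fill_survey_negatives()]), so that takers who left a condition
#' unchecked count as "no". A participant with both a yes- and a
#' no-valued entry counts once, as yes.
#'
#' @param cohort a cohort.
#' @param phenotypes phenotypes to tabulate (default: all with at least
#'   one yes/no answer).
#' @param yes_values,no_values case-insensitive answer sets (defaults
#'   `"yes"` / `"no"`).
#' @return tibble with `phenotype`, `n_yes`, `n_no`,
#'   `prevalence_percent`, sorted by descending prevalence; prevalence is
#'   `NA` (flagged undefined) when there are no respondents.
#' @export
prevalence_table <- function(cohort, phenotypes = NULL,
                             yes_values = "yes", no_values = "no") {
  stopifnot(inherits(cohort, "cohort"))
  rec <- cohort$records
  v <- tolower(trimws(rec$value))
  ans <- ifelse(v %in% tolower(yes_values), "yes",
                ifelse(v %in% tolower(no_values), "no", NA))
  rec <- rec[!is.na(ans), ]
  ans <- ans[!is.na(ans)]
  if (!is.null(phenotypes)) {
    keep <- tolower(rec$phenotype) %in% tolower(phenotypes)
    rec <- rec[keep, ]
    ans <- ans[keep]
  }
  if (nrow(rec) == 0L) {
    return(tibble(phenotype = character(), n_yes = integer(),
                  n_no = integer(), prevalence_percent = numeric()))
  }
  tibble(key = tolower(rec$phenotype), phenotype = rec$phenotype,
         participant_id = rec$participant_id, yes = ans == "yes") %>%
    group_by(.data$key, .data$participant_id) %>%
    summarise(phenotype = first(.data$phenotype),
              yes = any(.data$yes), .groups = "drop") %>%
    group_by(.data$key) %>%
    summarise(phenotype = first(.data$phenotype),
              n_yes = sum(.data$yes),
              n_no = sum(!.data$yes), .groups = "drop") %>%
    mutate(prevalence_percent = ifelse(
      .data$n_yes + .data$n_no > 0,
      100 * .data$n_yes / (.data$n_yes + .data$n_no), NA_real_)) %>%
    arrange(desc(.data$prevalence_percent), .data$key) %>%
    select("phenotype", "n_yes", "n_no", "prevalence_percent")
}

#' Summarize the P-index distribution
#'
#' Counts of participants strictly above `hi`, strictly below `lo` and
#' exactly zero, medians over all and over nonzero participants, and the
#' corresponding percentage shares — including the "dichotomy" share, the
#' fraction of the cohort sitting in either tail. A strongly dichotomized
#' distribution indicates participants either answer most surveys or none.
#'
#' @param ptable table with a `p_index` column.
#' @param hi,lo strict thresholds (defaults 90 and 10).
#' @return list with `n`, `n_above_hi`, `n_below_lo`, `n_zero`,
#'   `median_all`, `median_nonzero` (`NA` if all are zero), `pct_above_hi`,
#'   `pct_below_lo`, `pct_zero`, `pct_dichotomy`.
#' @export
pindex_distribution <- function(ptable, hi = 90, lo = 10) {
  p <- ptable$p_index
  if (length(p) == 0L) stop("empty P-index table")
  n <- length(p)
  n_above <- sum(p > hi)
  n_below <- sum(p < lo)
  n_zero <- sum(p == 0)
  list(n = n,
       n_above_hi = n_above,
       n_below_lo = n_below,
       n_zero = n_zero,
       median_all = stats::median(p),
       median_nonzero = if (any(p > 0)) stats::median(p[p > 0]) else NA_real_,
       pct_above_hi = 100 * n_above / n,
       pct_below_lo = 100 * n_below / n,
       pct_zero = 100 * n_zero / n,
       pct_dichotomy = 100 * (n_above + n_below) / n)
}

#' Exact binomial test of the cohort sex ratio
#'
#' Tests whether the male/female split departs from the null that both
#' sexes are equally likely to enroll (proportion `p_null` = 0.5). The
#' one-sided p-value is the upper tail P(X >= n_male); the two-sided
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed count (the standard exact two-sided convention), making it
#' symmetric in its two arguments.
#'
#' @param n_male,n_female non-negative counts.
#' @param sided `"two"` (default) or `"one"`.
#' @param p_null null proportion of males (default 0.5).
#' @return the p-value.
#' @export
binomial_sex_test <- function(n_male, n_female, sided = c("two", "one"),
                              p_null = 0.5) {
  sided <- match.arg(sided)
  if (n_male < 0 || n_female < 0) stop("counts must be non-negative")
  n <- n_male + n_female
  if (n < 1) stop("need at least one observation")
  ht <- stats::binom.test(n_male, n, p = p_null,
                          alternative = if (sided == "one") "greater"
                                        else "two.sided")
  unname(ht$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney) comparison of two groups
#'
#' Two-sided test that the two samples come from the same distribution.
#' Uses exact enumeration of the rank distribution when the combined
#' sample size is at most `exact_max` and there are no ties; otherwise
#' the normal approximation with tie-corrected variance and a 0.5
#' continuity correction.
#'
#' @param group_a,group_b non-empty numeric vectors (e.g. P-indexes of
#'   males and females).
#' @param exact_max largest combined sample size for the exact path
#'   (default 12).
#' @return the two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, exact_max = 12L) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- !ties && (length(group_a) + length(group_b)) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  unname(ht$p.value)
}

#' Stratify P-indexes by a reported field
#'
#' Groups participants by their valid value of a categorical field
#' phenotype (e.g. `"State"` or `"Sex/Gender"`); a participant reporting
#' several distinct valid values forms a combined stratum (sorted values
#' joined with " + "), so e.g. dual-listed sex entries become their own
#' group rather than polluting the two-group comparison. Groups smaller
#' than `min_group` are dropped (recorded in `attr(, "dropped")`);
#' participants lacking a valid field value are excluded.
#'
#' @param ptable table with `participant_id` and `p_index`.
#' @param cohort a cohort.
#' @param field_phenotype name of the grouping phenotype
#'   (case-insensitive).
#' @param min_group minimum stratum size to retain (default 30).
#' @param hi,lo strict thresholds for the percentage columns.
#' @param invalid_values see [default_invalid_values()].
#' @return tibble with `label`, `n`, `median_p_index`, `pct_above_90`,
#'   `pct_below_10`, sorted by descending median.
#' @export
stratify_by_field <- function(ptable, cohort, field_phenotype,
                              min_group = 30L, hi = 90, lo = 10,
                              invalid_values = default_invalid_values()) {
  stopifnot(inherits(cohort, "cohort"))
  rec <- cohort$records
  rec <- rec[tolower(rec$phenotype) == tolower(field_phenotype) &
               is_valid_value(rec$value, invalid_values), ]
  if (nrow(rec) == 0L) {
    out <- tibble(label = character(), n = integer(),
                  median_p_index = numeric(), pct_above_90 = numeric(),
                  pct_below_10 = numeric())
    attr(out, "dropped") <- out
    return(out)
  }
  labels <- tibble(participant_id = rec$participant_id,
                   value = trimws(rec$value)) %>%
    group_by(.data$participant_id) %>%
    summarise(label = {
      vals <- .data$value[!duplicated(tolower(.data$value))]
      paste(vals[order(tolower(vals))], collapse = " + ")
    }, .groups = "drop")
  merged <- left_join(labels, ptable[, c("participant_id", "p_index")],
                      by = "participant_id")
  merged <- merged[!is.na(merged$p_index), ]
  summ <- merged %>%
    group_by(.data$label) %>%
    summarise(n = n(),
              median_p_index = stats::median(.data$p_index),
              pct_above_90 = 100 * sum(.data$p_index > hi) / n(),
              pct_below_10 = 100 * sum(.data$p_index < lo) / n(),
              .groups = "drop") %>%
    arrange(desc(.data$median_p_index), .data$label)
  out <- summ[summ$n >= min_group, ]
  attr(out, "dropped") <- summ[summ$n < min_group, ]
  out
}

#' Geocode participants from their reported zip codes
#'
#' Normalizes each participant's zip value ([normalize_zip()]: strip to 5
#' digits, left-pad zeros) and looks it up in the gazetteer. One point
#' per participant (first matched zip if several are reported); the
#' number of participants whose zips could not be matched is recorded in
#' `attr(, "n_unmatched")`.
#'
#' @param cohort a cohort.
#' @param gazetteer a [load_gazetteer()] object.
#' @param zip_phenotype name of the zip-code phenotype (default
#'   `"Zip code"`, case-insensitive).
#' @param invalid_values see [default_invalid_values()].
#' @return tibble with `participant_id`, `zip`, `latitude`, `longitude`.
#' @export
geocode_participants <- function(cohort, gazetteer,
                                 zip_phenotype = "Zip code",
                                 invalid_values = default_invalid_values()) {
  stopifnot(inherits(cohort, "cohort"))
  rec <- cohort$records
  rec <- rec[tolower(rec$phenotype) == tolower(zip_phenotype) &
               is_valid_value(rec$value, invalid_values), ]
  rec$zip <- normalize_zip(rec$value)
  hit <- match(rec$zip, gazetteer$zip)
  matched <- rec[!is.na(hit), ]
  matched$latitude <- gazetteer$latitude[hit[!is.na(hit)]]
  matched$longitude <- gazetteer$longitude[hit[!is.na(hit)]]
  matched <- matched[!duplicated(matched$participant_id), ]
  n_unmatched <- dplyr::n_distinct(rec$participant_id) -
    nrow(matched)
  out <- matched[, c("participant_id", "zip", "latitude", "longitude")]
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Cluster geocoded participants into one-degree cells
#'
#' Each participant's location is rounded to a one-degree grid cell keyed
#' by (floor(latitude), ceiling(longitude)) — note that with negative
#' (western) longitudes the mathematical ceiling rounds toward zero, so
#' (42.36, -71.06) falls in cell (42, -71). Per cell: member count,
#' median P-index, and the *unrounded* median coordinates to use for
#' plotting.
#'
#' @param points tibble from [geocode_participants()].
#' @param ptable table with `participant_id` and `p_index`.
#' @return tibble with `cell_lat`, `cell_lon`, `n`, `median_p_index`,
#'   `plot_lat`, `plot_lon` and a `member_ids` list-column, sorted by
#'   descending `n`.
#' @export
cluster_geopoints <- function(points, ptable) {
  if (nrow(points) == 0L) stop("no geocoded points to cluster")
  merged <- left_join(points, ptable[, c("participant_id", "p_index")],
                      by = "participant_id")
  merged %>%
    mutate(cell_lat = floor(.data$latitude),
           cell_lon = ceiling(.data$longitude)) %>%
    group_by(.data$cell_lat, .data$cell_lon) %>%
    summarise(n = n(),
              median_p_index = stats::median(.data$p_index),
              plot_lat = stats::median(.data$latitude),
              plot_lon = stats::median(.data$longitude),
              member_ids = list(.data$participant_id),
              .groups = "drop") %>%
    arrange(desc(.data$n), .data$cell_lat, .data$cell_lon)
}
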