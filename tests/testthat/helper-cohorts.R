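# Small fixture cohorts and independent brute-force oracles.
# The oracles deliberately use plain double loops and share no code with
# the package implementation.

cohort_t1 <- function() {
  as_cohort(data.frame(
    participant_id = c("A", "A", "B", "B", "C"),
    phenotype = c("Height", "Weight", "Height", "Eye Color", "Height"),
    value = c("170 cm", "70 kg", "180", "blue", "unsure")
  ))
}

cohort_t2 <- function() {
  as_cohort(data.frame(
    participant_id = c("A", "A", "B", "B", "C"),
    phenotype = c("Height", "Weight", "Height", "Weight", "Height"),
    value = c("170", "70", "180", "80", "175")
  ))
}

make_catalog <- function(...) {
  load_survey_catalog(list(...))
}

# random cohort drawn from the *current* RNG state
random_cohort <- function(max_participants = 20L, max_phenotypes = 15L) {
  n_p <- sample(2:max_participants, 1L)
  n_f <- sample(2:max_phenotypes, 1L)
  ids <- sprintf("P%02d", seq_len(n_p))
  phens <- sprintf("Trait %02d", seq_len(n_f))
  values <- c("yes", "no", "170 cm", "blue", "12", "unsure", "not sure",
              "unspecified")
  n_rec <- sample(1:(3L * n_p), 1L)
  rec <- data.frame(
    participant_id = sample(ids, n_rec, replace = TRUE),
    phenotype = sample(phens, n_rec, replace = TRUE),
    value = sample(values, n_rec, replace = TRUE)
  )
  as_cohort(rec, roster = ids)
}

# oracle: phenotype score by explicit participant x phenotype double loop
brute_scores <- function(cohort, invalid = default_invalid_values()) {
  rec <- cohort$records
  phens <- unique(rec$phenotype[!duplicated(tolower(rec$phenotype))])
  out <- integer(length(phens))
  names(out) <- phens
  for (f in phens) {
    for (p in cohort$participants) {
      vals <- rec$value[rec$participant_id == p &
                          tolower(rec$phenotype) == tolower(f)]
      ok <- FALSE
      for (v in vals) {
        lv <- tolower(trimws(v))
        if (nzchar(lv) && !(lv %in% invalid)) ok <- TRUE
      }
      if (ok) out[f] <- out[f] + 1L
    }
  }
  out
}

# oracle: P-index from a named score vector restricted to valid_names
brute_p_index <- function(cohort, scores, valid_names,
                          invalid = default_invalid_values()) {
  rec <- cohort$records
  denom <- sum(scores[valid_names])
  out <- numeric(length(cohort$participants))
  names(out) <- cohort$participants
  for (p in cohort$participants) {
    s <- 0
    for (f in valid_names) {
      vals <- rec$value[rec$participant_id == p &
                          tolower(rec$phenotype) == tolower(f)]
      ok <- FALSE
      for (v in vals) {
        lv <- tolower(trimws(v))
        if (nzchar(lv) && !(lv %in% invalid)) ok <- TRUE
      }
      if (ok) s <- s + scores[[f]]
    }
    out[p] <- 100 * s / denom
  }
  out
}

# oracle: exact two-sided rank-sum p by enumerating all C(m+n, m)
# assignments of the pooled values to group A (assumes no ties)
enum_wilcox_p <- function(a, b) {
  vals <- c(a, b)
  m <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  combos <- utils::combn(length(vals), m)
  u_all <- apply(combos, 2, function(ix) u_of(vals[ix], vals[-ix]))
  p <- if (u_obs > m * length(b) / 2) mean(u_all >= u_obs)
       else mean(u_all <= u_obs)
  min(1, 2 * p)
}
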