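#' Simulation parameters for a synthetic self-reported cohort
#'
#' Defines the generative model used to emulate the structure of an
#' open-enrollment, self-reported phenotype cohort: a large group that
#' contributes nothing, a large group that answers essentially all
#' surveys, a partial-taker remainder, sex-dependent participation,
#' state/zip geography, occasional non-informative answers and duplicated
#' records. Defaults reproduce the study conditions the package's tests
#' exercise: 27% zero contributors, 30% full survey takers, and a
#' participation dichotomy.
#'
#' Participants fall into three latent classes: `zero` (appear only on
#' the roster), `full` (take every survey) and `partial` (take each
#' checklist survey with probability `p_answer` and the
#' demographic/profile survey with probability `p_demo_answer` — the
#' profile survey is the enrollment entry point, hence taken far more
#' often). A checklist survey whose taker checked nothing is invisible on
#' a real profile, so "taking" a checklist survey here means *visibly*
#' taking it: at least one item is affirmative, and partial takers take
#' at least one visible survey (otherwise they would be
#' indistinguishable from the zero class).
#'
#' `sex_effect` is an additive shift in survey-taking propensity for
#' females, applied to both the full-taker probability and the partial
#' per-survey answer probability, split so the cohort-wide marginals are
#' preserved (females get `+sex_effect * male_share`, males
#' `-sex_effect * female_share`).
#'
#' @param n_participants cohort size (default 2000).
#' @param surveys data frame with columns `name`, `n_phenotypes`,
#'   `checklist` describing the checklist surveys; default: 16 surveys
#'   with sizes 4-34 phenotypes mirroring a trait-and-disease survey
#'   battery. A fixed 13-item demographic profile survey is always added.
#' @param p_zero probability of the zero-contribution class (0.27).
#' @param p_full_taker probability of the full-taker class (0.30).
#' @param p_answer partial takers' per-checklist-survey probability (0.10).
#' @param p_demo_answer partial takers' probability of taking the
#'   demographic survey (0.70).
#' @param p_yes per-item probability of an affirmative checklist answer
#'   (0.30).
#' @param sex_ratio_male probability of male sex (0.582).
#' @param p_nonbinary probability of a non-binary entry (0.005).
#' @param sex_effect additive female participation shift (0.10).
#' @param states named numeric vector of state weights (normalized to
#'   sum 1).
#' @param zips_per_state synthetic zip codes per state (5).
#' @param p_invalid_value probability a record's value is replaced by a
#'   non-informative answer (0.02).
#' @param p_duplicate_record probability a record line is duplicated
#'   (0.01).
#' @param seed RNG seed; all sampling is routed through one stream seeded
#'   with it.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_participants = 2000L,
                       surveys = NULL,
                       p_zero = 0.27,
                       p_full_taker = 0.30,
                       p_answer = 0.10,
                       p_demo_answer = 0.70,
                       p_yes = 0.30,
                       sex_ratio_male = 0.582,
                       p_nonbinary = 0.005,
                       sex_effect = 0.10,
                       states = NULL,
                       zips_per_state = 5L,
                       p_invalid_value = 0.02,
                       p_duplicate_record = 0.01,
                       seed = 1L) {
  if (is.null(surveys)) surveys <- default_checklist_surveys()
  surveys <- as_tibble(surveys)
  stopifnot(all(c("name", "n_phenotypes", "checklist") %in% names(surveys)))
  if (anyDuplicated(tolower(surveys$name))) stop("duplicate survey name")
  if (any(surveys$n_phenotypes < 1L)) stop("surveys need >= 1 phenotype")
  if (is.null(states)) {
    states <- c("Massachusetts" = 0.20, "California" = 0.20,
                "Missouri" = 0.15, "New York" = 0.12, "Texas" = 0.12,
                "Utah" = 0.08, "Minnesota" = 0.07, "South Carolina" = 0.06)
  }
  if (any(states < 0) || sum(states) <= 0 || is.null(names(states))) {
    stop("states must be a named vector of non-negative weights")
  }
  states <- states / sum(states)
  probs <- c(p_zero = p_zero, p_full_taker = p_full_taker,
             p_answer = p_answer, p_demo_answer = p_demo_answer,
             p_yes = p_yes, sex_ratio_male = sex_ratio_male,
             p_nonbinary = p_nonbinary,
             p_invalid_value = p_invalid_value,
             p_duplicate_record = p_duplicate_record)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (p_zero + p_full_taker > 1) stop("p_zero + p_full_taker must be <= 1")
  if (n_participants < 1L) stop("n_participants must be >= 1")
  structure(list(n_participants = as.integer(n_participants),
                 surveys = surveys, p_zero = p_zero,
                 p_full_taker = p_full_taker, p_answer = p_answer,
                 p_demo_answer = p_demo_answer, p_yes = p_yes,
                 sex_ratio_male = sex_ratio_male,
                 p_nonbinary = p_nonbinary, sex_effect = sex_effect,
                 states = states, zips_per_state = as.integer(zips_per_state),
                 p_invalid_value = p_invalid_value,
                 p_duplicate_record = p_duplicate_record,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# checklist-survey battery emulating a trait-and-disease survey set
default_checklist_surveys <- function() {
  tibble(
    name = c("Trait & Disease Survey: Blood",
             "Trait & Disease Survey: Cancers",
             "Trait & Disease Survey: Circulatory System",
             "Trait & Disease Survey: Congenital Traits",
             "Trait & Disease Survey: Digestive System",
             "Trait & Disease Survey: Endocrine and Metabolic",
             "Trait & Disease Survey: Genitourinary Systems",
             "Trait & Disease Survey: Musculoskeletal System",
             "Trait & Disease Survey: Nervous System",
             "Trait & Disease Survey: Respiratory System",
             "Trait & Disease Survey: Skin and Subcutaneous Tissue",
             "Trait & Disease Survey: Vision and Hearing",
             "Basic Phenotypes Survey",
             "Absolute Pitch Survey",
             "Trait Survey A",
             "Trait Survey B"),
    n_phenotypes = c(13L, 25L, 28L, 22L, 23L, 18L, 15L, 23L, 22L, 9L,
                     16L, 25L, 9L, 4L, 23L, 34L),
    checklist = TRUE
  )
}

# the fixed demographic/profile survey (non-checklist)
demographic_phenotypes <- function() {
  c("Sex/Gender", "State", "Zip code", "Date of Birth", "Blood Type",
    "Height", "Weight", "Race/ethnicity", "Handedness", "Eye Color",
    "Hair Color", "Diastolic blood pressure", "Systolic blood pressure")
}

#' Build the survey catalog implied by simulation parameters
#'
#' One 13-item demographic profile survey (not a checklist: its items —
#' sex, state, height, ... — cannot meaningfully be filled with "no")
#' plus the checklist surveys in `params$surveys`, with phenotype names
#' unique across surveys.
#'
#' @param params a [sim_params()] object.
#' @return a `survey_catalog`.
#' @export
default_survey_catalog <- function(params = sim_params()) {
  surveys <- list(list(name = "Participant Survey", checklist = FALSE,
                       phenotypes = demographic_phenotypes()))
  sv <- params$surveys
  for (i in seq_len(nrow(sv))) {
    surveys[[length(surveys) + 1L]] <- list(
      name = sv$name[i],
      checklist = isTRUE(sv$checklist[i]),
      phenotypes = sprintf("%s: condition %02d", sv$name[i],
                           seq_len(sv$n_phenotypes[i]))
    )
  }
  load_survey_catalog(surveys)
}

#' Generate a synthetic zip-code gazetteer
#'
#' Each state receives `zips_per_state` synthetic 5-digit zips with
#' coordinates drawn uniformly inside a disjoint 2 x 2 degree bounding
#' box per state, so state membership is recoverable from coordinates.
#'
#' @param params a [sim_params()] object.
#' @return a `zip_gazetteer` with an extra `state` column; the per-state
#'   boxes are in `attr(, "boxes")`.
#' @export
generate_gazetteer <- function(params = sim_params()) {
  st <- names(params$states)
  k <- params$zips_per_state
  boxes <- tibble(
    state = st,
    lat_lo = 20 + 3 * ((seq_along(st) - 1L) %% 23L),
    lon_lo = -170 + 7 * ((seq_along(st) - 1L) %% 24L)
  )
  boxes$lat_hi <- boxes$lat_lo + 2
  boxes$lon_hi <- boxes$lon_lo + 2
  withr::with_seed(params$seed, {
    out <- tibble(
      zip = sprintf("%05d", rep(10000L + 100L * seq_along(st), each = k) +
                      seq_len(k) - 1L),
      latitude = rep(boxes$lat_lo, each = k) + stats::runif(length(st) * k, 0, 2),
      longitude = rep(boxes$lon_lo, each = k) + stats::runif(length(st) * k, 0, 2),
      state = rep(st, each = k)
    )
  })
  structure(out, boxes = boxes, n_dropped = 0L,
            class = c("zip_gazetteer", class(out)))
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from the generative model described in [sim_params()]
#' and returns the raw profile records (duplicates and invalid values
#' included, as a scraper would emit them), the enrollment roster, the
#' per-participant latent truth, and the matching survey catalog and
#' gazetteer. Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return list with `records` (tibble: participant_id, phenotype,
#'   value), `roster` (character), `truth` (tibble: participant_id,
#'   class, sex, state, zip), `catalog`, `gazetteer` and `params`.
#' @export
generate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  catalog <- default_survey_catalog(params)
  gazetteer <- generate_gazetteer(params)
  zips_by_state <- split(gazetteer$zip, gazetteer$state)
  n <- params$n_participants
  sv <- params$surveys
  S <- nrow(sv)
  eff_f <- params$sex_effect * params$sex_ratio_male
  eff_m <- -params$sex_effect * (1 - params$sex_ratio_male)
  clamp <- function(p) pmin(1, pmax(0, p))
  withr::with_seed(params$seed, {
    ids <- sprintf("SYN%05d", seq_len(n))
    sex <- sample(c("Male", "Female", "Non-binary"), n, replace = TRUE,
                  prob = c(params$sex_ratio_male * (1 - params$p_nonbinary),
                           (1 - params$sex_ratio_male) * (1 - params$p_nonbinary),
                           params$p_nonbinary))
    shift <- ifelse(sex == "Female", eff_f, ifelse(sex == "Male", eff_m, 0))
    p_full_i <- clamp(params$p_full_taker + shift)
    u <- stats::runif(n)
    class <- ifelse(u < params$p_zero, "zero",
                    ifelse(u < params$p_zero + p_full_i, "full", "partial"))
    state <- sample(names(params$states), n, replace = TRUE,
                    prob = params$states)
    zip <- vapply(state, function(s) sample(zips_by_state[[s]], 1L), "")
    truth <- tibble(participant_id = ids, class = class, sex = sex,
                    state = state, zip = unname(zip))

    active <- class != "zero"
    p_ans_i <- clamp(params$p_answer + shift)
    take <- matrix(FALSE, n, S)
    take[class == "full", ] <- TRUE
    part <- which(class == "partial")
    if (length(part) > 0L) {
      take[part, ] <- stats::runif(length(part) * S) <
        rep(p_ans_i[part], times = S)
    }
    demo <- class == "full"
    demo[part] <- stats::runif(length(part)) < params$p_demo_answer
    # a partial taker with no visible survey would be indistinguishable
    # from the zero class: force one survey, demographic or checklist
    none <- part[rowSums(take[part, , drop = FALSE]) == 0L & !demo[part]]
    if (length(none) > 0L) {
      pick <- sample.int(S + 1L, length(none), replace = TRUE)
      demo[none[pick == S + 1L]] <- TRUE
      forced <- none[pick <= S]
      take[cbind(forced, pick[pick <= S])] <- TRUE
    }

    rows <- list()
    # demographic profile survey
    dg <- which(demo)
    if (length(dg) > 0L) {
      nd <- length(dg)
      vals <- rbind(
        sex[dg], state[dg], zip[dg],
        sprintf("%02d/%02d/%d", sample.int(12L, nd, TRUE),
                sample.int(28L, nd, TRUE), sample(1940:2000, nd, TRUE)),
        sample(c("A+", "A-", "B+", "B-", "AB+", "AB-", "O+", "O-"), nd, TRUE),
        sprintf("%d cm", round(stats::rnorm(nd, 170, 10))),
        sprintf("%d kg", round(stats::rnorm(nd, 75, 12))),
        sample(c("White", "Asian", "Black", "Hispanic", "Other"), nd, TRUE,
               prob = c(0.7, 0.1, 0.08, 0.08, 0.04)),
        sample(c("Right", "Left", "Ambidextrous"), nd, TRUE,
               prob = c(0.85, 0.12, 0.03)),
        sample(c("Brown", "Blue", "Green", "Hazel"), nd, TRUE),
        sample(c("Brown", "Black", "Blonde", "Red", "Gray"), nd, TRUE),
        sprintf("%d mmHg", round(stats::rnorm(nd, 78, 8))),
        sprintf("%d mmHg", round(stats::rnorm(nd, 120, 10)))
      )
      rows[[length(rows) + 1L]] <- tibble(
        participant_id = rep(ids[dg], each = length(demographic_phenotypes())),
        phenotype = rep(demographic_phenotypes(), times = length(dg)),
        value = as.vector(vals)
      )
    }
    # checklist surveys: only affirmative answers surface, at least one
    for (s in seq_len(S)) {
      takers <- which(take[, s])
      if (length(takers) == 0L) next
      k <- sv$n_phenotypes[s]
      yes <- matrix(stats::runif(length(takers) * k) < params$p_yes,
                    nrow = length(takers))
      empty <- which(rowSums(yes) == 0L)
      if (length(empty) > 0L) {
        yes[cbind(empty, sample.int(k, length(empty), replace = TRUE))] <- TRUE
      }
      idx <- which(yes, arr.ind = TRUE)
      rows[[length(rows) + 1L]] <- tibble(
        participant_id = ids[takers[idx[, 1]]],
        phenotype = sprintf("%s: condition %02d", sv$name[s], idx[, 2]),
        value = "yes"
      )
    }
    # administrative bookkeeping rows for every active participant, and
    # genotype-data rows for a subset: both must be excluded downstream
    act <- which(active)
    rows[[length(rows) + 1L]] <- tibble(
      participant_id = rep(ids[act], times = 2L),
      phenotype = rep(c("Enrolled", "Consent"), each = length(act)),
      value = "yes"
    )
    geno <- act[stats::runif(length(act)) < 0.15]
    if (length(geno) > 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        participant_id = ids[geno],
        phenotype = "Whole-genome sequencing data",
        value = "download"
      )
    }
    records <- dplyr::bind_rows(rows)
    # non-informative answers
    inv <- stats::runif(nrow(records)) < params$p_invalid_value
    if (any(inv)) {
      records$value[inv] <- sample(default_invalid_values(), sum(inv),
                                   replace = TRUE)
    }
    # scraper-style exact duplicate lines
    dup <- stats::runif(nrow(records)) < params$p_duplicate_record
    records <- dplyr::bind_rows(records, records[dup, ])
    records <- records[order(records$participant_id, method = "radix"), ]
  })
  list(records = records, roster = ids, truth = truth, catalog = catalog,
       gazetteer = gazetteer, params = params)
}

#' Write a generated simulation to disk
#'
#' Emits `profiles.tsv` (raw records, duplicates preserved),
#' `roster.txt`, `catalog.yaml`, `gazetteer.csv` and `truth.tsv` under
#' `dir`.
#'
#' @param sim result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("profiles.tsv", "roster.txt", "catalog.yaml",
                            "gazetteer.csv", "truth.tsv"))
  con <- file(paths[1], "w", encoding = "UTF-8")
  writeLines("participant_id\tphenotype\tvalue", con)
  writeLines(paste(sim$records$participant_id, sim$records$phenotype,
                   sim$records$value, sep = "\t"), con)
  close(con)
  write_roster(sim$roster, paths[2])
  write_survey_catalog(sim$catalog, paths[3])
  utils::write.csv(as.data.frame(sim$gazetteer)[, c("zip", "latitude", "longitude")],
                   paths[4], row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth, paths[5], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
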