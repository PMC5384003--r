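#' Build a cohort from a data frame of phenotype records
#'
#' A cohort is the package's central container: a tibble of deduplicated
#' `(participant_id, phenotype, value)` records plus the full participant
#' roster. Participants enrolled but contributing nothing are represented
#' by appearing in the roster without records; they receive a P-index of 0
#' downstream.
#'
#' Records are whitespace-trimmed and deduplicated case-insensitively on
#' the full triple (the first-seen casing is kept). A record with an empty
#' participant id or phenotype name after trimming is an error.
#'
#' @param records data frame with columns `participant_id`, `phenotype`,
#'   `value` (a `source` column is kept if present, else set to
#'   `"reported"`).
#' @param roster optional character vector of all enrolled participant
#'   ids; the cohort roster is the union of these and the ids seen in
#'   `records`.
#' @return An object of class `cohort`: a list with `records` (tibble) and
#'   `participants` (sorted character vector). The number of duplicate
#'   records dropped is recorded in `attr(, "load_report")`.
#' @export
as_cohort <- function(records, roster = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("participant_id", "phenotype", "value")
  if (!all(need %in% names(records))) {
    stop("records must have columns participant_id, phenotype, value")
  }
  rec <- as_tibble(records)
  rec$participant_id <- trimws(as.character(rec$participant_id))
  rec$phenotype <- trimws(as.character(rec$phenotype))
  rec$value <- trimws(as.character(rec$value))
  if (!"source" %in% names(rec)) rec$source <- "reported"
  bad <- !nzchar(rec$participant_id) | !nzchar(rec$phenotype)
  if (any(bad)) {
    stop("empty participant_id or phenotype in record(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  key <- paste(rec$participant_id, tolower(rec$phenotype),
               tolower(rec$value), sep = "\r")
  dup <- duplicated(key)
  rec <- rec[!dup, c("participant_id", "phenotype", "value", "source")]
  participants <- sort(unique(c(rec$participant_id,
                                if (!is.null(roster)) trimws(as.character(roster)))))
  participants <- participants[nzchar(participants)]
  structure(
    list(records = rec, participants = participants),
    load_report = list(n_records = nrow(rec), n_duplicates = sum(dup)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants (%d with records), %d records\n",
              n_participants(x),
              dplyr::n_distinct(x$records$participant_id),
              nrow(x$records)))
  invisible(x)
}

#' Number of enrolled participants (N)
#'
#' @param cohort a [as_cohort()] object.
#' @return integer count, including zero-contribution participants present
#'   only in the roster.
#' @export
n_participants <- function(cohort) length(cohort$participants)

#' Read a tab-separated phenotype profile table
#'
#' Parses the 3-column profile format
#' `participant_id<TAB>phenotype<TAB>value` (UTF-8, optional header line
#' whose first field is `participant_id`). Duplicate identical triples are
#' dropped silently and counted in the load report; a line that does not
#' have exactly three tab-separated fields is a parse error citing the
#' line number.
#'
#' @param path file path (or connection) to the TSV.
#' @param roster optional character vector, or path to a one-id-per-line
#'   roster file, enumerating all enrolled participants so that
#'   zero-contribution participants are representable.
#' @return a [as_cohort()] object.
#' @export
parse_profile_table <- function(path, roster = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (is.character(roster) && length(roster) == 1L && file.exists(roster)) {
    roster <- read_roster(roster)
  }
  offset <- 0L
  if (length(lines) > 0L &&
      grepl("^participant_id(\t|$)", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1L]
    offset <- 1L
  }
  lines_keep <- nzchar(trimws(lines))
  idx <- which(lines_keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty value after the final tab is dropped by strsplit
  two_with_tab <- nf == 2L & grepl("\t$", lines[idx])
  fields[two_with_tab] <- lapply(fields[two_with_tab], function(f) c(f, ""))
  nf[two_with_tab] <- 3L
  if (any(nf != 3L)) {
    bad <- idx[which(nf != 3L)[1L]] + offset
    stop(sprintf("malformed profile line %d: expected 3 tab-separated fields", bad))
  }
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  records <- tibble(participant_id = m[, 1], phenotype = m[, 2], value = m[, 3])
  # empty-value rows act as roster sentinels: the id is enrolled, no record
  sentinel <- !nzchar(trimws(records$value))
  roster <- unique(c(roster, trimws(records$participant_id[sentinel])))
  as_cohort(records[!sentinel, ], roster = roster)
}

#' Write a cohort back to the tab-separated profile format
#'
#' Inverse of [parse_profile_table()]: parsing the written file with the
#' cohort's roster reproduces the cohort up to record order.
#'
#' @param cohort a cohort.
#' @param path output file path.
#' @param audit if `TRUE`, append a fourth `source` column
#'   (reported/imputed) for audit purposes; [parse_profile_table()] reads
#'   only the 3-column form.
#' @export
write_profile_table <- function(cohort, path, audit = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  cols <- c("participant_id", "phenotype", "value", if (audit) "source")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(cohort$records) > 0L) {
    rec <- cohort$records[, cols]
    writeLines(do.call(paste, c(unname(as.list(rec)), sep = "\t")), con)
  }
  invisible(NULL)
}

#' Read / write a participant roster (one id per line)
#'
#' @param path file path.
#' @return `read_roster`: character vector of ids.
#' @export
read_roster <- function(path) {
  ids <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  ids[nzchar(ids)]
}

#' @rdname read_roster
#' @param ids character vector of participant ids.
#' @export
write_roster <- function(ids, path) {
  writeLines(ids, path)
  invisible(NULL)
}

#' Load a survey catalog
#'
#' The catalog maps each survey to its phenotype list and records whether
#' it is a *checklist* survey (one that surfaces only affirmative answers,
#' so that takers' missing items must be filled with "no" during
#' normalization). The on-disk form is a YAML document: a sequence of
#' surveys, each with `name`, `checklist` and `phenotypes`.
#'
#' @param path YAML file path, or an already-parsed list of surveys.
#' @return object of class `survey_catalog`: a list of surveys, each a
#'   list with `name` (string), `checklist` (flag) and `phenotypes`
#'   (character vector); input order is preserved.
#' @export
load_survey_catalog <- function(path) {
  surveys <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(surveys)) surveys <- list()
  out <- lapply(surveys, function(s) {
    if (is.null(s$name) || !nzchar(trimws(s$name))) stop("survey without a name")
    phen <- trimws(as.character(unlist(s$phenotypes)))
    if (length(phen) == 0L) {
      stop(sprintf("survey '%s' has an empty phenotype list", s$name))
    }
    if (anyDuplicated(tolower(phen))) {
      stop(sprintf("survey '%s' lists duplicate phenotypes", s$name))
    }
    list(name = trimws(s$name),
         checklist = isTRUE(s$checklist),
         phenotypes = phen)
  })
  nms <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(tolower(nms))) stop("duplicate survey name in catalog")
  structure(out, class = "survey_catalog")
}

#' Write a survey catalog to YAML
#'
#' @param catalog a `survey_catalog`.
#' @param path output file path.
#' @export
write_survey_catalog <- function(catalog, path) {
  yaml::write_yaml(lapply(unclass(catalog), function(s) {
    list(name = s$name, checklist = s$checklist,
         phenotypes = as.list(s$phenotypes))
  }), path)
  invisible(NULL)
}

#' Load a zip-code gazetteer
#'
#' Reads a CSV with columns `zip`, `latitude`, `longitude` used to link
#' participants' reported zip codes to coordinates. Rows with unparseable
#' or out-of-range coordinates (|lat| > 90, |lon| > 180) are dropped and
#' counted in `attr(, "n_dropped")`.
#'
#' @param path CSV file path.
#' @return object of class `zip_gazetteer`: a tibble with normalized
#'   5-digit `zip` keys plus `latitude` and `longitude` (decimal degrees).
#' @export
load_gazetteer <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("zip", "latitude", "longitude")
  if (!all(need %in% names(df))) {
    stop("gazetteer must have columns zip, latitude, longitude")
  }
  lat <- suppressWarnings(as.numeric(df$latitude))
  lon <- suppressWarnings(as.numeric(df$longitude))
  zip <- normalize_zip(df$zip)
  ok <- !is.na(lat) & !is.na(lon) & !is.na(zip) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
  out <- tibble(zip = zip[ok], latitude = lat[ok], longitude = lon[ok])
  out <- out[!duplicated(out$zip), ]
  structure(out, n_dropped = sum(!ok), class = c("zip_gazetteer", class(out)))
}

#' Normalize free-text zip values to 5-digit keys
#'
#' Strips non-digits (a ZIP+4 like `02144-1234` keeps its leading 5
#' digits) and left-pads with zeros, so `"2144"` becomes `"02144"`.
#' Values that cannot be reduced to a plausible zip return `NA`.
#'
#' @param x character vector of raw zip values.
#' @return character vector of 5-digit zips or `NA`.
#' @export
normalize_zip <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("-.*$", "", x)            # drop ZIP+4 suffix
  digits <- gsub("[^0-9]", "", x)
  out <- rep(NA_character_, length(x))
  n <- nchar(digits)
  ok5 <- n >= 1L & n <= 5L
  out[ok5] <- sprintf("%05d", as.integer(digits[ok5]))
  out[n == 9L] <- substr(digits[n == 9L], 1L, 5L)  # ZIP+4 without the dash
  out
}
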