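#' CDM-lite data store
#'
#' A `cdm_store` holds the minimal set of OMOP-CDM-style tables the signal
#' detection pipeline consumes: persons (with the two utilisation covariates
#' used for propensity matching), drug exposures, condition occurrences and
#' measurements, plus the study observation window. It is deliberately a
#' "CDM-lite": only the columns the pipeline reads, not the full OMOP DDL.
#'
#' Tables are plain data frames:
#' \describe{
#'   \item{persons}{`person_id` (character, unique), `sex`
#'     (`"male"`/`"female"`/`"unknown"`), `birth_year` (integer, 1900--2018),
#'     `n_outpatient_visits` (integer >= 0), `hospitalization_days`
#'     (integer >= 0).}
#'   \item{drug_exposures}{`person_id`, `drug_code`, `start_date` (Date).}
#'   \item{conditions}{`person_id`, `condition_code`, `date` (Date).}
#'   \item{measurements}{`person_id`, `date`, `measurement_code`,
#'     `value_categorical` (`"NORMAL"`, `"L"`, `"R"`, `"LR"` or `NA`),
#'     `value_numeric` (numeric or `NA`); at least one value present per row.}
#' }
#'
#' @param persons,drug_exposures,conditions,measurements data frames as above;
#'   missing tables default to empty.
#' @param study_start,study_end study observation window (Dates or ISO strings),
#'   `study_start < study_end`.
#' @return an object of class `cdm_store`.
#' @examples
#' st <- cdm_store(
#'   persons = data.frame(person_id = "p1", sex = "female", birth_year = 1980,
#'                        n_outpatient_visits = 4L, hospitalization_days = 0L),
#'   study_start = "2014-01-01", study_end = "2018-12-31")
#' st
#' @export
cdm_store <- function(persons = NULL, drug_exposures = NULL, conditions = NULL,
                      measurements = NULL,
                      study_start = "2014-01-01", study_end = "2018-12-31") {
  empty <- cdm_empty_tables()
  store <- structure(list(
    persons        = coerce_table(persons %||% empty$persons, empty$persons, "person"),
    drug_exposures = coerce_table(drug_exposures %||% empty$drug_exposures,
                                  empty$drug_exposures, "drug_exposure"),
    conditions     = coerce_table(conditions %||% empty$conditions,
                                  empty$conditions, "condition_occurrence"),
    measurements   = coerce_table(measurements %||% empty$measurements,
                                  empty$measurements, "measurement"),
    study_start = as_iso_date(study_start, "study_start"),
    study_end   = as_iso_date(study_end, "study_end")
  ), class = "cdm_store")
  validate_cdm_store(store)
}

cdm_empty_tables <- function() {
  list(
    persons = data.frame(person_id = character(), sex = character(),
                         birth_year = integer(),
                         n_outpatient_visits = integer(),
                         hospitalization_days = integer(),
                         stringsAsFactors = FALSE),
    drug_exposures = data.frame(person_id = character(), drug_code = character(),
                                start_date = as.Date(character()),
                                stringsAsFactors = FALSE),
    conditions = data.frame(person_id = character(), condition_code = character(),
                            date = as.Date(character()),
                            stringsAsFactors = FALSE),
    measurements = data.frame(person_id = character(), date = as.Date(character()),
                              measurement_code = character(),
                              value_categorical = character(),
                              value_numeric = numeric(),
                              stringsAsFactors = FALSE)
  )
}

coerce_table <- function(x, template, table_name) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(template), names(x))
  if (length(missing_cols) > 0) {
    stop_validation("table '%s': missing column(s) %s", table_name,
                    paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(x), names(template))
  if (length(extra) > 0) {
    stop_validation("table '%s': unknown column(s) %s", table_name,
                    paste(extra, collapse = ", "))
  }
  x <- x[names(template)]
  for (col in names(template)) {
    if (inherits(template[[col]], "Date")) {
      x[[col]] <- as_iso_date(x[[col]], paste0(table_name, ".", col))
    } else if (is.character(template[[col]])) {
      x[[col]] <- as.character(x[[col]])
    } else if (is.integer(template[[col]])) {
      x[[col]] <- as.integer(x[[col]])
    } else if (is.numeric(template[[col]])) {
      x[[col]] <- as.numeric(x[[col]])
    }
  }
  rownames(x) <- NULL
  x
}

#' Validate a CDM-lite store
#'
#' Checks person-id uniqueness, field domains, referential integrity of every
#' child table against `persons`, and the study window. Errors name the
#' offending table and row.
#'
#' @param store a [cdm_store()].
#' @return the store, invisibly unchanged, if valid.
#' @export
validate_cdm_store <- function(store) {
  p <- store$persons
  if (anyDuplicated(p$person_id)) {
    stop_validation("table 'person': duplicated person_id '%s'",
                    p$person_id[anyDuplicated(p$person_id)])
  }
  bad_sex <- which(!p$sex %in% c("male", "female", "unknown"))
  if (length(bad_sex) > 0) {
    stop_validation("table 'person' row %d: invalid sex '%s'",
                    bad_sex[1], p$sex[bad_sex[1]])
  }
  bad_by <- which(is.na(p$birth_year) | p$birth_year < 1900 | p$birth_year > 2018)
  if (length(bad_by) > 0) {
    stop_validation("table 'person' row %d: implausible birth_year %s",
                    bad_by[1], p$birth_year[bad_by[1]])
  }
  bad_cnt <- which(p$n_outpatient_visits < 0 | p$hospitalization_days < 0)
  if (length(bad_cnt) > 0) {
    stop_validation("table 'person' row %d: negative visit/hospitalization count",
                    bad_cnt[1])
  }
  if (!(store$study_start < store$study_end)) {
    stop_validation("study_start (%s) must precede study_end (%s)",
                    store$study_start, store$study_end)
  }
  check_ref <- function(tab, name) {
    dangling <- which(!tab$person_id %in% p$person_id)
    if (length(dangling) > 0) {
      stop_validation("table '%s' row %d: person_id '%s' not in person table",
                      name, dangling[1], tab$person_id[dangling[1]])
    }
  }
  check_ref(store$drug_exposures, "drug_exposure")
  check_ref(store$conditions, "condition_occurrence")
  check_ref(store$measurements, "measurement")
  m <- store$measurements
  bad_val <- which(is.na(m$value_categorical) & is.na(m$value_numeric))
  if (length(bad_val) > 0) {
    stop_validation(
      "table 'measurement' row %d: needs value_categorical or value_numeric",
      bad_val[1])
  }
  invisible(store)
}

#' @export
print.cdm_store <- function(x, ...) {
  cat("CDM-lite store:", nrow(x$persons), "persons,",
      nrow(x$drug_exposures), "drug exposures,",
      nrow(x$conditions), "conditions,",
      nrow(x$measurements), "measurements\n")
  cat("Study window:", format(x$study_start), "to", format(x$study_end), "\n")
  invisible(x)
}

cdm_csv_files <- c(
  persons = "person.csv", drug_exposures = "drug_exposure.csv",
  conditions = "condition_occurrence.csv", measurements = "measurement.csv"
)

#' Read a CDM-lite store from a directory of CSV files
#'
#' Expects `person.csv`, `visit_summary.csv`, `drug_exposure.csv`,
#' `condition_occurrence.csv`, `measurement.csv` and `study_window.csv`
#' (UTF-8, header row, comma-delimited, ISO-8601 dates). `person.csv` carries
#' `person_id, sex, birth_year`; the two utilisation covariates live in
#' `visit_summary.csv` and are joined on `person_id`.
#'
#' @param path directory containing the CSV tables.
#' @return a validated [cdm_store()].
#' @seealso [write_cdm_store()] for the inverse; the round trip is lossless.
#' @export
read_cdm_store <- function(path) {
  need <- c("person.csv", "visit_summary.csv", unname(cdm_csv_files[-1]),
            "study_window.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing) > 0) {
    stop_validation("missing table file(s) in '%s': %s", path,
                    paste(missing, collapse = ", "))
  }
  rd <- function(f, classes) {
    utils::read.csv(file.path(path, f), colClasses = classes,
                    stringsAsFactors = FALSE)
  }
  person <- rd("person.csv",
               c(person_id = "character", sex = "character", birth_year = "integer"))
  visits <- rd("visit_summary.csv",
               c(person_id = "character", n_outpatient_visits = "integer",
                 hospitalization_days = "integer"))
  persons <- merge(person, visits, by = "person_id", all.x = TRUE, sort = FALSE)
  if (anyNA(persons$n_outpatient_visits)) {
    stop_validation("table 'visit_summary': missing row for person_id '%s'",
                    persons$person_id[which(is.na(persons$n_outpatient_visits))[1]])
  }
  persons <- persons[order(persons$person_id), ]
  win <- rd("study_window.csv",
            c(study_start = "character", study_end = "character"))
  drug <- rd("drug_exposure.csv",
             c(person_id = "character", drug_code = "character",
               start_date = "character"))
  cond <- rd("condition_occurrence.csv",
             c(person_id = "character", condition_code = "character",
               date = "character"))
  meas <- rd("measurement.csv",
             c(person_id = "character", date = "character",
               measurement_code = "character", value_categorical = "character",
               value_numeric = "numeric"))
  meas$value_categorical[meas$value_categorical == ""] <- NA_character_
  cdm_store(persons = persons, drug_exposures = drug, conditions = cond,
            measurements = meas,
            study_start = win$study_start[1], study_end = win$study_end[1])
}

#' Write a CDM-lite store to a directory of CSV files
#'
#' Emits one CSV per table in canonical column order with ISO-8601 dates, plus
#' `study_window.csv`. Rows are sorted on their key columns, so
#' `write_cdm_store(read_cdm_store(d), d2)` reproduces the files byte for byte.
#'
#' @param store a [cdm_store()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cdm_store <- function(store, path) {
  validate_cdm_store(store)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) {
    for (col in names(df)) if (inherits(df[[col]], "Date")) {
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
    utils::write.csv(df, file.path(path, f), row.names = FALSE, quote = FALSE,
                     na = "")
  }
  p <- store$persons[order(store$persons$person_id), ]
  wr(p[c("person_id", "sex", "birth_year")], "person.csv")
  wr(p[c("person_id", "n_outpatient_visits", "hospitalization_days")],
     "visit_summary.csv")
  ord <- function(df, cols) df[do.call(order, df[cols]), , drop = FALSE]
  wr(ord(store$drug_exposures, c("person_id", "drug_code", "start_date")),
     "drug_exposure.csv")
  wr(ord(store$conditions, c("person_id", "condition_code", "date")),
     "condition_occurrence.csv")
  wr(ord(store$measurements, c("person_id", "date", "measurement_code")),
     "measurement.csv")
  wr(data.frame(study_start = format(store$study_start),
                study_end = format(store$study_end)), "study_window.csv")
  invisible(path)
}

#' Tabulate a population by sex
#'
#' Counts and percentages by sex for either an EHR store (its person table) or
#' a set of spontaneous reports. Percentages are rounded half-up, one decimal
#' by default (two decimals where finer tables are wanted).
#'
#' @param x a [cdm_store()], a data frame of SRS reports with a `sex` column,
#'   or a character vector of sexes.
#' @param digits decimal places for the percentage (half-up).
#' @return data frame with columns `sex`, `n`, `pct`; counts sum to the
#'   population size.
#' @examples
#' summarize_demographics(c(rep("male", 85), rep("female", 170)))
#' @export
summarize_demographics <- function(x, digits = 1) {
  sex <- if (inherits(x, "cdm_store")) x$persons$sex
         else if (is.data.frame(x)) x$sex
         else as.character(x)
  if (length(sex) == 0) stop_validation("empty population")
  levs <- intersect(c("male", "female", "unknown"), unique(sex))
  n <- vapply(levs, function(l) sum(sex == l), 0L)
  data.frame(sex = levs, n = as.integer(n),
             pct = round_half_up(100 * n / length(sex), digits),
             row.names = NULL, stringsAsFactors = FALSE)
}
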