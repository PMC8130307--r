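#' Standard pure-tone audiometry frequencies
#'
#' The six air-conduction test frequencies (Hz) averaged by the PTA6 hearing
#' index.
#' @export
PTA_FREQUENCIES <- c(250, 500, 1000, 2000, 4000, 8000)

check_thresholds <- function(thresholds, ear = "ear") {
  nm <- names(thresholds)
  if (is.null(nm)) {
    if (length(thresholds) == length(PTA_FREQUENCIES)) {
      nm <- as.character(PTA_FREQUENCIES)
      names(thresholds) <- nm
    } else {
      stop_validation("%s: expected thresholds at the six frequencies %s",
                      ear, paste(PTA_FREQUENCIES, collapse = ", "))
    }
  }
  missing <- setdiff(as.character(PTA_FREQUENCIES), nm)
  if (length(missing) > 0) {
    stop_validation("%s: missing threshold at %s Hz", ear,
                    paste(missing, collapse = ", "))
  }
  th <- as.numeric(thresholds[as.character(PTA_FREQUENCIES)])
  if (anyNA(th)) stop_validation("%s: NA threshold", ear)
  if (any(th < -10 | th > 120)) {
    stop_validation("%s: thresholds must lie in [-10, 120] dB HL", ear)
  }
  th
}

#' Six-frequency pure-tone average (PTA6)
#'
#' Arithmetic mean of the air-conduction hearing thresholds at 250, 500, 1000,
#' 2000, 4000 and 8000 Hz, the conventional summary of a whole audiogram.
#'
#' @param thresholds numeric vector of six thresholds in dB HL, named by
#'   frequency in Hz (unnamed vectors of length six are taken in ascending
#'   frequency order).
#' @return the mean threshold in dB HL, rounded half-up to one decimal.
#' @examples
#' pta6(c(`250` = 0, `500` = 10, `1000` = 20, `2000` = 30, `4000` = 40,
#'        `8000` = 50))  # 25
#' @export
pta6 <- function(thresholds) {
  th <- check_thresholds(thresholds)
  round_half_up(mean(th), 1)
}

#' Classify one ear as normal or abnormal
#'
#' An ear is abnormal when the threshold at any of the six test frequencies
#' exceeds the cutoff. The default reads "above 20 dB" strictly: a flat
#' 20 dB HL audiogram is still normal; set `strict = FALSE` for >= semantics.
#'
#' @inheritParams pta6
#' @param cutoff_db cutoff in dB HL (default 20).
#' @param strict if `TRUE` (default) abnormal requires a threshold strictly
#'   greater than `cutoff_db`.
#' @return `"normal"` or `"abnormal"`.
#' @export
classify_ear <- function(thresholds, cutoff_db = 20, strict = TRUE) {
  th <- check_thresholds(thresholds)
  abnormal <- if (strict) any(th > cutoff_db) else any(th >= cutoff_db)
  if (abnormal) "abnormal" else "normal"
}

#' Classify a patient from both ears
#'
#' Combines per-ear classifications into the four-level category stored in the
#' EHR: `NORMAL` (neither ear abnormal), `L`, `R`, or `LR` (both).
#'
#' @param left_thresholds,right_thresholds six thresholds per ear as in
#'   [pta6()].
#' @inheritParams classify_ear
#' @return one of `"NORMAL"`, `"L"`, `"R"`, `"LR"`.
#' @export
classify_patient <- function(left_thresholds, right_thresholds,
                             cutoff_db = 20, strict = TRUE) {
  if (missing(left_thresholds) || is.null(left_thresholds)) {
    stop_validation("left ear thresholds missing")
  }
  if (missing(right_thresholds) || is.null(right_thresholds)) {
    stop_validation("right ear thresholds missing")
  }
  l <- classify_ear(check_thresholds(left_thresholds, "left ear"),
                    cutoff_db, strict) == "abnormal"
  r <- classify_ear(check_thresholds(right_thresholds, "right ear"),
                    cutoff_db, strict) == "abnormal"
  if (l && r) "LR" else if (l) "L" else if (r) "R" else "NORMAL"
}

#' Measurement code used for categorical audiometry results
#' @export
PTA_MEASUREMENT_CODE <- "PTA_CLASS"

#' Convert paired-ear audiograms to categorical EHR measurements
#'
#' Takes a long table of per-ear audiograms and emits one measurement row per
#' person and test date, carrying the four-level normal/abnormal category
#' (the form in which audiometry enters the outcome definition: any category
#' other than `NORMAL` counts as an abnormal hearing test).
#'
#' @param audiograms data frame with columns `person_id`, `date`, `ear`
#'   (`"left"`/`"right"`), and `f250`, `f500`, `f1000`, `f2000`, `f4000`,
#'   `f8000` thresholds in dB HL. Each person-date must have both ears.
#' @inheritParams classify_ear
#' @return data frame of measurement rows (`person_id`, `date`,
#'   `measurement_code`, `value_categorical`, `value_numeric` = mean PTA6 of
#'   the two ears).
#' @export
audiograms_to_measurements <- function(audiograms, cutoff_db = 20, strict = TRUE) {
  empty <- cdm_empty_tables()$measurements
  if (is.null(audiograms) || nrow(audiograms) == 0) return(empty)
  fcols <- paste0("f", PTA_FREQUENCIES)
  key <- paste(audiograms$person_id, as.character(audiograms$date), sep = "\r")
  out <- lapply(split(seq_len(nrow(audiograms)), key), function(idx) {
    rows <- audiograms[idx, ]
    li <- which(rows$ear == "left")[1]
    ri <- which(rows$ear == "right")[1]
    if (is.na(li) || is.na(ri)) {
      stop_validation("person %s on %s: need both ears", rows$person_id[1],
                      rows$date[1])
    }
    lt <- stats::setNames(as.numeric(rows[li, fcols]), PTA_FREQUENCIES)
    rt <- stats::setNames(as.numeric(rows[ri, fcols]), PTA_FREQUENCIES)
    data.frame(person_id = rows$person_id[1],
               date = as_iso_date(rows$date[1]),
               measurement_code = PTA_MEASUREMENT_CODE,
               value_categorical = classify_patient(lt, rt, cutoff_db, strict),
               value_numeric = round_half_up((pta6(lt) + pta6(rt)) / 2, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$person_id, out$date), ]
  rownames(out) <- NULL
  out
}
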