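#' Round half-up
#'
#' Population tables are conventionally printed with half-up rounding
#' (0.05 -> 0.1), whereas base [round()] rounds half to even. Used for all
#' printed percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# abort with a class so callers can distinguish validation failures
stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("adrsignal_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

as_iso_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- tryCatch(as.Date(x, format = "%Y-%m-%d"),
                  error = function(e) rep(as.Date(NA), length(x)))
  if (anyNA(out) && !all(is.na(x))) {
    stop_validation("invalid %s: expected ISO-8601 (YYYY-MM-DD), got '%s'",
                    what, paste(utils::head(x[is.na(out)], 3), collapse = ", "))
  }
  out
}

# match a code inside a pipe-delimited code string, exact token match
has_code <- function(codes, code) {
  grepl(paste0("|", code, "|"), paste0("|", codes, "|"), fixed = TRUE)
}

split_codes <- function(codes) {
  strsplit(ifelse(is.na(codes) | codes == "", "", codes), "|", fixed = TRUE)
}

join_codes <- function(code_list) {
  vapply(code_list, function(x) paste(sort(unique(x)), collapse = "|"), "")
}
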