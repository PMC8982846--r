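# Internal helpers shared across modules.

# Coerce to Date, erroring informatively on unparseable input.
as_reg_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(out) && !all(is.na(x))) {
    bad <- which(is.na(out) & !is.na(x))
    stop("unparseable ", what, ": ", paste(head(x[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  out
}

days_between <- function(from, to) as.integer(as.numeric(to - from))

#' Normalize ICD-10 codes
#'
#' Uppercases and strips dots/whitespace so that code-set prefixes written as
#' 4-character categories (e.g. `T401`) match full 7-character claim codes
#' (e.g. `T40.1X1A`).
#'
#' @param x Character vector of ICD-10 codes.
#' @return Character vector of normalized codes.
#' @export
#' @examples
#' normalize_icd(c("t40.1X1A", " X42 "))
normalize_icd <- function(x) {
  gsub("[. ]", "", toupper(trimws(as.character(x))))
}

# Split a ";"-separated diagnosis string into a normalized code vector.
split_codes <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), normalize_icd)
}

# TRUE where any code in the (already normalized) vector starts with any prefix.
any_prefix_match <- function(codes, prefixes) {
  if (length(codes) == 0 || length(prefixes) == 0) return(FALSE)
  any(vapply(prefixes, function(p) any(startsWith(codes, p)), logical(1)))
}

# Vectorized over a list of code vectors.
any_prefix_match_list <- function(code_list, prefixes) {
  vapply(code_list, any_prefix_match, logical(1), prefixes = prefixes)
}

# Largest gap (in days) not covered by any span within [period_start,
# period_end), per period. Spans may overlap or abut; half-open intervals.
# `spans` must have patient_id, start_date, end_date; `periods` must have
# patient_id, period_id, period_start, period_end (several periods per
# patient allowed). Returns a data.table with period_id and max_gap;
# periods with no overlapping span get the full period length.
max_uncovered_gap <- function(spans, periods) {
  sp <- data.table::as.data.table(spans)[, .(patient_id,
    span_start = as.integer(as.Date(start_date)),
    span_end = as.integer(as.Date(end_date)))]
  pr <- data.table::as.data.table(periods)
  pr[, `:=`(p_start = as.integer(as.Date(period_start)),
            p_end = as.integer(as.Date(period_end)))]
  sp <- sp[pr, on = "patient_id", nomatch = NULL, allow.cartesian = TRUE]
  sp[, `:=`(span_start = pmax(span_start, p_start),
            span_end = pmin(span_end, p_end))]
  sp <- sp[span_end > span_start]
  if (nrow(sp) == 0) {
    return(pr[, .(period_id, max_gap = as.numeric(p_end - p_start))])
  }
  data.table::setorder(sp, period_id, span_start, span_end)
  sp[, cov_end := cummax(span_end), by = period_id]
  sp[, prev_cov := data.table::shift(cov_end), by = period_id]
  # leading gap on the first row of each period, internal gaps elsewhere
  sp[, gap := pmax(0, span_start - data.table::fifelse(
    is.na(prev_cov), p_start, prev_cov))]
  gaps <- sp[, .(max_gap = as.numeric(max(gap))), by = period_id]
  tails <- sp[sp[, .I[.N], by = period_id]$V1,
              .(period_id, tail_gap = as.numeric(p_end - cov_end))]
  gaps <- gaps[tails, on = "period_id"]
  gaps[, max_gap := pmax(max_gap, tail_gap, 0)]
  gaps[, tail_gap := NULL]
  no_span <- pr[!gaps, on = "period_id"]
  if (nrow(no_span) > 0) {
    gaps <- rbind(gaps, no_span[, .(period_id,
      max_gap = as.numeric(p_end - p_start))])
  }
  gaps
}

hash_config <- function(config) rlang::hash(config)
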