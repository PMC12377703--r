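# Shared helpers: calendar quarters, partial dates, FAERS unit codes.

#' Quarter label arithmetic
#'
#' FAERS data are released per calendar quarter, labelled e.g. `"2004Q1"`.
#' `quarter_index()` maps a label to an integer on a contiguous scale
#' (4 per year) so quarters can be compared and sequenced;
#' `quarter_label()` inverts it.
#'
#' @param q character vector of labels like `"2010Q3"`.
#' @return integer vector (`quarter_index`) or character vector
#'   (`quarter_label`).
#' @examples
#' quarter_index("2004Q2") - quarter_index("2004Q1")  # 1
#' quarter_label(quarter_index("2024Q2"))
#' @export
quarter_index <- function(q) {
  m <- regmatches(q, regexec("^([0-9]{4})Q([1-4])$", q))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed quarter label(s): ", paste(unique(q[bad]), collapse = ", "))
  }
  yr <- as.integer(vapply(m, `[`, character(1), 2L))
  qq <- as.integer(vapply(m, `[`, character(1), 3L))
  yr * 4L + (qq - 1L)
}

#' @rdname quarter_index
#' @param idx integer vector as produced by `quarter_index()`.
#' @export
quarter_label <- function(idx) {
  sprintf("%dQ%d", idx %/% 4L, idx %% 4L + 1L)
}

#' @rdname quarter_index
#' @param from,to quarter labels bounding the (inclusive) sequence.
#' @export
quarter_seq <- function(from, to) {
  quarter_label(seq.int(quarter_index(from), quarter_index(to)))
}

# First calendar day of a quarter as a Date.
quarter_start_date <- function(q) {
  idx <- quarter_index(q)
  as.Date(sprintf("%d-%02d-01", idx %/% 4L, (idx %% 4L) * 3L + 1L))
}

# Number of days in each quarter (vectorized over labels).
quarter_ndays <- function(q) {
  idx <- quarter_index(q)
  as.integer(quarter_start_date(quarter_label(idx + 1L)) - quarter_start_date(q))
}

#' Parse a FAERS partial date string
#'
#' FAERS date fields hold `YYYYMMDD`, `YYYYMM`, or `YYYY` depending on how
#' much the reporter knew.  The precision is recorded and never imputed;
#' downstream stages decide whether a partial date is usable.
#'
#' @param x character vector of raw date fields.
#' @return data.frame with columns `date` (normalized digit string, `NA`
#'   when missing/invalid) and `precision` (`"day"`, `"month"`, `"year"`,
#'   `"missing"`).
#' @export
parse_partial_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  prec <- rep("missing", length(x))
  out <- rep(NA_character_, length(x))
  day <- grepl("^[0-9]{8}$", x)
  mon <- grepl("^[0-9]{6}$", x)
  yr <- grepl("^[0-9]{4}$", x)
  # a "day" string must be a real calendar date
  if (any(day)) {
    d <- as.Date(x[day], format = "%Y%m%d")
    ok <- !is.na(d)
    idx <- which(day)
    prec[idx[ok]] <- "day"
    out[idx[ok]] <- x[day][ok]
  }
  prec[mon] <- "month"
  out[mon] <- x[mon]
  prec[yr] <- "year"
  out[yr] <- x[yr]
  data.frame(date = out, precision = prec, stringsAsFactors = FALSE)
}

# Day-precision partial date -> Date (NA otherwise).
partial_date_to_date <- function(date, precision) {
  out <- rep(as.Date(NA), length(date))
  i <- which(precision == "day" & !is.na(date))
  if (length(i)) out[i] <- as.Date(date[i], format = "%Y%m%d")
  out
}

# FAERS age unit codes -> years.  DEC = decades; HR uses the mean
# Gregorian year of 8766 h.
.age_factors <- c(
  DEC = 10, YR = 1, MON = 1 / 12, WK = 7 / 365.25,
  DY = 1 / 365.25, HR = 1 / 8766
)

#' Convert FAERS age and weight fields to standard units
#'
#' @param age,age_cod raw age value and unit code (`DEC`, `YR`, `MON`,
#'   `WK`, `DY`, `HR`; empty/unknown codes give `NA`).
#' @param wt,wt_cod raw weight value and unit code (`KG`/`KGS` or
#'   `LBS`/`LB`/`POUNDS`).
#' @return numeric vector of years (`convert_age`) or kilograms
#'   (`convert_weight`); unparseable values become `NA`, never errors.
#' @examples
#' convert_age("6", "MON")        # 0.5
#' convert_weight("154", "LBS")   # 69.853...
#' @export
convert_age <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  f <- .age_factors[toupper(trimws(age_cod))]
  f[is.na(f) & !is.na(v)] <- 1  # bare number: assume years
  out <- v * unname(f)
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' @rdname convert_age
#' @export
convert_weight <- function(wt, wt_cod) {
  v <- suppressWarnings(as.numeric(wt))
  cod <- toupper(trimws(wt_cod))
  f <- ifelse(cod %in% c("LBS", "LB", "POUNDS"), 0.45359237,
    ifelse(cod %in% c("KG", "KGS", ""), 1, NA_real_)
  )
  f[is.na(cod)] <- 1
  out <- v * f
  out[!is.na(out) & out <= 0] <- NA_real_
  out
}

# stable utility: named list -> one "key=value" provenance detail string
kv_string <- function(...) {
  x <- c(...)
  paste(sprintf("%s=%s", names(x), as.character(x)), collapse = " ")
}
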