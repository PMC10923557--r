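#' Weighted dates
#'
#' Dates in digitised family reconstitution records carry a numeric
#' "weighting" code describing their precision or derivation (not a
#' statistical weight). A date token looks like \code{"15-7-1780"}, optionally
#' followed by a bracketed second date (\code{"15-7-1780 (21-6-1780)"}, e.g.
#' baptism with known birth date) and/or an asterisk-prefixed weighting
#' (\code{"0-7-1780*101"}, a date known only to the month). Day or month may
#' be recorded as 0 when unknown; \code{\link{normalize_date}} resolves these
#' to valid calendar dates while encoding the ambiguity into the weighting.
#'
#' @param day,month,year integer date parts as recorded (day 0--31,
#'   month 0--12, year > 0).
#' @param weighting optional non-negative integer precision code, or `NA`.
#' @param secondary optional nested `weighted_date`: the bracketed second
#'   date of a pair. A secondary date may not itself carry a secondary.
#' @return An object of class `weighted_date`.
#' @examples
#' weighted_date(0, 7, 1780, weighting = 101)
#' parse_weighted_date("15-7-1780 (21-6-1780)")
#' @export
weighted_date <- function(day, month, year, weighting = NA_integer_,
                          secondary = NULL) {
  day <- as.integer(day); month <- as.integer(month); year <- as.integer(year)
  if (is.na(year) || year <= 0L)
    stop("weighted_date: year must be a positive integer, got ", year)
  if (is.na(day) || day < 0L || day > 31L)
    stop("weighted_date: day must be in 0..31, got ", day)
  if (is.na(month) || month < 0L || month > 12L)
    stop("weighted_date: month must be in 0..12, got ", month)
  if (!is.na(weighting)) {
    weighting <- as.integer(weighting)
    if (weighting < 0L) stop("weighted_date: weighting must be non-negative")
  }
  if (!is.null(secondary)) {
    stopifnot(inherits(secondary, "weighted_date"))
    if (!is.null(secondary$secondary))
      stop("weighted_date: secondary date may not have a secondary of its own")
  }
  structure(list(day = day, month = month, year = year,
                 weighting = as.integer(weighting), secondary = secondary),
            class = "weighted_date")
}

#' @export
print.weighted_date <- function(x, ...) {
  cat("<weighted_date>", format_weighted_date(x), "\n")
  invisible(x)
}

#' @export
format.weighted_date <- function(x, ...) format_weighted_date(x)

#' @export
`==.weighted_date` <- function(e1, e2) {
  identical(unclass(e1), unclass(e2))
}

# single regex for "d-m-yyyy", optional " (d-m-yyyy)", optional "*w"
.wd_regex <- paste0(
  "^\\s*(\\d{1,2})-(\\d{1,2})-(\\d{1,4})",
  "(?:\\s*\\((\\d{1,2})-(\\d{1,2})-(\\d{1,4})\\))?",
  "(?:\\s*\\*(\\d+))?\\s*$"
)

# Vectorised parse of raw date tokens. Returns a data.frame with columns
# day, month, year, weighting, s_day, s_month, s_year (NA where absent) and
# ok (logical; FALSE = malformed). The missing marker "-" and "" give all-NA
# rows with ok = TRUE.
.parse_wd_vec <- function(tokens) {
  tokens <- as.character(tokens)
  n <- length(tokens)
  if (!n)
    return(data.frame(day = integer(), month = integer(), year = integer(),
                      weighting = integer(), s_day = integer(),
                      s_month = integer(), s_year = integer(),
                      ok = logical()))
  out <- data.frame(day = rep(NA_integer_, n), month = NA_integer_,
                    year = NA_integer_, weighting = NA_integer_,
                    s_day = NA_integer_, s_month = NA_integer_,
                    s_year = NA_integer_, ok = TRUE)
  trimmed <- trimws(tokens)
  absent <- trimmed == "-" | trimmed == "" | is.na(trimmed)
  todo <- which(!absent)
  if (!length(todo)) return(out)
  tt <- trimmed[todo]
  matched <- grepl(.wd_regex, tt)
  out$ok[todo[!matched]] <- FALSE
  hit <- todo[matched]
  tt <- tt[matched]
  grab <- function(ref) {
    v <- sub(.wd_regex, ref, tt)
    suppressWarnings(as.integer(v))  # empty optional group -> NA
  }
  out$day[hit] <- grab("\\1")
  out$month[hit] <- grab("\\2")
  out$year[hit] <- grab("\\3")
  out$s_day[hit] <- grab("\\4")
  out$s_month[hit] <- grab("\\5")
  out$s_year[hit] <- grab("\\6")
  out$weighting[hit] <- grab("\\7")
  out
}

#' Parse a raw FRF date token
#'
#' @param token a single raw date field, e.g. `"0-7-1780*101"`,
#'   `"15-7-1780 (21-6-1780)"`, or the missing marker `"-"`.
#' @return A `weighted_date`, or `NULL` when the token is the missing
#'   marker. Components are returned exactly as recorded: a 0 day or month
#'   is preserved at this stage.
#' @seealso [normalize_date()] for resolving 0 parts and impossible leap days.
#' @export
parse_weighted_date <- function(token) {
  stopifnot(length(token) == 1L)
  p <- .parse_wd_vec(token)
  if (!p$ok[1L])
    stop("malformed date token: ", sQuote(token))
  if (is.na(p$year[1L])) return(NULL)
  sec <- NULL
  if (!is.na(p$s_year[1L]))
    sec <- weighted_date(p$s_day[1L], p$s_month[1L], p$s_year[1L])
  weighted_date(p$day[1L], p$month[1L], p$year[1L], p$weighting[1L], sec)
}

#' Serialize a weighted date back to its token form
#'
#' Inverse of [parse_weighted_date()]: `d-m-yyyy`, with the secondary date in
#' brackets and the weighting after an asterisk.
#'
#' @param wd a `weighted_date`, or `NULL` for a missing date (gives `"-"`).
#' @return A single character token.
#' @export
format_weighted_date <- function(wd) {
  if (is.null(wd)) return("-")
  stopifnot(inherits(wd, "weighted_date"))
  s <- paste(wd$day, wd$month, wd$year, sep = "-")
  if (!is.null(wd$secondary))
    s <- paste0(s, " (", paste(wd$secondary$day, wd$secondary$month,
                               wd$secondary$year, sep = "-"), ")")
  if (!is.na(wd$weighting)) s <- paste0(s, "*", wd$weighting)
  s
}

#' Gregorian and Julian leap years
#'
#' @param year integer vector of calendar years.
#' @return Logical vector.
#' @keywords internal
is_gregorian_leap <- function(year) {
  (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
}

#' @rdname is_gregorian_leap
#' @keywords internal
is_julian_leap <- function(year) year %% 4L == 0L

.days_in_month_greg <- function(month, year) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- dm[month]
  d[month == 2L & is_gregorian_leap(year)] <- 29L
  d
}

# Vectorised normalization core. Inputs are integer vectors (day/month may be
# 0; weighting NA = absent). Returns a list of vectors day, month, year,
# weighting plus the component breakdown.
.normalize_dmyw <- function(day, month, year, weighting) {
  n <- length(day)
  if (any(is.na(year) | year <= 0L)) stop("normalize_date: year must be > 0")
  if (any(day > 31L | month > 12L | day < 0L | month < 0L))
    stop("normalize_date: day must be in 0..31 and month in 0..12")
  base <- ifelse(is.na(weighting), 0L, as.integer(weighting))
  add <- integer(n)

  day_zero <- day == 0L
  day[day_zero] <- 1L
  add <- add + 1000L * day_zero

  month_zero <- month == 0L
  month[month_zero] <- 1L
  add <- add + 2000L * month_zero

  # 29 February in a Gregorian non-leap year is impossible: move to 28
  # February; +3000 if the date was invalid in the Julian calendar too,
  # +4000 if it was a valid Julian date.
  bad_leap <- month == 2L & day == 29L & !is_gregorian_leap(year)
  add <- add + ifelse(bad_leap,
                      ifelse(is_julian_leap(year), 4000L, 3000L), 0L)
  day[bad_leap] <- 28L

  # remaining impossible day-of-month values (e.g. 31 April) are data errors
  over <- day > .days_in_month_greg(month, year)
  if (any(over))
    stop("normalize_date: impossible day of month at position ",
         which(over)[1L])

  w <- ifelse(base == 0L & add == 0L & is.na(weighting),
              NA_integer_, base + add)
  list(day = day, month = month, year = year, weighting = as.integer(w),
       base = base, day_ambiguous = day_zero, month_ambiguous = month_zero,
       leap_adjustment = ifelse(bad_leap,
                                ifelse(is_julian_leap(year), 4000L, 3000L),
                                0L))
}

#' Normalize a recorded date to a valid Gregorian calendar date
#'
#' Day and month parts recorded as 0 are changed to 1, and the weighting is
#' augmented by 1000 (day ambiguity) and/or 2000 (month ambiguity) so no
#' information is lost; base weighting codes are at most 3 digits, so the
#' offsets are decodable. Impossible leap-year dates of 29 February are
#' changed to 28 February with the weighting augmented by 3000 when the date
#' was also invalid in the Julian calendar (year not divisible by 4) or 4000
#' when it was valid in Julian. A date with no prior weighting and no
#' adjustment keeps an absent weighting. Normalization is idempotent. The
#' secondary date of a pair, when present, is normalized the same way.
#'
#' @param wd a `weighted_date` (or `NULL`, returned as `NULL`).
#' @return A `weighted_date` whose day/month are valid Gregorian values.
#' @examples
#' normalize_date(weighted_date(0, 7, 1780, 101))   # 1-7-1780, weighting 1101
#' normalize_date(weighted_date(29, 2, 1700))       # 28-2-1700, weighting 4000
#' @export
normalize_date <- function(wd) {
  if (is.null(wd)) return(NULL)
  stopifnot(inherits(wd, "weighted_date"))
  r <- .normalize_dmyw(wd$day, wd$month, wd$year, wd$weighting)
  sec <- if (!is.null(wd$secondary)) normalize_date(wd$secondary)
  weighted_date(r$day, r$month, r$year, r$weighting, sec)
}

#' Decompose a normalized weighting into its components
#'
#' A weighting produced by [normalize_date()] is base code (< 1000) plus a
#' subset of \{1000, 2000\} (day/month ambiguity) plus at most one of
#' \{3000, 4000\} (leap-day adjustment). The bare number 3000 + base is
#' ambiguous between day+month ambiguity and a Julian-invalid leap fix, but
#' the normalized date disambiguates: a leap adjustment always leaves the
#' date at 28 February of a non-leap year, whereas day/month ambiguity forces
#' the adjusted part to 1.
#'
#' @param weighting integer weighting (possibly `NA`) as stored after
#'   normalization.
#' @param day,month,year the normalized date parts the weighting is attached
#'   to.
#' @return A list with elements `base`, `day_ambiguous`, `month_ambiguous`,
#'   `leap_adjustment` (0, 3000 or 4000).
#' @export
decode_weighting <- function(weighting, day, month, year) {
  if (is.na(weighting))
    return(list(base = NA_integer_, day_ambiguous = FALSE,
                month_ambiguous = FALSE, leap_adjustment = 0L))
  w <- as.integer(weighting)
  base <- w %% 1000L
  hi <- w - base
  on_feb28_nonleap <- !is.na(day) && day == 28L && month == 2L &&
    !is_gregorian_leap(year)
  if (hi == 0L)
    comp <- c(FALSE, FALSE, 0L)
  else if (hi == 1000L)
    comp <- c(TRUE, FALSE, 0L)
  else if (hi == 2000L)
    comp <- c(FALSE, TRUE, 0L)
  else if (hi == 4000L)
    comp <- c(FALSE, FALSE, 4000L)
  else if (hi == 3000L) {
    if (on_feb28_nonleap) comp <- c(FALSE, FALSE, 3000L)
    else comp <- c(TRUE, TRUE, 0L)
  } else
    stop("decode_weighting: unrecognised weighting offset ", hi)
  list(base = base, day_ambiguous = as.logical(comp[1L]),
       month_ambiguous = as.logical(comp[2L]),
       leap_adjustment = as.integer(comp[3L]))
}

#' Convert a normalized weighted date to a base `Date`
#'
#' @param wd a normalized `weighted_date` (day/month must be valid), or
#'   `NULL`.
#' @return A `Date`, or `NA` for `NULL` input.
#' @export
wd_as_date <- function(wd) {
  if (is.null(wd)) return(as.Date(NA))
  as.Date(sprintf("%04d-%02d-%02d", wd$year, wd$month, wd$day))
}
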