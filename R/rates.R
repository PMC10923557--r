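#' Age-specific marital fertility rates from episodes
#'
#' Accumulates weighted person-years and weighted birth events per
#' (5-year age group x calendar period) cell and forms occurrence/exposure
#' rates (births per married-woman-year). Multiple births count as one
#' event upstream. Cells with zero person-years carry no rate (`NA`,
#' undefined — never 0). Margins over periods and over age groups are
#' attached.
#'
#' @param episodes an episode data.frame from [make_episodes()].
#' @return A data.frame of class `rate_table` with columns `age_group`,
#'   `period`, `person_years`, `births`, `rate`; age-group and period
#'   margins in attributes `"by_age"` and `"by_period"`.
#' @export
person_years_and_births <- function(episodes) {
  ep <- episodes
  if (nrow(ep) && (any(is.na(ep$age_group)) || any(is.na(ep$period))))
    stop("person_years_and_births: episodes with undefined age group or ",
         "period cell; extend the grids")
  cell <- function(keys) {
    if (!nrow(ep)) {
      out <- data.frame(person_years = numeric(), births = numeric())
      for (k in keys) out[[k]] <- character()
      return(out[c(keys, "person_years", "births")])
    }
    f <- interaction(ep[keys], drop = TRUE, sep = "\r")
    py <- tapply(ep$duration_years * ep$weight, f, sum)
    bt <- tapply(ep$event * ep$weight, f, sum)
    ks <- do.call(rbind, strsplit(names(py), "\r", fixed = TRUE))
    out <- data.frame(ks, person_years = as.numeric(py),
                      births = as.numeric(bt), stringsAsFactors = FALSE)
    names(out)[seq_along(keys)] <- keys
    out[do.call(order, out[keys]), , drop = FALSE]
  }
  tab <- cell(c("age_group", "period"))
  tab$rate <- ifelse(tab$person_years > 0, tab$births / tab$person_years,
                     NA_real_)
  by_age <- cell("age_group")
  by_age$rate <- ifelse(by_age$person_years > 0,
                        by_age$births / by_age$person_years, NA_real_)
  by_period <- cell("period")
  by_period$rate <- ifelse(by_period$person_years > 0,
                           by_period$births / by_period$person_years,
                           NA_real_)
  rownames(tab) <- rownames(by_age) <- rownames(by_period) <- NULL
  structure(tab, by_age = by_age, by_period = by_period,
            class = c("rate_table", class(tab)))
}

#' Age-group margin of a rate table
#' @param rate_table a [person_years_and_births()] result.
#' @return The age-group (or period) margin data.frame.
#' @export
rates_by_age <- function(rate_table) attr(rate_table, "by_age")

#' @rdname rates_by_age
#' @export
rates_by_period <- function(rate_table) attr(rate_table, "by_period")

#' Total marital fertility rate
#'
#' TMFR = 5 x the sum of age-group marital fertility rates over the stated
#' age range (default 20--49): the births a woman married throughout the
#' range would average at the observed rates.
#'
#' @param rate_table a [person_years_and_births()] result (the age margin
#'   is used).
#' @param age_lo,age_hi inclusive bounds of the age range.
#' @return A single number, or `NA` with a message when any age group in
#'   the range has an undefined rate.
#' @export
tmfr <- function(rate_table, age_lo = 20, age_hi = 49) {
  by_age <- rates_by_age(rate_table)
  lo <- seq(age_lo, age_hi, 5)
  wanted <- sprintf("%d-%d", lo, lo + 4)
  r <- by_age$rate[match(wanted, by_age$age_group)]
  if (anyNA(r)) {
    message("tmfr undefined: no person-years in age group(s) ",
            paste(wanted[is.na(r)], collapse = ", "))
    return(NA_real_)
  }
  5 * sum(r)
}

#' Compare rate tables across criteria sets
#'
#' Aligns the age profiles and period series of several criteria sets
#' computed on the same input, with ratio-to-reference columns. Cells
#' undefined in either member of a comparison stay `NA`.
#'
#' @param episode_sets named list of episode data.frames (one per criteria
#'   set); the first, or the one named `reference`, is the baseline.
#' @return A list with data.frames `age_profiles` and `period_series`.
#' @export
compare_criteria <- function(episode_sets) {
  stopifnot(is.list(episode_sets), length(episode_sets) >= 2L,
            !is.null(names(episode_sets)))
  ref_name <- if ("reference" %in% names(episode_sets)) "reference"
              else names(episode_sets)[1L]
  tabs <- lapply(episode_sets, person_years_and_births)
  ages <- sort(unique(unlist(lapply(tabs, function(t)
    rates_by_age(t)$age_group))))
  age_profiles <- data.frame(age_group = ages, stringsAsFactors = FALSE)
  for (nm in names(tabs)) {
    ba <- rates_by_age(tabs[[nm]])
    age_profiles[[nm]] <- ba$rate[match(ages, ba$age_group)]
  }
  for (nm in setdiff(names(tabs), ref_name))
    age_profiles[[paste0(nm, "_ratio")]] <-
      age_profiles[[nm]] / age_profiles[[ref_name]]

  periods <- sort(unique(unlist(lapply(tabs, function(t)
    rates_by_period(t)$period))))
  period_series <- data.frame(period = periods, stringsAsFactors = FALSE)
  for (nm in names(tabs)) {
    bp <- rates_by_period(tabs[[nm]])
    period_series[[nm]] <- bp$rate[match(periods, bp$period)]
  }
  for (nm in setdiff(names(tabs), ref_name))
    period_series[[paste0(nm, "_ratio")]] <-
      period_series[[nm]] / period_series[[ref_name]]
  list(age_profiles = age_profiles, period_series = period_series)
}

#' Inflate rates for multiple-birth share
#'
#' Because multiple births are collapsed to single events, the rates
#' understate births by the multiple-birth share (about 1.5% of all
#' births); for comparison with other sources they can be inflated by that
#' amount. Off by default everywhere; this is an explicit, separate step.
#'
#' @param rate_table a [person_years_and_births()] result.
#' @param multiple_birth_share share in \[0, 0.1\].
#' @return The rate table with rates (including margins) multiplied by
#'   `1 + multiple_birth_share`.
#' @export
inflate_for_multiplicity <- function(rate_table, multiple_birth_share) {
  if (!is.numeric(multiple_birth_share) || multiple_birth_share < 0 ||
      multiple_birth_share > 0.1)
    stop("multiple_birth_share must be in [0, 0.1]")
  f <- 1 + multiple_birth_share
  rate_table$rate <- rate_table$rate * f
  for (a in c("by_age", "by_period")) {
    m <- attr(rate_table, a)
    m$rate <- m$rate * f
    attr(rate_table, a) <- m
  }
  rate_table
}
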