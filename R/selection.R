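#' Assemble per-family analysis views from IDS tables
#'
#' Collects, for every union, the dates and estimations needed by the
#' family-selection rules: marriage date, the wife's birth (or proxy
#' baptism) date, both spouses' death (or proxy burial) dates, husband's
#' occupation presence, remarriage indicators, parish membership, and the
#' union's children with their birth-proxy dates. Remarriage is inferred
#' only from record links and dates (via harmonized IDs and the union
#' marriage-date order), never from the original widowhood flags.
#'
#' @param ids a harmonized `ids_tables` object.
#' @return A list with data.frames `families` (one row per union) and
#'   `children` (one row per child of a union).
#' @export
assemble_families <- function(ids) {
  stopifnot(inherits(ids, "ids_tables"))
  ctx <- ids$CONTEXT
  unions <- ctx[ctx$type == "Union", c("id_c", "date", "estimation")]
  names(unions) <- c("union", "marriage_date", "marriage_estimation")
  ic <- ids$INDIV_CONTEXT
  pd <- .person_dates(ids)
  ind <- ids$INDIVIDUAL

  role_of <- function(rel) {
    x <- ic[ic$relation == rel, c("id_i", "id_c")]
    x[!duplicated(x$id_c), ]
  }
  wiv <- role_of("Wife"); hus <- role_of("Husband")
  fam <- unions
  fam$wife_id <- wiv$id_i[match(fam$union, wiv$id_c)]
  fam$husband_id <- hus$id_i[match(fam$union, hus$id_c)]

  add_pd <- function(fam, who, id_col) {
    j <- match(fam[[id_col]], pd$id_i)
    fam[[paste0(who, "_birth")]] <- pd$birth_date[j]
    fam[[paste0(who, "_birth_estimation")]] <- pd$birth_estimation[j]
    fam[[paste0(who, "_death")]] <- pd$death_date[j]
    fam[[paste0(who, "_death_estimation")]] <- pd$death_estimation[j]
    fam
  }
  fam <- add_pd(fam, "wife", "wife_id")
  fam <- add_pd(fam, "husband", "husband_id")

  occ <- ind[ind$type == "OCCUPATION" & !is.na(ind$value), "id_i"]
  fam$husband_occupation <- fam$husband_id %in% occ

  ## remarriage: a spouse id appearing in several unions, ordered by
  ## marriage date (ties by union id) — every union after the first is a
  ## remarriage for that spouse
  spouse_rows <- rbind(
    data.frame(id = fam$wife_id, union = fam$union,
               date = fam$marriage_date, stringsAsFactors = FALSE),
    data.frame(id = fam$husband_id, union = fam$union,
               date = fam$marriage_date, stringsAsFactors = FALSE))
  spouse_rows <- spouse_rows[!is.na(spouse_rows$id), ]
  o <- order(spouse_rows$id, spouse_rows$date, spouse_rows$union,
             na.last = TRUE)
  spouse_rows <- spouse_rows[o, ]
  spouse_rows$remarriage <- duplicated(spouse_rows$id)
  key <- paste(spouse_rows$id, spouse_rows$union)
  fam$wife_remarriage <- spouse_rows$remarriage[
    match(paste(fam$wife_id, fam$union), key)]
  fam$husband_remarriage <- spouse_rows$remarriage[
    match(paste(fam$husband_id, fam$union), key)]
  fam$wife_remarriage[is.na(fam$wife_remarriage)] <- FALSE
  fam$husband_remarriage[is.na(fam$husband_remarriage)] <- FALSE

  cc <- ids$CONTEXT_CONTEXT
  pl <- cc[cc$relation == "Union in parish", ]
  fam$parish <- pl$id_c_2[match(fam$union, pl$id_c_1)]

  kids <- ic[ic$relation == "Child", c("id_i", "id_c")]
  names(kids) <- c("id_i", "union")
  j <- match(kids$id_i, pd$id_i)
  kids$birth_date <- pd$birth_date[j]
  kids$birth_estimation <- pd$birth_estimation[j]
  kids$death_date <- pd$death_date[j]
  fam$n_children <- as.integer(table(factor(kids$union,
                                            levels = fam$union)))
  rownames(fam) <- NULL
  list(families = fam, children = kids)
}

#' Family-selection criteria sets
#'
#' A criteria set is a named bundle of toggles reproducing the selection
#' rules used for marital fertility analysis. The reference set is the
#' conjunction: computable pre-requisites (wife's birth/baptism date and a
#' marriage date), the Henry requirement that the observation window end
#' with a spouse death (or the wife's 50th birthday, whichever comes
#' first), date-precision filters (month of marriage, wife's birth and
#' spouse death must not be estimated; children's birth months must be
#' known, with burial-derived dummy births allowed), first marriages for
#' both spouses, and the parish/period rules (quality years, sample groups,
#' parish weights). Alternative `henry_mode`s reproduce the variant
#' samples: `"ends_age_50"`, `"spouse_died_lt50"`, `"two_spouse_deaths"`,
#' and the diagnostic `"violating_child_end"` whose windows end at the last
#' child event — the informative-censoring violation.
#'
#' @param name label for reports.
#' @param require_wife_birthdate,require_marriage_date pre-requisites.
#' @param henry_mode one of `"reference"`, `"ends_age_50"`,
#'   `"spouse_died_lt50"`, `"two_spouse_deaths"`, `"violating_child_end"`,
#'   `"none"`.
#' @param precision_filter exclude families whose marriage, wife-birth or
#'   spouse-death month is estimated.
#' @param child_month_known exclude families with a child birth of
#'   month-level-or-worse estimation.
#' @param allow_dummy_births treat burial-derived dummy birth dates as
#'   precise enough (day-level) for inclusion.
#' @param first_marriage_only exclude widow/widower remarriages.
#' @param enforce_quality_years,enforce_sample_groups window must begin and
#'   end inside the parish's quality years / sample-group years.
#' @param require_husband_occupation keep only families with a recorded
#'   husband occupation.
#' @return A list of class `criteria_set`.
#' @export
criteria_set <- function(name = "custom",
                         require_wife_birthdate = TRUE,
                         require_marriage_date = TRUE,
                         henry_mode = c("reference", "ends_age_50",
                                        "spouse_died_lt50",
                                        "two_spouse_deaths",
                                        "violating_child_end", "none"),
                         precision_filter = TRUE,
                         child_month_known = TRUE,
                         allow_dummy_births = TRUE,
                         first_marriage_only = TRUE,
                         enforce_quality_years = TRUE,
                         enforce_sample_groups = TRUE,
                         require_husband_occupation = FALSE) {
  structure(list(
    name = name,
    require_wife_birthdate = require_wife_birthdate,
    require_marriage_date = require_marriage_date,
    henry_mode = match.arg(henry_mode),
    precision_filter = precision_filter,
    child_month_known = child_month_known,
    allow_dummy_births = allow_dummy_births,
    first_marriage_only = first_marriage_only,
    enforce_quality_years = enforce_quality_years,
    enforce_sample_groups = enforce_sample_groups,
    require_husband_occupation = require_husband_occupation),
    class = "criteria_set")
}

#' @rdname criteria_set
#' @export
reference_criteria <- function() criteria_set(name = "reference")

#' @rdname criteria_set
#' @export
violating_criteria <- function()
  criteria_set(name = "violating_child_end",
               henry_mode = "violating_child_end")

#' @rdname criteria_set
#' @export
ends_age_50_criteria <- function()
  criteria_set(name = "ends_age_50", henry_mode = "ends_age_50")

#' @rdname criteria_set
#' @export
spouse_died_lt50_criteria <- function()
  criteria_set(name = "spouse_died_lt50", henry_mode = "spouse_died_lt50")

#' @rdname criteria_set
#' @export
two_spouse_deaths_criteria <- function()
  criteria_set(name = "two_spouse_deaths", henry_mode = "two_spouse_deaths")

#' @rdname criteria_set
#' @export
occupation_criteria <- function()
  criteria_set(name = "occupation", require_husband_occupation = TRUE)

.month_known <- function(est) {
  est %in% c(.EST_EXACT, .EST_DD)
}

#' Apply a criteria set to assembled families
#'
#' Rules are applied as a conjunction; every family receives an ordered
#' list of exclusion-reason codes (empty = included) and, when a window is
#' computable, the observation window `[entry, exit)` with
#' `entry = max(marriage date, wife's 15th birthday)` and exit per the
#' Henry mode (reference: `min(first spouse death, wife's 50th birthday)`).
#' The result also carries a funnel report: families and person-years
#' surviving each rule stage cumulatively.
#'
#' @param families,children output of [assemble_families()].
#' @param criteria a [criteria_set()].
#' @param parish_meta a [parish_metadata()] object, or a named list of them
#'   keyed by parish code for multi-parish data.
#' @return A data.frame of class `selection_decisions`: `union`,
#'   `included`, `reasons` (ordered, `;`-separated), `entry`, `exit`,
#'   `weight`, with the funnel in attribute `"funnel"`.
#' @export
select_families <- function(families, children, criteria, parish_meta) {
  stopifnot(inherits(criteria, "criteria_set"))
  if (inherits(parish_meta, "parish_metadata"))
    parish_meta <- stats::setNames(list(parish_meta), parish_meta$code)
  fam <- families
  n <- nrow(fam)
  reasons <- vector("list", n)
  flag <- function(bad, code) {
    for (i in which(bad)) reasons[[i]] <<- c(reasons[[i]], code)
  }

  ## stage 1: pre-requisites
  if (criteria$require_wife_birthdate)
    flag(is.na(fam$wife_birth), "NO_WIFE_BIRTHDATE")
  if (criteria$require_marriage_date)
    flag(is.na(fam$marriage_date), "NO_MARRIAGE_DATE")
  stage1 <- lengths(reasons) == 0L

  ## stage 2: Henry requirements and observation window
  wife15 <- .age_boundary(fam$wife_birth, 15)
  wife50 <- .age_boundary(fam$wife_birth, 50)
  first_death <- as.Date(pmin(as.numeric(fam$wife_death),
                              as.numeric(fam$husband_death), na.rm = TRUE),
                         origin = "1970-01-01")
  has_death <- !is.na(fam$wife_death) | !is.na(fam$husband_death)
  entry <- as.Date(pmax(as.numeric(fam$marriage_date),
                        as.numeric(wife15)), origin = "1970-01-01")
  exit <- rep(as.Date(NA), n)
  mode <- criteria$henry_mode
  if (mode %in% c("reference", "ends_age_50", "spouse_died_lt50",
                  "two_spouse_deaths")) {
    flag(!has_death, "NO_SPOUSE_DEATH")
    exit <- as.Date(pmin(as.numeric(first_death), as.numeric(wife50)),
                    origin = "1970-01-01")
    if (mode == "ends_age_50")
      flag(has_death & first_death < wife50, "SPOUSE_DIED_BEFORE_50")
    if (mode == "spouse_died_lt50")
      flag(has_death & first_death >= wife50, "SPOUSE_SURVIVED_TO_50")
    if (mode == "two_spouse_deaths")
      flag(is.na(fam$wife_death) | is.na(fam$husband_death),
           "MISSING_SECOND_SPOUSE_DEATH")
  } else if (mode == "violating_child_end") {
    ## diagnostic complement: no spouse death; history ends with a child
    ## birth or a child death under age 15
    flag(has_death, "HAS_SPOUSE_DEATH")
    ch <- children
    u15 <- !is.na(ch$death_date) & !is.na(ch$birth_date) &
      as.numeric(ch$death_date - ch$birth_date) / 365.25 < 15
    ev <- c(ch$birth_date, ifelse(u15, ch$death_date, as.Date(NA)))
    evu <- c(ch$union, ch$union)
    keep <- !is.na(ev)
    last_ev <- rep(-Inf, n)
    if (any(keep)) {
      agg <- tapply(as.numeric(ev[keep]), evu[keep], max)
      j <- match(fam$union, names(agg))
      last_ev[!is.na(j)] <- agg[j[!is.na(j)]]
    }
    flag(!is.finite(last_ev), "NO_CHILD_END_EVENT")
    exit <- as.Date(pmin(ifelse(is.finite(last_ev), last_ev, NA),
                         as.numeric(wife50)), origin = "1970-01-01")
  } else {  # mode "none": observe to whatever endpoint exists
    exit <- as.Date(pmin(as.numeric(first_death), as.numeric(wife50),
                         na.rm = TRUE), origin = "1970-01-01")
  }
  flag(!is.na(entry) & !is.na(exit) & entry >= exit, "EMPTY_WINDOW")
  stage2 <- lengths(reasons) == 0L

  ## stage 3: precision of dates
  if (criteria$precision_filter) {
    flag(!.month_known(fam$marriage_estimation), "MARRIAGE_DATE_ESTIMATED")
    flag(!is.na(fam$wife_birth) &
           !.month_known(fam$wife_birth_estimation) &
           fam$wife_birth_estimation != .EST_DUMMY,
         "WIFE_BIRTHDATE_ESTIMATED")
    which_death_est <- ifelse(
      !is.na(fam$wife_death) & (is.na(fam$husband_death) |
                                  fam$wife_death <= fam$husband_death),
      fam$wife_death_estimation, fam$husband_death_estimation)
    flag(has_death & !.month_known(which_death_est),
         "SPOUSE_DEATH_ESTIMATED")
  }
  if (criteria$child_month_known) {
    ok_child <- .month_known(children$birth_estimation) |
      (criteria$allow_dummy_births &
         children$birth_estimation == .EST_DUMMY)
    bad_union <- unique(children$union[!is.na(children$birth_date) &
                                         !ok_child])
    flag(fam$union %in% bad_union, "CHILD_BIRTH_MONTH_ESTIMATED")
  }
  stage3 <- lengths(reasons) == 0L

  ## stage 4: marriage order
  if (criteria$first_marriage_only) {
    flag(fam$wife_remarriage, "WIFE_REMARRIAGE")
    flag(fam$husband_remarriage, "HUSBAND_REMARRIAGE")
  }
  stage4 <- lengths(reasons) == 0L

  ## stage 5: parish and period rules
  weight <- rep(1, n)
  meta <- parish_meta[fam$parish]
  missing_meta <- vapply(meta, is.null, TRUE)
  if (any(missing_meta & !is.na(fam$parish)))
    stop("select_families: no parish metadata for ",
         paste(unique(fam$parish[missing_meta]), collapse = ", "))
  weight <- vapply(meta, function(m)
    if (is.null(m)) 1 else m$fertility_weight, 1)
  flag(weight == 0, "PARISH_EXCLUDED")

  in_intervals <- function(year, iv) {
    ok <- rep(FALSE, length(year))
    for (k in seq_len(nrow(iv)))
      ok <- ok | (!is.na(year) & year >= iv$start[k] & year <= iv$end[k])
    ok
  }
  yr <- function(d) as.POSIXlt(d)$year + 1900L
  if (criteria$enforce_quality_years || criteria$enforce_sample_groups) {
    for (p in unique(fam$parish[!is.na(fam$parish)])) {
      m <- parish_meta[[p]]
      rows <- which(fam$parish == p & !is.na(entry) & !is.na(exit))
      if (!length(rows)) next
      if (criteria$enforce_quality_years) {
        ok <- in_intervals(yr(entry[rows]), m$quality_years) &
          in_intervals(yr(exit[rows]), m$quality_years)
        flag(seq_len(n) %in% rows[!ok], "OUTSIDE_QUALITY_YEARS")
      }
      if (criteria$enforce_sample_groups) {
        sg <- m$sample_groups
        ok <- in_intervals(yr(entry[rows]), sg) &
          in_intervals(yr(exit[rows]), sg)
        flag(seq_len(n) %in% rows[!ok], "OUTSIDE_SAMPLE_GROUPS")
      }
    }
  }
  if (criteria$require_husband_occupation)
    flag(!fam$husband_occupation, "NO_OCCUPATION")
  stage5 <- lengths(reasons) == 0L

  included <- lengths(reasons) == 0L
  decisions <- data.frame(
    union = fam$union,
    included = included,
    reasons = vapply(reasons, function(r)
      if (is.null(r)) "" else paste(r, collapse = ";"), ""),
    entry = entry, exit = exit, weight = weight,
    stringsAsFactors = FALSE)
  decisions$entry[!included] <- as.Date(NA)
  decisions$exit[!included] <- as.Date(NA)

  py <- function(keep) {
    ok <- keep & !is.na(entry) & !is.na(exit) & entry < exit
    sum(as.numeric(exit[ok] - entry[ok])) / 365.25
  }
  funnel <- data.frame(
    stage = c("all", "prerequisites", "henry_window", "date_precision",
              "marriage_order", "parish_period"),
    families = c(n, sum(stage1), sum(stage2), sum(stage3), sum(stage4),
                 sum(stage5)),
    person_years = c(py(rep(TRUE, n)), py(stage1), py(stage2), py(stage3),
                     py(stage4), py(stage5)))
  attr(decisions, "funnel") <- funnel
  attr(decisions, "criteria") <- criteria$name
  class(decisions) <- c("selection_decisions", class(decisions))
  decisions
}

#' Observation windows for episode construction
#'
#' Joins selection decisions back to the family view, keeping included
#' families only, in the column layout [make_episodes()] expects.
#'
#' @param families the [assemble_families()] `families` table.
#' @param decisions a [select_families()] result.
#' @return A windows data.frame (`id`, `union`, `birth_date`, `entry`,
#'   `exit`, `weight`, `parish`, `occupation`, `marriage_order`).
#' @export
selection_windows <- function(families, decisions) {
  d <- decisions[decisions$included, , drop = FALSE]
  j <- match(d$union, families$union)
  data.frame(
    id = families$wife_id[j],
    union = d$union,
    birth_date = families$wife_birth[j],
    entry = d$entry, exit = d$exit, weight = d$weight,
    parish = families$parish[j],
    occupation = families$husband_occupation[j],
    marriage_order = ifelse(families$wife_remarriage[j] |
                              families$husband_remarriage[j],
                            "remarriage", "first"),
    stringsAsFactors = FALSE)
}
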