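#' Collapse multiple births into single events
#'
#' Twins were often baptized at different times (weak infants were baptized
#' early, and birth-baptism delays grew in the 18th century), so all
#' baptisms of one union falling within 60 days are classified as a multiple
#' birth, and the fertility analysis treats a multiple birth as a single
#' event. Clustering is greedy left-to-right: a date joins the current
#' cluster when it falls within `window_days` of the cluster's first date,
#' and the event is placed at that earliest date.
#'
#' @param dates `Date` vector of a union's child birth(-proxy) dates.
#' @param window_days clustering window, default 60.
#' @return A list: `events` (Date vector of collapsed event dates),
#'   `sizes` (births per event), `n_collapsed` (births absorbed into
#'   earlier events).
#' @export
collapse_multiple_births <- function(dates, window_days = 60) {
  cl <- .collapse_numeric(as.numeric(dates), window_days)
  list(events = as.Date(cl$events, origin = "1970-01-01"),
       sizes = cl$sizes, n_collapsed = cl$n_collapsed)
}

.collapse_numeric <- function(dates, window_days = 60) {
  dates <- sort(dates[!is.na(dates)])
  n <- length(dates)
  if (!n) return(list(events = numeric(), sizes = integer(),
                      n_collapsed = 0L))
  starts <- numeric(n); sizes <- integer(n)
  k <- 1L; starts[1L] <- dates[1L]; sizes[1L] <- 1L
  for (j in seq_len(n - 1L) + 1L) {
    if (dates[j] - starts[k] <= window_days) {
      sizes[k] <- sizes[k] + 1L
    } else {
      k <- k + 1L
      starts[k] <- dates[j]
      sizes[k] <- 1L
    }
  }
  list(events = starts[seq_len(k)], sizes = sizes[seq_len(k)],
       n_collapsed = n - k)
}

#' Build the fertility chronicle from IDS tables
#'
#' The chronicle is a dated list of attribute changes per married woman, the
#' intermediate between IDS and episodes: marital status (single at birth,
#' married at each marriage, widowed at the spouse's death), parity
#' (incremented at each collapsed birth event), a lactation indicator
#' (opens at each birth, closes at the earlier of the newborn's death and a
#' configurable weaning horizon), and an indicator that the previous child
#' has died. Twin baptisms are collapsed to single events via
#' [collapse_multiple_births()] before parity is incremented. Same-day
#' conflicts are resolved by the fixed ordering birth < marriage < death
#' within a day; remaining duplicate (id, attribute, date) entries would
#' break episode construction and raise an error.
#'
#' @param ids a (preferably harmonized) `ids_tables` object.
#' @param weaning_months lactation horizon in months, default 24.
#' @param collapse_window_days multiple-birth window in days, default 60.
#' @return A data.frame of class `chronicle` with columns `id`, `union`,
#'   `attribute`, `value`, `date`, `is_event`.
#' @export
build_chronicle <- function(ids, weaning_months = 24,
                            collapse_window_days = 60) {
  stopifnot(inherits(ids, "ids_tables"))
  pd <- .person_dates(ids)
  pd_birth <- as.numeric(pd$birth_date)
  pd_death <- as.numeric(pd$death_date)
  ctx <- ids$CONTEXT
  unions <- ctx[ctx$type == "Union", c("id_c", "date")]
  union_date <- as.numeric(unions$date)
  ic <- ids$INDIV_CONTEXT
  wives <- ic[ic$relation == "Wife", ]
  husbands <- ic[ic$relation == "Husband", ]
  kid_rows <- ic$relation == "Child"
  kid_union <- ic$id_c[kid_rows]
  kid_birth <- pd_birth[match(ic$id_i[kid_rows], pd$id_i)]
  kid_death <- pd_death[match(ic$id_i[kid_rows], pd$id_i)]
  ksp_birth <- split(kid_birth, kid_union)
  ksp_death <- split(kid_death, kid_union)
  hus_of_union <- husbands$id_i[match(unions$id_c, husbands$id_c)]
  hus_death_of_union <- pd_death[match(hus_of_union, pd$id_i)]
  weaning_days <- round(weaning_months * 365.25 / 12)

  unions_of <- split(seq_len(nrow(wives)),
                     factor(wives$id_i, levels = unique(wives$id_i)))
  urow <- match(wives$id_c, unions$id_c)
  wife_birth <- pd_birth[match(wives$id_i, pd$id_i)]

  nW <- length(unions_of)
  col_id <- vector("list", nW); col_un <- vector("list", nW)
  col_at <- vector("list", nW); col_va <- vector("list", nW)
  col_dt <- vector("list", nW); col_ev <- vector("list", nW)
  widx <- 0L
  for (wi in seq_along(unions_of)) {
    rows <- unions_of[[wi]]
    w <- wives$id_i[rows[1L]]
    uns <- wives$id_c[rows]
    mdates <- union_date[urow[rows]]
    ord <- order(mdates, uns, na.last = TRUE)
    uns <- uns[ord]; mdates <- mdates[ord]
    hdd <- hus_death_of_union[urow[rows]][ord]

    a_id <- character(); a_un <- character(); a_at <- character()
    a_va <- character(); a_dt <- numeric(); a_ev <- logical()
    add <- function(un, at, va, dt, ev = FALSE) {
      a_id[length(a_id) + 1L] <<- w
      a_un[length(a_un) + 1L] <<- un
      a_at[length(a_at) + 1L] <<- at
      a_va[length(a_va) + 1L] <<- va
      a_dt[length(a_dt) + 1L] <<- dt
      a_ev[length(a_ev) + 1L] <<- ev
    }
    wb <- wife_birth[rows[1L]]
    if (!is.na(wb)) add(NA_character_, "marital_status", "single", wb)
    parity <- 0L
    for (u in seq_along(uns)) {
      un <- uns[u]; md <- mdates[u]
      if (!is.na(md)) add(un, "marital_status", "married", md)
      hd <- hdd[u]
      if (!is.na(hd)) add(un, "marital_status", "widowed", hd)

      kb <- ksp_birth[[un]]
      kd <- ksp_death[[un]]
      keep <- !is.na(kb)
      kb <- kb[keep]; kd <- kd[keep]
      cl <- .collapse_numeric(kb, collapse_window_days)
      if (u == 1L && parity == 0L && !is.na(md)) {
        add(un, "parity", "0", md)
        add(un, "lactation", "0", md)
        add(un, "prev_child_dead", "0", md)
      }
      for (e in seq_along(cl$events)) {
        ev <- cl$events[e]
        parity <- parity + 1L
        dths <- kd[kb >= ev & kb <= ev + collapse_window_days]
        dths <- dths[!is.na(dths)]
        first_death <- if (length(dths)) min(dths) else Inf
        next_ev <- if (e < length(cl$events)) cl$events[e + 1L] else Inf
        add(un, "birth", as.character(parity), ev, ev = TRUE)
        add(un, "parity", as.character(parity), ev)
        add(un, "lactation", "1", ev)
        add(un, "prev_child_dead", "0", ev)
        lact_end <- min(ev + weaning_days, first_death)
        if (lact_end < next_ev) add(un, "lactation", "0", lact_end)
        if (is.finite(first_death) && first_death < next_ev)
          add(un, "prev_child_dead", "1", first_death)
      }
    }
    widx <- widx + 1L
    col_id[[widx]] <- a_id; col_un[[widx]] <- a_un
    col_at[[widx]] <- a_at; col_va[[widx]] <- a_va
    col_dt[[widx]] <- a_dt; col_ev[[widx]] <- a_ev
  }
  chron <- data.frame(
    id = unlist(col_id) %||% character(),
    union = unlist(col_un) %||% character(),
    attribute = unlist(col_at) %||% character(),
    value = unlist(col_va) %||% character(),
    date = as.Date(unlist(col_dt) %||% numeric(), origin = "1970-01-01"),
    is_event = unlist(col_ev) %||% logical(),
    stringsAsFactors = FALSE)
  ## same-day duplicates: keep the last emitted entry per (id, attribute,
  ## date); emission order above encodes birth < marriage < death priority
  key <- paste(chron$id, chron$attribute, chron$date)
  dupev <- duplicated(paste(chron$id, chron$date)[chron$is_event])
  if (any(dupev))
    stop("build_chronicle: duplicate birth events on the same day for one ",
         "woman; collapse multiple births first")
  keep <- !duplicated(key, fromLast = TRUE) | chron$is_event
  chron <- chron[keep, , drop = FALSE]
  rownames(chron) <- NULL
  class(chron) <- c("chronicle", class(chron))
  chron
}

# exact date at which a person born on `birth` reaches age `a` years, under
# the age definition age(d) = (d - birth) / 365.25: the first day with
# age >= a
.age_boundary <- function(birth, a) birth + ceiling(a * 365.25)

.age_group_label <- function(age, breaks) {
  i <- findInterval(age + 1e-9, breaks)
  lab <- sprintf("%d-%d", breaks[-length(breaks)], breaks[-1L] - 1L)
  ifelse(i >= 1L & i < length(breaks), lab[i], NA_character_)
}

.period_label <- function(year, breaks) {
  i <- findInterval(year, breaks)
  lab <- sprintf("%d-%d", breaks[-length(breaks)], breaks[-1L] - 1L)
  ifelse(i >= 1L & i < length(breaks), lab[i], NA_character_)
}

#' Split observation windows into constant-covariate episodes
#'
#' Each woman's observation window is partitioned at every covariate change
#' recorded in the chronicle, every birthday crossing a 5-year age-group
#' bound, and every calendar-period bound, so that all covariates, the age
#' group, and the period are constant within an episode. Intervals are
#' half-open `[start, end)`; age is exact years (days/365.25) from the
#' birth-proxy date. An episode ends with `event = 1` exactly when its end
#' date is a collapsed birth event; all other terminal episodes are right
#' censored. A birth on the same day the window closes counts (passive
#' registration proves presence at the event). Zero-length segments are
#' dropped.
#'
#' @param chronicle a [build_chronicle()] result.
#' @param windows data.frame with one row per woman-union under
#'   observation: columns `id`, `union`, `birth_date` (the woman's),
#'   `entry`, `exit` (`Date`s, `entry < exit`), `weight`, plus any constant
#'   covariate columns to carry through (e.g. `parish`, `occupation`,
#'   `marriage_order`).
#' @param age_breaks 5-year age-group bounds, default `seq(15, 50, 5)`.
#' @param period_breaks calendar period bounds, default
#'   `seq(1575, 1900, 25)` (25-year bands).
#' @return A data.frame of episodes: start/end dates and exact ages,
#'   `age_group`, `period`, `parity`, `lactation`, `prev_child_dead`,
#'   carried covariates, `event`, `duration_years`, `weight`.
#' @export
make_episodes <- function(chronicle, windows,
                          age_breaks = seq(15L, 50L, 5L),
                          period_breaks = seq(1575L, 1900L, 25L)) {
  stopifnot(all(c("id", "union", "birth_date", "entry", "exit", "weight")
                %in% names(windows)))
  extra <- setdiff(names(windows),
                   c("id", "union", "birth_date", "entry", "exit", "weight"))
  period_days <- as.numeric(as.Date(sprintf("%04d-01-01", period_breaks)))

  ## pre-split the chronicle into per-woman numeric step functions
  chid <- chronicle$id
  chdt <- as.numeric(chronicle$date)
  o <- order(chid, chdt)
  chid <- chid[o]; chdt <- chdt[o]
  chat <- chronicle$attribute[o]
  chva <- chronicle$value[o]
  chev <- chronicle$is_event[o]
  per_id <- function(keep) split(which(keep), chid[keep])
  sp_par <- per_id(chat == "parity")
  sp_lac <- per_id(chat == "lactation")
  sp_pcd <- per_id(chat == "prev_child_dead")
  sp_all <- per_id(rep(TRUE, length(chid)))
  sp_ev <- per_id(chev)

  w_entry <- as.numeric(windows$entry)
  w_exit <- as.numeric(windows$exit)
  w_birth <- as.numeric(windows$birth_date)
  n <- nrow(windows)
  res_start <- vector("list", n); res_end <- vector("list", n)
  res_par <- vector("list", n); res_lac <- vector("list", n)
  res_pcd <- vector("list", n); res_ev <- vector("list", n)
  res_win <- vector("list", n)
  step_at <- function(rows, at) {
    if (is.null(rows)) return(rep(0L, length(at)))
    i <- findInterval(at, chdt[rows])
    ifelse(i == 0L, 0L, as.integer(chva[rows])[pmax(i, 1L)])
  }
  for (i in seq_len(n)) {
    if (is.na(w_entry[i]) || is.na(w_exit[i])) next
    if (w_entry[i] > w_exit[i])
      stop("make_episodes: window entry after exit for ", windows$id[i])
    if (w_entry[i] == w_exit[i]) next
    wid <- windows$id[i]
    rows <- sp_all[[wid]]
    chd <- if (is.null(rows)) numeric() else chdt[rows]
    cuts <- c(w_entry[i], w_exit[i],
              chd[chd > w_entry[i] & chd < w_exit[i]],
              .age_boundary(w_birth[i], age_breaks),
              period_days)
    cuts <- sort(unique(cuts[cuts >= w_entry[i] & cuts <= w_exit[i]]))
    if (length(cuts) < 2L) next
    starts <- cuts[-length(cuts)]
    ends <- cuts[-1L]
    evd <- sp_ev[[wid]]
    evd <- if (is.null(evd)) numeric() else chdt[evd]
    res_start[[i]] <- starts
    res_end[[i]] <- ends
    res_par[[i]] <- step_at(sp_par[[wid]], starts)
    res_lac[[i]] <- step_at(sp_lac[[wid]], starts)
    res_pcd[[i]] <- step_at(sp_pcd[[wid]], starts)
    res_ev[[i]] <- as.integer(ends %in% evd)
    res_win[[i]] <- rep.int(i, length(starts))
  }
  widx <- unlist(res_win)
  if (is.null(widx)) widx <- integer()
  starts <- unlist(res_start) %||% numeric()
  ends <- unlist(res_end) %||% numeric()
  start_age <- (starts - w_birth[widx]) / 365.25
  end_age <- (ends - w_birth[widx]) / 365.25
  eps <- data.frame(
    id = windows$id[widx],
    union = windows$union[widx],
    start = as.Date(starts, origin = "1970-01-01"),
    end = as.Date(ends, origin = "1970-01-01"),
    start_age = start_age, end_age = end_age,
    age_group = .age_group_label(start_age, age_breaks),
    period = .period_label(as.POSIXlt(
      as.Date(starts, origin = "1970-01-01"))$year + 1900L, period_breaks),
    parity = unlist(res_par) %||% integer(),
    lactation = unlist(res_lac) %||% integer(),
    prev_child_dead = unlist(res_pcd) %||% integer(),
    event = unlist(res_ev) %||% integer(),
    duration_years = (ends - starts) / 365.25,
    weight = windows$weight[widx],
    stringsAsFactors = FALSE)
  for (nm in extra) eps[[nm]] <- windows[[nm]][widx]
  rownames(eps) <- NULL
  eps
}
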