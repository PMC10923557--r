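#' Configuration for the synthetic parish register simulator
#'
#' The simulator emulates the statistical structure family-reconstitution
#' analysis assumes: marriage formation with a wife age-at-marriage
#' distribution, fecundability-driven birth intervals with a postpartum
#' non-susceptible period (shortened when the infant dies), stillbirths and
#' twins, infant and adult mortality, couple out-migration (which truncates
#' registration but not the demographic process), baptism and burial
#' delays, and under-registration. Widowed spouses may remarry in the
#' parish, and surviving daughters may marry in the parish, creating the
#' cross-family record links that ID harmonization consumes. All
#' probabilities are per event, hazards per year, and fecundability per
#' month, as in the demographic literature.
#'
#' @param n_couples number of base couples.
#' @param window registration window, `c(first_year, last_year)`; must span
#'   at least 50 years.
#' @param wife_marriage_age_mean,wife_marriage_age_sd wife age-at-marriage
#'   distribution (normal, truncated to `wife_marriage_age_range`).
#' @param wife_marriage_age_range truncation bounds, default 15--45.
#' @param fecundability_base monthly conception probability at young ages.
#' @param fecundability_decline_start age from which fecundability declines
#'   linearly.
#' @param fecundability_zero_age age at which fecundability reaches 0.
#' @param gestation_months gestation length in months.
#' @param nonsusceptible_months postpartum non-susceptible period.
#' @param nonsusceptible_after_infant_death_months residual non-susceptible
#'   period after the nursling dies (lactation interrupted).
#' @param stillbirth_prob probability a baby is stillborn.
#' @param twin_prob probability a birth event is a twin birth.
#' @param infant_death_prob probability a live-born child dies in the first
#'   year.
#' @param child_death_prob probability a child surviving infancy dies
#'   before age 15 (death age uniform over 1--15 years).
#' @param adult_mortality_hazard spouse death hazard per year from marriage.
#' @param migration_hazard couple out-migration hazard per year.
#' @param baptism_delay_mean_days mean birth-to-baptism delay (Poisson),
#'   with a `baptism_delay_long_prob` chance of an extra uniform 30--90 day
#'   delay so the 60-day multiple-birth collapsing is exercised.
#' @param baptism_delay_long_prob see above.
#' @param burial_delay_days death-to-burial delay.
#' @param under_registration_prob probability any single event goes
#'   unrecorded.
#' @param remarriage_prob probability a widowed spouse remarries in the
#'   parish.
#' @param wife_baptism_recorded_prob probability a base-couple wife born
#'   inside the window has a findable baptism.
#' @param daughter_marriage_prob probability a surviving daughter marries
#'   in the parish.
#' @param marriage_year_only_prob probability a marriage date is recorded
#'   to the year only (exercises the date-precision filters).
#' @param occupation_prob probability the husband's occupation is recorded.
#' @param parish,parish_code parish name and code for the output.
#' @param seed integer seed governing all randomness.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_couples = 500L,
                         window = c(1580L, 1837L),
                         wife_marriage_age_mean = 24,
                         wife_marriage_age_sd = 5,
                         wife_marriage_age_range = c(15, 45),
                         fecundability_base = 0.12,
                         fecundability_decline_start = 24,
                         fecundability_zero_age = 47,
                         gestation_months = 9,
                         nonsusceptible_months = 12,
                         nonsusceptible_after_infant_death_months = 2,
                         stillbirth_prob = 0.02,
                         twin_prob = 0.015,
                         infant_death_prob = 0.15,
                         child_death_prob = 0.08,
                         adult_mortality_hazard = 0.02,
                         migration_hazard = 0.05,
                         baptism_delay_mean_days = 7,
                         baptism_delay_long_prob = 0.05,
                         burial_delay_days = 2,
                         under_registration_prob = 0.03,
                         remarriage_prob = 0.3,
                         wife_baptism_recorded_prob = 0.9,
                         daughter_marriage_prob = 0.25,
                         marriage_year_only_prob = 0.03,
                         occupation_prob = 0.5,
                         parish = "Simfield",
                         parish_code = "SIM",
                         seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$stillbirth_prob, cfg$twin_prob, cfg$infant_death_prob,
             cfg$child_death_prob,
             cfg$under_registration_prob, cfg$remarriage_prob,
             cfg$wife_baptism_recorded_prob, cfg$daughter_marriage_prob,
             cfg$marriage_year_only_prob, cfg$occupation_prob,
             cfg$baptism_delay_long_prob)
  if (any(probs < 0 | probs > 1))
    stop("synth_config: probabilities must be in [0, 1]")
  if (cfg$adult_mortality_hazard < 0 || cfg$migration_hazard < 0)
    stop("synth_config: hazards must be >= 0")
  if (diff(window) < 50)
    stop("synth_config: registration window must span at least 50 years")
  structure(cfg, class = "synth_config")
}

.MONTH_DAYS <- 365.25 / 12

.fecundability <- function(age, cfg) {
  f <- rep(cfg$fecundability_base, length(age))
  d <- age > cfg$fecundability_decline_start
  f[d] <- cfg$fecundability_base *
    pmax(0, (cfg$fecundability_zero_age - age[d]) /
           (cfg$fecundability_zero_age - cfg$fecundability_decline_start))
  f
}

.rtnorm <- function(n, mean, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

.rexp_or_inf <- function(n, hazard) {
  if (hazard <= 0) rep(Inf, n) else stats::rexp(n, hazard)
}

# Vectorised monthly birth-process engine. `st` has one row per union with
# numeric-day columns wife_birth, marriage, wife_death, husband_death
# (Inf = never within horizon). Returns the complete (ground-truth) birth
# events and babies: registration is applied later.
.sim_engine <- function(st, cfg) {
  n <- nrow(st)
  st_marriage <- st$marriage
  st_wife_birth <- st$wife_birth
  st_wife_death <- st$wife_death
  st_husband_death <- st$husband_death
  empty <- list(
    events = data.frame(union_row = integer(), date = numeric()),
    babies = data.frame(union_row = integer(), event = integer(),
                        birth = numeric(), sex = character(),
                        stillborn = logical(), death = numeric(),
                        posthumous = logical(), stringsAsFactors = FALSE))
  if (!n) return(empty)
  next_ok <- rep(0, n)
  max_m <- ceiling(36 * 12)
  ev_u <- list(); ev_d <- list()
  bb <- list()
  n_events <- 0L
  for (m in 0:max_m) {
    date_m <- st_marriage + m * .MONTH_DAYS
    age <- (date_m - st_wife_birth) / 365.25
    if (all(age >= 49.3)) break
    active <- date_m < st_wife_death & date_m < st_husband_death &
      age < 49.3
    cand <- which(active & m >= next_ok)
    if (!length(cand)) next
    f <- .fecundability(age[cand], cfg)
    conc <- cand[stats::runif(length(cand)) < f]
    if (!length(conc)) next
    birth <- date_m[conc] + cfg$gestation_months * .MONTH_DAYS +
      floor(stats::runif(length(conc), 0, .MONTH_DAYS))
    ok <- birth < st_wife_death[conc]
    ## conception blocks further conception regardless of outcome
    born <- conc[ok]; birth <- birth[ok]
    k <- length(born)
    min_dd <- rep(Inf, length(conc))
    if (k) {
      ev_base <- n_events
      twin <- stats::runif(k) < cfg$twin_prob
      nb <- 1L + twin
      bu <- rep(born, nb)
      bev <- rep(ev_base + seq_len(k), nb)
      bbirth <- rep(birth, nb)
      nb_tot <- length(bu)
      sexes <- c("m", "f")[1L + (stats::runif(nb_tot) < 0.5)]
      still <- stats::runif(nb_tot) < cfg$stillbirth_prob
      idie <- !still & stats::runif(nb_tot) < cfg$infant_death_prob
      cdie <- !still & !idie &
        stats::runif(nb_tot) < cfg$child_death_prob
      dd <- rep(NA_real_, nb_tot)
      dd[still] <- 0
      dd[idie] <- floor(stats::runif(sum(idie), 0, 365))
      dd[cdie] <- floor(stats::runif(sum(cdie), 365, 15 * 365.25))
      death <- bbirth + dd
      post <- bbirth > st_husband_death[bu]
      ev_u[[length(ev_u) + 1L]] <- born
      ev_d[[length(ev_d) + 1L]] <- birth
      bb[[length(bb) + 1L]] <- data.frame(
        union_row = bu, event = bev, birth = bbirth, sex = sexes,
        stillborn = still, death = death, posthumous = post,
        stringsAsFactors = FALSE)
      n_events <- ev_base + k
      ## earliest baby death per event shortens the non-susceptible period
      first_dd <- tapply(ifelse(is.na(dd), Inf, dd), bev, min)
      min_dd[match(born, conc)] <-
        as.numeric(first_dd[as.character(ev_base + seq_len(k))])
    }
    ns <- rep(cfg$nonsusceptible_months, length(conc))
    short <- is.finite(min_dd) &
      min_dd < cfg$nonsusceptible_months * .MONTH_DAYS
    ns[short] <- ceiling(min_dd[short] / .MONTH_DAYS) +
      cfg$nonsusceptible_after_infant_death_months
    next_ok[conc] <- m + cfg$gestation_months + 1 + ns
  }
  if (!length(ev_u)) return(empty)
  list(events = data.frame(union_row = unlist(ev_u),
                           date = unlist(ev_d)),
       babies = do.call(rbind, bb))
}

# attribute a person's burial to their latest union begun before the death
.attribute_burial <- function(key, marriage, death) {
  n <- length(key)
  here <- rep(FALSE, n)
  ok <- is.finite(death) & marriage < death
  sp <- split(seq_len(n)[ok], key[ok])
  for (ix in sp) here[ix[which.max(marriage[ix])]] <- TRUE
  here
}

# proleptic-Gregorian civil date from days-since-epoch, pure arithmetic
# (called per token during register emission; POSIXlt is far too slow here)
.num_date_parts <- function(d) {
  z <- as.integer(floor(d)) + 719468L
  era <- (z - ifelse(z < 0L, 146096L, 0L)) %/% 146097L
  doe <- z - era * 146097L
  yoe <- (doe - doe %/% 1460L + doe %/% 36524L - doe %/% 146096L) %/% 365L
  y <- yoe + era * 400L
  doy <- doe - (365L * yoe + yoe %/% 4L - yoe %/% 100L)
  mp <- (5L * doy + 2L) %/% 153L
  day <- doy - (153L * mp + 2L) %/% 5L + 1L
  month <- mp + ifelse(mp < 10L, 3L, -9L)
  list(day = day, month = month, year = y + (month <= 2L))
}

# date token from numeric days; precision one of "exact", "month_only"
# (day 0, weighting 101), "year_only" (day and month 0); optional paired
# secondary date and weighting override
.date_token <- function(d, precision = "exact", secondary = NULL,
                        weighting = NULL) {
  if (!is.finite(d)) return("-")
  p <- .num_date_parts(d)
  tok <- switch(precision,
    exact = sprintf("%d-%d-%d", p$day, p$month, p$year),
    month_only = sprintf("0-%d-%d", p$month, p$year),
    year_only = sprintf("0-0-%d", p$year))
  if (!is.null(secondary) && is.finite(secondary)) {
    s <- .num_date_parts(secondary)
    tok <- paste0(tok, " (", sprintf("%d-%d-%d", s$day, s$month, s$year),
                  ")")
  }
  if (precision == "month_only") tok <- paste0(tok, "*101")
  if (!is.null(weighting)) tok <- paste0(tok, "*", weighting)
  tok
}

#' Simulate a synthetic parish register with known ground truth
#'
#' Runs the demographic process (three waves: base couples, remarriages of
#' widowed spouses, marriages of surviving daughters), then applies passive
#' registration: events are recorded only while the couple is in the parish
#' (before out-migration), inside the registration window, and surviving an
#' under-registration coin. The complete event log is returned as ground
#' truth, unaffected by registration. The register is serialized through
#' the FRF text format, including cross-family links (remarriage
#' earlier/later-FRF, daughters' own-first-marriage), stillbirth/twin/
#' posthumous flags, paired burial(death) dates, burial-only children
#' (dummy-birth candidates), and date-precision noise — so every pipeline
#' stage is exercised.
#'
#' @param config a [synth_config()].
#' @return A list of class `synth_parish`: `text` (FRF lines), `truth`
#'   (complete `unions`, `events`, `babies` data.frames), `parish_meta`,
#'   `config`.
#' @export
simulate_parish <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  w0 <- as.numeric(as.Date(sprintf("%d-01-01", cfg$window[1])))
  w1 <- as.numeric(as.Date(sprintf("%d-12-31", cfg$window[2])))
  hz <- cfg$adult_mortality_hazard
  mig_hz <- cfg$migration_hazard

  ## wave 1: base couples
  n <- cfg$n_couples
  marriage <- floor(stats::runif(n, w0, w1 - 60 * 365.25))
  wage <- .rtnorm(n, cfg$wife_marriage_age_mean, cfg$wife_marriage_age_sd,
                  cfg$wife_marriage_age_range[1],
                  cfg$wife_marriage_age_range[2])
  u1 <- data.frame(
    frf = seq_len(n), wave = 1L,
    wife_key = sprintf("P%05dW", seq_len(n)),
    husband_key = sprintf("P%05dH", seq_len(n)),
    wife_birth = round(marriage - wage * 365.25),
    marriage = marriage,
    wife_death = marriage + .rexp_or_inf(n, hz) * 365.25,
    husband_death = marriage + .rexp_or_inf(n, hz) * 365.25,
    migration = marriage + .rexp_or_inf(n, mig_hz) * 365.25,
    pred_frf = NA_integer_, pred_role = NA_character_,
    origin_frf = NA_integer_, origin_baby = NA_integer_,
    stringsAsFactors = FALSE)
  r1 <- .sim_engine(u1, cfg)

  ## wave 2: remarriage of widowed spouses
  make_wave2 <- function(widow) {
    first_death <- if (widow) u1$husband_death else u1$wife_death
    other_death <- if (widow) u1$wife_death else u1$husband_death
    cand <- which(is.finite(first_death) & first_death < other_death &
                    stats::runif(n) < cfg$remarriage_prob)
    if (!length(cand)) return(NULL)
    gap <- round((0.5 + stats::rexp(length(cand), 1 / 1.5)) * 365.25)
    nm <- floor(first_death[cand]) + gap
    lim <- pmin(other_death[cand], w1 - 365.25,
                if (widow) u1$wife_birth[cand] + 48 * 365.25 else Inf)
    keep <- nm < lim
    cand <- cand[keep]; nm <- nm[keep]
    k <- length(cand)
    if (!k) return(NULL)
    if (widow) {
      wb <- u1$wife_birth[cand]
      wk <- u1$wife_key[cand]
      wd <- u1$wife_death[cand]
      hk <- sprintf("R%05dH", cand)
      hd <- nm + .rexp_or_inf(k, hz) * 365.25
    } else {
      nwage <- .rtnorm(k, 26, 4, 18, 40)
      wb <- round(nm - nwage * 365.25)
      wk <- sprintf("R%05dW", cand)
      wd <- nm + .rexp_or_inf(k, hz) * 365.25
      hk <- u1$husband_key[cand]
      hd <- u1$husband_death[cand]
    }
    data.frame(
      frf = NA_integer_, wave = 2L, wife_key = wk, husband_key = hk,
      wife_birth = wb, marriage = nm, wife_death = wd, husband_death = hd,
      migration = nm + .rexp_or_inf(k, mig_hz) * 365.25,
      pred_frf = cand, pred_role = if (widow) "W" else "H",
      origin_frf = NA_integer_, origin_baby = NA_integer_,
      stringsAsFactors = FALSE)
  }
  u2 <- rbind(make_wave2(TRUE), make_wave2(FALSE))
  if (!is.null(u2) && nrow(u2)) {
    u2$frf <- n + seq_len(nrow(u2))
    r2 <- .sim_engine(u2, cfg)
  } else {
    u2 <- u1[0, ]
    r2 <- .sim_engine(u2, cfg)
  }

  ## collect babies of waves 1-2 with global ids and union frfs
  glue_babies <- function(res, uns) {
    b <- res$babies
    if (!nrow(b)) return(cbind(b, frf = integer()))
    b$frf <- uns$frf[b$union_row]
    b
  }
  b12 <- rbind(glue_babies(r1, u1), glue_babies(r2, u2))
  if (nrow(b12)) b12$baby_id <- seq_len(nrow(b12))

  ## wave 3: marriages of surviving daughters
  u3 <- u1[0, ]
  if (nrow(b12)) {
    girls <- which(b12$sex == "f" & !b12$stillborn & !is.finite(b12$death) &
                     stats::runif(nrow(b12)) < cfg$daughter_marriage_prob)
    if (length(girls)) {
      dage <- .rtnorm(length(girls), 25, 4, 18, 38)
      dm <- round(b12$birth[girls] + dage * 365.25)
      keep <- dm > w0 & dm < w1 - 365.25
      girls <- girls[keep]; dm <- dm[keep]
      k <- length(girls)
      if (k) {
        u3 <- data.frame(
          frf = NA_integer_, wave = 3L,
          wife_key = sprintf("B%06d", b12$baby_id[girls]),
          husband_key = sprintf("D%06dH", b12$baby_id[girls]),
          wife_birth = b12$birth[girls], marriage = dm,
          wife_death = dm + .rexp_or_inf(k, hz) * 365.25,
          husband_death = dm + .rexp_or_inf(k, hz) * 365.25,
          migration = dm + .rexp_or_inf(k, mig_hz) * 365.25,
          pred_frf = NA_integer_, pred_role = NA_character_,
          origin_frf = b12$frf[girls], origin_baby = b12$baby_id[girls],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (nrow(u3)) {
    u3$frf <- max(u1$frf, u2$frf, 0L) + seq_len(nrow(u3))
    r3 <- .sim_engine(u3, cfg)
  } else r3 <- .sim_engine(u3, cfg)

  unions <- rbind(u1, u2, u3)
  b3 <- glue_babies(r3, u3)
  if (nrow(b3)) b3$baby_id <- nrow(b12) + seq_len(nrow(b3))
  babies <- rbind(b12, b3)
  ev <- rbind(
    data.frame(frf = u1$frf[r1$events$union_row], date = r1$events$date),
    data.frame(frf = u2$frf[r2$events$union_row], date = r2$events$date),
    data.frame(frf = u3$frf[r3$events$union_row], date = r3$events$date))

  text <- .emit_frf(unions, babies, cfg, w0, w1)

  truth <- list(
    unions = transform(unions,
      wife_birth = as.Date(wife_birth, origin = "1970-01-01"),
      marriage = as.Date(marriage, origin = "1970-01-01")),
    events = data.frame(frf = ev$frf,
                        date = as.Date(ev$date, origin = "1970-01-01")),
    babies = babies)
  pmeta <- parish_metadata(cfg$parish, cfg$parish_code,
                           county = "Simshire",
                           quality_years = data.frame(
                             start = cfg$window[1], end = cfg$window[2]),
                           sample_groups = data.frame(
                             group = 1L, start = cfg$window[1],
                             end = cfg$window[2]))
  structure(list(text = text, truth = truth, parish_meta = pmeta,
                 config = cfg),
            class = "synth_parish")
}

.tok_int <- function(x) ifelse(is.na(x), "-", as.character(x))

# Passive registration + FRF serialization: events are registered only
# before the couple's out-migration, inside the window, and surviving the
# under-registration coin. Returns the FRF text lines of the register.
.emit_frf <- function(unions, babies, cfg, w0, w1) {
  U <- unions
  nU <- nrow(U)
  if (!nU) return(character())
  row_of_frf <- match(seq_len(max(U$frf)), U$frf)
  ur <- cfg$under_registration_prob
  reg_ok <- function(d, mig) {
    ok <- !is.na(d) & is.finite(d) & d >= w0 & d <= w1 & d <= mig
    ok & stats::runif(length(d)) >= ur
  }

  ## which unions appear in the register at all: a remarriage or daughter
  ## marriage formed after the predecessor family migrated happened
  ## elsewhere
  emitted <- rep(TRUE, nU)
  w2 <- which(U$wave == 2L)
  if (length(w2)) {
    predrow <- row_of_frf[U$pred_frf[w2]]
    emitted[w2] <- U$migration[predrow] > U$marriage[w2]
  }
  w3 <- which(U$wave == 3L)
  if (length(w3)) {
    orow <- row_of_frf[U$origin_frf[w3]]
    emitted[w3] <- U$migration[orow] > U$marriage[w3]
  }

  ## children: baptism (unless stillborn or dead first) and burial
  B <- babies
  nB <- nrow(B)
  if (nB) {
    B$mig <- U$migration[row_of_frf[B$frf]]
    delay <- stats::rpois(nB, cfg$baptism_delay_mean_days) +
      ifelse(stats::runif(nB) < cfg$baptism_delay_long_prob,
             floor(stats::runif(nB, 30, 91)), 0)
    B$bap_date <- ifelse(B$stillborn, NA_real_, B$birth + delay)
    died_first <- !is.na(B$bap_date) & is.finite(B$death) &
      B$death < B$bap_date
    B$bap_date[died_first] <- NA_real_
    B$bap_reg <- reg_ok(B$bap_date, B$mig)
    B$burial_date <- ifelse(is.finite(B$death),
                            B$death + cfg$burial_delay_days, NA_real_)
    B$bur_reg <- reg_ok(B$burial_date, B$mig)
    B$present <- (B$bap_reg | B$bur_reg) & emitted[row_of_frf[B$frf]]
    evkey <- paste(B$frf, B$event)
    B$twin <- duplicated(evkey) | duplicated(evkey, fromLast = TRUE)
    B$marriage_tok <- "-"
    B$own_frf <- NA_integer_
  }

  ## wife baptism tokens, one per woman (a remarried widow shows the same
  ## baptism on both of her W lines)
  wkeys <- unique(U$wife_key)
  wrow1 <- match(wkeys, U$wife_key)
  wb <- U$wife_birth[wrow1]
  is_daughter <- U$wave[wrow1] == 3L
  bap_tok <- rep("-", length(wkeys))
  nd <- which(!is_daughter)
  if (length(nd)) {
    rec <- stats::runif(length(nd)) < cfg$wife_baptism_recorded_prob &
      wb[nd] >= w0
    bapd <- wb[nd] + stats::rpois(length(nd), cfg$baptism_delay_mean_days)
    yo <- stats::runif(length(nd)) < cfg$marriage_year_only_prob
    for (j in seq_along(nd)) {
      if (!rec[j]) next
      bap_tok[nd[j]] <- .date_token(bapd[j],
                                    if (yo[j]) "year_only" else "exact")
    }
  }
  dts <- which(is_daughter)
  if (nB && length(dts)) {
    brow <- match(U$origin_baby[wrow1[dts]], B$baby_id)
    for (j in seq_along(dts)) {
      b <- brow[j]
      if (!is.na(b) && B$present[b] && B$bap_reg[b])
        bap_tok[dts[j]] <- .date_token(B$bap_date[b])
    }
  }
  names(bap_tok) <- wkeys

  ## spouse burials, attributed to the union in progress at death
  w_here <- .attribute_burial(U$wife_key, U$marriage, U$wife_death)
  h_here <- .attribute_burial(U$husband_key, U$marriage, U$husband_death)
  wbur_tok <- rep("-", nU)
  hbur_tok <- rep("-", nU)
  spouse_burial <- function(rows, death) {
    toks <- rep("-", nU)
    if (!length(rows)) return(toks)
    bd <- death[rows] + cfg$burial_delay_days
    okr <- reg_ok(bd, U$migration[rows])
    paired <- stats::runif(length(rows)) < 0.5
    for (j in seq_along(rows)) {
      if (!okr[j]) next
      toks[rows[j]] <- .date_token(
        bd[j], secondary = if (paired[j]) death[rows[j]])
    }
    toks
  }
  wbur_tok <- spouse_burial(which(w_here & emitted), U$wife_death)
  hbur_tok <- spouse_burial(which(h_here & emitted), U$husband_death)

  ## cross-family links; an unregistered spouse burial followed by an
  ## in-parish remarriage is proxied by the remarriage date (weighting 150,
  ## "before this date")
  w_earlier <- w_later <- h_earlier <- h_later <- rep(NA_integer_, nU)
  for (i in which(U$wave == 2L & emitted)) {
    p <- row_of_frf[U$pred_frf[i]]
    if (U$pred_role[i] == "W") {
      w_earlier[i] <- U$frf[p]
      w_later[p] <- U$frf[i]
      if (hbur_tok[p] == "-" && is.finite(U$husband_death[p]))
        hbur_tok[p] <- .date_token(U$marriage[i], weighting = 150L)
    } else {
      h_earlier[i] <- U$frf[p]
      h_later[p] <- U$frf[i]
      if (wbur_tok[p] == "-" && is.finite(U$wife_death[p]))
        wbur_tok[p] <- .date_token(U$marriage[i], weighting = 150L)
    }
  }
  if (nB) {
    for (i in which(U$wave == 3L & emitted)) {
      b <- match(U$origin_baby[i], B$baby_id)
      if (!is.na(b) && B$present[b]) {
        B$marriage_tok[b] <- .date_token(U$marriage[i])
        B$own_frf[b] <- U$frf[i]
      }
    }
  }

  ## marriage-date precision noise
  pu <- stats::runif(nU)
  mar_prec <- ifelse(pu < cfg$marriage_year_only_prob, "year_only",
                     ifelse(pu < cfg$marriage_year_only_prob + 0.05,
                            "month_only", "exact"))
  occ_tok <- ifelse(stats::runif(nU) < cfg$occupation_prob, "lab", "-")
  lit <- stats::runif(nU) < 0.5
  lit_h <- c("y", "n")[1L + (stats::runif(nU) < 0.4)]
  lit_w <- c("y", "n")[1L + (stats::runif(nU) < 0.7)]

  kb_idx <- vector("list", max(U$frf))
  if (nB) {
    tmp <- split(which(B$present), B$frf[B$present])
    kb_idx[as.integer(names(tmp))] <- tmp
  }
  u_bap_tok <- bap_tok[match(U$wife_key, wkeys)]
  lines <- vector("list", nU)
  for (i in which(emitted)) {
    frf <- U$frf[i]
    ml <- paste(c("M", frf, .date_token(U$marriage[i], mar_prec[i]), "-"),
                collapse = "/")
    hl <- paste(c("H", paste0("H", frf), "-", hbur_tok[i], "-",
                  occ_tok[i], .tok_int(h_earlier[i]),
                  .tok_int(h_later[i])), collapse = "/")
    wl <- paste(c("W", paste0("W", frf), u_bap_tok[i],
                  wbur_tok[i], "-", "-", .tok_int(w_earlier[i]),
                  .tok_int(w_later[i])), collapse = "/")
    cl <- character()
    fpairs <- character()
    kb <- if (is.null(kb_idx[[frf]])) NULL else B[kb_idx[[frf]], , drop = FALSE]
    if (!is.null(kb) && nrow(kb)) {
      kb <- kb[order(kb$birth, kb$baby_id), , drop = FALSE]
      for (j in seq_len(nrow(kb))) {
        bapt <- "-"
        if (kb$bap_reg[j])
          bapt <- .date_token(kb$bap_date[j],
                              secondary = if (stats::runif(1) < 0.5)
                                kb$birth[j])
        burt <- "-"
        if (kb$bur_reg[j])
          burt <- .date_token(kb$burial_date[j],
                              secondary = if (stats::runif(1) < 0.5)
                                kb$death[j])
        cl <- c(cl, paste(c("C", sprintf("c%d_%d", frf, j), kb$sex[j],
                            bapt, burt, kb$marriage_tok[j],
                            .tok_int(kb$own_frf[j])), collapse = "/"))
        fl <- paste(c(if (kb$stillborn[j]) "Z", if (kb$twin[j]) "2",
                      if (kb$posthumous[j]) "O"), collapse = "")
        if (nzchar(fl)) fpairs <- c(fpairs, sprintf("C%d", j), fl)
      }
    }
    if (U$wave[i] == 2L)  # widow(er) flag on the remarried spouse's line
      fpairs <- c(fpairs, U$pred_role[i], "W")
    lines[[i]] <- c(ml, hl, wl, cl,
                    if (lit[i]) paste(c("L", lit_h[i], lit_w[i]),
                                      collapse = "/"),
                    if (length(fpairs)) paste(c("F", fpairs),
                                              collapse = "/"),
                    "$")
  }
  unlist(lines[!vapply(lines, is.null, TRUE)])
}

#' True age-specific marital fertility rates from the complete event log
#'
#' Computes rates from complete exposure (marriage to the first spouse
#' death or the wife's 50th birthday), unaffected by migration,
#' registration delays or under-registration — the oracle against which
#' pipeline estimates are judged. Multiple births count as one event, as
#' in the estimator.
#'
#' @param truth a `synth_parish` object or its `truth` element.
#' @param age_breaks,period_breaks grids as in [make_episodes()]; the
#'   default period grid runs to 1900 because complete histories extend
#'   beyond the registration window.
#' @return A [person_years_and_births()] rate table.
#' @export
true_rates <- function(truth, age_breaks = seq(15L, 50L, 5L),
                       period_breaks = seq(1575L, 1900L, 25L)) {
  if (inherits(truth, "synth_parish")) truth <- truth$truth
  un <- truth$unions
  wb <- as.numeric(un$wife_birth)
  mar <- as.numeric(un$marriage)
  entry <- floor(pmax(mar, wb + ceiling(15 * 365.25)))
  exit <- floor(pmin(ifelse(is.finite(un$wife_death), un$wife_death, Inf),
                     ifelse(is.finite(un$husband_death), un$husband_death,
                            Inf),
                     wb + ceiling(50 * 365.25)))
  keep <- is.finite(exit) & exit > entry
  win <- data.frame(
    id = un$wife_key[keep], union = as.character(un$frf[keep]),
    birth_date = as.Date(wb[keep], origin = "1970-01-01"),
    entry = as.Date(entry[keep], origin = "1970-01-01"),
    exit = as.Date(exit[keep], origin = "1970-01-01"),
    weight = 1, stringsAsFactors = FALSE)
  ev <- truth$events
  k <- nrow(ev)
  chron <- data.frame(
    id = un$wife_key[match(ev$frf, un$frf)],
    union = as.character(ev$frf), attribute = rep_len("birth", k),
    value = rep_len("1", k), date = ev$date,
    is_event = rep_len(TRUE, k), stringsAsFactors = FALSE)
  eps <- make_episodes(chron, win, age_breaks, period_breaks)
  person_years_and_births(eps)
}

#' Demonstrate the informative-censoring bias of violating the Henry rules
#'
#' Runs the full pipeline (simulate, parse, relational, IDS, harmonize,
#' select, episodes, rates) on replicate synthetic parishes under both the
#' reference criteria and the diagnostic criteria whose observation windows
#' end at the last child event, and compares both to the true rates from
#' the complete event log. Ending histories at a child event keeps the
#' woman's exposure only up to her last birth, so time at risk is
#' understated and rates are overstated — most strongly at older ages,
#' where the gap between the last birth and the (unobserved) departure is
#' longest.
#'
#' @param config a [synth_config()]; replicate r uses seed
#'   `config$seed + r - 1`.
#' @param n_reps number of replicates.
#' @param age_breaks,period_breaks grids as in [make_episodes()].
#' @return A list of class `bias_experiment`: `tmfr` (one row per
#'   replicate: truth, reference, violating), `age_rates` (per replicate
#'   and age group), `age_summary` (means, Monte-Carlo standard errors and
#'   mean bias per age group), `share_violating_above_truth`.
#' @export
bias_experiment <- function(config, n_reps = 20,
                            age_breaks = seq(15L, 50L, 5L),
                            period_breaks = seq(1575L, 1900L, 25L)) {
  stopifnot(inherits(config, "synth_config"))
  crits <- list(reference = reference_criteria(),
                violating = violating_criteria())
  tm <- vector("list", n_reps)
  ar <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_parish(cfg)
    tr <- true_rates(sim, age_breaks, period_breaks)
    prep <- prepare_parish(text = sim$text,
                           parish_code = cfg$parish_code,
                           parish_meta = sim$parish_meta)
    res <- lapply(crits, function(cs)
      fertility_rates_for(prep, cs, age_breaks = age_breaks,
                          period_breaks = period_breaks))
    tm[[r]] <- data.frame(
      rep = r, truth = tmfr(tr),
      reference = res$reference$tmfr,
      violating = res$violating$tmfr)
    prof <- function(nm, rt) {
      ba <- rates_by_age(rt)
      data.frame(rep = r, criteria = nm, age_group = ba$age_group,
                 rate = ba$rate, stringsAsFactors = FALSE)
    }
    ar[[r]] <- rbind(prof("truth", tr),
                     prof("reference", res$reference$rates),
                     prof("violating", res$violating$rates))
  }
  tmfrs <- do.call(rbind, tm)
  age_rates <- do.call(rbind, ar)
  mean_tab <- stats::aggregate(rate ~ criteria + age_group, age_rates,
                               mean)
  se_tab <- stats::aggregate(rate ~ criteria + age_group, age_rates,
                             function(x) stats::sd(x) / sqrt(length(x)))
  names(mean_tab)[3] <- "mean_rate"
  names(se_tab)[3] <- "mc_se"
  age_summary <- merge(mean_tab, se_tab)
  wide <- stats::reshape(age_summary[, c("criteria", "age_group",
                                         "mean_rate")],
                         idvar = "age_group", timevar = "criteria",
                         direction = "wide")
  names(wide) <- sub("^mean_rate\\.", "", names(wide))
  wide$violating_bias <- wide$violating - wide$truth
  wide$reference_bias <- wide$reference - wide$truth
  wide <- wide[order(wide$age_group), ]
  rownames(wide) <- NULL
  structure(list(
    tmfr = tmfrs, age_rates = age_rates, age_summary = age_summary,
    bias_profile = wide,
    share_violating_above_truth =
      mean(tmfrs$violating > tmfrs$truth, na.rm = TRUE)),
    class = "bias_experiment")
}

#' @export
print.bias_experiment <- function(x, ...) {
  cat("<bias_experiment>", nrow(x$tmfr), "replicates\n")
  cat("mean TMFR: truth", round(mean(x$tmfr$truth), 3),
      "| reference", round(mean(x$tmfr$reference), 3),
      "| violating", round(mean(x$tmfr$violating), 3), "\n")
  cat("share of replicates with violating TMFR above truth:",
      x$share_violating_above_truth, "\n")
  invisible(x)
}
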