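#' Run the reconstitution pipeline up to the chronicle
#'
#' Convenience wrapper chaining the stages: parse FRF text, build the
#' relational bundle, resolve cross-family links, build and harmonize the
#' IDS tables, assemble family views and the fertility chronicle. The
#' result feeds [fertility_rates_for()], which applies a criteria set and
#' computes rates; keeping the two apart lets several criteria sets share
#' one prepared parish.
#'
#' @param text FRF text (character scalar or vector of lines), or
#' @param records an already-parsed list of [frf_record()]s.
#' @param parish_code short parish code for parfrf keys.
#' @param parish_meta a [parish_metadata()] object.
#' @param pad_width zero-padding for [make_parfrf()].
#' @param weaning_months lactation horizon for [build_chronicle()].
#' @return A list of class `parish_prep` with elements `records`, `bundle`,
#'   `links`, `ids` (harmonized), `families`, `children`, `chronicle`,
#'   `parish_meta`.
#' @export
prepare_parish <- function(text = NULL, records = NULL, parish_code,
                           parish_meta, pad_width = 6L,
                           weaning_months = 24) {
  if (is.null(records)) records <- read_frf(text = text)
  bundle <- records_to_bundle(records, parish_code, pad_width)
  links <- resolve_links(bundle)
  ids <- build_ids(bundle, parish_meta)
  ids <- harmonize_ids(ids, links)
  af <- assemble_families(ids)
  chron <- build_chronicle(ids, weaning_months = weaning_months)
  structure(list(records = records, bundle = bundle, links = links,
                 ids = ids, families = af$families,
                 children = af$children, chronicle = chron,
                 parish_meta = parish_meta),
            class = "parish_prep")
}

#' Apply a criteria set to a prepared parish and compute fertility rates
#'
#' @param prep a [prepare_parish()] result.
#' @param criteria a [criteria_set()].
#' @param age_breaks,period_breaks grids as in [make_episodes()].
#' @return A list: `decisions`, `windows`, `episodes`, `rates` (a
#'   [person_years_and_births()] table), `tmfr`.
#' @export
fertility_rates_for <- function(prep, criteria,
                                age_breaks = seq(15L, 50L, 5L),
                                period_breaks = seq(1575L, 1900L, 25L)) {
  stopifnot(inherits(prep, "parish_prep"))
  decisions <- select_families(prep$families, prep$children, criteria,
                               prep$parish_meta)
  windows <- selection_windows(prep$families, decisions)
  episodes <- make_episodes(prep$chronicle, windows,
                            age_breaks = age_breaks,
                            period_breaks = period_breaks)
  rates <- person_years_and_births(episodes)
  list(decisions = decisions, windows = windows, episodes = episodes,
       rates = rates, tmfr = tmfr(rates))
}

#' One-call fertility pipeline
#'
#' [prepare_parish()] followed by [fertility_rates_for()] under one
#' criteria set.
#'
#' @inheritParams prepare_parish
#' @inheritParams fertility_rates_for
#' @return As [fertility_rates_for()], plus the `prep` object.
#' @export
fertility_pipeline <- function(text = NULL, records = NULL, parish_code,
                               parish_meta,
                               criteria = reference_criteria(),
                               age_breaks = seq(15L, 50L, 5L),
                               period_breaks = seq(1575L, 1900L, 25L),
                               weaning_months = 24) {
  prep <- prepare_parish(text = text, records = records,
                         parish_code = parish_code,
                         parish_meta = parish_meta,
                         weaning_months = weaning_months)
  out <- fertility_rates_for(prep, criteria, age_breaks = age_breaks,
                             period_breaks = period_breaks)
  out$prep <- prep
  out
}
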