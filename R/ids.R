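#' Intermediate Data Structure (IDS) tables
#'
#' IDS is a five-table entity-attribute-value standard for longitudinal
#' historical microdata: INDIVIDUAL and CONTEXT hold one datum per row
#' (a Type, an optional Value, an optional date with an Estimation of its
#' precision), and INDIV_INDIV, INDIV_CONTEXT, CONTEXT_CONTEXT hold
#' relations between entities. Each reconstituted family (FRF) becomes a
#' "Union" context timestamped at the marriage; every person in the FRF is
#' linked to the union, and kinship is recorded in mirrored INDIV_INDIV
#' pairs (always given in both directions).
#'
#' @name ids_tables
#' @keywords internal
NULL

.IDS_ROLES <- c(wife = "W", husband = "H", child = "C",
                wife_father = "WF", wife_mother = "WM",
                husband_father = "HF", husband_mother = "HM")

.EST_EXACT <- "Exact"
.EST_DD <- "Estimated (dd)"
.EST_DDMM <- "Estimated (dd/mm)"
.EST_EST <- "Estimated"
.EST_BEFORE <- "Before this date"
.EST_AFTER <- "After this date"
.EST_DUMMY <- "Dummy birth (burial date)"

#' Build an individual ID from a parfrf and role
#'
#' A role suffix is appended to the family key: `W` wife, `H` husband,
#' `Cxx` child (xx = two-digit child number so IDs sort), `WF`/`WM`/`HF`/`HM`
#' the spouses' parents.
#'
#' @param parfrf family key (vectorised).
#' @param role one of `"wife"`, `"husband"`, `"child"`, `"wife_father"`,
#'   `"wife_mother"`, `"husband_father"`, `"husband_mother"`, or the
#'   corresponding suffix code.
#' @param child_number required iff `role` is child; 1-based.
#' @return Character vector of individual IDs.
#' @examples
#' make_individual_id("ALC000017", "wife")       # "ALC000017W"
#' make_individual_id("ALC000017", "child", 2)   # "ALC000017C02"
#' @export
make_individual_id <- function(parfrf, role, child_number = NULL) {
  suffix <- if (role %in% names(.IDS_ROLES)) .IDS_ROLES[[role]]
            else if (role %in% .IDS_ROLES) role
            else stop("make_individual_id: unknown role ", sQuote(role))
  if (!length(parfrf)) return(character())
  if (suffix == "C") {
    if (is.null(child_number))
      stop("make_individual_id: child role requires a child_number")
    if (any(child_number < 1L))
      stop("make_individual_id: child_number must be >= 1")
    return(sprintf("%sC%02d", parfrf, as.integer(child_number)))
  }
  paste0(parfrf, suffix)
}

# Vectorised weighting -> Estimation mapping. `date` is the normalized Date
# the weighting is attached to (used to disambiguate the 3000 offset).
.estimation_vec <- function(weighting, date, unknown_default = .EST_EST) {
  n <- length(weighting)
  out <- rep(.EST_EXACT, n)
  idx <- which(!is.na(weighting))
  if (!length(idx)) return(out)
  w <- as.integer(weighting[idx])
  base <- w %% 1000L
  hi <- w - base
  lt <- as.POSIXlt(date[idx])
  feb28nl <- !is.na(date[idx]) & lt$mon == 1L & lt$mday == 28L &
    !is_gregorian_leap(lt$year + 1900L)
  month_amb <- hi == 2000L | (hi == 3000L & !feb28nl)
  day_amb <- hi == 1000L | (hi == 3000L & !feb28nl) | base == 101L

  codes <- .weighting_codes_cached()
  base_label <- codes$estimation[match(base, codes$code)]
  known <- base == 0L | !is.na(base_label)
  lab <- rep(.EST_EXACT, length(w))
  lab[!known] <- unknown_default
  lab[known & !is.na(base_label)] <- base_label[known & !is.na(base_label)]
  # ambiguity offsets escalate the label unless a before/after semantics
  # from the base code dominates
  rank <- function(x) match(x, c(.EST_EXACT, .EST_DD, .EST_EST, .EST_DDMM,
                                 .EST_BEFORE, .EST_AFTER))
  esc <- ifelse(month_amb, .EST_DDMM, ifelse(day_amb, .EST_DD, .EST_EXACT))
  take_esc <- rank(esc) > rank(lab) & !(lab %in% c(.EST_BEFORE, .EST_AFTER))
  lab[take_esc] <- esc[take_esc]
  if (any(!known))
    warning("unknown weighting base code(s) ",
            paste(unique(base[!known]), collapse = ", "),
            " mapped to ", sQuote(unknown_default), call. = FALSE)
  out[idx] <- lab
  out
}

#' Map a date weighting to an IDS Estimation label
#'
#' A date with no weighting is assumed fully known (`"Exact"`). Day
#' ambiguity (the +1000 offset, or base code 101) gives
#' `"Estimated (dd)"`; month ambiguity (+2000) gives `"Estimated (dd/mm)"`;
#' base codes meaning a bound (e.g. a spouse death proxied by the survivor's
#' remarriage, or a father's death inferred from a posthumous birth) give
#' `"Before this date"`/`"After this date"`. A +3000/+4000 leap-day
#' adjustment alone leaves the label `"Exact"` (the source provided a full
#' date; only 29 February was moved to 28). Unknown base codes map to a
#' conservative configurable default with a warning.
#'
#' @param weighting integer weighting or `NA`.
#' @param date the normalized `Date` the weighting belongs to (used to
#'   disambiguate the 3000 offset); may be `NA`.
#' @param unknown_default label for unknown base codes.
#' @return A single Estimation label.
#' @export
map_weighting_to_estimation <- function(weighting, date = as.Date(NA),
                                        unknown_default = "Estimated") {
  .estimation_vec(weighting, date, unknown_default)[1L]
}

.empty_individual <- function() {
  data.frame(id_i = character(), type = character(), value = character(),
             date = as.Date(character()), estimation = character(),
             stringsAsFactors = FALSE)
}

.ind_rows <- function(id, type, value = NA_character_,
                      date = as.Date(NA), weighting = NA_integer_,
                      estimation = NULL) {
  n <- length(id)
  if (!n) return(.empty_individual())
  value <- rep_len(as.character(value), n)
  date <- rep_len(date, n)
  if (is.null(estimation)) {
    estimation <- rep(NA_character_, n)
    dated <- !is.na(date)
    if (any(dated))
      estimation[dated] <- .estimation_vec(rep_len(weighting, n)[dated],
                                           date[dated])
  } else estimation <- rep_len(estimation, n)
  # a datum must carry something: drop rows with neither value nor date
  keep <- !is.na(value) | !is.na(date)
  data.frame(id_i = id, type = type, value = value, date = date,
             estimation = estimation,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

.mirror_pairs <- function(id_a, id_b, rel_ab, rel_ba) {
  keep <- !is.na(id_a) & !is.na(id_b)
  data.frame(
    id_i_1 = c(id_a[keep], id_b[keep]),
    id_i_2 = c(id_b[keep], id_a[keep]),
    relation = c(rep_len(rel_ab, sum(keep)), rep_len(rel_ba, sum(keep))),
    stringsAsFactors = FALSE)
}

#' Parish metadata for IDS context information
#'
#' @param parish parish name.
#' @param code short parish code (also the parish context ID).
#' @param county county name.
#' @param quality_years data.frame with columns `start`, `end` (calendar
#'   years): periods judged to have complete event registration.
#' @param sample_groups data.frame with columns `group`, `start`, `end`:
#'   period-specific sample-group membership.
#' @param fertility_weight parish analysis weight for fertility rates
#'   (0 drops the parish, 0.5 half-weights it).
#' @return A list of class `parish_metadata`.
#' @export
parish_metadata <- function(parish, code, county = NA_character_,
                            quality_years = data.frame(start = 1538L,
                                                       end = 1851L),
                            sample_groups = data.frame(group = 1L,
                                                       start = 1538L,
                                                       end = 1851L),
                            fertility_weight = NULL) {
  if (is.null(fertility_weight)) {
    rules <- parish_weight_rules()
    i <- match(parish, rules$parish)
    fertility_weight <- if (is.na(i)) 1 else rules$fertility_weight[i]
  }
  structure(list(parish = parish, code = code, county = county,
                 quality_years = quality_years,
                 sample_groups = sample_groups,
                 fertility_weight = fertility_weight),
            class = "parish_metadata")
}

#' Build the five IDS tables from a relational bundle
#'
#' Every FRF becomes a CONTEXT "Union" timestamped at the marriage date;
#' members get INDIV_CONTEXT links (Wife/Husband/Child) and mirrored
#' INDIV_INDIV kinship pairs. All dated fields become dated INDIVIDUAL
#' records, with birth kept distinct from baptism and death from burial.
#' For a child with a burial but neither birth nor baptism date, a dummy
#' birth record is created with the burial date and Estimation
#' `"Dummy birth (burial date)"`. Flags are emitted as Types (Pauper,
#' Posthumous, Religion, SUFFIX_NAME, Stillbirth, Illegitimate); flags whose
#' content is inferable elsewhere are not imported — in particular the
#' widowhood 'W' flags are ignored and widowhood is inferred from burial
#' dates only. Parish-level information (county, quality years, sample
#' groups) is recorded once in CONTEXT and tied to each union by a
#' "Union in parish" CONTEXT_CONTEXT link.
#'
#' @param bundle an [records_to_bundle()] result.
#' @param parish_meta a [parish_metadata()] object.
#' @return An object of class `ids_tables`: a list with elements
#'   `INDIVIDUAL`, `CONTEXT`, `INDIV_INDIV`, `INDIV_CONTEXT`,
#'   `CONTEXT_CONTEXT`.
#' @export
build_ids <- function(bundle, parish_meta) {
  stopifnot(inherits(bundle, "frf_bundle"),
            inherits(parish_meta, "parish_metadata"))
  mar <- bundle$marriages
  uid <- mar$parfrf

  ## CONTEXT: one Union per FRF + parish rows
  context <- data.frame(
    id_c = uid, type = "Union", value = NA_character_,
    date = mar$marriage_date,
    estimation = .estimation_vec(mar$marriage_weighting, mar$marriage_date),
    stringsAsFactors = FALSE)
  pm <- parish_meta
  prow <- function(type, value) data.frame(
    id_c = pm$code, type = type, value = value, date = as.Date(NA),
    estimation = NA_character_, stringsAsFactors = FALSE)
  context <- rbind(context,
    prow("Parish", pm$parish),
    if (!is.na(pm$county)) prow("County", pm$county),
    prow("QUALITY_YEARS",
         paste(sprintf("%d-%d", pm$quality_years$start,
                       pm$quality_years$end), collapse = ";")),
    prow("SAMPLE_GROUP",
         paste(sprintf("%s:%d-%d", pm$sample_groups$group,
                       pm$sample_groups$start, pm$sample_groups$end),
               collapse = ";")),
    prow("FERTILITY_WEIGHT", as.character(pm$fertility_weight)))

  cc <- data.frame(id_c_1 = uid, id_c_2 = pm$code,
                   relation = "Union in parish", stringsAsFactors = FALSE)

  ## individual ids
  hus <- bundle$husbands; wiv <- bundle$wives; ch <- bundle$children
  hid <- make_individual_id(hus$parfrf, "husband")
  wid <- make_individual_id(wiv$parfrf, "wife")
  cid <- make_individual_id(ch$parfrf, "child", ch$child_number)

  spouse_ind <- function(t, id, sexval) {
    rbind(
      .ind_rows(id, "NAME", value = t$name),
      .ind_rows(id, "SEX", value = sexval),
      .ind_rows(id, "BAPTISM_DATE", date = t$baptism_date,
                weighting = t$baptism_weighting),
      .ind_rows(id, "BIRTH_DATE", date = t$birth_date,
                weighting = t$birth_weighting),
      .ind_rows(id, "FUNERAL_DATE", date = t$burial_date,
                weighting = t$burial_weighting),
      .ind_rows(id, "DEATH_DATE", date = t$death_date,
                weighting = t$death_weighting),
      .ind_rows(id, "BIRTHPLACE", value = t$birthplace),
      .ind_rows(id, "OCCUPATION", value = t$occupation))
  }
  individual <- rbind(
    spouse_ind(hus, hid, "m"),
    spouse_ind(wiv, wid, "f"),
    .ind_rows(cid, "NAME", value = ch$name),
    .ind_rows(cid, "SEX", value = ch$sex),
    .ind_rows(cid, "BAPTISM_DATE", date = ch$baptism_date,
              weighting = ch$baptism_weighting),
    .ind_rows(cid, "BIRTH_DATE", date = ch$birth_date,
              weighting = ch$birth_weighting),
    .ind_rows(cid, "FUNERAL_DATE", date = ch$burial_date,
              weighting = ch$burial_weighting),
    .ind_rows(cid, "DEATH_DATE", date = ch$death_date,
              weighting = ch$death_weighting),
    .ind_rows(cid, "MARRIAGE_DATE", date = ch$marriage_date,
              weighting = ch$marriage_weighting))

  ## dummy births: burial but neither birth nor baptism; the death date,
  ## when the burial token carried one, is the better birth estimate
  dummy <- is.na(ch$birth_date) & is.na(ch$baptism_date) &
    !is.na(ch$burial_date)
  if (any(dummy)) {
    ddate <- ch$death_date[dummy]
    ddate[is.na(ddate)] <- ch$burial_date[dummy][is.na(ddate)]
    individual <- rbind(individual,
      .ind_rows(cid[dummy], "BIRTH_DATE", date = ddate,
                estimation = .EST_DUMMY))
  }

  ## flag-derived Types (the widowhood 'W' flag is deliberately not imported)
  flag_type <- function(id, fl, code, type, value) {
    hit <- .has_code(fl, code)
    .ind_rows(id[hit], type, value = value)
  }
  all_id <- c(hid, wid, cid)
  all_fl <- c(hus$flags, wiv$flags, ch$flags)
  individual <- rbind(individual,
    flag_type(all_id, all_fl, "P", "Pauper", "y"),
    flag_type(all_id, all_fl, "O", "Posthumous", "y"),
    flag_type(all_id, all_fl, "I", "Illegitimate", "y"),
    flag_type(all_id, all_fl, "D", "Religion", "dissenter"),
    flag_type(all_id, all_fl, "S", "SUFFIX_NAME", "senior"),
    flag_type(all_id, all_fl, "J", "SUFFIX_NAME", "junior"),
    flag_type(cid, ch$flags, "Z", "Stillbirth", "y"))

  ## parents
  par_ind <- function(t, role) {
    id <- make_individual_id(t$parfrf, role)
    rbind(.ind_rows(id, "NAME", value = t$name),
          if ("residence" %in% names(t))
            .ind_rows(id, "RESIDENCE", value = t$residence),
          if ("occupation" %in% names(t))
            .ind_rows(id, "OCCUPATION", value = t$occupation))
  }
  individual <- rbind(individual,
    par_ind(bundle$husbands_fathers, "husband_father"),
    par_ind(bundle$husbands_mothers, "husband_mother"),
    par_ind(bundle$wives_fathers, "wife_father"),
    par_ind(bundle$wives_mothers, "wife_mother"))

  ## literacy: signature in the marriage register, dated at marriage
  lit <- bundle$literacy
  if (nrow(lit)) {
    mdate <- mar$marriage_date[match(lit$parfrf, mar$parfrf)]
    individual <- rbind(individual,
      .ind_rows(make_individual_id(lit$parfrf, "husband"), "SIGNATURE",
                value = lit$husband_signs, date = mdate,
                estimation = .EST_EXACT),
      .ind_rows(make_individual_id(lit$parfrf, "wife"), "SIGNATURE",
                value = lit$wife_signs, date = mdate,
                estimation = .EST_EXACT))
  }

  ## INDIV_CONTEXT: members of the union
  ic_rows <- function(id_i, id_c, rel)
    data.frame(id_i = id_i, id_c = id_c,
               relation = rep_len(rel, length(id_i)),
               stringsAsFactors = FALSE)
  indiv_context <- rbind(ic_rows(hid, hus$parfrf, "Husband"),
                         ic_rows(wid, wiv$parfrf, "Wife"),
                         ic_rows(cid, ch$parfrf, "Child"))

  ## INDIV_INDIV: mirrored kinship
  hus_of <- hid[match(ch$parfrf, hus$parfrf)]
  wiv_of <- wid[match(ch$parfrf, wiv$parfrf)]
  indiv_indiv <- rbind(
    .mirror_pairs(hid[match(wiv$parfrf, hus$parfrf)], wid,
                  "husband of", "wife of"),
    .mirror_pairs(wiv_of, cid, "mother of", "child of"),
    .mirror_pairs(hus_of, cid, "father of", "child of"),
    .mirror_pairs(make_individual_id(bundle$husbands_fathers$parfrf,
                                     "husband_father"),
                  make_individual_id(bundle$husbands_fathers$parfrf,
                                     "husband"),
                  "father of", "child of"),
    .mirror_pairs(make_individual_id(bundle$husbands_mothers$parfrf,
                                     "husband_mother"),
                  make_individual_id(bundle$husbands_mothers$parfrf,
                                     "husband"),
                  "mother of", "child of"),
    .mirror_pairs(make_individual_id(bundle$wives_fathers$parfrf,
                                     "wife_father"),
                  make_individual_id(bundle$wives_fathers$parfrf, "wife"),
                  "father of", "child of"),
    .mirror_pairs(make_individual_id(bundle$wives_mothers$parfrf,
                                     "wife_mother"),
                  make_individual_id(bundle$wives_mothers$parfrf, "wife"),
                  "mother of", "child of"))

  ids <- structure(list(INDIVIDUAL = individual, CONTEXT = context,
                        INDIV_INDIV = indiv_indiv,
                        INDIV_CONTEXT = indiv_context,
                        CONTEXT_CONTEXT = cc),
                   class = "ids_tables",
                   parish_code = pm$code)
  for (nm in names(ids)) rownames(ids[[nm]]) <- NULL
  ids
}

#' @export
print.ids_tables <- function(x, ...) {
  cat("<ids_tables>",
      paste(sprintf("%s: %d", names(x),
                    vapply(x, nrow, 0L)), collapse = ", "), "\n")
  invisible(x)
}

# earliest dated INDIVIDUAL event per id (NA -> no date)
.earliest_event <- function(ids) {
  ind <- ids$INDIVIDUAL
  dated <- ind[!is.na(ind$date), c("id_i", "date")]
  if (!nrow(dated))
    return(data.frame(id_i = character(), date = as.Date(character())))
  agg <- stats::aggregate(date ~ id_i, data = dated, FUN = min)
  agg
}

#' Harmonize individual IDs across families
#'
#' A person can appear in several FRFs: a child marries and becomes a
#' husband or wife in a new family (the child line's own-first-marriage
#' link), or a widowed spouse remarries (earlier/later-marriage links).
#' Link rows are turned into equivalence classes of individual IDs
#' (union-find), and each class is rewritten everywhere to the ID whose
#' earliest dated event occurs first in the database; ties break to the
#' lexicographically smaller ID. Children's roles in their marriage family
#' are resolved through their recorded sex; a child link without a recorded
#' sex is reported as unresolvable.
#'
#' @param ids an `ids_tables` object.
#' @param links the [resolve_links()] table for the same parish.
#' @return The rewritten `ids_tables`, with the mapping in attribute
#'   `"id_map"` (data.frame original/canonical) and a report in attribute
#'   `"harmonization_report"` (dangling or unresolvable links, cyclic
#'   marriage-order faults).
#' @export
harmonize_ids <- function(ids, links) {
  stopifnot(inherits(ids, "ids_tables"))
  report <- list(dangling = links[!links$resolved, , drop = FALSE],
                 unresolvable = links[0, , drop = FALSE],
                 cycles = character())
  lk <- links[links$resolved, , drop = FALSE]

  sex <- ids$INDIVIDUAL[ids$INDIVIDUAL$type == "SEX", c("id_i", "value")]
  pairs <- list()
  for (i in seq_len(nrow(lk))) {
    role <- lk$role[i]
    if (lk$link_kind[i] %in% c("earlier_marriage", "later_marriage")) {
      a <- paste0(lk$parfrf[i], role)
      b <- paste0(lk$target_parfrf[i], role)
    } else {
      a <- paste0(lk$parfrf[i], role)
      s <- sex$value[match(a, sex$id_i)]
      if (is.na(s) || !s %in% c("m", "f")) {
        report$unresolvable <- rbind(report$unresolvable,
                                     lk[i, , drop = FALSE])
        next
      }
      b <- paste0(lk$target_parfrf[i], if (s == "f") "W" else "H")
    }
    pairs[[length(pairs) + 1L]] <- c(a, b)
  }

  ## chronological sanity: directed earlier->later edges between unions
  ## must be acyclic
  dir <- lk[lk$link_kind %in% c("earlier_marriage", "later_marriage"), ,
            drop = FALSE]
  if (nrow(dir)) {
    from <- ifelse(dir$link_kind == "earlier_marriage",
                   dir$target_parfrf, dir$parfrf)
    to <- ifelse(dir$link_kind == "earlier_marriage",
                 dir$parfrf, dir$target_parfrf)
    report$cycles <- .find_cycles(from, to)
    if (length(report$cycles))
      warning("harmonize_ids: cyclic marriage-order links detected: ",
              paste(report$cycles, collapse = "; "), call. = FALSE)
  }

  if (!length(pairs)) {
    attr(ids, "id_map") <- data.frame(original = character(),
                                      canonical = character())
    attr(ids, "harmonization_report") <- report
    return(ids)
  }

  ## union-find over integer node indices
  m <- do.call(rbind, pairs)
  nodes <- unique(c(m))
  ia <- match(m[, 1L], nodes)
  ib <- match(m[, 2L], nodes)
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(ia)) {
    ra <- find(ia[i]); rb <- find(ib[i])
    if (ra != rb) parent[rb] <- ra
  }
  root <- nodes[vapply(seq_along(nodes), find, 0L)]

  ## canonical id per class: earliest dated event, ties lexicographic
  ev <- .earliest_event(ids)
  node_date <- ev$date[match(nodes, ev$id_i)]
  ord <- order(root, node_date, nodes, na.last = TRUE)
  first <- !duplicated(root[ord])
  canon_of_root <- stats::setNames(nodes[ord][first], root[ord][first])
  canonical <- unname(canon_of_root[root])
  id_map <- data.frame(original = nodes, canonical = canonical,
                       stringsAsFactors = FALSE)
  id_map <- id_map[id_map$original != id_map$canonical, , drop = FALSE]
  rownames(id_map) <- NULL

  remap <- function(x) {
    i <- match(x, id_map$original)
    ifelse(is.na(i), x, id_map$canonical[i])
  }
  ids$INDIVIDUAL$id_i <- remap(ids$INDIVIDUAL$id_i)
  ids$INDIVIDUAL <- unique(ids$INDIVIDUAL)
  ids$INDIV_INDIV$id_i_1 <- remap(ids$INDIV_INDIV$id_i_1)
  ids$INDIV_INDIV$id_i_2 <- remap(ids$INDIV_INDIV$id_i_2)
  ids$INDIV_INDIV <- unique(ids$INDIV_INDIV)
  ids$INDIV_CONTEXT$id_i <- remap(ids$INDIV_CONTEXT$id_i)
  ids$INDIV_CONTEXT <- unique(ids$INDIV_CONTEXT)
  for (nm in names(ids)) rownames(ids[[nm]]) <- NULL
  attr(ids, "id_map") <- id_map
  attr(ids, "harmonization_report") <- report
  ids
}

# simple DFS cycle detection on a directed edge list; returns descriptions
.find_cycles <- function(from, to) {
  nodes <- unique(c(from, to))
  adj <- split(to, factor(from, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  cycles <- character()
  visit <- function(v, path) {
    state[[v]] <<- 1L
    for (w in adj[[v]]) {
      if (is.null(w) || is.na(w)) next
      if (!w %in% nodes) next
      if (state[[w]] == 1L)
        cycles <<- c(cycles, paste(c(path, v, w), collapse = " -> "))
      else if (state[[w]] == 0L) visit(w, c(path, v))
    }
    state[[v]] <<- 2L
  }
  for (v in nodes) if (state[[v]] == 0L) visit(v, character())
  cycles
}

# per-person proxy dates: birth (birth else baptism), death (death else
# burial), with the estimation of whichever date was used
.person_dates <- function(ids) {
  ind <- ids$INDIVIDUAL
  pick <- function(primary, fallback) {
    p <- ind[ind$type == primary & !is.na(ind$date), ]
    f <- ind[ind$type == fallback & !is.na(ind$date), ]
    p <- p[!duplicated(p$id_i), ]
    f <- f[!duplicated(f$id_i), ]
    f <- f[!f$id_i %in% p$id_i, ]
    out <- rbind(p, f)[, c("id_i", "date", "estimation")]
    out
  }
  b <- pick("BIRTH_DATE", "BAPTISM_DATE")
  d <- pick("DEATH_DATE", "FUNERAL_DATE")
  all_id <- unique(ind$id_i)
  data.frame(
    id_i = all_id,
    birth_date = b$date[match(all_id, b$id_i)],
    birth_estimation = b$estimation[match(all_id, b$id_i)],
    death_date = d$date[match(all_id, d$id_i)],
    death_estimation = d$estimation[match(all_id, d$id_i)],
    stringsAsFactors = FALSE)
}

#' Consistency checks on an IDS database
#'
#' Non-mutating data-quality tests: vital events of each person must be in
#' order (birth before marriage before death, using baptism/burial as
#' proxies); mothers must be aged 15--50 at each child's birth; fathers
#' outside 18--60 are flagged; and intervals between a mother's successive
#' child baptisms that are greater than 0 and less than 250 days are
#' counted (physiologically impossible spacings point to linkage problems
#' or delayed baptism).
#'
#' @param ids an `ids_tables` object (harmonized or not).
#' @return A list of class `ids_check_report`: per-check data.frames of
#'   offending IDs plus a `counts` summary.
#' @export
run_consistency_checks <- function(ids) {
  stopifnot(inherits(ids, "ids_tables"))
  pd <- .person_dates(ids)
  ctx <- ids$CONTEXT
  unions <- ctx[ctx$type == "Union", c("id_c", "date")]
  ic <- ids$INDIV_CONTEXT
  spouse <- ic[ic$relation %in% c("Husband", "Wife"), ]
  spouse$marriage_date <- unions$date[match(spouse$id_c, unions$id_c)]

  ## 1. event ordering per person
  b <- pd$birth_date[match(spouse$id_i, pd$id_i)]
  d <- pd$death_date[match(spouse$id_i, pd$id_i)]
  bad_bm <- !is.na(b) & !is.na(spouse$marriage_date) &
    spouse$marriage_date < b
  bad_md <- !is.na(d) & !is.na(spouse$marriage_date) &
    d < spouse$marriage_date
  bad_bd <- !is.na(pd$birth_date) & !is.na(pd$death_date) &
    pd$death_date < pd$birth_date
  issue_df <- function(ids_, label)
    data.frame(id_i = ids_, issue = rep(label, length(ids_)),
               stringsAsFactors = FALSE)
  ordering <- rbind(
    issue_df(spouse$id_i[bad_bm], "marriage before birth"),
    issue_df(spouse$id_i[bad_md], "death before marriage"),
    issue_df(pd$id_i[bad_bd], "death before birth"))
  ordering <- unique(ordering)

  ## 2./3. parent ages at children's births
  ii <- ids$INDIV_INDIV
  mo <- ii[ii$relation == "mother of", ]
  fa <- ii[ii$relation == "father of", ]
  age_at <- function(parent, child) {
    pb <- pd$birth_date[match(parent, pd$id_i)]
    cb <- pd$birth_date[match(child, pd$id_i)]
    as.numeric(cb - pb) / 365.25
  }
  mo$age <- age_at(mo$id_i_1, mo$id_i_2)
  fa$age <- age_at(fa$id_i_1, fa$id_i_2)
  mother_age <- mo[!is.na(mo$age) & (mo$age < 15 | mo$age > 50),
                   c("id_i_1", "id_i_2", "age")]
  father_age <- fa[!is.na(fa$age) & (fa$age < 18 | fa$age > 60),
                   c("id_i_1", "id_i_2", "age")]
  names(mother_age) <- names(father_age) <- c("parent", "child", "age")

  ## 4. short intervals between a mother's successive baptisms
  bap <- ids$INDIVIDUAL[ids$INDIVIDUAL$type == "BAPTISM_DATE" &
                          !is.na(ids$INDIVIDUAL$date), c("id_i", "date")]
  mo_ch <- ii[ii$relation == "mother of", c("id_i_1", "id_i_2")]
  mo_ch$bap <- bap$date[match(mo_ch$id_i_2, bap$id_i)]
  mo_ch <- mo_ch[!is.na(mo_ch$bap), ]
  short <- list()
  if (nrow(mo_ch)) {
    sp <- split(mo_ch$bap, mo_ch$id_i_1)
    for (m in names(sp)) {
      dts <- sort(sp[[m]])
      if (length(dts) < 2L) next
      gap <- as.numeric(diff(dts))
      hit <- which(gap > 0 & gap < 250)
      if (length(hit))
        short[[m]] <- data.frame(mother = m, interval_days = gap[hit],
                                 stringsAsFactors = FALSE)
    }
  }
  short <- if (length(short)) do.call(rbind, short)
           else data.frame(mother = character(), interval_days = numeric())
  rownames(short) <- NULL

  structure(list(
    ordering_issues = ordering,
    mother_age_issues = mother_age,
    father_age_issues = father_age,
    short_baptism_intervals = short,
    counts = c(ordering = nrow(ordering),
               mother_age = nrow(mother_age),
               father_age = nrow(father_age),
               short_baptism_intervals = nrow(short))),
    class = "ids_check_report")
}

#' @export
print.ids_check_report <- function(x, ...) {
  cat("<ids_check_report>\n")
  print(x$counts)
  invisible(x)
}

#' Write IDS tables to CSV files
#'
#' @param ids an `ids_tables` object.
#' @param dir output directory.
#' @return Invisibly, the file paths written.
#' @export
write_ids <- function(ids, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(ids), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(ids[[nm]], p, row.names = FALSE, na = "")
    p
  }, "")
  invisible(paths)
}
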